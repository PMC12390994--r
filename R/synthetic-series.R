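#' Scenario configuration for synthetic experiments
#'
#' Bundles the knobs of a simulated multi-plot coverage experiment: the true
#' piecewise parameters, the imaging schedule (days after heading; field
#' practice is one visit every 3-7 days through the season), the coverage
#' observation noise, and the rendering colours used for synthetic imagery.
#'
#' @param true_params Piecewise parameters (named vector/list or one-row
#'   data frame with `K`, `g`, `d0`, `a`, `d1`); defaults to the first
#'   reference treatment.
#' @param sampling_days Strictly increasing non-negative day offsets.
#' @param noise_sd Additive Gaussian observation noise on coverage
#'   (fraction units), `>= 0`.
#' @param n_plots Number of replicate plots, `>= 1`.
#' @param seed Integer seed; all generator outputs are deterministic in it.
#' @param image_size Square synthetic image side in pixels.
#' @param panicle_color,background_color RGB triples in `[0, 1]`.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(true_params = reference_params()[1, ],
                            sampling_days = seq(0, 56, by = 4),
                            noise_sd = 0.01,
                            n_plots = 1L,
                            seed = 1L,
                            image_size = 1536L,
                            panicle_color = c(0.82, 0.72, 0.38),
                            background_color = c(0.20, 0.42, 0.18)) {
  p <- check_piecewise_params(true_params)
  if (length(sampling_days) == 0L) abort("`sampling_days` must be non-empty.")
  if (any(sampling_days < 0)) abort("`sampling_days` must be non-negative.")
  if (is.unsorted(sampling_days, strictly = TRUE)) {
    abort("`sampling_days` must be strictly increasing.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_plots < 1) abort("`n_plots` must be >= 1.")
  stopifnot(length(panicle_color) == 3L, length(background_color) == 3L)
  structure(
    list(true_params = p, sampling_days = as.numeric(sampling_days),
         noise_sd = noise_sd, n_plots = as.integer(n_plots),
         seed = as.integer(seed), image_size = as.integer(image_size),
         panicle_color = panicle_color, background_color = background_color),
    class = "scenario_config"
  )
}

#' Simulate per-plot coverage time series
#'
#' Coverage at each sampling day is the piecewise model value plus additive
#' Gaussian noise, truncated to `[0, 1]`:
#' `clamp(f(day; true_params) + N(0, noise_sd), 0, 1)`.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `plot_id`, `day`, `coverage`,
#'   `true_coverage` (the noiseless model value). Bit-identical for
#'   identical seed and config.
#' @examples
#' cfg <- scenario_config(noise_sd = 0)
#' simulate_coverage_series(cfg)
#' @export
simulate_coverage_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr_seed(config$seed, {
    f <- piecewise_coverage(config$sampling_days, config$true_params)
    purrr::map(seq_len(config$n_plots), function(i) {
      obs <- clamp01(f + rnorm(length(f), 0, config$noise_sd))
      tibble(plot_id = sprintf("plot_%03d", i),
             day = config$sampling_days, coverage = obs, true_coverage = f)
    }) |> list_rbind()
  })
}

# evaluate expr with a temporary RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample plausible piecewise parameter sets
#'
#' Draws each parameter independently and uniformly within the reference
#' envelope (see [param_envelope()]), rejecting draws with `d1 <= d0`.
#'
#' @param n Number of parameter sets.
#' @param envelope Tibble from [param_envelope()].
#' @param seed Integer seed.
#' @return Tibble with columns `plot_id`, `K`, `g`, `d0`, `a`, `d1`.
#' @export
sample_params <- function(n, envelope = param_envelope(), seed = 1L) {
  lo <- setNames(envelope$min, envelope$parameter)
  hi <- setNames(envelope$max, envelope$parameter)
  withr_seed(seed, {
    draws <- vector("list", n)
    i <- 0L
    while (i < n) {
      d <- vapply(envelope$parameter, function(p) runif(1, lo[[p]], hi[[p]]),
                  numeric(1))
      if (d[["d1"]] > d[["d0"]]) {
        i <- i + 1L
        draws[[i]] <- tibble(plot_id = sprintf("plot_%03d", i),
                             K = d[["K"]], g = d[["g"]], d0 = d[["d0"]],
                             a = d[["a"]], d1 = d[["d1"]])
      }
    }
    list_rbind(draws)
  })
}

#' Default yield-component loadings for the synthetic generator
#'
#' Each yield component is generated as
#' `location + scale * (loadings . z(params) + N(0, noise_sd))` where
#' `z()` standardises the five dynamic parameters across plots. The default
#' loadings encode the correlation structure seen in the motivating field
#' trials: maximum coverage `K` strongly positive with Yield and grain
#' number, the timing parameters `d0`/`d1` negative with yield and
#' especially with filled-grain ratio, and `K` mildly negative with
#' 1000-grain weight (the yield-component compensation effect).
#' `GNP` is derived exactly as `GN / PN`.
#'
#' @return A list with elements `loadings` (5 x 5 matrix, rows `K, g, d0,
#'   a, d1`, columns `Yield, GN, PN, TGW, FGR`), `noise_sd`, `location`
#'   and `scale` (named per component).
#' @export
yield_coeffs <- function() {
  comp <- c("Yield", "GN", "PN", "TGW", "FGR")
  L <- matrix(
    c( # Yield   GN     PN     TGW    FGR
       0.90,   0.85,  0.70, -0.45,  0.00,   # K
       0.05,   0.05,  0.10,  0.00,  0.00,   # g
      -0.35,  -0.30,  0.00,  0.20, -0.75,   # d0
       0.00,   0.00,  0.00,  0.00,  0.00,   # a
      -0.30,  -0.30, -0.20,  0.20, -0.70),  # d1
    nrow = 5, byrow = TRUE,
    dimnames = list(c("K", "g", "d0", "a", "d1"), comp)
  )
  list(
    loadings = L,
    noise_sd = c(Yield = 0.20, GN = 0.25, PN = 0.45, TGW = 0.75, FGR = 0.30),
    location = c(Yield = 6500, GN = 30000, PN = 380, TGW = 21.5, FGR = 0.85),
    scale    = c(Yield = 900,  GN = 6000,  PN = 60,  TGW = 1.6,  FGR = 0.05)
  )
}

#' Simulate a plot-level yield-component table
#'
#' @param params Parameter table with one row per plot (`plot_id`, `K`,
#'   `g`, `d0`, `a`, `d1`), e.g. from [sample_params()] or
#'   [fit_coverage_table()].
#' @param coeffs Generator settings, see [yield_coeffs()].
#' @param seed Integer seed.
#' @return Tibble with columns `plot_id`, `Yield` (kg/ha), `GN`
#'   (grains/m^2), `PN` (panicles/m^2), `GNP` (= `GN / PN` exactly),
#'   `TGW` (g), `FGR` (fraction, clamped to `[0, 1]`). All components are
#'   floored at 0.
#' @examples
#' simulate_yield_table(sample_params(10))
#' @export
simulate_yield_table <- function(params, coeffs = yield_coeffs(), seed = 1L) {
  nm <- c("K", "g", "d0", "a", "d1")
  if (!all(nm %in% names(params))) abort("`params` must contain K, g, d0, a, d1.")
  n <- nrow(params)
  if (n < 1L) abort("`params` is empty.")
  Z <- vapply(nm, function(p) {
    x <- params[[p]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, n) else (x - mean(x)) / s
  }, numeric(n))
  if (n == 1L) Z <- matrix(Z, nrow = 1, dimnames = list(NULL, nm))
  comp <- colnames(coeffs$loadings)
  withr_seed(seed, {
    out <- tibble(plot_id = if ("plot_id" %in% names(params)) {
      params$plot_id
    } else sprintf("plot_%03d", seq_len(n)))
    for (cn in comp) {
      signal <- as.numeric(Z %*% coeffs$loadings[, cn])
      val <- coeffs$location[[cn]] +
        coeffs$scale[[cn]] * (signal + rnorm(n, 0, coeffs$noise_sd[[cn]]))
      out[[cn]] <- pmax(val, 0)
    }
    out$FGR <- pmin(out$FGR, 1)
    out$GNP <- out$GN / out$PN
    dplyr::select(out, "plot_id", "Yield", "GN", "PN", "GNP", "TGW", "FGR")
  })
}

#' Simulate joined plot records (parameters + yield components)
#'
#' Convenience wrapper producing the table the yield-prediction stage
#' consumes: [sample_params()] joined with [simulate_yield_table()].
#'
#' @param n_plots Number of plots.
#' @param coeffs See [yield_coeffs()].
#' @param seed Integer seed (parameters and yields use derived sub-seeds).
#' @return Tibble with `plot_id`, the five parameters and the six yield
#'   components.
#' @export
simulate_plot_records <- function(n_plots = 200L, coeffs = yield_coeffs(),
                                  seed = 1L) {
  params <- sample_params(n_plots, seed = seed)
  yields <- simulate_yield_table(params, coeffs = coeffs, seed = seed + 1L)
  dplyr::left_join(params, yields, by = "plot_id")
}

#' Write a coverage series table as CSV
#'
#' Columns `plot_id`, `day`, `coverage`.
#'
#' @param series Coverage series tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series[, c("plot_id", "day", "coverage")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a coverage series CSV written by [write_series_csv()]
#' @param path CSV file with columns `plot_id`, `day`, `coverage`.
#' @return Tibble sorted by plot and day.
#' @export
read_series_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)) |>
    dplyr::arrange(.data$plot_id, .data$day)
}
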