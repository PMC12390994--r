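#' Piecewise sigmoid-growth / quadratic-decline coverage model
#'
#' Panicle coverage after heading first rises along a logistic curve and
#' then declines roughly quadratically as grains fill and panicles droop.
#' The model is
#' \deqn{f(x) = K / (1 + e^{-g (x - d_0)}) \quad (x \le d_1)}
#' \deqn{f(x) = K / (1 + e^{-g (d_1 - d_0)}) - a (x - d_1)^2 \quad (x > d_1)}
#' with `K` the maximum coverage (fraction), `g` the growth rate (1/day),
#' `d0` the day of maximum growth rate (inflection), `d1` the
#' growth-to-decline transition day and `a` the decline curvature
#' (1/day^2). The two branches join continuously at `d1`, and
#' `f(d0) = K/2` whenever `d0 <= d1`.
#'
#' The raw model value is returned without clamping; far past `d1` it can
#' go negative.
#'
#' @param day Numeric vector of days (0 = first post-heading observation).
#' @param params Parameters: a named vector, named list or one-row data
#'   frame with elements `K`, `g`, `d0`, `a`, `d1`.
#' @return Numeric vector of model coverage values, same length as `day`.
#' @examples
#' p <- reference_params()[1, ]
#' piecewise_coverage(p$d0, p) # == K / 2
#' @export
piecewise_coverage <- function(day, params) {
  p <- check_piecewise_params(params)
  sig_end <- p[["K"]] / (1 + exp(-p[["g"]] * (p[["d1"]] - p[["d0"]])))
  ifelse(
    day <= p[["d1"]],
    p[["K"]] / (1 + exp(-p[["g"]] * (day - p[["d0"]]))),
    sig_end - p[["a"]] * (day - p[["d1"]])^2
  )
}

#' Validate piecewise-model parameters
#'
#' Enforces `K > 0`, `g > 0`, `a >= 0`, `d1 > d0` and returns the
#' parameters as a named numeric vector in canonical `(K, g, d0, a, d1)`
#' order.
#'
#' @inheritParams piecewise_coverage
#' @return Named numeric vector `c(K, g, d0, a, d1)`.
#' @export
check_piecewise_params <- function(params) {
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) abort("`params` data frame must have exactly one row.")
    params <- as.list(params)
  }
  nm <- c("K", "g", "d0", "a", "d1")
  if (!all(nm %in% names(params))) {
    abort(sprintf("`params` must contain %s.", paste(nm, collapse = ", ")))
  }
  p <- vapply(nm, function(n) as.numeric(params[[n]]), numeric(1))
  if (any(!is.finite(p))) abort("piecewise parameters must be finite.")
  if (p[["K"]] <= 0) abort("`K` must be > 0.")
  if (p[["g"]] <= 0) abort("`g` must be > 0.")
  if (p[["a"]] < 0) abort("`a` must be >= 0.")
  if (p[["d1"]] <= p[["d0"]]) abort("`d1` must be > `d0`.")
  p
}

#' Data-driven initial parameter guesses
#'
#' Heuristics estimated from the observed series shape: `K0` is the maximum
#' observed coverage; `d1_0` the day of the maximum; `d0_0` the first
#' half-maximum crossing (linear interpolation); `g0 = 4 * max finite
#' difference slope / K0` (the logistic maximum-slope identity
#' `f'(d0) = gK/4`); `a0` the least-squares quadratic coefficient of
#' (peak - coverage) against (day - d1_0)^2 over post-peak observations,
#' floored at 0.
#'
#' @param data Data frame with columns `day` and `coverage`.
#' @return Named numeric vector `c(K, g, d0, a, d1)`.
#' @seealso [piecewise_fit()]
#' @export
piecewise_guess <- function(data) {
  day <- data$day
  cov <- data$coverage
  if (length(day) < 5L) abort("need at least 5 observations to guess 5 parameters.")
  if (is.unsorted(day, strictly = TRUE)) abort("`day` must be strictly increasing.")
  if (max(cov) <= min(cov)) abort("constant series: no growth phase to estimate from.")
  if (all(diff(cov) <= 0)) abort("monotone-decreasing series: no growth phase to estimate from.")

  K0 <- max(cov)
  i_peak <- which.max(cov)
  d1_0 <- day[i_peak]
  half <- K0 / 2
  j <- which(cov >= half)[1]
  d0_0 <- if (j == 1L) day[1] else {
    approx(cov[(j - 1L):j], day[(j - 1L):j], xout = half, ties = "ordered")$y
  }
  slopes <- diff(cov) / diff(day)
  g0 <- min(max(4 * max(slopes) / K0, 1e-3), 5)
  post <- which(day > d1_0)
  a0 <- 0
  if (length(post) >= 2L) {
    drop <- cov[i_peak] - cov[post]
    x2 <- (day[post] - d1_0)^2
    a0 <- max(0, sum(drop * x2) / sum(x2 * x2))
  }
  c(K = K0, g = g0, d0 = d0_0, a = a0, d1 = max(d1_0, d0_0 + 1))
}

#' Fit the piecewise coverage model by bounded nonlinear least squares
#'
#' Minimises the residual sum of squares with trust-region
#' Levenberg-Marquardt (via [minpack.lm::nls.lm()]) under box bounds.
#' The ordering constraint `d1 > d0` is enforced structurally by fitting
#' `delta = d1 - d0 > 0` instead of `d1`. Default bounds: `K` in (0, 1],
#' `g` in (0, 5], `d0` in [0, max(day)], `delta` in (0, max(day) + 10],
#' `a` in [0, 0.05].
#'
#' Goodness of fit is the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` against the series mean; it is not clipped
#' and can be negative for fits worse than the mean. Non-convergence never
#' raises: the best parameters found are returned with `converged = FALSE`.
#'
#' @param data Data frame with columns `day` (strictly increasing) and
#'   `coverage` (fractions in `[0, 1]`); at least 5 observations.
#' @param guess Optional named starting values `(K, g, d0, a, d1)`;
#'   defaults to [piecewise_guess()].
#' @param lower,upper Optional named bound overrides on
#'   `(K, g, d0, delta, a)`.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `piecewise_fit`: a list with `params` (named
#'   vector `K, g, d0, a, d1`), `r_squared`, `residuals`, `fitted`,
#'   `converged`, `n_obs`, `bounds_hit` (names of parameters at a bound),
#'   `rss_trace` (objective per iteration), `info`/`message` (solver
#'   diagnostics) and `data`.
#' @examples
#' truth <- reference_params()[1, ]
#' obs <- tibble::tibble(day = 0:60, coverage = piecewise_coverage(0:60, truth))
#' fit <- piecewise_fit(obs)
#' tidy(fit)
#' glance(fit)
#' @export
piecewise_fit <- function(data, guess = NULL, lower = NULL, upper = NULL,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-15, ptol = 1e-15
                          )) {
  day <- as.numeric(data$day)
  cov <- as.numeric(data$coverage)
  if (length(day) < 5L) abort("need at least 5 observations to fit 5 parameters.")
  if (is.unsorted(day, strictly = TRUE)) abort("`day` must be strictly increasing.")
  # raw model values are unbounded below far past d1, so values outside
  # [0, 1] are tolerated here; only non-finite observations are rejected
  if (any(!is.finite(cov))) abort("`coverage` must be finite.")

  if (is.null(guess)) guess <- piecewise_guess(data)
  g0 <- check_piecewise_params(guess)
  start <- c(K = g0[["K"]], g = g0[["g"]], d0 = g0[["d0"]],
             delta = g0[["d1"]] - g0[["d0"]], a = g0[["a"]])

  max_day <- max(day)
  lo <- c(K = 1e-6, g = 1e-6, d0 = 0, delta = 1e-6, a = 0)
  hi <- c(K = 1, g = 5, d0 = max_day, delta = max_day + 10, a = 0.05)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  start <- pmin(pmax(start, lo), hi)

  resid_fn <- function(p) {
    cov - piecewise_coverage(day, c(K = p[["K"]], g = p[["g"]], d0 = p[["d0"]],
                                    a = p[["a"]], d1 = p[["d0"]] + p[["delta"]]))
  }

  out <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lo, upper = hi, fn = resid_fn,
                       control = control),
    error = function(e) NULL
  )

  if (is.null(out)) {
    params <- g0
    fitted <- piecewise_coverage(day, params)
    res <- cov - fitted
    converged <- FALSE
    bounds_hit <- character(0)
    rss_trace <- sum(res^2)
    info <- NA_integer_
    msg <- "solver error; returning initial guess"
  } else {
    p <- out$par
    params <- c(K = p[["K"]], g = p[["g"]], d0 = p[["d0"]], a = p[["a"]],
                d1 = p[["d0"]] + p[["delta"]])
    fitted <- piecewise_coverage(day, params)
    res <- cov - fitted
    converged <- out$info %in% 1:4
    tol <- 1e-8
    at_bound <- names(p)[abs(unlist(p) - lo) < tol | abs(unlist(p) - hi) < tol]
    bounds_hit <- sub("^delta$", "d1", at_bound)
    rss_trace <- out$rsstrace
    info <- out$info
    msg <- out$message
  }

  ss_tot <- sum((cov - mean(cov))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_

  structure(
    list(params = params, r_squared = r2, residuals = res, fitted = fitted,
         converged = converged, n_obs = length(day), bounds_hit = bounds_hit,
         rss_trace = rss_trace, info = info, message = msg,
         data = tibble(day = day, coverage = cov)),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Piecewise coverage model fit\n")
  cat(sprintf("  n = %d, R^2 = %.4f, converged: %s\n",
              x$n_obs, x$r_squared, x$converged))
  print(round(x$params, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.piecewise_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method generics::glance
glance.piecewise_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, rss = sum(x$residuals^2),
         n_obs = x$n_obs, converged = x$converged,
         n_bounds_hit = length(x$bounds_hit))
}

#' @exportS3Method generics::augment
augment.piecewise_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' @exportS3Method ggplot2::autoplot
autoplot.piecewise_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(
    day = seq(min(object$data$day), max(object$data$day), length.out = n_grid)
  )
  grid$coverage <- piecewise_coverage(grid$day, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$day, .data$coverage)) +
    ggplot2::geom_line(data = grid, colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$params[["d1"]], linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "days after heading", y = "panicle coverage (fraction)",
                  title = sprintf("K = %.3f, g = %.3f, d0 = %.1f, d1 = %.1f",
                                  object$params[["K"]], object$params[["g"]],
                                  object$params[["d0"]], object$params[["d1"]]))
}

#' Fit the piecewise model to every plot in a coverage table
#'
#' @param series Data frame with columns `plot_id`, `day`, `coverage`.
#' @param ... Passed to [piecewise_fit()].
#' @return A tibble with one row per plot: `plot_id`, the five parameters
#'   in canonical order (`K`, `g`, `d0`, `a`, `d1`), `r_squared`,
#'   `converged` and `n_obs`. Per-plot failures are recorded as
#'   `converged = FALSE` rows with `NA` parameters; the run continues.
#' @export
fit_coverage_table <- function(series, ...) {
  if (nrow(series) == 0L) abort("`series` is empty.")
  series |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::group_map(function(df, key) {
      row <- tryCatch({
        fit <- piecewise_fit(df, ...)
        tibble(plot_id = key$plot_id, K = fit$params[["K"]],
               g = fit$params[["g"]], d0 = fit$params[["d0"]],
               a = fit$params[["a"]], d1 = fit$params[["d1"]],
               r_squared = fit$r_squared, converged = fit$converged,
               n_obs = fit$n_obs)
      }, error = function(e) {
        tibble(plot_id = key$plot_id, K = NA_real_, g = NA_real_,
               d0 = NA_real_, a = NA_real_, d1 = NA_real_,
               r_squared = NA_real_, converged = FALSE, n_obs = nrow(df))
      })
      row
    }) |>
    list_rbind()
}
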