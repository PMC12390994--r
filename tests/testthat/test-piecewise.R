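ref <- reference_params()

test_that("model value at the inflection day is half the plateau", {
  for (i in seq_len(nrow(ref))) {
    p <- ref[i, ]
    expect_equal(piecewise_coverage(p$d0, p), p$K / 2, tolerance = 1e-12)
  }
  # frozen spot value for the first reference treatment
  expect_equal(piecewise_coverage(9.9412, ref[1, ]), 0.1256, tolerance = 1e-10)
})

test_that("the two branches join continuously at the transition day", {
  eps <- 1e-7
  for (i in seq_len(nrow(ref))) {
    p <- ref[i, ]
    left <- piecewise_coverage(p$d1 - eps, p)
    right <- piecewise_coverage(p$d1 + eps, p)
    expect_lt(abs(left - right), 1e-6)
  }
})

test_that("growth branch rises, decline branch falls, lower asymptote is 0", {
  p <- ref[1, ]
  pre <- piecewise_coverage(seq(-10, p$d1, length.out = 200), p)
  expect_true(all(diff(pre) > 0))
  post <- piecewise_coverage(seq(p$d1, p$d1 + 30, length.out = 100), p)
  expect_true(all(diff(post) < 0)) # a > 0 for this row
  expect_equal(piecewise_coverage(-1e4, p), 0, tolerance = 1e-12)
})

test_that("parameter validation rejects degenerate values", {
  expect_error(check_piecewise_params(c(K = 0, g = 1, d0 = 1, a = 0, d1 = 2)), "K")
  expect_error(check_piecewise_params(c(K = 1, g = -1, d0 = 1, a = 0, d1 = 2)), "g")
  expect_error(check_piecewise_params(c(K = 1, g = 1, d0 = 1, a = -1, d1 = 2)), "a")
  expect_error(check_piecewise_params(c(K = 1, g = 1, d0 = 5, a = 0, d1 = 2)), "d1")
})

test_that("initial guesses land within 50% of truth on dense noiseless grids", {
  for (i in seq_len(nrow(ref))) {
    p <- ref[i, ]
    day <- seq(0, 60, by = 0.5)
    obs <- tibble::tibble(day = day, coverage = piecewise_coverage(day, p))
    g <- piecewise_guess(obs)
    for (nm in c("K", "g", "d0", "d1")) {
      expect_lt(abs(g[[nm]] - p[[nm]]) / p[[nm]], 0.5,
                label = sprintf("row %d, %s rel err", i, nm))
    }
    if (p$a > 0) expect_lt(abs(g[["a"]] - p$a) / p$a, 0.5)
  }
})

test_that("guess fails cleanly without a growth phase", {
  expect_error(piecewise_guess(tibble::tibble(day = 1:6, coverage = rep(0.2, 6))),
               "constant")
  expect_error(piecewise_guess(tibble::tibble(day = 1:6,
                                              coverage = seq(0.5, 0.1, length.out = 6))),
               "decreasing")
  expect_error(piecewise_guess(tibble::tibble(day = 1:4, coverage = c(1, 2, 3, 4) / 10)),
               "5 observations")
})

test_that("a series peaking on its last day yields a zero decline guess", {
  p <- ref[1, ]
  day <- seq(0, floor(p$d1))
  obs <- tibble::tibble(day = day, coverage = piecewise_coverage(day, p))
  expect_equal(piecewise_guess(obs)[["a"]], 0)
})

test_that("noiseless fits recover the generating parameters", {
  # spot rows spanning the envelope; the full sweep lives in the acceptance suite
  for (i in c(1, 12, 16)) {
    p <- ref[i, ]
    obs <- tibble::tibble(day = 0:60, coverage = piecewise_coverage(0:60, p))
    fit <- piecewise_fit(obs)
    expect_true(fit$converged)
    expect_gte(fit$r_squared, 0.9999)
    truth <- c(K = p$K, g = p$g, d0 = p$d0, a = p$a, d1 = p$d1)
    for (nm in names(truth)) {
      err <- if (truth[[nm]] == 0) abs(fit$params[[nm]]) else
        abs(fit$params[[nm]] - truth[[nm]]) / abs(truth[[nm]])
      expect_lt(err, 1e-3, label = sprintf("row %d, %s", i, nm))
    }
  }
})

test_that("the fitted ordering constraint d1 > d0 always holds", {
  set.seed(42)
  for (rep in 1:5) {
    p <- sample_params(1, seed = rep)
    day <- seq(0, 56, by = 4)
    obs <- tibble::tibble(
      day = day,
      coverage = pmin(pmax(piecewise_coverage(day, p) + rnorm(length(day), 0, 0.02), 0), 1)
    )
    fit <- piecewise_fit(obs)
    expect_gt(fit$params[["d1"]], fit$params[["d0"]])
  }
})

test_that("solver objective is non-increasing across iterations", {
  set.seed(7)
  p <- ref[3, ]
  day <- seq(0, 56, by = 4)
  obs <- tibble::tibble(
    day = day,
    coverage = pmin(pmax(piecewise_coverage(day, p) + rnorm(length(day), 0, 0.01), 0), 1)
  )
  fit <- piecewise_fit(obs)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
})

test_that("tidy, glance and augment expose the fit in tabular form", {
  p <- ref[2, ]
  obs <- tibble::tibble(day = 0:60, coverage = piecewise_coverage(0:60, p))
  fit <- piecewise_fit(obs)
  td <- tidy(fit)
  expect_equal(td$term, c("K", "g", "d0", "a", "d1"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 61L)
  expect_true(gl$converged)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$coverage, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit_coverage_table records per-plot failures and continues", {
  p <- ref[1, ]
  day <- seq(0, 56, by = 4)
  good <- tibble::tibble(plot_id = "ok", day = day,
                         coverage = piecewise_coverage(day, p))
  bad <- tibble::tibble(plot_id = "flat", day = day, coverage = rep(0.2, length(day)))
  tab <- fit_coverage_table(dplyr::bind_rows(good, bad))
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab)[2:7], c("K", "g", "d0", "a", "d1", "r_squared"))
  ok_row <- tab[tab$plot_id == "ok", ]
  expect_true(ok_row$converged)
  expect_equal(ok_row$K, p$K, tolerance = 1e-6)
  flat_row <- tab[tab$plot_id == "flat", ]
  expect_false(flat_row$converged)
  expect_true(is.na(flat_row$K))
  expect_error(fit_coverage_table(good[0, ]), "empty")
})
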