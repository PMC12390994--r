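test_that("rmse follows the mean-square convention with a legacy alternative", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  a <- c(0, 0, 0); p <- c(3, 4, 0)
  expect_equal(rmse(a, p), sqrt(25 / 3))
  expect_equal(rmse(a, p, literal_half = TRUE), sqrt(25 / 2))
  # absolute homogeneity
  expect_equal(rmse(3 * a, 3 * p), 3 * rmse(a, p))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("r_squared matches hand computation and is not clipped", {
  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(r_squared(c(1, 2, 3, 4), rep(2.5, 4)), 0)
  # 4-point hand example: SSres = 0.07, SStot = 5
  expect_equal(r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9)), 1 - 0.07 / 5)
  expect_lt(r_squared(c(1, 2, 3, 4), c(4, 3, 2, 1)), 0)
  expect_error(r_squared(rep(1, 4), 1:4), "zero variance")
})

test_that("pooled LOOCV metrics are mutually consistent", {
  set.seed(2)
  actual <- rnorm(30)
  predicted <- actual + rnorm(30, 0, 0.5)
  r2 <- r_squared(actual, predicted)
  rm <- rmse(actual, predicted)
  ss_tot <- sum((actual - mean(actual))^2)
  expect_equal(r2, 1 - length(actual) * rm^2 / ss_tot, tolerance = 1e-12)
})

test_that("the correlation screen scores every feature-target pair", {
  rec <- simulate_plot_records(100, seed = 4)
  cs <- correlation_screen(rec)
  expect_equal(nrow(cs), 30L)
  expect_s3_class(cs, "corr_screen")
  # a feature screened against itself correlates perfectly
  rec$selfK <- rec$K
  self <- correlation_screen(rec, features = "K", targets = "selfK")
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$stars, "***")
  expect_s3_class(autoplot(cs), "ggplot")
})

test_that("zero-variance columns are flagged rather than scored", {
  rec <- simulate_plot_records(30, seed = 5)
  rec$flat <- 5
  expect_warning(cs <- correlation_screen(rec, features = "K", targets = "flat"),
                 "zero-variance")
  expect_true(is.na(cs$r))
  expect_equal(cs$stars, "undef")
})

test_that("independent noise columns rarely show |r| above 0.2 at n = 200", {
  set.seed(6)
  d <- as.data.frame(matrix(rnorm(200 * 8), 200, 8))
  names(d) <- c("K", "g", "d0", "a", "d1", "t1", "t2", "t3")
  cs <- correlation_screen(d, targets = c("t1", "t2", "t3"))
  expect_gte(mean(abs(cs$r) < 0.2), 0.9)
})

test_that("LOOCV predicts each record exactly once from the other n-1", {
  rec <- simulate_plot_records(25, seed = 7)
  res <- loocv(rec, "Yield", "plsr")
  expect_equal(res$predictions$row, 1:25)
  expect_equal(res$n, 25L)
  expect_equal(res$predictions$actual, rec$Yield)
  expect_equal(glance(res)$r_squared, res$r_squared)
  expect_equal(nrow(tidy(res)), 25L)
  expect_s3_class(autoplot(res), "ggplot")
  expect_error(loocv(rec[1:2, ], "Yield", "plsr"), "at least 3")
  expect_error(loocv(rec, "Yield", "nonsense"), "arg")
})

test_that("an exact linear signal is recovered by the latent-component model", {
  rec <- simulate_plot_records(40, seed = 8)
  rec$lin <- 100 + 50 * rec$K
  res <- loocv(rec, "lin", "plsr")
  expect_gt(res$r_squared, 0.99)
})

test_that("no model family explains pure noise under LOOCV", {
  rec <- simulate_plot_records(100, seed = 9)
  set.seed(10)
  rec$noise <- rnorm(100)
  for (m in c("plsr", "rfr", "gbr", "xgbr")) {
    res <- loocv(rec, "noise", m, seed = 11)
    expect_lte(res$r_squared, 0.1, label = sprintf("model %s", m))
  }
})

test_that("tree-ensemble LOOCV is reproducible under a fixed seed", {
  rec <- simulate_plot_records(20, seed = 12)
  r1 <- loocv(rec, "Yield", "rfr", seed = 3)
  r2 <- loocv(rec, "Yield", "rfr", seed = 3)
  expect_identical(r1$predictions$predicted, r2$predictions$predicted)
})

test_that("the report table lays out targets x metrics against models", {
  fake <- function(model, target, r2, rm) {
    structure(list(model = model, target = target, r_squared = r2, rmse = rm,
                   n = 10L, predictions = tibble::tibble()),
              class = "loocv_result")
  }
  grid <- expand.grid(model = c("plsr", "xgbr", "rfr", "gbr"),
                      target = c("Yield", "GN", "PN", "GNP", "TGW", "FGR"),
                      stringsAsFactors = FALSE)
  results <- Map(fake, grid$model, grid$target,
                 seq_len(nrow(grid)) / 30, seq_len(nrow(grid)))
  tab <- report_table(results)
  expect_equal(dim(tab), c(12L, 6L)) # 6 targets x 2 metrics, 4 model columns
  expect_equal(sum(!is.na(as.matrix(tab[, 3:6]))), 48L)

  one <- report_table(results[1])
  expect_equal(nrow(one), 2L)
  expect_equal(one$plsr, c(results[[1]]$r_squared, results[[1]]$rmse))
})

test_that("least-squares boosting reduces training error monotonically in stages", {
  set.seed(13)
  d <- data.frame(x1 = runif(60), x2 = runif(60))
  y <- 3 * d$x1 + rnorm(60, 0, 0.1)
  small <- ls_boost(d, y, n_trees = 5)
  big <- ls_boost(d, y, n_trees = 100)
  expect_lt(rmse(y, predict(big, d)), rmse(y, predict(small, d)))
})
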