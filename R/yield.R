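yield_features <- function() c("K", "g", "d0", "a", "d1")
yield_targets <- function() c("Yield", "GN", "PN", "GNP", "TGW", "FGR")

#' Pearson correlation screen between dynamic parameters and yield components
#'
#' Computes the Pearson correlation and two-sided p-value for every
#' feature-target pair, with significance stars at 0.05 / 0.01 / 0.001
#' (`ns` otherwise). Zero-variance columns yield `NA` correlations and a
#' warning.
#'
#' @param data Data frame containing the feature and target columns.
#' @param features,targets Column names to screen; defaults to the five
#'   dynamic parameters against the six yield components.
#' @return A tibble of class `corr_screen` with columns `feature`,
#'   `target`, `r`, `p_value`, `stars`, `n`.
#' @examples
#' correlation_screen(simulate_plot_records(50))
#' @export
correlation_screen <- function(data, features = yield_features(),
                               targets = yield_targets()) {
  missing_cols <- setdiff(c(features, targets), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  flagged <- character(0)
  grid <- tidyr::expand_grid(feature = features, target = targets)
  res <- pmap(grid, function(feature, target) {
    x <- data[[feature]]; y <- data[[target]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) abort("need at least 3 complete records per pair.")
    if (sd(x) == 0 || sd(y) == 0) {
      flagged <<- c(flagged, sprintf("%s~%s", feature, target))
      return(tibble(feature = feature, target = target, r = NA_real_,
                    p_value = NA_real_, stars = "undef", n = length(x)))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(feature = feature, target = target, r = unname(ct$estimate),
           p_value = ct$p.value,
           stars = if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
             else if (ct$p.value < 0.05) "*" else "ns",
           n = length(x))
  }) |> list_rbind()
  if (length(flagged) > 0) {
    warn(sprintf("zero-variance pairs, correlation undefined: %s",
                 paste(flagged, collapse = ", ")))
  }
  structure(res, class = c("corr_screen", class(res)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.corr_screen <- function(object, ...) {
  object$feature <- factor(object$feature, levels = rev(yield_features()))
  ggplot2::ggplot(object, ggplot2::aes(.data$target, .data$feature,
                                       fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r,
                      ifelse(.data$stars == "ns", "", .data$stars))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' Root mean squared error
#'
#' `sqrt(mean((predicted - actual)^2))`. A legacy variant dividing the sum
#' of squares by 2 instead of `n` is available behind `literal_half =
#' TRUE` for compatibility with sources that typeset the formula that way;
#' the mean form is the default because RMSE is defined as the square root
#' of the *mean* squared difference.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @param literal_half Divide the sum of squares by 2 instead of `n`.
#' @return Non-negative scalar in target units.
#' @export
rmse <- function(actual, predicted, literal_half = FALSE) {
  if (length(actual) != length(predicted)) abort("length mismatch.")
  if (length(actual) == 0L) abort("empty input.")
  ss <- sum((predicted - actual)^2)
  if (literal_half) sqrt(ss / 2) else sqrt(ss / length(actual))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)`.
#' Not clipped: worse-than-mean predictions give negative values. Intended
#' for pooled cross-validation predictions.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) abort("length mismatch.")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) abort("`actual` has zero variance; R^2 undefined.")
  1 - sum((actual - predicted)^2) / ss_tot
}

# ---- model family registry -------------------------------------------------

yield_models <- function() c("plsr", "rfr", "gbr", "xgbr")

fit_yield_model <- function(model, x, y, seed = 1L) {
  x <- as.data.frame(x)
  switch(model,
    plsr = {
      fit <- mixOmics::pls(as.matrix(x), y, ncomp = 3, mode = "regression",
                           scale = TRUE)
      structure(list(fit = fit, features = names(x)), class = "plsr_yield")
    },
    rfr = withr_seed(seed, {
      # all features tried at every split and unit leaf size, the
      # conventional defaults for regression random forests in the
      # framework this configuration replicates
      randomForest::randomForest(x = x, y = y, ntree = 100L,
                                 mtry = ncol(x), nodesize = 1L)
    }),
    gbr = withr_seed(seed, {
      ls_boost(x, y, n_trees = 100L, learning_rate = 0.05)
    }),
    xgbr = {
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      xgboost::xgb.train(
        params = list(eta = 0.05, max_depth = 6, objective = "reg:squarederror",
                      nthread = 1, seed = seed),
        data = dm, nrounds = 100L, verbose = 0
      )
    },
    abort(sprintf("unknown model `%s`; use one of %s.", model,
                  paste(yield_models(), collapse = ", ")))
  )
}

predict_yield_model <- function(fit, x) {
  x <- as.data.frame(x)
  if (inherits(fit, "plsr_yield")) {
    pr <- predict(fit$fit, newdata = as.matrix(x[, fit$features, drop = FALSE]))
    as.numeric(pr$predict[, 1, 3])
  } else if (inherits(fit, "xgb.Booster")) {
    predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))
  } else {
    as.numeric(predict(fit, x))
  }
}

#' Leave-one-out cross-validated yield regression
#'
#' Fits one of four regression families to predict a yield component from
#' the five dynamic parameters, under leave-one-out cross-validation: fold
#' i trains on all records but i and predicts record i, so every record is
#' predicted exactly once. RMSE and R^2 are computed on the pooled
#' out-of-fold predictions (the only convention well-defined for
#' single-observation folds).
#'
#' Model families and fixed hyperparameters:
#' * `"plsr"` - partial least squares regression, 3 latent components,
#'   features standardised inside each training fold;
#' * `"rfr"` - random forest, 100 trees;
#' * `"gbr"` - least-squares gradient boosting ([ls_boost()]), 100
#'   stages, learning rate 0.05;
#' * `"xgbr"` - XGBoost, 100 rounds, learning rate 0.05.
#'
#' @param data Data frame of plot records (features + target columns).
#' @param target Name of the yield component to predict.
#' @param model One of `"plsr"`, `"rfr"`, `"gbr"`, `"xgbr"`.
#' @param features Predictor column names.
#' @param seed Integer seed fixing tree-ensemble randomness (each fold
#'   uses a seed derived from it).
#' @return An object of class `loocv_result`: list with `predictions`
#'   (tibble `row`, `actual`, `predicted`), `model`, `target`,
#'   `r_squared`, `rmse`, `n`.
#' @examples
#' rec <- simulate_plot_records(30)
#' loocv(rec, "Yield", "rfr")
#' @export
loocv <- function(data, target, model = c("plsr", "rfr", "gbr", "xgbr"),
                  features = yield_features(), seed = 1L) {
  model <- match.arg(model)
  missing_cols <- setdiff(c(features, target), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 3L) abort("need at least 3 records for leave-one-out CV.")
  x <- as.data.frame(data[, features, drop = FALSE])
  y <- data[[target]]
  if (any(!is.finite(as.matrix(x)))) abort("features must be finite.")
  preds <- vapply(seq_len(n), function(i) {
    fit <- fit_yield_model(model, x[-i, , drop = FALSE], y[-i],
                           seed = seed + i)
    predict_yield_model(fit, x[i, , drop = FALSE])
  }, numeric(1))
  structure(
    list(predictions = tibble(row = seq_len(n), actual = y, predicted = preds),
         model = model, target = target,
         r_squared = r_squared(y, preds), rmse = rmse(y, preds), n = n),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV %s ~ dynamic parameters [%s]: R^2 = %.3f, RMSE = %.4g (n = %d)\n",
              x$target, x$model, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loocv_result <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.loocv_result <- function(x, ...) {
  tibble(model = x$model, target = x$target, r_squared = x$r_squared,
         rmse = x$rmse, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.loocv_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$actual, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2c7fb8", linewidth = 0.6) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = sprintf("%s, %s: R² = %.2f, RMSE = %.3g",
                                  object$target, object$model,
                                  object$r_squared, object$rmse),
                  x = "observed", y = "LOOCV prediction")
}

#' Run LOOCV across targets and model families
#'
#' @param data Plot-record data frame.
#' @param targets,models Vectors of target / model names.
#' @inheritParams loocv
#' @return List of `loocv_result` objects.
#' @export
loocv_table <- function(data, targets = yield_targets(),
                        models = yield_models(),
                        features = yield_features(), seed = 1L) {
  grid <- tidyr::expand_grid(target = targets, model = models)
  pmap(grid, function(target, model) {
    loocv(data, target, model, features = features, seed = seed)
  })
}

#' Wide performance table from LOOCV results
#'
#' One row per target x metric (R^2 and RMSE), one column per model
#' family.
#'
#' @param results List of `loocv_result` objects (e.g. from
#'   [loocv_table()]).
#' @return Wide tibble with columns `target`, `metric`, then one column
#'   per model.
#' @export
report_table <- function(results) {
  if (length(results) == 0L) abort("no results supplied.")
  long <- map(results, function(r) {
    tibble(target = r$target, model = r$model,
           metric = c("r_squared", "rmse"), value = c(r$r_squared, r$rmse))
  }) |> list_rbind()
  long |>
    dplyr::mutate(
      target = factor(.data$target, levels = unique(.data$target)),
      metric = factor(.data$metric, levels = c("r_squared", "rmse"))
    ) |>
    dplyr::arrange(.data$metric, .data$target) |>
    tidyr::pivot_wider(names_from = "model", values_from = "value")
}
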