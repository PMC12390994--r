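#' Exact Shapley feature attribution for fitted tree ensembles
#'
#' Computes interventional Shapley values by exact enumeration of all
#' feature subsets (2^5 = 32 for the five dynamic parameters): the value
#' of a coalition S for record x is the model prediction averaged over
#' background rows with the features outside S replaced by the background
#' values, and each feature's attribution is its Shapley-weighted marginal
#' contribution. Exact enumeration makes the additivity (efficiency)
#' property hold to machine precision: `base_value + sum(contributions) =
#' prediction` for every record.
#'
#' Supported models are the tree ensembles used by [loocv()]:
#' `randomForest`, [ls_boost()] and `xgb.Booster`. The linear PLSR model
#' is rejected with a pointer to its coefficients, which already are its
#' additive attribution.
#'
#' @param model A fitted tree-ensemble model.
#' @param data Data frame of records to explain (feature columns).
#' @param features Feature column names.
#' @param background Background data frame the marginalisation averages
#'   over; defaults to `data`.
#' @return An object of class `shap_attribution`: list with
#'   `contributions` (tibble `row`, `feature`, `value` in target units),
#'   `base_value` (mean background prediction), `predictions`, and
#'   `ranking` (features by decreasing mean absolute contribution).
#' @examples
#' rec <- simulate_plot_records(40)
#' fit <- fit_tree_model(rec, "Yield", "rfr")
#' shap_attribution(fit, rec)$ranking
#' @export
shap_attribution <- function(model, data, features = yield_features(),
                             background = data) {
  if (inherits(model, "plsr_yield")) {
    abort(paste("Shapley attribution supports tree ensembles only;",
                "for the PLSR model use its (standardised) coefficients,",
                "which are already additive attributions."))
  }
  if (!inherits(model, c("randomForest", "ls_boost", "xgb.Booster"))) {
    abort("unsupported model class; expected randomForest, ls_boost or xgb.Booster.")
  }
  x <- as.data.frame(data[, features, drop = FALSE])
  bg <- as.data.frame(background[, features, drop = FALSE])
  n <- nrow(x); nb <- nrow(bg); p <- length(features)

  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  names(subsets) <- features
  n_sub <- nrow(subsets)

  # v[i, s]: mean prediction for record i with features outside subset s
  # drawn from the background
  v <- matrix(NA_real_, n, n_sub)
  for (s in seq_len(n_sub)) {
    keep <- unlist(subsets[s, ])
    if (!any(keep)) {
      v[, s] <- mean(predict_yield_model(model, bg))
      next
    }
    big <- bg[rep(seq_len(nb), times = n), , drop = FALSE]
    for (j in which(keep)) {
      big[[j]] <- rep(x[[features[j]]], each = nb)
    }
    pr <- predict_yield_model(model, big)
    v[, s] <- colMeans(matrix(pr, nrow = nb))
  }

  sub_size <- rowSums(subsets)
  sub_key <- apply(subsets, 1, function(r) paste(as.integer(r), collapse = ""))
  idx <- setNames(seq_len(n_sub), sub_key)

  phi <- matrix(0, n, p, dimnames = list(NULL, features))
  for (j in seq_len(p)) {
    without_j <- which(!subsets[[j]])
    for (s in without_j) {
      size <- sub_size[s]
      w <- factorial(size) * factorial(p - size - 1) / factorial(p)
      with_row <- as.integer(unlist(subsets[s, ]))
      with_row[j] <- 1L
      s_with <- idx[[paste(with_row, collapse = "")]]
      phi[, j] <- phi[, j] + w * (v[, s_with] - v[, s])
    }
  }

  base_value <- v[1, idx[[paste(rep(0L, p), collapse = "")]]]
  preds <- predict_yield_model(model, x)
  contrib <- as_tibble(phi) |>
    dplyr::mutate(row = seq_len(n)) |>
    tidyr::pivot_longer(-"row", names_to = "feature", values_to = "value")
  ranking <- contrib |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_abs = mean(abs(.data$value)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs))
  structure(
    list(contributions = contrib, base_value = base_value,
         predictions = preds, ranking = ranking),
    class = "shap_attribution"
  )
}

#' Fit one of the tree-ensemble yield models on the full data
#'
#' Convenience wrapper around the model families of [loocv()] for use with
#' [shap_attribution()] (which explains a model fitted once on all
#' records, as feature-importance summaries conventionally are).
#'
#' @inheritParams loocv
#' @return The fitted model object.
#' @export
fit_tree_model <- function(data, target, model = c("rfr", "gbr", "xgbr"),
                           features = yield_features(), seed = 1L) {
  model <- match.arg(model)
  fit_yield_model(model, data[, features, drop = FALSE], data[[target]],
                  seed = seed)
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution over %d records (base value %.4g)\n",
              max(x$contributions$row), x$base_value))
  print(x$ranking)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.shap_attribution <- function(x, ...) x$contributions

#' @exportS3Method ggplot2::autoplot
autoplot.shap_attribution <- function(object, ...) {
  object$ranking$feature <- factor(object$ranking$feature,
                                   levels = rev(object$ranking$feature))
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(.data$mean_abs, .data$feature)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "mean |contribution| (target units)", y = NULL)
}
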