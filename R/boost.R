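#' Least-squares gradient boosting over regression trees
#'
#' Classic forward-stagewise boosting for squared-error loss: start from
#' the mean, then repeatedly fit a shallow [rpart::rpart()] regression
#' tree to the current residuals and add `learning_rate` times its
#' prediction. Depth-limited trees (default depth 3) keep each stage a
#' weak learner.
#'
#' @param x Data frame or matrix of predictors.
#' @param y Numeric response.
#' @param n_trees Number of boosting stages.
#' @param learning_rate Shrinkage applied to every stage.
#' @param max_depth Maximum depth of each tree.
#' @param min_split Minimum observations to attempt a split.
#' @return An object of class `ls_boost` with a [predict()] method.
#' @examples
#' d <- data.frame(x1 = runif(50), x2 = runif(50))
#' fit <- ls_boost(d, d$x1 * 2, n_trees = 25)
#' predict(fit, d)[1:3]
#' @export
ls_boost <- function(x, y, n_trees = 100L, learning_rate = 0.05,
                     max_depth = 3L, min_split = 5L) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y), n_trees >= 1, learning_rate > 0)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", n_trees)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minsplit = min_split,
                               cp = 0, xval = 0, maxsurrogate = 0)
  df <- x
  for (m in seq_len(n_trees)) {
    df$.resid <- resid
    tr <- rpart::rpart(.resid ~ ., data = df, method = "anova", control = ctrl)
    trees[[m]] <- tr
    resid <- resid - learning_rate * predict(tr, x)
  }
  structure(list(init = f0, trees = trees, learning_rate = learning_rate,
                 feature_names = names(x)),
            class = "ls_boost")
}

#' @export
predict.ls_boost <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  pred <- rep(object$init, nrow(newdata))
  for (tr in object$trees) {
    pred <- pred + object$learning_rate * predict(tr, newdata)
  }
  unname(pred)
}

#' @export
print.ls_boost <- function(x, ...) {
  cat(sprintf("least-squares boosting: %d trees, learning rate %.3g\n",
              length(x$trees), x$learning_rate))
  invisible(x)
}
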