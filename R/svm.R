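#' Train an RBF support-vector classifier with grid-searched hyperparameters
#'
#' Features are z-scored with training statistics, then the box constraint
#' `C` and kernel scale `s` (kernel `K(x, z) = exp(-||x - z||^2 / s^2)`) are
#' searched over a 13 x 13 log grid spanning `10^-3 .. 10^3`, scored by
#' stratified 10-fold cross-validated misclassification (seeded folds, fixed
#' across the grid). Ties prefer the smaller `C`, then the larger kernel
#' scale. The winning pair is refit on all data with a deterministic SMO
#' solver.
#'
#' @param X Matrix or data frame of the selected features (n >= 20).
#' @param y Binary labels; `positive` names the disease class (default: the
#'   second factor level).
#' @param seed Integer seed for the CV folds.
#' @param positive Label treated as the positive (disease) class.
#' @param cost_grid,scale_grid Hyperparameter grids (defaults
#'   `10^seq(-3, 3, length.out = 13)`).
#' @param n_folds CV folds (default 10).
#' @return An `osteotex_svm`: support coefficients, intercept, standardized
#'   training data, standardization parameters, `C`, `kernel_scale`,
#'   `cv_error`, `feature_names`, class `levels`, `positive`, `seed`.
#' @export
train_svm <- function(X, y, seed = 1L, positive = NULL,
                      cost_grid = 10^seq(-3, 3, length.out = 13),
                      scale_grid = 10^seq(-3, 3, length.out = 13),
                      n_folds = 10L) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("label error: single-class input")
  if (nlevels(y) > 2L) stop("label error: expected binary labels")
  if (nrow(X) < 20L) stop("need at least 20 samples")
  if (is.null(positive)) positive <- levels(y)[2L]
  if (!positive %in% levels(y)) stop("`positive` is not a label level")
  ypm <- ifelse(as.character(y) == positive, 1, -1)

  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-300] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  d2 <- as.matrix(dist(Xs))^2
  folds <- stratified_folds(y, n_folds, seed)

  results <- expand.grid(C = cost_grid, s = scale_grid)
  results$err <- NA_real_
  for (si in seq_along(scale_grid)) {
    K <- exp(-d2 / scale_grid[si]^2)
    for (ci in seq_along(cost_grid)) {
      errs <- vapply(seq_len(n_folds), function(f) {
        tr <- which(folds != f)
        te <- which(folds == f)
        if (length(unique(ypm[tr])) < 2L) return(NA_real_)
        sol <- cpp_svm_smo(K[tr, tr, drop = FALSE], ypm[tr], cost_grid[ci])
        sc <- as.vector(K[te, tr, drop = FALSE] %*% (sol$alpha * ypm[tr])) + sol$b
        mean(sign(sc) != ypm[te])
      }, numeric(1))
      results$err[(si - 1L) * length(cost_grid) + ci] <- mean(errs, na.rm = TRUE)
    }
  }
  # ties: smaller C, then larger kernel scale
  ord <- order(results$err, results$C, -results$s)
  bestC <- results$C[ord[1L]]
  bests <- results$s[ord[1L]]
  Kbest <- exp(-d2 / bests^2)
  sol <- cpp_svm_smo(Kbest, ypm, bestC)

  structure(
    list(alpha = as.numeric(sol$alpha), b = sol$b, y = ypm, X = Xs,
         mu = mu, sd = sdv, C = bestC, kernel_scale = bests,
         cv_error = results$err[ord[1L]], cv_table = results,
         feature_names = colnames(X), levels = levels(y),
         positive = positive, seed = seed),
    class = "osteotex_svm"
  )
}

#' @export
print.osteotex_svm <- function(x, ...) {
  cat(sprintf(
    "<osteotex_svm> RBF: C = %.4g, kernel scale = %.4g, CV error = %.3f, %d SVs\n",
    x$C, x$kernel_scale, x$cv_error, sum(x$alpha > 1e-8)
  ))
  invisible(x)
}

#' Signed decision scores
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` on new rows; positive scores
#' predict the positive (disease) class. Column names, when present, must
#' match the training features.
#'
#' @param clf An `osteotex_svm`.
#' @param X New feature rows (same features and order as training).
#' @return Numeric vector of decision values.
#' @export
decision_scores <- function(clf, X) {
  stopifnot(inherits(clf, "osteotex_svm"))
  X <- as.matrix(as.data.frame(X))
  if (ncol(X) != length(clf$feature_names)) {
    stop("schema error: expected ", length(clf$feature_names), " features")
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), clf$feature_names)) {
    stop("schema error: feature names do not match the training schema")
  }
  Xs <- sweep(sweep(X, 2L, clf$mu), 2L, clf$sd, "/")
  cross <- outer(rowSums(Xs^2), rowSums(clf$X^2), "+") -
    2 * Xs %*% t(clf$X)
  K <- exp(-pmax(cross, 0) / clf$kernel_scale^2)
  as.vector(K %*% (clf$alpha * clf$y)) + clf$b
}

#' Predict class labels
#'
#' @param object An `osteotex_svm`.
#' @param newdata Feature rows.
#' @param type `"class"` for labels or `"score"` for decision values.
#' @param ... Unused.
#' @return Factor of predicted labels, or numeric scores.
#' @export
predict.osteotex_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- decision_scores(object, newdata)
  if (type == "score") return(sc)
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(sc > 0, object$positive, neg), levels = object$levels)
}

#' Serialize / restore a trained classifier as JSON
#'
#' Stores kernel parameters, dual coefficients, standardization statistics
#' and the standardized training rows, so that reloaded models reproduce
#' decision scores exactly.
#'
#' @param clf An `osteotex_svm`.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `osteotex_svm` (read).
#' @export
svm_write_json <- function(clf, path) {
  stopifnot(inherits(clf, "osteotex_svm"))
  obj <- unclass(clf)
  obj$X <- as.data.frame(obj$X)
  obj$cv_table <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svm_write_json
#' @export
svm_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$X <- as.matrix(obj$X)
  dimnames(obj$X) <- NULL
  obj$mu <- unlist(obj$mu)
  obj$sd <- unlist(obj$sd)
  structure(obj, class = "osteotex_svm")
}
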