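#' Validate a labeled feature table
#'
#' Checks the fixed 11-feature schema (see [texture_feature_names()]) plus a
#' binary `label` column, no missing values, and at least two samples per
#' class.
#'
#' @param df Data frame with the 11 feature columns and `label`.
#' @return The data frame, with `label` as a factor, invisibly classed as
#'   `feature_table`.
#' @export
feature_table <- function(df) {
  missing_cols <- setdiff(c(OSTEOTEX_FEATURES, "label"), names(df))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, c(OSTEOTEX_FEATURES, "label")]
  if (anyNA(df)) stop("feature table contains missing values")
  df$label <- droplevels(as.factor(df$label))
  if (nlevels(df$label) != 2L) stop("`label` must have exactly 2 classes")
  if (any(table(df$label) < 2L)) stop("need >= 2 samples per class")
  class(df) <- c("feature_table", "data.frame")
  df
}

# stratified k-fold assignment; returns an integer fold id per sample
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (lev in levels(as.factor(y))) {
    idx <- which(y == lev)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fit regularized neighborhood-component feature weights
#'
#' Maximises `F(w) = sum_i p_i - lambda * sum_j w_j^2` by gradient ascent
#' with backtracking line search from `w = 1`, where
#' `d_w(x_i, x_l) = sum_j w_j^2 |x_ij - x_lj|`,
#' `p_il = exp(-d_w(x_i, x_l)) / sum_{m != i} exp(-d_w(x_i, x_m))` (kernel
#' width 1) and `p_i` is the probability that a soft nearest neighbour of
#' `x_i` shares its label (the expected leave-one-out accuracy at sample i).
#' Iteration stops when the objective gain drops below `1e-6` or after 200
#' iterations; weights are kept nonnegative.
#'
#' @param X Numeric matrix, z-scored per feature by the caller.
#' @param y Binary labels.
#' @param lambda Regularization weight (`>= 0`).
#' @return An `nca_fit`: list with `weights` (named if `X` has column
#'   names), `lambda`, `loss` (`1 - mean(p_i)`, the expected leave-one-out
#'   error), `objective`, `trace` (objective after every accepted step).
#' @export
ncfs_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in feature matrix")
  if (lambda < 0) stop("`lambda` must be >= 0")
  yi <- as.integer(as.factor(y))
  fit <- cpp_ncfs_fit(X, yi, lambda)
  w <- as.numeric(fit$w)
  names(w) <- colnames(X)
  structure(
    list(weights = w, lambda = lambda, loss = fit$loss,
         objective = fit$objective, trace = as.numeric(fit$trace)),
    class = "nca_fit"
  )
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("<nca_fit> lambda %.5g, loss %.4f, %d accepted steps\n",
              x$lambda, x$loss, length(x$trace) - 1L))
  invisible(x)
}

#' Cross-validated regularization selection for NCA
#'
#' Stratified 5-fold selection over the grid of 20 equally spaced lambda
#' values on `[0, 2] / n` (`n` = number of samples). Per fold and lambda the
#' feature weights are fitted on the training part and the held-out loss is
#' the error rate of weighted-distance 1-nearest-neighbour classification
#' against the training part; the lambda with the smallest mean held-out
#' loss wins (ties to the smaller lambda) and the final fit uses all data.
#'
#' @param table A [feature_table()], or any data frame with the 11 feature
#'   columns and `label`. Features are z-scored internally.
#' @param seed Integer seed for the fold partition.
#' @param n_folds Number of CV folds (default 5).
#' @return List with `lambda` (selected value), `fit` (final [ncfs_fit()]),
#'   `grid`, `mean_loss` (per grid value), `folds`.
#' @export
cv_select_lambda <- function(table, seed, n_folds = 5L) {
  table <- feature_table(as.data.frame(table))
  n <- nrow(table)
  if (n < 10L) stop("need at least 10 samples")
  X <- zscore_cols(as.matrix(table[, OSTEOTEX_FEATURES]))
  y <- table$label
  yi <- as.integer(y)
  grid <- seq(0, 2, length.out = 20L) / n

  folds <- stratified_folds(y, n_folds, seed)
  tries <- 0L
  while (any(vapply(seq_len(n_folds), function(f) {
    length(unique(yi[folds != f])) < 2L
  }, logical(1)))) {
    tries <- tries + 1L
    if (tries > 100L) stop("could not build folds with both classes")
    warning("a fold lost a class; repartitioning with the next seed")
    folds <- stratified_folds(y, n_folds, seed + tries)
  }

  mean_loss <- vapply(grid, function(lam) {
    losses <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- cpp_ncfs_fit(X[tr, , drop = FALSE], yi[tr], lam)
      pred <- cpp_wnn_predict(X[tr, , drop = FALSE], yi[tr],
                              X[!tr, , drop = FALSE], as.numeric(fit$w))
      mean(pred != yi[!tr])
    }, numeric(1))
    mean(losses)
  }, numeric(1))

  best <- which.min(mean_loss) # ties -> first = smaller lambda
  fit <- ncfs_fit(X, yi, grid[best])
  list(lambda = grid[best], fit = fit, grid = grid, mean_loss = mean_loss,
       folds = folds)
}

#' Ballot-based feature ranking over repeated NCA rounds
#'
#' Runs `n_rounds` independent rounds of [cv_select_lambda()] under seeded
#' sub-streams of `seed`, keeps the half with the smallest final-fit loss,
#' and lets every kept round cast a ballot: its features ranked by weight
#' (descending) receive scores 6, 5, 4, 3, 2, 1 for the top six and 0
#' otherwise. Ballot totals give the overall ranking (ties broken by larger
#' mean weight across kept rounds, then by canonical feature order); the
#' top `k` features are the selection.
#'
#' @param table A [feature_table()].
#' @param n_rounds Number of rounds (default 60).
#' @param seed Master seed.
#' @param k Number of features to select (default 6).
#' @return A `ballot_result`: list with `scores` (named totals), `ranking`
#'   (feature names by descending score), `selected` (top `k`), `kept_runs`
#'   (data frame of retained rounds), `weights` (kept-round weight matrix).
#' @export
ballot_rank <- function(table, n_rounds = 60L, seed = 1L, k = 6L) {
  table <- feature_table(as.data.frame(table))
  set.seed(seed)
  round_seeds <- sample.int(.Machine$integer.max - 1L, n_rounds)
  rounds <- lapply(round_seeds, function(s) cv_select_lambda(table, s))
  losses <- vapply(rounds, function(r) r$fit$loss, numeric(1))
  lambdas <- vapply(rounds, function(r) r$lambda, numeric(1))
  n_keep <- n_rounds %/% 2L
  keep_idx <- order(losses)[seq_len(n_keep)] # stable: ties by round order

  d <- length(OSTEOTEX_FEATURES)
  wmat <- t(vapply(rounds[keep_idx], function(r) unname(r$fit$weights),
                   numeric(d)))
  colnames(wmat) <- OSTEOTEX_FEATURES
  scores <- setNames(numeric(d), OSTEOTEX_FEATURES)
  points <- c(6, 5, 4, 3, 2, 1)
  for (i in seq_len(nrow(wmat))) {
    ord <- order(-wmat[i, ], seq_len(d)) # ties -> canonical order
    scores[ord[1:6]] <- scores[ord[1:6]] + points
  }
  mean_w <- colMeans(wmat)
  ranking <- OSTEOTEX_FEATURES[order(-scores, -mean_w, seq_len(d))]
  structure(
    list(scores = scores, ranking = ranking, selected = ranking[seq_len(k)],
         kept_runs = data.frame(round = keep_idx, seed = round_seeds[keep_idx],
                                lambda = lambdas[keep_idx],
                                loss = losses[keep_idx]),
         weights = wmat),
    class = "ballot_result"
  )
}

#' @export
print.ballot_result <- function(x, ...) {
  cat("<ballot_result> totals:\n")
  print(sort(x$scores, decreasing = TRUE))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
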