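# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct formulas) so they cannot share a
# defect with the vectorised implementation paths they check.

rand_gray <- function(nr, nc = nr, seed = 1) {
  set.seed(seed)
  gray_image(matrix(runif(nr * nc), nr, nc))
}

ramp_gray <- function(n = 64, a = NULL) {
  # horizontal ramp spanning [0, 1]; slope a overrides the span
  if (is.null(a)) a <- 1 / (n - 1)
  gray_image(matrix(rep(a * (0:(n - 1)), each = n), n, byrow = FALSE))
}

# Mann-Whitney AUC: concordant pairs + half credit for ties
oracle_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# offset-averaged DBC lacunarity by direct loops over offsets and boxes
oracle_mean_lacunarity <- function(img, r) {
  q <- quantize_256(img)
  nr <- nrow(q); nc <- ncol(q)
  h <- 256 * r / min(nr, nc)
  lams <- c()
  for (dy in 0:(r - 1)) {
    for (dx in 0:(r - 1)) {
      masses <- c()
      for (by in seq(dy + 1, nr - r + 1, by = r)) {
        for (bx in seq(dx + 1, nc - r + 1, by = r)) {
          box <- q[by:(by + r - 1), bx:(bx + r - 1)]
          masses <- c(masses, floor(max(box) / h) - floor(min(box) / h) + 1)
        }
      }
      lams <- c(lams, mean(masses^2) / mean(masses)^2)
    }
  }
  mean(lams)
}

# Davies-Bouldin by direct double loop
oracle_dbi <- function(points, labels) {
  lev <- unique(labels)
  k <- length(lev)
  cent <- lapply(lev, function(l) colMeans(points[labels == l, , drop = FALSE]))
  scat <- sapply(seq_len(k), function(i) {
    rows <- points[labels == lev[i], , drop = FALSE]
    mean(apply(rows, 1, function(x) sqrt(sum((x - cent[[i]])^2))))
  })
  tot <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      sep <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (scat[i] + scat[j]) / sep)
    }
    tot <- tot + best
  }
  tot / k
}

# per-pixel local range by direct loops (boundary uses in-image disk part)
oracle_range_map <- function(img, r) {
  q <- quantize_256(img)
  nr <- nrow(q); nc <- ncol(q)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (di in -r:r) {
        for (dj in -r:r) {
          if (di^2 + dj^2 > r^2) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            vals <- c(vals, q[ii, jj])
          }
        }
      }
      out[i, j] <- max(vals) - min(vals)
    }
  }
  out
}

# a standard labeled noise table in the 11-feature schema
noise_feature_table <- function(n, seed, informative = integer(0), shift = 2) {
  set.seed(seed)
  y <- rep(c("healthy", "osteoporotic"), length.out = n)
  X <- matrix(rnorm(n * 11), n)
  for (j in informative) X[, j] <- X[, j] + (y == "osteoporotic") * shift
  df <- as.data.frame(X)
  names(df) <- texture_feature_names()
  df$label <- factor(y, levels = c("healthy", "osteoporotic"))
  df
}

sort_rows <- function(m) {
  m <- unname(m)
  m[order(round(m[, 1], 9), round(m[, 2], 9)), , drop = FALSE]
}

polygon_area_for_test <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# plain R bilinear resize (independent of the package's sampler)
bilinear_resize_for_test <- function(m, nr, nc) {
  rs <- pmin(pmax((seq_len(nr) - 0.5) * nrow(m) / nr - 0.5, 0), nrow(m) - 1)
  cs <- pmin(pmax((seq_len(nc) - 0.5) * ncol(m) / nc - 0.5, 0), ncol(m) - 1)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    r0 <- min(floor(rs[i]), nrow(m) - 2); fr <- rs[i] - r0
    for (j in seq_len(nc)) {
      c0 <- min(floor(cs[j]), ncol(m) - 2); fc <- cs[j] - c0
      out[i, j] <- m[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
        m[r0 + 2, c0 + 1] * fr * (1 - fc) +
        m[r0 + 1, c0 + 2] * (1 - fr) * fc +
        m[r0 + 2, c0 + 2] * fr * fc
    }
  }
  out
}
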