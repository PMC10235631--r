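#' Davies-Bouldin index
#'
#' Cluster-validity ratio of within-class cohesion to between-class
#' separation: with per-class scatter `S_k` (mean Euclidean distance to the
#' class centroid) and centroids `c_k`,
#' `DBI = (1/K) * sum_k max_{l != k} (S_k + S_l) / ||c_k - c_l||`.
#' Smaller is better separated. Coincident centroids give `+Inf` with a
#' warning.
#'
#' @param points Numeric matrix (n x d); standardize features beforehand if
#'   their scales differ.
#' @param labels Class labels (>= 2 classes, each with >= 1 point).
#' @return A `dbi_score`: list with `value`, `classes`, `per_class_scatter`,
#'   `centroids`.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  if (nrow(points) != length(labels)) stop("points/labels length mismatch")
  lev <- levels(droplevels(labels))
  k <- length(lev)
  if (k < 2L) stop("need at least 2 classes")
  cent <- do.call(rbind, lapply(lev, function(l) {
    colMeans(points[labels == l, , drop = FALSE])
  }))
  scat <- vapply(seq_len(k), function(i) {
    d <- sweep(points[labels == lev[i], , drop = FALSE], 2L, cent[i, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  val <- 0
  warned <- FALSE
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      sep <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      rij <- if (sep < 1e-300) {
        if (!warned) warning("coincident class centroids; DBI is +Inf")
        warned <- TRUE
        Inf
      } else {
        (scat[i] + scat[j]) / sep
      }
      if (rij > best) best <- rij
    }
    val <- val + best
  }
  structure(
    list(value = val / k, classes = k, per_class_scatter = scat,
         centroids = cent),
    class = "dbi_score"
  )
}

#' @export
print.dbi_score <- function(x, ...) {
  cat(sprintf("<dbi_score> %.4f over %d classes\n", x$value, x$classes))
  invisible(x)
}

# z-score columns; all-constant columns become 0
zscore_cols <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-300] <- 1
  sweep(sweep(m, 2L, mu), 2L, sdv, "/")
}

#' Candidate scale grid
#'
#' @param fd_ranges List of `c(r_min, r_max)` fractal radii ranges.
#' @param entropy_pairs List of `c(r_measure, r_count)` entropy radii.
#' @param lac_sizes Integer vector of lacunarity box sizes.
#' @return A `candidate_grid` object.
#' @export
candidate_grid <- function(fd_ranges = list(c(1, 3), c(1, 4), c(1, 5), c(1, 6), c(1, 7)),
                           entropy_pairs = list(c(1, 4), c(1, 5), c(1, 6), c(1, 7), c(1, 8),
                                                c(2, 5), c(2, 6), c(2, 7)),
                           lac_sizes = 2:7) {
  if (!length(fd_ranges) || !length(entropy_pairs) || !length(lac_sizes)) {
    stop("candidate lists must be non-empty")
  }
  structure(list(fd_ranges = fd_ranges, entropy_pairs = entropy_pairs,
                 lac_sizes = as.integer(lac_sizes)),
            class = "candidate_grid")
}

#' Exhaustive Davies-Bouldin scan over candidate scales
#'
#' For every candidate scale configuration the corresponding per-image
#' summary statistics are extracted (fractal: the 5 FD distribution
#' statistics; entropy: the 4 entropy statistics; lacunarity: the
#' offset-averaged scalar), z-scored across images, and scored with the
#' Davies-Bouldin index of the class labels. The best (smallest-DBI) fractal
#' range and entropy pair are selected, together with the two smallest-DBI
#' lacunarity sizes.
#'
#' @param images List of [gray_image] objects.
#' @param labels Class labels, one per image (2 classes).
#' @param grid A [candidate_grid()].
#' @param masks Optional list of logical ROI masks (default: full frames).
#' @param keep Residual-filter fraction for the fractal statistics.
#' @return List with `fd` (selected [scale_series()]), `entropy`
#'   (`c(r_measure, r_count)`), `lac_sizes` (two sizes, ascending DBI), and
#'   `report` (per-category data frames of candidate DBIs).
#' @export
scan_scales <- function(images, labels, grid, masks = NULL, keep = 0.8) {
  stopifnot(inherits(grid, "candidate_grid"))
  labels <- as.factor(labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes of images")
  if (is.null(masks)) masks <- vector("list", length(images))

  eval_candidate <- function(fun) {
    # fun(img, mask) -> numeric stat vector; returns DBI value or NA
    stats <- tryCatch(
      do.call(rbind, mapply(function(im, mk) fun(im, mk), images, masks,
                            SIMPLIFY = FALSE)),
      error = function(e) {
        warning("candidate skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(stats)) return(NA_real_)
    davies_bouldin(zscore_cols(stats), labels)$value
  }

  fd_dbi <- vapply(grid$fd_ranges, function(rr) {
    eval_candidate(function(im, mk) {
      sc <- scale_series(rr[1], rr[2])
      st <- fd_distribution_stats(residual_filter(pixelwise_fd(im, mk, sc), keep))
      c(st$mode, st$sigma, st$skewness, st$kurtosis, st$shannon_bits)
    })
  }, numeric(1))

  ent_dbi <- vapply(grid$entropy_pairs, function(rr) {
    eval_candidate(function(im, mk) {
      st <- entropy_distribution_stats(local_entropy(im, rr[1], rr[2], mk))
      c(st$mode, st$sigma, st$skewness, st$kurtosis)
    })
  }, numeric(1))

  lac_dbi <- vapply(grid$lac_sizes, function(r) {
    eval_candidate(function(im, mk) mean_lacunarity(im, r, mk)$mean_lac)
  }, numeric(1))

  if (all(is.na(fd_dbi)) || all(is.na(ent_dbi)) || all(is.na(lac_dbi))) {
    stop("all candidates infeasible for at least one feature category")
  }
  fd_best <- grid$fd_ranges[[which.min(fd_dbi)]]
  ent_best <- grid$entropy_pairs[[which.min(ent_dbi)]]
  lac_ord <- order(lac_dbi, grid$lac_sizes)
  lac_ord <- lac_ord[!is.na(lac_dbi[lac_ord])]
  lac_best <- if (length(lac_ord) >= 2L) {
    grid$lac_sizes[lac_ord[1:2]]
  } else {
    warning("only one feasible lacunarity size; using it for both A and B")
    rep(grid$lac_sizes[lac_ord[1L]], 2L)
  }
  list(
    fd = scale_series(fd_best[1], fd_best[2]),
    entropy = ent_best,
    lac_sizes = lac_best,
    report = list(
      fd = data.frame(
        r_min = vapply(grid$fd_ranges, `[`, numeric(1), 1),
        r_max = vapply(grid$fd_ranges, `[`, numeric(1), 2),
        dbi = fd_dbi
      ),
      entropy = data.frame(
        r_measure = vapply(grid$entropy_pairs, `[`, numeric(1), 1),
        r_count = vapply(grid$entropy_pairs, `[`, numeric(1), 2),
        dbi = ent_dbi
      ),
      lacunarity = data.frame(size = grid$lac_sizes, dbi = lac_dbi)
    )
  )
}
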