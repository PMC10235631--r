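#' Integer offsets of a centred disk
#'
#' All integer `(i, j)` with `i^2 + j^2 <= r^2`; the measuring neighbourhood
#' used by the fractal and entropy operators.
#'
#' @param r Integer radius (>= 0).
#' @return Integer matrix with columns `i`, `j` (row offset, column offset).
#' @export
disk_offsets <- function(r) {
  if (r < 0) stop("`r` must be >= 0")
  r <- as.integer(r)
  g <- expand.grid(i = -r:r, j = -r:r)
  m <- as.matrix(g[g$i^2 + g$j^2 <= r^2, , drop = FALSE])
  dimnames(m) <- list(NULL, c("i", "j"))
  storage.mode(m) <- "integer"
  m
}

#' Multiscale series for the modified blanket method
#'
#' A radii range `r_min..r_max` enumerates rescaled disc radii
#' `s = r_min, ..., r_max`; each is paired with the (possibly fractional)
#' pixel binning factor `b_s = r_max / s`, so the physical radius of the
#' measuring disk is constant at `r_max` pixels across all scales.
#'
#' @param r_min,r_max Integer rescaled radii, `1 <= r_min < r_max`, with at
#'   least 3 scales (`r_max - r_min >= 2`), otherwise the log-log fit has no
#'   residual.
#' @return A `scale_series`: list with `r_min`, `r_max`, `s` (descending
#'   rescaled radii), `b` (binning factors), `physical_radius`.
#' @export
scale_series <- function(r_min, r_max) {
  r_min <- as.integer(r_min); r_max <- as.integer(r_max)
  if (r_min < 1L || r_min >= r_max) stop("need 1 <= r_min < r_max")
  if (r_max - r_min < 2L) stop("configuration error: fewer than 3 scales")
  s <- seq(r_max, r_min)
  structure(
    list(r_min = r_min, r_max = r_max, s = s, b = r_max / s,
         physical_radius = r_max),
    class = "scale_series"
  )
}

#' @export
print.scale_series <- function(x, ...) {
  cat(sprintf("<scale_series> radii %d-%d: s = {%s}, b = {%s}\n",
              x$r_min, x$r_max, paste(x$s, collapse = ", "),
              paste(signif(x$b, 4), collapse = ", ")))
  invisible(x)
}

# integer lattice offsets within a (possibly fractional) radius
disk_offsets_real <- function(r) {
  ri <- floor(r + 1e-9)
  g <- expand.grid(i = -ri:ri, j = -ri:ri)
  m <- as.matrix(g[g$i^2 + g$j^2 <= r^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

# Surface-area map at one scale. The intensity terrain is binned with the
# (fractional) b x b mean filter; the lag-b forward-difference magnitudes
# |I_b(q + (b, 0)) - I_b(q)| + |I_b(q + (0, b)) - I_b(q)| are the exposed
# side areas of the rescaled columns per unit column width. They are summed
# over every physical lattice pixel q of the *fixed* physical disk
# |q - p| <= s*b and scaled by 1/b (each rescaled column of side area b*|dh|
# covers b^2 physical pixels), so the disk's pixel count is identical across
# scales and cancels from the log-log slope. NA where a sample leaves the
# raster.
surface_area_map <- function(px, s, b) {
  ib <- box_mean_frac(px, b)
  gr <- abs(cpp_bilinear_accum(ib, b, 0) - ib) # vertical (row) gradient
  gc <- abs(cpp_bilinear_accum(ib, 0, b) - ib) # horizontal (col) gradient
  g <- gr + gc
  off <- disk_offsets_real(s * b)
  cpp_bilinear_accum(g, off[, "i"], off[, "j"]) / b
}

#' Rescaled surface area at one pixel
#'
#' The 3D topological surface area of the intensity terrain in the disk of
#' rescaled radius `s` around pixel `p`, measured at pixel binning `b`:
#' rescaled pixels are treated as columns of width `b` whose exposed side
#' area is `b` times the absolute lag-`b` forward difference of the
#' `b`-binned image; the per-physical-pixel share of that area is accumulated
#' over every lattice pixel of the fixed physical disk of radius `s * b`.
#'
#' @param img A [gray_image].
#' @param p Pixel as `c(row, col)` (1-based).
#' @param s Rescaled disk radius (integer >= 0).
#' @param b Binning factor (>= 1; fractional values use bilinear sampling of
#'   the area-weighted box-filtered image).
#' @return Surface area (numeric scalar).
#' @export
rescaled_surface_area <- function(img, p, s, b) {
  stopifnot(is_gray_image(img))
  sa <- surface_area_map(img$pixels, s, b)
  v <- sa[p[1L], p[2L]]
  if (is.na(v)) stop("boundary error: measuring disk exits the image")
  v
}

#' Pixel-wise fractal dimension by the modified blanket method
#'
#' For every pixel whose measuring disk (physical radius `r_max` plus filter
#' support) lies inside the mask, the surface area `SA` is measured over the
#' scale series and `FD = 2 - slope` of the OLS fit of `ln SA` against
#' `ln b`. The fit residual (sum of squared residuals in log units) is kept
#' per pixel; pixels with `SA = 0` at any scale carry no fractal signal and
#' are marked fit-ineligible.
#'
#' @param img A [gray_image].
#' @param mask Logical ROI matrix (default: whole image).
#' @param scales A [scale_series()].
#' @return An `fd_result`: list with `fd_map`, `residual_map` (NA outside the
#'   eligible set), `valid_mask` (currently retained pixels), `eligible_mask`
#'   (fit-eligible pixels), `scales`, `keep` (retained fraction, 1 before
#'   filtering).
#' @export
pixelwise_fd <- function(img, mask = NULL, scales) {
  stopifnot(is_gray_image(img), inherits(scales, "scale_series"))
  px <- img$pixels
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  stopifnot(identical(dim(mask), dim(px)))
  if (length(scales$s) < 3L) stop("configuration error: fewer than 3 scales")

  # conservative margin: farthest bilinear sample is r_max + b (disk plus
  # gradient lag), plus the box-filter support b/2 + 1
  reach <- max(scales$physical_radius + scales$b + scales$b / 2 + 1)
  margin <- ceiling(reach)
  region <- erode_square(mask, margin)

  sa_list <- lapply(seq_along(scales$s), function(k) {
    surface_area_map(px, scales$s[k], scales$b[k])
  })
  eligible <- region
  for (sa in sa_list) eligible <- eligible & is.finite(sa) & (sa > 0)

  fd_map <- matrix(NA_real_, nrow(px), ncol(px))
  res_map <- matrix(NA_real_, nrow(px), ncol(px))
  idx <- which(eligible)
  if (length(idx)) {
    x <- log(scales$b)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    y <- vapply(sa_list, function(sa) log(sa[idx]), numeric(length(idx)))
    if (length(idx) == 1L) y <- matrix(y, nrow = 1L)
    slope <- as.vector(y %*% xc) / sxx
    fitted_err <- y - outer(slope, xc) - rowMeans(y)
    fd_map[idx] <- 2 - slope
    res_map[idx] <- rowSums(fitted_err^2)
  }
  structure(
    list(fd_map = fd_map, residual_map = res_map, valid_mask = eligible,
         eligible_mask = eligible, scales = scales, keep = 1),
    class = "fd_result"
  )
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf(
    "<fd_result> radii %d-%d: %d eligible px, %d retained (keep = %.2f)\n",
    x$scales$r_min, x$scales$r_max, sum(x$eligible_mask), sum(x$valid_mask),
    x$keep
  ))
  invisible(x)
}

#' Exclude poorly fitting pixels by fit residual
#'
#' Restricts the valid mask to the `keep` fraction of fit-eligible pixels
#' with the smallest log-log fit residuals (threshold at the `keep` order
#' statistic; all pixels tied at the threshold are retained).
#'
#' @param res An `fd_result` from [pixelwise_fd()].
#' @param keep Fraction of eligible pixels to retain, `0 < keep <= 1`
#'   (default 0.8).
#' @return The `fd_result` with an updated `valid_mask` and `keep`.
#' @export
residual_filter <- function(res, keep = 0.8) {
  stopifnot(inherits(res, "fd_result"))
  if (!is.numeric(keep) || keep <= 0 || keep > 1) {
    stop("`keep` must be in (0, 1]")
  }
  idx <- which(res$eligible_mask)
  if (!length(idx)) stop("empty eligible set")
  if (keep == 1) {
    res$valid_mask <- res$eligible_mask
    res$keep <- 1
    return(res)
  }
  r <- res$residual_map[idx]
  k <- max(1L, ceiling(keep * length(idx) - 1e-9))
  thr <- sort(r, partial = k)[k]
  retained <- idx[r <= thr]
  vm <- matrix(FALSE, nrow(res$fd_map), ncol(res$fd_map))
  vm[retained] <- TRUE
  res$valid_mask <- vm
  res$keep <- keep
  res
}

#' Distribution statistics of the retained fractal dimensions
#'
#' Histogram summary (bin width 0.005, sliding-window mode of width 0.011 in
#' steps of 0.001) of the FD values on the valid mask, including the Shannon
#' entropy of the FDs requantized to 16 bits. These are the five fractal
#' features `fd_mode`, `fd_sigma`, `fd_skewness`, `fd_kurtosis`,
#' `fd_entropy`.
#'
#' @param res An `fd_result` (usually after [residual_filter()]).
#' @return A [histogram_summary()].
#' @export
fd_distribution_stats <- function(res) {
  stopifnot(inherits(res, "fd_result"))
  v <- res$fd_map[res$valid_mask]
  if (length(v) < 2L) stop("need at least 2 retained pixels")
  histogram_summary(v, with_entropy = TRUE)
}
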