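#' Extract the 11 texture features from one image
#'
#' Chains the three texture operators at the configured scales: five fractal
#' distribution statistics (after the 80% residual filter), the
#' offset-averaged lacunarity at the two selected box sizes, and four
#' local-entropy distribution statistics. On degenerate input (e.g. a
#' constant image) the fractal statistics are `NA` (no pixel carries a
#' fractal signal), lacunarity is exactly 1 and the entropy statistics are
#' 0.
#'
#' @param img A [gray_image].
#' @param mask Optional logical ROI matrix.
#' @param fd_radii `c(r_min, r_max)` fractal radii range.
#' @param ent_radii `c(r_measure, r_count)` entropy radii.
#' @param lac_sizes Two lacunarity box sizes `c(A, B)`.
#' @param keep Residual-filter fraction (default 0.8).
#' @return Named numeric vector of the 11 features (see
#'   [texture_feature_names()]), with attribute `fd_retained` (retained
#'   pixel count).
#' @export
extract_features <- function(img, mask = NULL, fd_radii = c(1L, 4L),
                             ent_radii = c(1L, 6L), lac_sizes = c(3L, 4L),
                             keep = 0.8) {
  stopifnot(is_gray_image(img))
  out <- setNames(rep(NA_real_, 11L), OSTEOTEX_FEATURES)

  fd_retained <- 0L
  fd_try <- tryCatch({
    sc <- scale_series(fd_radii[1L], fd_radii[2L])
    res <- residual_filter(pixelwise_fd(img, mask, sc), keep)
    fd_retained <- sum(res$valid_mask)
    fd_distribution_stats(res)
  }, error = function(e) NULL)
  if (!is.null(fd_try)) {
    out["fd_mode"] <- fd_try$mode
    out["fd_sigma"] <- fd_try$sigma
    out["fd_skewness"] <- fd_try$skewness
    out["fd_kurtosis"] <- fd_try$kurtosis
    out["fd_entropy"] <- fd_try$shannon_bits
  }

  out["lac_A"] <- mean_lacunarity(img, lac_sizes[1L], mask)$mean_lac
  out["lac_B"] <- mean_lacunarity(img, lac_sizes[2L], mask)$mean_lac

  ent <- local_entropy(img, ent_radii[1L], ent_radii[2L], mask)
  est <- entropy_distribution_stats(ent)
  out["ent_mode"] <- est$mode
  out["ent_sigma"] <- est$sigma
  out["ent_skewness"] <- est$skewness
  out["ent_kurtosis"] <- est$kurtosis

  attr(out, "fd_retained") <- fd_retained
  out
}

#' Apply the enhancement chain to an image
#'
#' Fixed order: flat-field correction, haze reduction, quantile contrast
#' windowing.
#'
#' @param img A [gray_image].
#' @param flatfield_sigma Gaussian background sd in pixels (0 disables).
#' @param dehaze_amount Dehaze blend in `[0, 1]` (0 disables).
#' @param clip Windowing tail mass per side (0 disables nothing; the window
#'   step always runs unless `clip < 0`).
#' @return An enhanced [gray_image].
#' @export
enhance_image <- function(img, flatfield_sigma = 20, dehaze_amount = 0.05,
                          clip = 0.001) {
  if (flatfield_sigma > 0) img <- flat_field_correct(img, flatfield_sigma)
  if (dehaze_amount > 0) img <- reduce_haze(img, dehaze_amount)
  if (clip >= 0) img <- stretch_window(img, clip)
  img
}
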