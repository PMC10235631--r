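#' Local gray-level range map
#'
#' The image is quantized to 256 levels and each pixel is assigned the
#' max - min gray level over the integer disk of radius `r_measure` centred
#' on it (boundary pixels use the in-image portion of the disk). These
#' integer observations are the raw material for the local-entropy map.
#'
#' @param img A [gray_image].
#' @param r_measure Measuring disk radius (integer >= 1).
#' @return Integer matrix of range observations in `0..255`.
#' @export
local_range_map <- function(img, r_measure) {
  stopifnot(is_gray_image(img))
  if (r_measure < 1) stop("`r_measure` must be >= 1")
  off <- disk_offsets(r_measure)
  cpp_disk_range(quantize_256(img), off[, "i"], off[, "j"])
}

#' Pixel-wise Shannon entropy of local range observations
#'
#' For each pixel whose counting disk (radius `r_count`) lies fully inside
#' the mask and the image, the empirical distribution `P(v_i)` of the exact
#' integer range observations inside the disk is formed and
#' `H = -sum P log2 P` (bits) is recorded. `H` is bounded by `log2(n)` where
#' `n` is the disk pixel count.
#'
#' @param ranges Integer range map from [local_range_map()].
#' @param mask Optional logical ROI matrix (default: whole image).
#' @param r_count Counting disk radius; must exceed the measuring radius.
#' @param r_measure Measuring radius used to build `ranges` (recorded, and
#'   validated against `r_count` when supplied).
#' @return An `entropy_result`: list with `range_map`, `entropy_map` (NA
#'   outside the valid set), `valid_mask`, `r_measure`, `r_count`, `n_disk`.
#' @export
entropy_map <- function(ranges, mask = NULL, r_count, r_measure = NA_integer_) {
  stopifnot(is.matrix(ranges))
  if (!is.na(r_measure) && r_count <= r_measure) {
    stop("`r_count` must exceed `r_measure`")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ranges), ncol(ranges))
  stopifnot(identical(dim(mask), dim(ranges)))
  off <- disk_offsets(r_count)
  valid <- erode_disk(mask, off)
  if (!any(valid)) stop("empty valid region: no counting disk fits the mask")
  storage.mode(ranges) <- "integer"
  ent <- cpp_entropy_map(ranges, valid, off[, "i"], off[, "j"])
  structure(
    list(range_map = ranges, entropy_map = ent, valid_mask = valid,
         r_measure = r_measure, r_count = as.integer(r_count),
         n_disk = nrow(off)),
    class = "entropy_result"
  )
}

#' Local entropy in one call
#'
#' Convenience wrapper chaining [local_range_map()] and [entropy_map()].
#'
#' @inheritParams local_range_map
#' @inheritParams entropy_map
#' @return An `entropy_result`.
#' @export
local_entropy <- function(img, r_measure, r_count, mask = NULL) {
  entropy_map(local_range_map(img, r_measure), mask, r_count, r_measure)
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "<entropy_result> r_measure = %s, r_count = %d (n = %d): %d valid px\n",
    as.character(x$r_measure), x$r_count, x$n_disk, sum(x$valid_mask)
  ))
  invisible(x)
}

#' Distribution statistics of the local-entropy map
#'
#' The same histogram machinery as [fd_distribution_stats()] (bin width
#' 0.005, sliding-window mode 0.011 / 0.001) applied to the valid entropy
#' values, without the 16-bit requantized entropy feature. These are the
#' features `ent_mode`, `ent_sigma`, `ent_skewness`, `ent_kurtosis`.
#'
#' @param res An `entropy_result`.
#' @return A [histogram_summary()].
#' @export
entropy_distribution_stats <- function(res) {
  stopifnot(inherits(res, "entropy_result"))
  v <- res$entropy_map[res$valid_mask]
  if (length(v) < 2L) stop("need at least 2 valid pixels")
  histogram_summary(v, with_entropy = FALSE)
}
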