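#' Flat-field (shading) correction
#'
#' Removes smooth exposure bias: the background `B` is a Gaussian blur of the
#' image with standard deviation `sigma` pixels, and the output is
#' `img * mean(B) / B`, clipped to `[0, 1]`. Mean intensity is preserved to
#' within about 1%.
#'
#' @param img A [gray_image].
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return A corrected [gray_image].
#' @export
flat_field_correct <- function(img, sigma) {
  stopifnot(is_gray_image(img))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  b <- blur_gaussian(img$pixels, sigma)
  if (any(b < 1e-12)) {
    stop("degenerate background: Gaussian background contains zeros")
  }
  out <- img$pixels * mean(b) / b
  gray_image(pmin(pmax(out, 0), 1), img$spacing_mm, img$bit_origin)
}

#' Haze / scatter reduction
#'
#' Simplified dark-channel-prior dehazing, blended with the input. The dark
#' channel is a 15x15 minimum filter; atmospheric light `A` is the mean
#' intensity over the brightest 0.1% of dark-channel pixels; transmission is
#' `t = 1 - 0.95 * D / A`, floored at 0.1; the dehazed image is
#' `J = (I - A) / t + A` and the result is `amount * J + (1 - amount) * I`,
#' clipped to `[0, 1]`.
#'
#' @param img A [gray_image].
#' @param amount Blend fraction in `[0, 1]` (`0.05` suppresses a mild veil;
#'   `0` returns the input unchanged).
#' @return A [gray_image].
#' @export
reduce_haze <- function(img, amount) {
  stopifnot(is_gray_image(img))
  if (!is.numeric(amount) || length(amount) != 1L || amount < 0 || amount > 1) {
    stop("`amount` must be a single value in [0, 1]")
  }
  px <- img$pixels
  if (amount == 0) return(img)
  d <- min_filter(px, 15L)
  thr <- quantile(d, 1 - 0.001, names = FALSE)
  a <- mean(px[d >= thr])
  a <- max(a, 1e-9)
  tr <- pmax(1 - 0.95 * d / a, 0.1)
  j <- (px - a) / tr + a
  out <- amount * j + (1 - amount) * px
  gray_image(pmin(pmax(out, 0), 1), img$spacing_mm, img$bit_origin)
}

#' Contrast windowing by quantile clipping
#'
#' Linearly rescales intensities so the `clip` quantile maps to 0 and the
#' `1 - clip` quantile maps to 1, saturating beyond. `clip = 0.001` saturates
#' the brightest 0.1% of pixels and cuts off the darkest 0.1%.
#'
#' @param img A [gray_image].
#' @param clip Clipped tail mass per side, `0 <= clip < 0.5`.
#' @return A [gray_image]; an all-equal input yields an all-zero image with a
#'   warning.
#' @export
stretch_window <- function(img, clip) {
  stopifnot(is_gray_image(img))
  if (!is.numeric(clip) || length(clip) != 1L || clip < 0 || clip >= 0.5) {
    stop("`clip` must be in [0, 0.5)")
  }
  v <- img$pixels
  lo <- quantile(v, clip, names = FALSE)
  hi <- quantile(v, 1 - clip, names = FALSE)
  if (hi - lo < 1e-12) {
    warning("degenerate (all-equal) image; returning all zeros")
    return(gray_image(v * 0, img$spacing_mm, img$bit_origin))
  }
  out <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  gray_image(out, img$spacing_mm, img$bit_origin)
}

#' Estimate a missing source-to-object distance
#'
#' Fits an ordinary least-squares line `SOD = a * SID + b` to calibration
#' pairs from machines reporting both distances, and evaluates it at
#' `query_sid` for images that report only the source-to-image distance.
#'
#' @param pairs Two-column matrix or data frame of `(sid, sod)` values
#'   (millimetres), at least two with distinct SIDs.
#' @param query_sid SID at which to predict the SOD.
#' @return Predicted SOD (numeric scalar) with attributes `a` (slope) and
#'   `b` (intercept).
#' @export
estimate_sod <- function(pairs, query_sid) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L || nrow(pairs) < 2L) {
    stop("`pairs` must contain at least two (sid, sod) rows")
  }
  names(pairs)[1:2] <- c("sid", "sod")
  if (length(unique(pairs$sid)) < 2L) {
    stop("rank-deficient calibration: all SIDs are equal")
  }
  fit <- lm(sod ~ sid, data = pairs)
  out <- as.numeric(predict(fit, data.frame(sid = query_sid)))
  attr(out, "a") <- unname(coef(fit)[2])
  attr(out, "b") <- unname(coef(fit)[1])
  out
}

#' Geometry calibration record
#'
#' @param sid_mm Source-to-image distance (mm).
#' @param sod_mm Source-to-object distance (mm); must satisfy
#'   `0 < sod_mm <= sid_mm`.
#' @return A `geometry_calibration` object.
#' @export
geometry_calibration <- function(sid_mm, sod_mm) {
  if (sid_mm <= 0 || sod_mm <= 0) stop("distances must be positive")
  if (sod_mm > sid_mm) stop("calibration error: sod_mm > sid_mm")
  structure(list(sid_mm = sid_mm, sod_mm = sod_mm),
            class = "geometry_calibration")
}

#' Normalise projection magnification
#'
#' A radiograph magnifies the object plane by `SID / SOD`; the effective
#' object-plane pixel pitch is `spacing_mm * SOD / SID`. The image is
#' bilinearly resampled so that its recorded spacing equals `target_spacing`,
#' making scale-sensitive texture features comparable across acquisitions.
#'
#' @param img A [gray_image] (detector-plane spacing in `spacing_mm`).
#' @param cal A [geometry_calibration].
#' @param target_spacing Desired object-plane pixel pitch (mm).
#' @return A resampled [gray_image] with `spacing_mm == target_spacing`.
#' @export
normalize_magnification <- function(img, cal, target_spacing) {
  stopifnot(is_gray_image(img), inherits(cal, "geometry_calibration"))
  obj_spacing <- img$spacing_mm * cal$sod_mm / cal$sid_mm
  f <- obj_spacing / target_spacing
  new_nr <- max(16L, round(nrow(img$pixels) * f))
  new_nc <- max(16L, round(ncol(img$pixels) * f))
  if (new_nr == nrow(img$pixels) && new_nc == ncol(img$pixels)) {
    return(gray_image(img$pixels, target_spacing, img$bit_origin))
  }
  out <- bilinear_resize(img$pixels, new_nr, new_nc)
  gray_image(pmin(pmax(out, 0), 1), target_spacing, img$bit_origin)
}

## ----------------------------------------------------------------- ROI ----

#' Region-of-interest quadrilateral from four manual corners
#'
#' Given the four manually picked corners of the outer quadrilateral (ordered
#' so that `(c1, c3)` and `(c2, c4)` are its diagonals), the points at
#' parameters 1/6 and 5/6 along each diagonal are taken as breakpoints; the
#' four breakpoints, ordered around their centroid, form the ROI
#' quadrilateral (the central 2/3 of each diagonal).
#'
#' @param corners 4x2 numeric matrix of `(x, y)` points in pixel coordinates
#'   (0-based, `x` = column, `y` = row).
#' @return An `roi_polygon`: list with `vertices` (4x2 matrix, ordered
#'   counter-clockwise around the centroid).
#' @export
roi_from_corners <- function(corners) {
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4L, 2L))) stop("`corners` must be a 4x2 matrix")
  d1 <- corners[c(1L, 3L), , drop = FALSE]
  d2 <- corners[c(2L, 4L), , drop = FALSE]
  pts <- rbind(
    d1[1L, ] + (1 / 6) * (d1[2L, ] - d1[1L, ]),
    d1[1L, ] + (5 / 6) * (d1[2L, ] - d1[1L, ]),
    d2[1L, ] + (1 / 6) * (d2[2L, ] - d2[1L, ]),
    d2[1L, ] + (5 / 6) * (d2[2L, ] - d2[1L, ])
  )
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])
  verts <- pts[order(ang), , drop = FALSE]
  if (abs(polygon_area(verts)) < 1e-9) {
    stop("degenerate polygon: corners are collinear")
  }
  dimnames(verts) <- list(NULL, c("x", "y"))
  structure(list(vertices = verts), class = "roi_polygon")
}

# signed shoelace area of an (x, y) polygon
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Rasterize an ROI polygon to a logical mask
#'
#' Even-odd (crossing-number) test of each pixel center against the polygon.
#' Pixel `(row, col)` has center `(x, y) = (col - 1, row - 1)` in the 0-based
#' corner coordinate system.
#'
#' @param poly An `roi_polygon` (or any list with 4x2 `vertices`).
#' @param nrow,ncol Output mask dimensions.
#' @return Logical matrix.
#' @export
roi_mask <- function(poly, nrow, ncol) {
  v <- poly$vertices
  xs <- rep(seq_len(ncol) - 1, each = nrow)
  ys <- rep(seq_len(nrow) - 1, times = ncol)
  inside <- rep(FALSE, length(xs))
  n <- base::nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow, ncol)
}

#' Read ROI corner coordinates from JSON
#'
#' Expects `{"corners": [[x, y], ...]}` with four 0-based pixel-coordinate
#' points ordered so that points 1,3 and 2,4 are the outer diagonals.
#'
#' @param path JSON file path.
#' @return 4x2 numeric matrix of corners.
#' @export
read_roi_corners <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$corners)) stop("ROI file lacks a `corners` entry: ", path)
  m <- as.matrix(obj$corners)
  if (!all(dim(m) == c(4L, 2L))) stop("ROI `corners` must be 4 (x, y) points")
  storage.mode(m) <- "double"
  m
}
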