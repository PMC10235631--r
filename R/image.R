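#' Grayscale image container
#'
#' A 2D intensity raster in `[0, 1]` with an isotropic physical pixel pitch.
#' All texture operators in the package take and return this container.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows = image rows).
#' @param spacing_mm Physical pixel pitch in millimetres (isotropic, > 0).
#' @param bit_origin Bit depth of the source data (informational).
#' @return An object of class `gray_image` with fields `pixels`, `spacing_mm`,
#'   `bit_origin`.
#' @export
gray_image <- function(pixels, spacing_mm = 1, bit_origin = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("image must be at least 16x16 pixels")
  }
  if (any(!is.finite(pixels))) stop("image intensities must be finite")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop("image intensities must lie in [0, 1]; rescale on input")
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("`spacing_mm` must be a single positive number")
  }
  structure(
    list(
      pixels = pmin(pmax(pixels, 0), 1),
      spacing_mm = as.numeric(spacing_mm),
      bit_origin = as.integer(bit_origin)
    ),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d px, spacing %.4g mm, source %d-bit, range [%.3f, %.3f]\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$bit_origin,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

#' Quantize an image to 256 gray levels
#'
#' Maps `[0, 1]` intensities to integers `0..255` by rounding; the common
#' substrate for the lacunarity and local-range operators.
#'
#' @param img A [gray_image].
#' @return Integer matrix with values in `0..255`.
#' @export
quantize_256 <- function(img) {
  stopifnot(is_gray_image(img))
  m <- round(img$pixels * 255)
  storage.mode(m) <- "integer"
  m
}

## ------------------------------------------------------------------ I/O ----

#' Read a grayscale image
#'
#' Supports plain/binary PGM (`P2`/`P5`, any maxval) and CSV rasters.
#' Intensities are rescaled to `[0, 1]` by the format's maximum value (PGM)
#' or left as-is when already within `[0, 1]` (CSV), otherwise min-max scaled.
#'
#' @param path File path (`.pgm` or `.csv`).
#' @param spacing_mm Pixel pitch to record, unless a JSON sidecar
#'   (`<path>.json`) provides `spacing_mm`.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, spacing_mm = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$spacing_mm)) spacing_mm <- as.numeric(meta$spacing_mm)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    dat <- read_pgm(path)
    gray_image(dat$pixels / dat$maxval, spacing_mm = spacing_mm,
               bit_origin = if (dat$maxval > 255) 16L else 8L)
  } else if (ext == "csv") {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    if (min(m) < 0 || max(m) > 1) m <- (m - min(m)) / (max(m) - min(m))
    gray_image(m, spacing_mm = spacing_mm)
  } else {
    stop("unsupported image format: .", ext, " (use .pgm or .csv)")
  }
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", path)
  tok <- character(0)
  buf <- ""
  # read header tokens (width, height, maxval), skipping '#' comments
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) {
        tok <- c(tok, buf)
        buf <- ""
      }
    } else {
      buf <- paste0(buf, ch)
    }
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); mx <- as.integer(tok[3])
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (mx > 255L) {
      raw2 <- readBin(con, "raw", n = 2L * n)
      vals <- as.integer(raw2[seq(1, 2 * n, 2)]) * 256L +
        as.integer(raw2[seq(2, 2 * n, 2)])
    } else {
      vals <- as.integer(readBin(con, "raw", n = n))
    }
  }
  if (length(vals) < n) stop("truncated PGM payload")
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE), maxval = mx)
}

#' Write a grayscale image or heat map
#'
#' `.pgm` writes plain-text 16-bit PGM (`P2`, maxval 65535); `.csv` writes the
#' raw numeric raster. Heat maps with `NA` entries are written as 0.
#'
#' @param img A [gray_image] (written with its `[0, 1]` intensities intact)
#'   or a bare numeric matrix (heat map; min-max scaled before export).
#' @param path Output path (`.pgm` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  m <- if (is_gray_image(img)) img$pixels else img
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  if (ext != "pgm") stop("unsupported output format: .", ext)
  if (is_gray_image(img)) {
    v <- m
  } else {
    v <- m
    v[!is.finite(v)] <- NA
    rng <- range(v, na.rm = TRUE)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    v[is.na(v)] <- 0
  }
  q <- matrix(as.integer(round(v * 65535)), nrow(m), ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "65535"), con)
  apply(q, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

## ------------------------------------------- low-level raster operators ----

# replicate-pad a matrix by k rows/cols on every side
pad_replicate <- function(m, k) {
  if (k <= 0) return(m)
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# separable convolution with an odd-length 1D kernel, replicate boundary
conv_sep <- function(m, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  if (k == 0L) return(m * kernel)
  p <- pad_replicate(m, k)
  nr <- nrow(m); nc <- ncol(m)
  # rows pass
  acc <- matrix(0, nr, nc + 2L * k)
  for (t in seq_along(kernel)) {
    acc <- acc + kernel[t] * p[(t - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * acc[, (t - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

blur_gaussian <- function(m, sigma) conv_sep(m, gaussian_kernel(sigma))

# 1D kernel of the continuous (area-weighted) box filter of width b >= 1;
# exact for fractional widths, identity at b = 1
box_kernel_frac <- function(b) {
  stopifnot(b >= 1)
  h <- b / 2
  r <- ceiling(h - 0.5 + 1e-12)
  t <- -r:r
  w <- pmax(0, pmin(t + 0.5, h) - pmax(t - 0.5, -h))
  w / sum(w)
}

# mean filter with (possibly fractional) square window b
box_mean_frac <- function(m, b) {
  if (abs(b - 1) < 1e-12) return(m)
  conv_sep(m, box_kernel_frac(b))
}

# separable running-min filter with square window w (odd), replicate boundary
min_filter <- function(m, w) {
  k <- (w - 1L) %/% 2L
  p <- pad_replicate(m, k)
  nr <- nrow(m); nc <- ncol(m)
  acc <- p[seq_len(nr), , drop = FALSE]
  for (t in seq_len(2L * k)) {
    acc <- pmin(acc, p[t + seq_len(nr), , drop = FALSE])
  }
  out <- acc[, seq_len(nc), drop = FALSE]
  for (t in seq_len(2L * k)) {
    out <- pmin(out, acc[, t + seq_len(nc), drop = FALSE])
  }
  out
}

# binary erosion of a logical mask with a (2k+1) square; pixels outside the
# image count as FALSE (conservative superset of disk erosion)
erode_square <- function(mask, k) {
  if (k <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L * k, nc + 2L * k)
  p[k + seq_len(nr), k + seq_len(nc)] <- mask
  acc <- p[seq_len(nr), , drop = FALSE]
  for (t in seq_len(2L * k)) acc <- acc & p[t + seq_len(nr), , drop = FALSE]
  out <- acc[, seq_len(nc), drop = FALSE]
  for (t in seq_len(2L * k)) out <- out & acc[, t + seq_len(nc), drop = FALSE]
  out
}

# binary erosion with an exact integer disk; out-of-image counts FALSE
erode_disk <- function(mask, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  k <- max(abs(offsets))
  p <- matrix(FALSE, nr + 2L * k, nc + 2L * k)
  p[k + seq_len(nr), k + seq_len(nc)] <- mask
  out <- matrix(TRUE, nr, nc)
  for (t in seq_len(nrow(offsets))) {
    out <- out & p[k + offsets[t, 1L] + seq_len(nr),
                   k + offsets[t, 2L] + seq_len(nc), drop = FALSE]
  }
  out
}

# scalar bilinear sample (1-based fractional row/col), NA outside
bilin_at <- function(m, r, c) {
  drop(cpp_bilinear_resample(m, r - 1, c - 1))
}

# bilinear resize to (new_nr, new_nc), pixel-center aligned
bilinear_resize <- function(m, new_nr, new_nc) {
  sr <- nrow(m) / new_nr
  sc <- ncol(m) / new_nc
  rs <- (seq_len(new_nr) - 0.5) * sr - 0.5
  cs <- (seq_len(new_nc) - 0.5) * sc - 0.5
  rs <- pmin(pmax(rs, 0), nrow(m) - 1)
  cs <- pmin(pmax(cs, 0), ncol(m) - 1)
  cpp_bilinear_resample(m, rs, cs)
}
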