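#' Fractional-Brownian surface by spectral synthesis
#'
#' Gaussian random field with isotropic power spectrum `P(f) ~ f^-(2H+2)`,
#' obtained by shaping complex white noise in Fourier space and inverse
#' transforming; the result is min-max normalised to `[0, 1]`. An fBm
#' surface with Hurst exponent `H` has theoretical fractal dimension
#' `3 - H`, which makes these surfaces the ground truth for the fractal
#' estimator.
#'
#' @param size Image side (power of 2, >= 16).
#' @param H Hurst exponent in `(0, 1)`.
#' @param seed Integer seed (same seed, same surface).
#' @return A [gray_image].
#' @export
fbm_surface <- function(size, H, seed) {
  if (H <= 0 || H >= 1) stop("`H` must be in (0, 1)")
  if (size < 16 || bitwAnd(size, size - 1L) != 0L) {
    stop("`size` must be a power of 2, >= 16")
  }
  set.seed(seed)
  k <- c(0:(size / 2), -(size / 2 - 1):-1) / size
  f <- sqrt(outer(k^2, k^2, "+"))
  amp <- f^(-(H + 1))
  amp[1L, 1L] <- 0
  z <- matrix(rnorm(size^2), size) + 1i * matrix(rnorm(size^2), size)
  surf <- Re(fft(amp * z, inverse = TRUE)) / size^2
  rng <- range(surf)
  gray_image((surf - rng[1]) / diff(rng))
}

#' Log-log radial periodogram slope
#'
#' Regresses log mean power against log frequency magnitude over logarithmic
#' radial bins of the 2D periodogram (mid-band frequencies only). For an fBm
#' surface with Hurst exponent `H` the slope is `-(2H + 2)`.
#'
#' @param img A [gray_image].
#' @param f_lo,f_hi Frequency band in cycles/pixel (defaults 0.01-0.35).
#' @param n_bins Number of logarithmic radial bins (default 24).
#' @return Slope (numeric scalar).
#' @export
periodogram_slope <- function(img, f_lo = 0.01, f_hi = 0.35, n_bins = 24L) {
  stopifnot(is_gray_image(img))
  px <- img$pixels - mean(img$pixels)
  n <- nrow(px)
  p <- Mod(fft(px))^2
  k <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  f <- sqrt(outer(k^2, k^2, "+"))
  sel <- f >= f_lo & f <= f_hi
  lf <- log(f[sel]); lp <- p[sel]
  edges <- seq(log(f_lo), log(f_hi), length.out = n_bins + 1L)
  bin <- findInterval(lf, edges, rightmost.closed = TRUE)
  mp <- tapply(lp, bin, mean)
  mf <- tapply(lf, bin, mean)
  keep <- is.finite(mp) & mp > 0
  unname(coef(lm(log(mp[keep]) ~ mf[keep]))[2L])
}

#' Superimpose dark lesion-like blobs
#'
#' Adds sparse Gaussian-profile dark blobs (radius 3-8 px, profile sd =
#' radius / 2) to a base texture, emulating the episodic radiolucent lesions
#' of osteoporotic bone loss. The expected blob count is
#' `density * area / (pi * E[radius^2])`, drawn from a Poisson distribution.
#'
#' @param base A [gray_image].
#' @param density Fraction of the area expected to be covered, in `(0, 1)`.
#' @param contrast Blob depth (> 0); intensities are clipped to `[0, 1]`.
#' @param seed Integer seed.
#' @return A [gray_image] with attribute `n_blobs`.
#' @export
blob_texture <- function(base, density, contrast, seed) {
  stopifnot(is_gray_image(base))
  if (density < 0 || density >= 1) stop("`density` must be in [0, 1)")
  if (contrast <= 0) stop("`contrast` must be > 0")
  set.seed(seed)
  px <- base$pixels
  nr <- nrow(px); nc <- ncol(px)
  mean_r2 <- (8^3 - 3^3) / (3 * (8 - 3)) # E[r^2], r ~ U(3, 8)
  n_blobs <- rpois(1L, density * nr * nc / (pi * mean_r2))
  if (n_blobs > 0) {
    for (bidx in seq_len(n_blobs)) {
      cy <- runif(1, 1, nr)
      cx <- runif(1, 1, nc)
      rad <- runif(1, 3, 8)
      sg <- rad / 2
      w <- ceiling(3 * sg)
      rows <- max(1L, floor(cy - w)):min(nr, ceiling(cy + w))
      cols <- max(1L, floor(cx - w)):min(nc, ceiling(cx + w))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
      px[rows, cols] <- px[rows, cols] - contrast * exp(-d2 / (2 * sg^2))
    }
  }
  out <- gray_image(pmin(pmax(px, 0), 1), base$spacing_mm, base$bit_origin)
  attr(out, "n_blobs") <- n_blobs
  out
}

#' Specification of a synthetic two-class cohort
#'
#' The stated world of the synthetic tests: class "healthy" is smoother fBm
#' texture (`H0 = 0.7`, FD 2.3); class "osteoporotic" is rougher fBm
#' (`H1 = 0.5`, FD 2.5) with dark lesion blobs (density 0.02, contrast 0.3)
#' raising its lacunarity. Mild additive Gaussian detector noise
#' (`noise_sd = 0.01`) is applied to both classes. The default image side of
#' 128 px keeps whole-cohort feature extraction within desk-scale runtime.
#'
#' @param n_per_class Images per class (>= 2).
#' @param image_size Image side (power of 2).
#' @param H0,H1 Hurst exponents of the two classes, in `(0, 1)`.
#' @param blob_density,blob_contrast Lesion overlay for class 1
#'   (`blob_density = 0` disables it).
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Master seed.
#' @param fd_radii,ent_radii,lac_sizes Feature-extraction scales (defaults:
#'   fractal radii 1-4, entropy radii 1 and 6, lacunarity sizes 3 and 4).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = 30L, image_size = 128L,
                        H0 = 0.7, H1 = 0.5,
                        blob_density = 0.02, blob_contrast = 0.3,
                        noise_sd = 0.01, seed = 1L,
                        fd_radii = c(1L, 4L), ent_radii = c(1L, 6L),
                        lac_sizes = c(3L, 4L)) {
  if (n_per_class < 2L) stop("`n_per_class` must be >= 2")
  if (H0 <= 0 || H0 >= 1 || H1 <= 0 || H1 >= 1) stop("Hurst exponents must be in (0, 1)")
  structure(
    list(n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size), H0 = H0, H1 = H1,
         blob_density = blob_density, blob_contrast = blob_contrast,
         noise_sd = noise_sd, seed = as.integer(seed),
         fd_radii = fd_radii, ent_radii = ent_radii, lac_sizes = lac_sizes),
    class = "cohort_spec"
  )
}

#' Generate a labeled synthetic cohort with its feature table
#'
#' Class 0 ("healthy") images are fBm surfaces with Hurst `H0`; class 1
#' ("osteoporotic") images are fBm surfaces with Hurst `H1` overlaid with
#' dark blobs; both receive additive Gaussian noise. The full 11-feature
#' texture table is extracted at the configured scales. Deterministic under
#' the master seed.
#'
#' @param spec A [cohort_spec()].
#' @param with_images If `FALSE`, drop the image list from the result (the
#'   feature table is always returned).
#' @return List with `images`, `labels` (factor `healthy` / `osteoporotic`),
#'   `features` (a [feature_table()]), `spec`.
#' @export
make_cohort <- function(spec, with_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 6L * n), ncol = 3L)
  gen_one <- function(i, cls) {
    row <- (cls - 1L) * n + i
    img <- fbm_surface(spec$image_size,
                       if (cls == 1L) spec$H0 else spec$H1,
                       seeds[row, 1L])
    if (cls == 2L && spec$blob_density > 0) {
      img <- blob_texture(img, spec$blob_density, spec$blob_contrast,
                          seeds[row, 2L])
    }
    if (spec$noise_sd > 0) {
      set.seed(seeds[row, 3L])
      px <- img$pixels + rnorm(length(img$pixels), sd = spec$noise_sd)
      img <- gray_image(pmin(pmax(px, 0), 1), img$spacing_mm, img$bit_origin)
    }
    img
  }
  images <- c(lapply(seq_len(n), gen_one, cls = 1L),
              lapply(seq_len(n), gen_one, cls = 2L))
  labels <- factor(rep(c("healthy", "osteoporotic"), each = n),
                   levels = c("healthy", "osteoporotic"))
  feats <- t(vapply(images, function(im) {
    extract_features(im, fd_radii = spec$fd_radii, ent_radii = spec$ent_radii,
                     lac_sizes = spec$lac_sizes)
  }, numeric(11L)))
  df <- as.data.frame(feats)
  names(df) <- OSTEOTEX_FEATURES
  df$label <- labels
  out <- list(images = if (with_images) images else NULL, labels = labels,
              features = feature_table(df), spec = spec)
  class(out) <- "cohort"
  out
}
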