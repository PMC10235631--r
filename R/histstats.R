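#' Distribution summary of a texture map
#'
#' Shared machinery behind [fd_distribution_stats()] and
#' [entropy_distribution_stats()]: a fixed-width histogram, a sliding-window
#' mode, raw-value moments, and (optionally) the Shannon entropy of the values
#' requantized to 16 bits.
#'
#' The mode is the center of the sliding window (width `window_width`, moved
#' in steps of `window_step` over `[min, max]`) that maximises the mean count
#' of the histogram bins whose centers fall inside the window; ties take the
#' smallest center. Sigma is the sample standard deviation; skewness and
#' kurtosis are the raw-moment estimators `m3 / m2^(3/2)` and `m4 / m2^2`
#' (kurtosis in the non-excess convention, so a Gaussian gives 3).
#'
#' @param values Numeric vector (at least 2 finite values).
#' @param bin_width Histogram bin width (default 0.005).
#' @param window_width,window_step Sliding-window mode parameters
#'   (defaults 0.011 and 0.001).
#' @param with_entropy If `TRUE`, also compute `shannon_bits`, the entropy of
#'   the values linearly mapped to integers `0..65535` over their min-max
#'   range.
#' @return A `histogram_summary`: list with `mode`, `sigma`, `skewness`,
#'   `kurtosis`, `shannon_bits` (`NA` unless requested), `bin_width`, and a
#'   `flags` character vector naming statistics that were undefined and
#'   reported as 0.
#' @export
histogram_summary <- function(values, bin_width = 0.005,
                              window_width = 0.011, window_step = 0.001,
                              with_entropy = FALSE) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 finite values")
  flags <- character(0)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-15) {
    # all values identical: mode is that value, dispersion is zero,
    # skewness/kurtosis undefined and reported as 0
    return(structure(
      list(mode = lo, sigma = 0, skewness = 0, kurtosis = 0,
           shannon_bits = if (with_entropy) 0 else NA_real_,
           bin_width = bin_width,
           flags = c("skewness", "kurtosis")),
      class = "histogram_summary"
    ))
  }

  edges <- seq(lo, hi + bin_width, by = bin_width)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  centers <- edges[-length(edges)] + bin_width / 2
  wins <- seq(lo, hi, by = window_step)
  half <- window_width / 2
  # mean bin count inside each window position; ties -> smallest center
  first <- findInterval(wins - half - 1e-12, centers) + 1L
  last <- findInterval(wins + half + 1e-12, centers)
  cs <- c(0, cumsum(counts))
  nb <- pmax(last - first + 1L, 0L)
  mw <- ifelse(nb > 0L, (cs[pmax(last, 0L) + 1L] - cs[pmax(first - 1L, 0L) + 1L]) / nb, -Inf)
  mode <- wins[which.max(mw)]

  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  sigma <- sd(v)
  if (m2 < 1e-300) {
    skew <- 0; kurt <- 0
    flags <- c(flags, "skewness", "kurtosis")
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  }
  sh <- NA_real_
  if (with_entropy) {
    ints <- round((v - lo) / (hi - lo) * 65535)
    p <- tabulate(ints + 1L, nbins = 65536L)
    p <- p[p > 0L] / n
    sh <- -sum(p * log2(p))
  }
  structure(
    list(mode = mode, sigma = sigma, skewness = skew, kurtosis = kurt,
         shannon_bits = sh, bin_width = bin_width, flags = flags),
    class = "histogram_summary"
  )
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf(
    "<histogram_summary> mode %.4f, sigma %.4f, skew %.4f, kurt %.4f%s\n",
    x$mode, x$sigma, x$skewness, x$kurtosis,
    if (is.finite(x$shannon_bits)) sprintf(", entropy %.3f bits", x$shannon_bits) else ""
  ))
  if (length(x$flags)) cat("  undefined (reported as 0):",
                           paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
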