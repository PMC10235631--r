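#' Differential box-counting mass grid
#'
#' The image is quantized to 256 gray levels and tiled with non-overlapping
#' `r x r` boxes starting at grid offset `(dx, dy)`. Each box's gray range is
#' converted to a column count ("mass") by the differential box-counting
#' rule `M = floor(max / h) - floor(min / h) + 1` with box height
#' `h = 256 * r / min(W, H)`. Boxes that are not fully inside the image and
#' the ROI mask are skipped.
#'
#' @param img A [gray_image].
#' @param r Box size in pixels, `2 <= r <= min(dim) / 4`.
#' @param offset Integer grid offset `c(dx, dy)` with `0 <= dx, dy < r`
#'   (`dx` along columns, `dy` along rows).
#' @param mask Optional logical ROI matrix.
#' @return List with `mass` (vector of box masses), `h`, `r`, `offset`,
#'   `n_boxes`.
#' @export
dbc_mass_grid <- function(img, r, offset = c(0L, 0L), mask = NULL) {
  stopifnot(is_gray_image(img))
  q <- quantize_256(img)
  dbc_mass_grid_q(q, r, offset, mask)
}

# internal: operates on an already-quantized integer matrix
dbc_mass_grid_q <- function(q, r, offset = c(0L, 0L), mask = NULL) {
  nr <- nrow(q); nc <- ncol(q)
  r <- as.integer(r)
  if (r < 2L || r > min(nr, nc) / 4) stop("`r` must satisfy 2 <= r <= min(dim)/4")
  dx <- as.integer(offset[1L]); dy <- as.integer(offset[2L])
  if (dx < 0L || dy < 0L || dx >= r || dy >= r) stop("offset must be in [0, r)")
  nbr <- (nr - dy) %/% r
  nbc <- (nc - dx) %/% r
  if (nbr < 1L || nbc < 1L) stop("empty grid: no complete box fits")
  h <- 256 * r / min(nr, nc)

  bmax <- matrix(-Inf, nbr, nbc)
  bmin <- matrix(Inf, nbr, nbc)
  ball <- if (is.null(mask)) NULL else matrix(TRUE, nbr, nbc)
  rows0 <- dy + seq.int(1L, by = r, length.out = nbr)
  cols0 <- dx + seq.int(1L, by = r, length.out = nbc)
  for (i0 in 0:(r - 1L)) {
    for (j0 in 0:(r - 1L)) {
      sub <- q[rows0 + i0, cols0 + j0, drop = FALSE]
      bmax <- pmax(bmax, sub)
      bmin <- pmin(bmin, sub)
      if (!is.null(ball)) {
        ball <- ball & mask[rows0 + i0, cols0 + j0, drop = FALSE]
      }
    }
  }
  mass <- floor(bmax / h) - floor(bmin / h) + 1
  keep <- if (is.null(ball)) rep(TRUE, length(mass)) else as.vector(ball)
  mass <- as.vector(mass)[keep]
  if (!length(mass)) stop("empty grid: no complete box inside the ROI")
  list(mass = mass, h = h, r = r, offset = c(dx, dy), n_boxes = length(mass))
}

#' Lacunarity of one box grid
#'
#' `Lambda = E[M^2] / E[M]^2` over the box masses, equivalently
#' `sigma^2 / mu^2 + 1`; always `>= 1`, with equality iff all masses are
#' equal.
#'
#' @param masses Numeric vector of box masses (each `>= 1`), or the list
#'   returned by [dbc_mass_grid()].
#' @return Lacunarity (numeric scalar).
#' @export
lacunarity_single_offset <- function(masses) {
  if (is.list(masses)) masses <- masses$mass
  if (!length(masses)) stop("need at least one box")
  mean(masses^2) / mean(masses)^2
}

#' Offset-averaged differential box-counting lacunarity
#'
#' Lacunarity of the `r x r` box tiling, averaged over all `G = r^2` grid
#' offsets so the result does not depend on an arbitrary grid origin.
#'
#' @inheritParams dbc_mass_grid
#' @return A `lacunarity_result`: list with `box_size`, `per_offset`
#'   (length `r^2`), `mean_lac`, `n_offsets`.
#' @export
mean_lacunarity <- function(img, r, mask = NULL) {
  stopifnot(is_gray_image(img))
  q <- quantize_256(img)
  r <- as.integer(r)
  per <- numeric(0)
  for (dy in 0:(r - 1L)) {
    for (dx in 0:(r - 1L)) {
      g <- dbc_mass_grid_q(q, r, c(dx, dy), mask)
      per <- c(per, lacunarity_single_offset(g$mass))
    }
  }
  structure(
    list(box_size = r, per_offset = per, mean_lac = mean(per),
         n_offsets = length(per)),
    class = "lacunarity_result"
  )
}

#' @export
print.lacunarity_result <- function(x, ...) {
  cat(sprintf("<lacunarity_result> r = %d: mean lacunarity %.5f over %d offsets\n",
              x$box_size, x$mean_lac, x$n_offsets))
  invisible(x)
}
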