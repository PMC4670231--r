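#' Pixelated disc kernel
#'
#' The disc b(x, r) on the pixel lattice: all integer offsets (di, dj) whose
#' Euclidean centre-to-centre distance from the origin is at most `radius`
#' (boundary inclusive).  The same geometry is shared by the K-function, the
#' edge-correction factors and the morphological operations, so that "within
#' radius r" means the same thing everywhere in the package.
#'
#' @param radius positive radius in pixels (need not be an integer).
#' @return An object of class `disc_kernel`: `radius`, `offsets` (two-column
#'   integer matrix of (di, dj) pairs), `pixel_count` = |b(x, r)| for an
#'   unclipped disc, and `ideal_area` = pi r^2.
#' @examples
#' k <- disc_kernel(3)
#' k$pixel_count   # 29 lattice points, vs an ideal area of ~28.27
#' @export
disc_kernel <- function(radius) {
  check_scalar_number(radius, "radius", positive = TRUE)
  rmax <- floor(radius)
  g <- seq.int(-rmax, rmax)
  off <- expand.grid(di = g, dj = g)
  keep <- off$di^2 + off$dj^2 <= radius^2
  off <- as.matrix(off[keep, , drop = FALSE])
  storage.mode(off) <- "integer"
  rownames(off) <- NULL
  # column-run decomposition: for each column offset dj the disc covers the
  # contiguous row range [-hd, hd] with hd = floor(sqrt(r^2 - dj^2))
  dj <- seq.int(-rmax, rmax)
  hd <- as.integer(floor(sqrt(pmax(radius^2 - dj^2, 0))))
  structure(
    list(
      radius = radius,
      offsets = off,
      pixel_count = nrow(off),
      ideal_area = pi * radius^2,
      run_dj = as.integer(dj),
      run_hd = hd
    ),
    class = "disc_kernel"
  )
}

is_disc_kernel <- function(x) inherits(x, "disc_kernel")

as_disc_kernel <- function(x) {
  if (is_disc_kernel(x)) x else disc_kernel(x)
}

#' @export
print.disc_kernel <- function(x, ...) {
  cat(sprintf(
    "<disc_kernel> r = %g px: %d lattice points (ideal area %.3f px^2)\n",
    x$radius, x$pixel_count, x$ideal_area
  ))
  invisible(x)
}

# Sum of `mat` over the kernel offsets around every pixel, off-lattice
# neighbours counting 0.  For integer-valued input the result is rounded to
# the exact integer counts it represents.
disc_filter <- function(mat, kernel) {
  disc_sum_filter_runs(mat, kernel$run_dj, kernel$run_hd)
}

#' Clipped disc area within the study region
#'
#' A_xr: the number of mask-true pixels covered by the pixelated disc of the
#' kernel centred on pixel `x`.  Off-lattice positions count as outside the
#' study region.
#'
#' @param field a [gray_field()].
#' @param x integer vector of length 2, 1-based (row, column) pixel indices.
#' @param kernel a [disc_kernel()] or a radius.
#' @return Integer area in pixel^2.
#' @export
disc_area_in_mask <- function(field, x, kernel) {
  stopifnot(is_gray_field(field))
  kernel <- as_disc_kernel(kernel)
  if (length(x) != 2L || any(x != round(x)))
    stopf("'x' must be a pair of integer pixel indices")
  d <- dim(field$intensities)
  if (x[1] < 1 || x[1] > d[1] || x[2] < 1 || x[2] > d[2])
    stopf("pixel (%d, %d) is outside the %d x %d lattice", x[1], x[2], d[1], d[2])
  ii <- x[1] + kernel$offsets[, 1L]
  jj <- x[2] + kernel$offsets[, 2L]
  keep <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
  sum(field$mask[cbind(ii[keep], jj[keep])])
}

# Field-wide map of A_xr, computed as one disc filter over the mask.
disc_area_map <- function(mask, kernel) {
  m <- mask
  storage.mode(m) <- "double"
  disc_filter(m, kernel)
}
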