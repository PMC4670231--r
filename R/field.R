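#' Construct a grayscale particle field
#'
#' A `gray_field` is the object all statistics in grayK consume: a 2-D lattice
#' of non-negative integer intensities, read as particles per pixel, plus a
#' boolean mask delimiting the study region Omega.  Pixels outside the mask
#' contribute neither particles nor area: their intensity is forced to zero
#' and they are excluded from all sums and edge corrections.
#'
#' @param intensities numeric matrix of non-negative integers (particles per
#'   pixel).  For `bit_depth = 8` the saturation value is 255.
#' @param mask logical matrix of the same dimensions, `TRUE` inside the study
#'   region, or one of `"full"` (whole lattice, the default) and `"nonzero"`
#'   (study region = pixels with positive intensity, the convention for
#'   thresholded experimental images whose background was set to zero).
#' @param bit_depth integer; intensities must not exceed `2^bit_depth - 1`.
#' @return An object of class `gray_field` with elements `intensities`
#'   (integer-valued numeric matrix, zeroed outside the mask), `mask`
#'   (logical matrix) and `bit_depth`.
#' @examples
#' f <- gray_field(matrix(0:3, 2, 2))
#' omega_area(f)
#' @seealso [simulate_csr()], [ripley_k()]
#' @export
gray_field <- function(intensities, mask = "full", bit_depth = 8L) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stopf("'intensities' must be a numeric matrix")
  if (anyNA(intensities)) stopf("'intensities' must not contain NA")
  if (any(intensities < 0)) stopf("intensities must be non-negative")
  if (any(intensities != round(intensities)))
    stopf("intensities must be whole numbers (particles per pixel)")
  check_scalar_number(bit_depth, "bit_depth", positive = TRUE, integer = TRUE)
  sat <- 2^bit_depth - 1
  if (any(intensities > sat))
    stopf("intensities exceed the %d-bit saturation value %d", bit_depth, sat)
  mask <- resolve_mask(mask, intensities)
  x <- intensities
  x[!mask] <- 0
  storage.mode(x) <- "double"
  structure(
    list(intensities = x, mask = mask, bit_depth = as.integer(bit_depth)),
    class = "gray_field"
  )
}

resolve_mask <- function(mask, intensities) {
  if (is.character(mask) && length(mask) == 1L) {
    mask <- switch(mask,
      full = matrix(TRUE, nrow(intensities), ncol(intensities)),
      nonzero = intensities > 0,
      stopf("unknown mask policy '%s' (use 'full' or 'nonzero')", mask)
    )
  }
  if (!is.logical(mask) || !is.matrix(mask))
    stopf("'mask' must be a logical matrix or a policy name")
  if (!identical(dim(mask), dim(intensities)))
    stopf("'mask' dimensions must match 'intensities'")
  if (anyNA(mask)) stopf("'mask' must not contain NA")
  mask
}

is_gray_field <- function(x) inherits(x, "gray_field")

as_gray_field <- function(x, ...) {
  if (is_gray_field(x)) x else gray_field(x, ...)
}

#' Study-region area and total particle count
#'
#' `omega_area()` returns |Omega|, the number of mask-true pixels (pixel^2);
#' `total_particles()` returns n, the summed intensity over the study region.
#'
#' @param field a [gray_field()].
#' @return A single number.
#' @export
omega_area <- function(field) {
  stopifnot(is_gray_field(field))
  sum(field$mask)
}

#' @rdname omega_area
#' @export
total_particles <- function(field) {
  stopifnot(is_gray_field(field))
  sum(field$intensities)
}

#' @export
print.gray_field <- function(x, ...) {
  cat(sprintf(
    "<gray_field> %d x %d, %d-bit, |Omega| = %d px^2, n = %.0f particles\n",
    nrow(x$intensities), ncol(x$intensities), x$bit_depth,
    omega_area(x), total_particles(x)
  ))
  invisible(x)
}

#' @export
dim.gray_field <- function(x) dim(x$intensities)

#' Geometric transforms of a field
#'
#' Rotates (90 degrees counter-clockwise), transposes or mirrors both the
#' intensity lattice and the mask.  K and K-tilde are invariant under these.
#'
#' @param field a [gray_field()].
#' @return A transformed `gray_field`.
#' @keywords internal
#' @export
rotate_field <- function(field) {
  stopifnot(is_gray_field(field))
  rot <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  gray_field(rot(field$intensities), rot(field$mask), field$bit_depth)
}

#' @rdname rotate_field
#' @export
transpose_field <- function(field) {
  stopifnot(is_gray_field(field))
  gray_field(t(field$intensities), t(field$mask), field$bit_depth)
}

#' @rdname rotate_field
#' @export
flip_field <- function(field) {
  stopifnot(is_gray_field(field))
  fl <- function(m) m[nrow(m):1, , drop = FALSE]
  gray_field(fl(field$intensities), fl(field$mask), field$bit_depth)
}
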