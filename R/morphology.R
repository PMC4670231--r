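# Flat grayscale morphology on the pixelated disc (the same inclusive-disc
# geometry as disc_kernel, so "radius" means the same thing in the K-function
# and in granulometry).  Border handling: out-of-lattice neighbours are
# ignored unless an explicit pad value is given.

morph_offsets <- function(kernel) {
  kernel <- as_disc_kernel(kernel)
  kernel$offsets
}

gray_erode <- function(mat, kernel, pad = NA_real_) {
  off <- morph_offsets(kernel)
  disc_min_filter(mat, off[, 1L], off[, 2L], pad)
}

gray_dilate <- function(mat, kernel, pad = NA_real_) {
  off <- morph_offsets(kernel)
  disc_max_filter(mat, off[, 1L], off[, 2L], pad)
}

#' Grayscale opening with a disc structuring element
#'
#' Erosion followed by dilation with the pixelated disc of the given radius.
#' Opening is anti-extensive (output <= input) and removes bright structures
#' that cannot contain the disc.  Out-of-lattice neighbours are ignored
#' rather than padded, so a flat object touching the border is not eaten away
#' artificially.
#'
#' @param field a [gray_field()] or numeric matrix.
#' @param radius structuring-element radius in pixels; radius 0 is the
#'   identity.
#' @return A numeric matrix of the opened intensities.
#' @export
gray_open <- function(field, radius) {
  mat <- if (is_gray_field(field)) field$intensities else field
  if (radius == 0) return(mat)
  kernel <- disc_kernel(radius)
  gray_dilate(gray_erode(mat, kernel), kernel)
}

# Binary closing with edge padding: the outside of the lattice is treated as
# foreground during erosion, so objects touching the border are not opened
# up (the ImageJ "Close-" with edge padding behaviour).
binary_close <- function(mask, radius) {
  if (radius == 0) return(mask)
  kernel <- disc_kernel(radius)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  d <- gray_dilate(m, kernel)               # outside ignored
  e <- gray_erode(d, kernel, pad = 1)       # outside = foreground
  e > 0.5
}
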