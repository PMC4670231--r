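#' Simulate complete spatial randomness on a masked lattice
#'
#' Places exactly n particles, each independently uniform over the mask-true
#' pixels (multinomial occupancy), so per-pixel counts follow
#' Binomial(n, 1/|Omega|), the fixed-n analogue of a homogeneous Poisson
#' field.  Pixels clip at the bit-depth saturation value; clipped particles
#' are discarded with a warning.
#'
#' @param shape lattice dimensions `c(rows, cols)` (default 256 x 256).
#' @param density particles per pixel; n = round(density * |Omega|).  Give
#'   either `density` or `n`.
#' @param n exact total particle count (>= 2).
#' @param mask logical matrix (study region); default full lattice.
#' @param seed integer seed (required: all generators are reproducible).
#' @param bit_depth saturation bit depth, default 8 (clip at 255).
#' @return A [gray_field()].
#' @examples
#' f <- simulate_csr(c(128, 128), density = 1, seed = 7)
#' total_particles(f)  # exactly 128 * 128
#' @export
simulate_csr <- function(shape = c(256L, 256L), density = NULL, n = NULL,
                         mask = NULL, seed, bit_depth = 8L) {
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  if (!is.logical(mask) || !is.matrix(mask))
    stopf("'mask' must be a logical matrix")
  shape <- dim(mask)
  omega <- sum(mask)
  if (omega == 0) stopf("empty mask")
  if (is.null(n)) {
    if (is.null(density)) stopf("give either 'density' or 'n'")
    check_scalar_number(density, "density", positive = TRUE)
    n <- round(density * omega)
  }
  check_scalar_number(n, "n", integer = TRUE)
  if (n < 2) stopf("'n' must be at least 2 (got %d)", n)
  sat <- 2^bit_depth - 1
  if (n > sat * omega)
    stopf("cannot hold %d particles: %d pixels saturate at %d", n, omega, sat)
  counts <- with_seed(seed, tabulate(sample.int(omega, n, replace = TRUE),
                                     nbins = omega))
  clipped <- sum(pmax(counts - sat, 0))
  if (clipped > 0) {
    counts <- pmin(counts, sat)
    warning(sprintf("%d particle(s) discarded by %d-bit saturation clipping",
                    clipped, bit_depth), call. = FALSE)
  }
  x <- matrix(0, shape[1], shape[2])
  x[which(mask)] <- counts
  gray_field(x, mask, bit_depth)
}

#' Cluster-field generative parameters
#'
#' Describes a field of randomly located circular aggregates over a diffuse
#' (CSR) background.  The background has density B particles/pixel over the
#' whole field; aggregate pixels receive, on top of that, an expected added
#' signal density S = SBR * B, so their expected intensity is B * (1 + SBR).
#' The aggregate-to-diffuse ratio is ADR = (aggregate particles) /
#' (background particles) = SBR * |union of discs| / |field|.  Supply exactly
#' two of `n_clusters`, `sbr`, `adr`; the third is derived.
#'
#' @param shape lattice dimensions, default 256 x 256.
#' @param n_clusters number of aggregates N_agg.
#' @param cluster_radius aggregate radius r_agg in pixels (default 8).
#' @param sbr signal-to-background ratio (added signal density / background
#'   density).
#' @param adr aggregate-to-diffuse ratio.
#' @param background_density diffuse background density, particles/pixel.
#'   Zero means no diffuse pool: supply `n_clusters` and `aggregate_density`
#'   instead of SBR/ADR (which are infinite without a background).
#' @param aggregate_density with `background_density = 0` only: total
#'   aggregate particles per pixel of the whole field.
#' @return An object of class `cluster_spec` with all five quantities
#'   resolved (the derived member is computed from the disc geometry).
#' @seealso [simulate_clusters()]
#' @export
cluster_spec <- function(shape = c(256L, 256L), n_clusters = NULL,
                         cluster_radius = 8, sbr = NULL, adr = NULL,
                         background_density, aggregate_density = NULL) {
  check_scalar_number(cluster_radius, "cluster_radius", positive = TRUE)
  check_scalar_number(background_density, "background_density")
  if (background_density < 0) stopf("'background_density' must be >= 0")
  if (background_density == 0) {
    # no diffuse pool: all particles live in the aggregates
    if (is.null(n_clusters) || is.null(aggregate_density))
      stopf(paste0("with background_density = 0, supply 'n_clusters' and ",
                   "'aggregate_density' (SBR/ADR are infinite)"))
    check_scalar_number(n_clusters, "n_clusters", positive = TRUE,
                        integer = TRUE)
    check_scalar_number(aggregate_density, "aggregate_density",
                        positive = TRUE)
    return(structure(
      list(shape = as.integer(shape), n_clusters = as.integer(n_clusters),
           cluster_radius = cluster_radius, sbr = Inf, adr = Inf,
           background_density = 0, aggregate_density = aggregate_density),
      class = "cluster_spec"
    ))
  }
  if (!is.null(aggregate_density))
    stopf("'aggregate_density' is only meaningful with background_density = 0")
  given <- !c(n_clusters = is.null(n_clusters), sbr = is.null(sbr),
              adr = is.null(adr))
  if (sum(given) != 2L)
    stopf("supply exactly two of 'n_clusters', 'sbr', 'adr' (got %d)",
          sum(given))
  disc_px <- disc_kernel(cluster_radius)$pixel_count
  npix <- prod(shape)
  # Nominal relation (ignoring overlap of clusters): adr = sbr * N * disc / npix
  if (is.null(n_clusters)) {
    n_clusters <- round(adr * npix / (sbr * disc_px))
    if (n_clusters < 1)
      stopf("infeasible spec: derived n_clusters = %d (< 1) from ADR %.3g, SBR %.3g",
            n_clusters, adr, sbr)
  } else if (is.null(sbr)) {
    check_scalar_number(n_clusters, "n_clusters", integer = TRUE)
    if (adr > 0 && n_clusters < 1)
      stopf("infeasible spec: ADR > 0 requires at least one cluster")
    sbr <- if (adr == 0) 0 else adr * npix / (n_clusters * disc_px)
  } else {
    check_scalar_number(n_clusters, "n_clusters", integer = TRUE)
    adr <- sbr * n_clusters * disc_px / npix
  }
  if (sbr < 0 || adr < 0) stopf("'sbr' and 'adr' must be >= 0")
  if (background_density * (1 + sbr) > 255)
    stopf("infeasible spec: expected aggregate intensity %.1f exceeds saturation 255",
          background_density * (1 + sbr))
  structure(
    list(shape = as.integer(shape), n_clusters = as.integer(n_clusters),
         cluster_radius = cluster_radius, sbr = sbr, adr = adr,
         background_density = background_density, aggregate_density = NULL),
    class = "cluster_spec"
  )
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat(sprintf(
    "<cluster_spec> %d x %d, N_agg = %d, r_agg = %g px, SBR = %.3g, ADR = %.3g, background = %.3g /px\n",
    x$shape[1], x$shape[2], x$n_clusters, x$cluster_radius, x$sbr, x$adr,
    x$background_density))
  invisible(x)
}

#' Simulate circular aggregates over a diffuse pool
#'
#' Draws `n_clusters` disc centres uniformly, with every disc fully inside
#' the lattice (cluster-cluster overlap permitted).  Background particles are
#' placed CSR over the whole field (n_bg = round(B * |field|)); aggregate
#' particles are placed CSR within the union of the discs, with their count
#' set by the requested ADR (n_agg = round(ADR * n_bg)).  The realized
#' per-pixel expectation inside aggregates is therefore B * (1 + SBR) up to
#' the quantization of disc areas.
#'
#' @param spec a [cluster_spec()].
#' @param seed integer seed.
#' @return A list with elements `field` (a [gray_field()] on a full mask) and
#'   `truth` (logical matrix, TRUE inside the union of aggregate discs).
#' @examples
#' sp <- cluster_spec(c(128, 128), n_clusters = 5, sbr = 3,
#'                    background_density = 1)
#' sim <- simulate_clusters(sp, seed = 2)
#' mean(sim$field$intensities[sim$truth])   # ~ 4 x the outside mean
#' @export
simulate_clusters <- function(spec, seed) {
  if (!inherits(spec, "cluster_spec")) stopf("'spec' must be a cluster_spec")
  shape <- spec$shape
  npix <- prod(shape)
  n_bg <- round(spec$background_density * npix)
  n_agg <- if (spec$background_density == 0)
    round(spec$aggregate_density * npix) else round(spec$adr * n_bg)
  if (n_bg + n_agg < 2)
    stopf("infeasible spec: fewer than two particles in total")
  with_seed(seed, {
    truth <- matrix(FALSE, shape[1], shape[2])
    if (spec$n_clusters > 0 && n_agg > 0) {
      r <- spec$cluster_radius
      rmax <- floor(r)
      if (shape[1] - 2 * rmax < 1 || shape[2] - 2 * rmax < 1)
        stopf("clusters of radius %g do not fit inside a %d x %d lattice",
              r, shape[1], shape[2])
      off <- disc_kernel(r)$offsets
      ci <- sample.int(shape[1] - 2 * rmax, spec$n_clusters, replace = TRUE) + rmax
      cj <- sample.int(shape[2] - 2 * rmax, spec$n_clusters, replace = TRUE) + rmax
      for (k in seq_len(spec$n_clusters))
        truth[cbind(ci[k] + off[, 1L], cj[k] + off[, 2L])] <- TRUE
    }
    x <- matrix(0, shape[1], shape[2])
    if (n_bg > 0)
      x <- x + tabulate_counts(npix, n_bg, shape)
    if (n_agg > 0) {
      inside <- which(truth)
      if (!length(inside)) stopf("ADR > 0 but the truth mask is empty")
      add <- tabulate(sample.int(length(inside), n_agg, replace = TRUE),
                      nbins = length(inside))
      x[inside] <- x[inside] + add
    }
    clipped <- sum(pmax(x - 255, 0))
    if (clipped > 0) {
      x <- pmin(x, 255)
      warning(sprintf("%d particle(s) discarded by 8-bit saturation clipping",
                      clipped), call. = FALSE)
    }
    list(field = gray_field(x, "full"), truth = truth)
  })
}

tabulate_counts <- function(npix, n, shape) {
  matrix(tabulate(sample.int(npix, n, replace = TRUE), nbins = npix),
         shape[1], shape[2])
}

#' Simulate a field with several aggregate size classes
#'
#' The granulometry validation world: `n_per_class` randomly located circular
#' aggregates of each radius in `radii` (discs fully inside the lattice,
#' overlap permitted), over a CSR background of `background_density`
#' particles/pixel.  Each class receives aggregate particles at an expected
#' added density of `sbr * background_density` inside its discs, so every
#' aggregate shows the same contrast (1 + SBR) regardless of its size.
#'
#' @param radii aggregate radii in pixels (default the four classes 2, 4, 6,
#'   8).
#' @param n_per_class aggregates per size class (default 20).
#' @param sbr signal-to-background ratio.  Under `"equal_density"` it is the
#'   contrast of every class; under `"equal_mass"` it is the contrast of the
#'   largest class.
#' @param background_density background density, particles/pixel.
#' @param shape lattice dimensions.
#' @param seed integer seed.
#' @param allocation how the signal is split across size classes:
#'   `"equal_density"` (default) gives every class the same added per-pixel
#'   signal `sbr * background_density`, so class masses scale with disc
#'   area; `"equal_mass"` gives every class the same total signal mass
#'   (that of the largest class under equal density), so smaller aggregates
#'   are proportionally brighter and each class registers a comparable
#'   granulometric trough.
#' @param deposition `"particles"` (default) deposits the signal as randomly
#'   placed particles (multinomial occupancy, Poisson-like texture inside
#'   aggregates); `"flat"` adds the signal as a deterministic flat pedestal —
#'   aggregate pixels take the value signal-plus-background exactly, which is
#'   what flat-disc granulometry assumes.
#' @return List with `field` (a [gray_field()]), `truth` (logical union of
#'   all aggregate discs) and `class_truth` (list of per-radius logical
#'   masks, named by radius).
#' @export
simulate_size_classes <- function(radii = c(2, 4, 6, 8), n_per_class = 20,
                                  sbr, background_density,
                                  shape = c(256L, 256L), seed,
                                  allocation = c("equal_density",
                                                 "equal_mass"),
                                  deposition = c("particles", "flat")) {
  allocation <- match.arg(allocation)
  deposition <- match.arg(deposition)
  check_scalar_number(sbr, "sbr")
  check_scalar_number(background_density, "background_density",
                      positive = TRUE)
  npix <- prod(shape)
  with_seed(seed, {
    class_truth <- list()
    x <- tabulate_counts(npix, round(background_density * npix), shape)
    for (r in radii) {
      off <- disc_kernel(r)$offsets
      rmax <- floor(r)
      truth_r <- matrix(FALSE, shape[1], shape[2])
      ci <- sample.int(shape[1] - 2 * rmax, n_per_class, replace = TRUE) + rmax
      cj <- sample.int(shape[2] - 2 * rmax, n_per_class, replace = TRUE) + rmax
      for (k in seq_len(n_per_class))
        truth_r[cbind(ci[k] + off[, 1L], cj[k] + off[, 2L])] <- TRUE
      inside <- which(truth_r)
      n_sig <- if (allocation == "equal_density")
        round(sbr * background_density * length(inside))
      else
        round(sbr * background_density * n_per_class *
                disc_kernel(max(radii))$pixel_count)
      if (n_sig > 0) {
        if (deposition == "flat") {
          x[inside] <- x[inside] + round(n_sig / length(inside))
        } else {
          add <- tabulate(sample.int(length(inside), n_sig, replace = TRUE),
                          nbins = length(inside))
          x[inside] <- x[inside] + add
        }
      }
      class_truth[[as.character(r)]] <- truth_r
    }
    clipped <- sum(pmax(x - 255, 0))
    if (clipped > 0) {
      x <- pmin(x, 255)
      warning(sprintf("%d particle(s) discarded by 8-bit saturation clipping",
                      clipped), call. = FALSE)
    }
    truth <- Reduce(`|`, class_truth)
    list(field = gray_field(x, "full"), truth = truth,
         class_truth = class_truth)
  })
}

#' Confocal microscope degradation parameters
#'
#' A truncated, normalized Gaussian point-spread function plus per-pixel
#' Poisson noise.  The Poisson rule (each pixel replaced by a draw with
#' lambda equal to its value) leaves no free noise amplitude, so SNR is a
#' derived diagnostic, not an input: with mean signal density S over a mean
#' background B, `snr_estimate()` reports S / sqrt(S + B).
#'
#' @param psf_diameter odd kernel diameter in pixels (default 3).
#' @param psf_sigma Gaussian sigma in pixels (default 1).
#' @return An object of class `microscope_spec`.
#' @export
microscope_spec <- function(psf_diameter = 3L, psf_sigma = 1) {
  check_scalar_number(psf_diameter, "psf_diameter", positive = TRUE,
                      integer = TRUE)
  if (psf_diameter %% 2 == 0) stopf("'psf_diameter' must be odd")
  check_scalar_number(psf_sigma, "psf_sigma", positive = TRUE)
  structure(list(psf_diameter = as.integer(psf_diameter),
                 psf_sigma = psf_sigma),
            class = "microscope_spec")
}

#' @rdname microscope_spec
#' @param signal_density mean added signal density S inside aggregates.
#' @param background_density mean background density B.
#' @export
snr_estimate <- function(signal_density, background_density) {
  signal_density / sqrt(signal_density + background_density)
}

gaussian_psf_kernel <- function(diameter, sigma) {
  h <- (diameter - 1) / 2
  g <- seq.int(-h, h)
  k <- exp(-outer(g^2, g^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

#' Apply a Gaussian point-spread function
#'
#' Convolves the intensity lattice with a normalized truncated Gaussian
#' (reflect-padded at the boundary), rounds to integer counts and clips to
#' the 8-bit range.  A constant field passes through unchanged.
#'
#' @param field a [gray_field()].
#' @param spec a [microscope_spec()].
#' @return A blurred [gray_field()] (mask unchanged).
#' @export
apply_psf <- function(field, spec = microscope_spec()) {
  field <- as_gray_field(field)
  if (!inherits(spec, "microscope_spec")) stopf("'spec' must be a microscope_spec")
  k <- gaussian_psf_kernel(spec$psf_diameter, spec$psf_sigma)
  h <- (spec$psf_diameter - 1) / 2
  x <- field$intensities
  nr <- nrow(x); nc <- ncol(x)
  ridx <- c(h:1, 1:nr, nr:(nr - h + 1))
  cidx <- c(h:1, 1:nc, nc:(nc - h + 1))
  xp <- x[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (a in seq_len(spec$psf_diameter))
    for (b in seq_len(spec$psf_diameter))
      out <- out + k[a, b] * xp[(a - 1) + 1:nr, (b - 1) + 1:nc]
  out <- pmin(pmax(round(out), 0), 2^field$bit_depth - 1)
  gray_field(out, field$mask, field$bit_depth)
}

#' Apply per-pixel Poisson noise
#'
#' Replaces every pixel by a Poisson draw with lambda equal to the pixel's
#' intensity (independent across pixels), then clips at saturation.  Zero
#' pixels remain zero.
#'
#' @param field a [gray_field()].
#' @param seed integer seed.
#' @return A noisy [gray_field()] (mask unchanged).
#' @export
apply_poisson_noise <- function(field, seed) {
  field <- as_gray_field(field)
  x <- field$intensities
  y <- with_seed(seed, rpois(length(x), lambda = as.vector(x)))
  y <- matrix(pmin(y, 2^field$bit_depth - 1), nrow(x), ncol(x))
  gray_field(y, field$mask, field$bit_depth)
}

#' Decimation parameters
#'
#' Circular holes punched out of the study region, used to test shape
#' invariance of K-tilde: the decimated pixels are outside the mask, creating
#' internal edges.
#'
#' @param n_decimations number of circular holes.
#' @param decimation_radius hole radius in pixels (default 20).
#' @param min_offset minimum gap between hole boundaries, pixels (default 1);
#'   centres are rejection-sampled so holes lie fully inside the lattice and
#'   pairwise centre distances are at least `2 * decimation_radius +
#'   min_offset`.
#' @return An object of class `decimation_spec`.
#' @export
decimation_spec <- function(n_decimations, decimation_radius = 20,
                            min_offset = 1) {
  check_scalar_number(n_decimations, "n_decimations", integer = TRUE)
  if (n_decimations < 0) stopf("'n_decimations' must be >= 0")
  check_scalar_number(decimation_radius, "decimation_radius", positive = TRUE)
  check_scalar_number(min_offset, "min_offset")
  structure(list(n_decimations = as.integer(n_decimations),
                 decimation_radius = decimation_radius,
                 min_offset = min_offset),
            class = "decimation_spec")
}

#' Simulate CSR on a randomly decimated study region
#'
#' Scatters circular decimations (holes) across the lattice, removes them
#' from the study region, then distributes particles CSR over the remaining
#' mask.  Intensities inside decimations are zero and those pixels are
#' ignored by all statistics (including edge correction).
#'
#' @inheritParams simulate_csr
#' @param spec a [decimation_spec()].
#' @param max_attempts rejection-sampling budget for hole placement.
#' @return A [gray_field()] whose mask excludes the decimations.
#' @export
simulate_decimated_csr <- function(shape = c(256L, 256L), density, spec, seed,
                                   max_attempts = 10000L) {
  if (!inherits(spec, "decimation_spec")) stopf("'spec' must be a decimation_spec")
  mask <- with_seed(derive_seed(seed, 1L),
                    decimation_mask(shape, spec, max_attempts))
  simulate_csr(shape, density = density, mask = mask,
               seed = derive_seed(seed, 2L))
}

decimation_mask <- function(shape, spec, max_attempts = 10000L) {
  mask <- matrix(TRUE, shape[1], shape[2])
  if (spec$n_decimations == 0) return(mask)
  r <- spec$decimation_radius
  rmax <- floor(r)
  if (shape[1] - 2 * rmax < 1 || shape[2] - 2 * rmax < 1)
    stopf("decimations of radius %g do not fit in a %d x %d lattice",
          r, shape[1], shape[2])
  dmin2 <- (2 * r + spec$min_offset)^2
  centres <- matrix(NA_real_, 0, 2)
  attempts <- 0L
  while (nrow(centres) < spec$n_decimations) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("failed to place %d decimations of radius %g after %d attempts",
            spec$n_decimations, r, max_attempts)
    ci <- sample.int(shape[1] - 2 * rmax, 1L) + rmax
    cj <- sample.int(shape[2] - 2 * rmax, 1L) + rmax
    if (nrow(centres) &&
        any((centres[, 1] - ci)^2 + (centres[, 2] - cj)^2 < dmin2)) next
    centres <- rbind(centres, c(ci, cj))
  }
  off <- disc_kernel(r)$offsets
  for (k in seq_len(nrow(centres)))
    mask[cbind(centres[k, 1] + off[, 1L], centres[k, 2] + off[, 2L])] <- FALSE
  mask
}
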