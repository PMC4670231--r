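EDGE_METHODS <- c("full_field", "ideal_border", "pixelated_border")

check_edge_method <- function(method) {
  match.arg(method, EDGE_METHODS)
}

# Field-wide edge-correction factors c_x for every mask-true pixel, given the
# clipped-area map A.  Pixels outside the mask get NA.
edge_correction_map <- function(mask, kernel, method, A = NULL) {
  method <- check_edge_method(method)
  if (is.null(A)) A <- disc_area_map(mask, kernel)
  cmap <- matrix(NA_real_, nrow(mask), ncol(mask))
  inside <- mask
  border <- inside & (A < kernel$pixel_count)
  if (method == "full_field") {
    cmap[inside] <- kernel$ideal_area / A[inside]
  } else {
    cmap[inside] <- 1
    num <- if (method == "ideal_border") kernel$ideal_area else kernel$pixel_count
    cmap[border] <- num / A[border]
  }
  cmap
}

#' Besag edge-correction factor at a pixel
#'
#' Three implementations of Besag's correction are supported.  For the two
#' border-only methods, a border pixel is one whose pixelated disc is clipped
#' by the study region (A_xr < |b(x, r)|), which covers both the lattice
#' margin and holes created by decimation:
#' \describe{
#'   \item{`ideal_border`}{pi r^2 / A_xr at border pixels, 1 elsewhere.}
#'   \item{`pixelated_border`}{|b(x, r)| / A_xr at border pixels, 1 elsewhere.}
#'   \item{`full_field`}{pi r^2 / A_xr at every pixel — the correction that
#'     keeps K-tilde centred at high densities, because it also compensates
#'     the pixelated disc's deficit relative to an ideal circle.}
#' }
#'
#' @inheritParams disc_area_in_mask
#' @param method one of `"full_field"`, `"ideal_border"`,
#'   `"pixelated_border"`.
#' @return A positive scalar correction factor.
#' @export
edge_correction_factor <- function(field, x, kernel,
                                   method = c("full_field", "ideal_border",
                                              "pixelated_border")) {
  method <- match.arg(method)
  kernel <- as_disc_kernel(kernel)
  A <- disc_area_in_mask(field, x, kernel)
  if (A == 0)
    stopf("pixel (%d, %d) lies outside the study region (A_xr = 0)", x[1], x[2])
  if (method == "full_field") return(kernel$ideal_area / A)
  if (A >= kernel$pixel_count) return(1)
  if (method == "ideal_border") kernel$ideal_area / A else kernel$pixel_count / A
}

#' Grayscale Ripley K-function
#'
#' Treats each intensity unit as one particle.  With P_x the intensity at
#' pixel x, n the total intensity over the study region Omega and c_x the
#' edge-correction factor,
#' \deqn{K(r, n) = \frac{|\Omega|}{n(n-1)} \sum_x c_x P_x
#'       \Big(P_x - 1 + \sum_{y \ne x,\, d_{xy} \le r} P_y\Big),}
#' the inner sum running over mask-true pixels within Euclidean distance r.
#' Co-resident particles are distance 0 apart, hence the within-pixel term
#' P_x - 1.  Under complete spatial randomness E[K] = pi r^2.  For binary
#' fields this reduces to the classic point-pattern K with Besag correction.
#'
#' The inner sum is evaluated as a linear disc filter of the masked intensity
#' image; because all quantities are integer counts, the filtered values are
#' exact and the result matches a direct double sum to floating-point
#' round-off.
#'
#' @param field a [gray_field()] (or an intensity matrix, coerced with a full
#'   mask).
#' @param kernel a [disc_kernel()] or a radius in pixels.
#' @param method edge-correction method, see [edge_correction_factor()].
#' @return K(r, n) in pixel^2.
#' @examples
#' f <- simulate_csr(c(64, 64), density = 1, seed = 1)
#' ripley_k(f, 5)          # close to pi * 25 under CSR
#' @export
ripley_k <- function(field, kernel,
                     method = c("full_field", "ideal_border",
                                "pixelated_border")) {
  method <- match.arg(method)
  field <- as_gray_field(field)
  kernel <- as_disc_kernel(kernel)
  omega <- omega_area(field)
  if (omega == 0) stopf("empty study region: the mask has no TRUE pixel")
  n <- total_particles(field)
  if (n < 2) stopf("fewer than two particles (n = %.0f)", n)
  P <- field$intensities
  C <- disc_filter(P, kernel)            # particles within r, centre included
  A <- disc_area_map(field$mask, kernel)
  cmap <- edge_correction_map(field$mask, kernel, method, A = A)
  idx <- field$mask & P > 0
  contrib <- cmap[idx] * P[idx] * (C[idx] - 1)
  omega / (n * (n - 1)) * sum(contrib)
}

#' Monte-Carlo CSR reference distribution for K
#'
#' Draws `replicates` complete-spatial-randomness fields with exactly `n`
#' particles on the masked lattice (multinomial occupancy, matching the
#' conditioning of K-tilde on the observed total intensity), computes K for
#' each, and summarizes the null distribution: moments, the empirical 1st and
#' 99th percentiles of K-tilde = (K - pi r^2) / sd(K), and their first-order
#' Cornish-Fisher approximants
#' \deqn{q_p \approx z_p + (z_p^2 - 1)\,\gamma/6}
#' built from the Monte-Carlo skewness.  Replicate i derives its RNG stream
#' from (seed, i), so the whole object regenerates bit-identically.
#'
#' @param mask logical matrix delimiting the study region, or a
#'   [gray_field()] whose mask is used.
#' @param n total particle count to condition on (>= 2).
#' @param kernel a [disc_kernel()] or radius.
#' @inheritParams ripley_k
#' @param replicates number of Monte-Carlo simulations B (>= 100).
#' @param seed integer seed.
#' @param bit_depth saturation assumed when placing particles (default 8).
#' @return An object of class `csr_reference` with fields `mask_signature`,
#'   `n`, `radius`, `edge_method`, `replicates`, `seed`, `mean_k`, `var_k`,
#'   `skew_k`, `q01_empirical`, `q99_empirical`, `q01_cf`, `q99_cf`.
#' @examples
#' ref <- csr_reference(matrix(TRUE, 32, 32), n = 1024, kernel = 3,
#'                      replicates = 100, seed = 1)
#' ref$mean_k / (pi * 9)   # ~ 1 under CSR
#' @export
csr_reference <- function(mask, n, kernel,
                          method = c("full_field", "ideal_border",
                                     "pixelated_border"),
                          replicates = 1000, seed, bit_depth = 8L) {
  method <- match.arg(method)
  if (is_gray_field(mask)) mask <- mask$mask
  if (!is.logical(mask) || !is.matrix(mask))
    stopf("'mask' must be a logical matrix or a gray_field")
  kernel <- as_disc_kernel(kernel)
  check_scalar_number(n, "n", positive = TRUE, integer = TRUE)
  if (n < 2) stopf("'n' must be at least 2")
  check_scalar_number(replicates, "replicates", positive = TRUE, integer = TRUE)
  if (replicates < 100) stopf("'replicates' must be at least 100")
  if (missing(seed)) stopf("'seed' is required: CSR references must be reproducible")
  sat <- 2^bit_depth - 1
  if (n > sat * sum(mask))
    stopf("mask cannot hold %d particles at saturation %d", n, sat)
  ks <- csr_k_samples(mask, n, kernel$radius, method, replicates, seed,
                      bit_depth)[, 1L, 1L]
  summarize_csr_reference(ks, mask, n, kernel, method, replicates, seed)
}

# Precomputed per-(mask, kernel, method) quantities for Monte-Carlo loops:
# correction weights over the mask pixels plus the normalization.
k_context <- function(mask, kernel, method) {
  A <- disc_area_map(mask, kernel)
  cmap <- edge_correction_map(mask, kernel, method, A = A)
  idx <- which(mask)
  list(idx = idx, weights = cmap[idx], omega = length(idx))
}

#' Monte-Carlo K samples under CSR, batched over radii and methods
#'
#' Simulates `replicates` fixed-n CSR fields on the mask and evaluates K for
#' every combination of radius and edge method, sharing each simulated field
#' across all combinations: the disc filter is computed once per radius, and
#' the edge methods differ only in their per-pixel weights.  Replicate i
#' derives its RNG stream from (seed, i), so any sub-battery reproduces the
#' corresponding values of a larger run.
#'
#' @inheritParams csr_reference
#' @param radii vector of radii in pixels.
#' @param methods character vector of edge-correction methods.
#' @return Numeric array `[replicate, radius, method]` of K values (pixel^2),
#'   with dimnames on the radius and method margins.
#' @export
csr_k_samples <- function(mask, n, radii, methods = "full_field",
                          replicates, seed, bit_depth = 8L) {
  if (is_gray_field(mask)) mask <- mask$mask
  methods <- vapply(methods, check_edge_method, character(1),
                    USE.NAMES = FALSE)
  kernels <- lapply(radii, disc_kernel)
  weights <- lapply(kernels, function(k)
    lapply(methods, function(m) k_context(mask, k, m)$weights))
  idx <- which(mask)
  omega <- length(idx)
  sat <- 2^bit_depth - 1
  dims <- dim(mask)
  out <- array(NA_real_, c(replicates, length(radii), length(methods)),
               dimnames = list(NULL, paste0("r", radii), methods))
  scale <- omega / (n * (n - 1))
  for (i in seq_len(replicates)) {
    counts <- with_seed(derive_seed(seed, i),
                        tabulate(sample.int(omega, n, replace = TRUE),
                                 nbins = omega))
    if (any(counts > sat)) counts <- pmin(counts, sat)
    P <- matrix(0, dims[1], dims[2])
    P[idx] <- counts
    Pm <- P[idx]
    for (a in seq_along(radii)) {
      C1 <- disc_filter(P, kernels[[a]])[idx] - 1
      for (b in seq_along(methods))
        out[i, a, b] <- scale * sum(weights[[a]][[b]] * Pm * C1)
    }
  }
  out
}

summarize_csr_reference <- function(ks, mask, n, kernel, method, replicates, seed) {
  mu <- mean(ks)
  v <- var(ks)
  s <- sd(ks)
  skew <- if (s > 0) mean((ks - mu)^3) / s^3 else 0
  kt <- (ks - kernel$ideal_area) / s
  q_emp <- quantile(kt, c(0.01, 0.99), names = FALSE, type = 7)
  q_cf <- cornish_fisher_quantile(c(0.01, 0.99), skew)
  structure(
    list(
      mask_signature = mask_signature(mask),
      n = as.integer(n),
      radius = kernel$radius,
      edge_method = method,
      replicates = as.integer(replicates),
      seed = as.integer(seed),
      mean_k = mu, var_k = v, skew_k = skew,
      q01_empirical = q_emp[1], q99_empirical = q_emp[2],
      q01_cf = q_cf[1], q99_cf = q_cf[2]
    ),
    class = "csr_reference"
  )
}

#' First-order Cornish-Fisher quantile approximant
#'
#' q_p = z_p + (z_p^2 - 1) * skewness / 6, the first skewness correction to a
#' normal quantile; with zero skewness it reduces to z_p.
#'
#' @param p probability (vectorized).
#' @param skewness standardized third moment of the null distribution.
#' @return Approximate quantiles of the centred, scaled statistic.
#' @export
cornish_fisher_quantile <- function(p, skewness) {
  z <- qnorm(p)
  z + (z^2 - 1) * skewness / 6
}

#' @export
print.csr_reference <- function(x, ...) {
  cat(sprintf(
    paste0("<csr_reference> r = %g px, n = %d, %s, B = %d (seed %d)\n",
           "  E[K] = %.3f (pi r^2 = %.3f), sd = %.3f, skew = %.3f\n",
           "  K-tilde quantiles: empirical [%.3f, %.3f], Cornish-Fisher [%.3f, %.3f]\n"),
    x$radius, x$n, x$edge_method, x$replicates, x$seed,
    x$mean_k, pi * x$radius^2, sqrt(x$var_k), x$skew_k,
    x$q01_empirical, x$q99_empirical, x$q01_cf, x$q99_cf
  ))
  invisible(x)
}

# Shared validation for operations that pair a field with a reference.
check_reference_match <- function(field, kernel, method, reference,
                                  n_tol = 0) {
  if (!inherits(reference, "csr_reference"))
    stopf("'reference' must be a csr_reference")
  if (!isTRUE(all.equal(reference$radius, kernel$radius)))
    stopf("reference radius (%g) does not match kernel radius (%g)",
          reference$radius, kernel$radius)
  if (!identical(reference$edge_method, method))
    stopf("reference edge method ('%s') does not match '%s'",
          reference$edge_method, method)
  if (!identical(reference$mask_signature, mask_signature(field$mask)))
    stopf("reference mask geometry does not match the field's mask")
  n <- total_particles(field)
  if (abs(n - reference$n) > n_tol * reference$n)
    stopf(paste0("reference n (%d) does not match field n (%.0f); ",
                 "K-tilde is only comparable under a matched null"),
          reference$n, n)
  invisible(TRUE)
}

#' Centered, variance-normalized K (K-tilde)
#'
#' K-tilde = (K(r, n) - pi r^2) / sqrt(var{K(r, n)}), where the variance is
#' the Monte-Carlo estimate held by a matched [csr_reference()].  The
#' centering constant is the analytic CSR expectation pi r^2, not the
#' Monte-Carlo mean (which is diagnostic only).  Under CSR, K-tilde has mean
#' 0 and unit variance; values outside the reference's critical quantiles
#' indicate clustering (above) or dispersion (below).
#'
#' @inheritParams ripley_k
#' @param reference a [csr_reference()] matched to the field's mask geometry,
#'   total intensity, radius and edge method.
#' @param n_tol relative tolerance on the match between the field's n and the
#'   reference's n.  Default 0 (exact).  A small tolerance (e.g. 0.05) is
#'   legitimate when noise perturbs n and var{K} varies slowly with n.
#' @return Dimensionless K-tilde.
#' @export
ktilde <- function(field, kernel,
                   method = c("full_field", "ideal_border", "pixelated_border"),
                   reference, n_tol = 0) {
  method <- match.arg(method)
  field <- as_gray_field(field)
  kernel <- as_disc_kernel(kernel)
  check_reference_match(field, kernel, method, reference, n_tol)
  if (reference$var_k <= 0) stopf("reference has non-positive variance")
  (ripley_k(field, kernel, method) - kernel$ideal_area) / sqrt(reference$var_k)
}

#' Relative error of Cornish-Fisher quantiles vs the empirical ones
#'
#' @param reference a [csr_reference()].
#' @return Named numeric vector `c(q01 = ..., q99 = ...)` of
#'   |CF - empirical| / |empirical|, as fractions.
#' @export
quantile_relative_error <- function(reference) {
  if (!inherits(reference, "csr_reference"))
    stopf("'reference' must be a csr_reference")
  if (reference$q01_empirical == 0 || reference$q99_empirical == 0)
    stopf("degenerate null: an empirical quantile is exactly zero")
  c(
    q01 = abs(reference$q01_cf - reference$q01_empirical) /
      abs(reference$q01_empirical),
    q99 = abs(reference$q99_cf - reference$q99_empirical) /
      abs(reference$q99_empirical)
  )
}

#' K and K-tilde over a radius sweep
#'
#' Computes K(r) and K-tilde(r) for each radius independently, using one
#' matched [csr_reference()] per radius.
#'
#' @inheritParams ripley_k
#' @param radii increasing vector of radii in pixels.
#' @param references list of [csr_reference()] objects, one per radius, each
#'   matched to the field.
#' @param n_tol relative tolerance on the n match, see [ktilde()].
#' @return An object of class `k_profile`: `radii`, `k_values`,
#'   `ktilde_values`, `n`, `omega_area`, `edge_method`.
#' @export
k_profile <- function(field, radii,
                      method = c("full_field", "ideal_border",
                                 "pixelated_border"),
                      references, n_tol = 0) {
  method <- match.arg(method)
  field <- as_gray_field(field)
  if (length(radii) && any(diff(radii) <= 0))
    stopf("'radii' must be strictly increasing")
  if (length(references) != length(radii))
    stopf("need one reference per radius (%d references for %d radii)",
          length(references), length(radii))
  kv <- numeric(length(radii))
  ktv <- numeric(length(radii))
  for (i in seq_along(radii)) {
    kernel <- disc_kernel(radii[i])
    check_reference_match(field, kernel, method, references[[i]], n_tol)
    kv[i] <- ripley_k(field, kernel, method)
    ktv[i] <- (kv[i] - kernel$ideal_area) / sqrt(references[[i]]$var_k)
  }
  new_k_profile(radii, kv, ktv, total_particles(field), omega_area(field),
                method)
}

new_k_profile <- function(radii, k_values, ktilde_values, n, omega, method) {
  structure(
    list(
      radii = as.numeric(radii),
      k_values = as.numeric(k_values),
      ktilde_values = as.numeric(ktilde_values),
      n = n,
      omega_area = omega,
      edge_method = method
    ),
    class = "k_profile"
  )
}

#' @export
print.k_profile <- function(x, ...) {
  cat(sprintf("<k_profile> %d radii (%s), n = %.0f, |Omega| = %d, %s\n",
              length(x$radii),
              if (length(x$radii)) sprintf("%g..%g px", min(x$radii), max(x$radii))
              else "empty",
              x$n, x$omega_area, x$edge_method))
  if (length(x$radii))
    print(data.frame(radius = x$radii, k = x$k_values,
                     ktilde = x$ktilde_values), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.k_profile <- function(x, ...) {
  data.frame(radius = x$radii, k = x$k_values, ktilde = x$ktilde_values)
}

#' Radius of maximal K-tilde
#'
#' The radius at which the K-tilde profile attains its maximum; ties are
#' broken toward the smallest radius (a conservative cluster-size estimate).
#' In binary point patterns this radius tracks the true aggregate radius
#' r_agg (landing between r_agg and 2 r_agg); at very high particle densities
#' with a diffuse pool that correspondence breaks down.
#'
#' @param profile a [k_profile()].
#' @return A radius in pixels.
#' @export
kmax_radius <- function(profile) {
  if (!inherits(profile, "k_profile")) stopf("'profile' must be a k_profile")
  if (!length(profile$radii)) stopf("empty profile")
  profile$radii[which.max(profile$ktilde_values)]
}
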