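#' Granulometric profile of a field
#'
#' Opens the image with pixelated discs of increasing radius and records the
#' total retained intensity at each radius (radius 0 = raw sum).  Because
#' opening is anti-extensive and increasing in the structuring element, the
#' sums are nonincreasing; troughs in the first differences mark dominant
#' object sizes: a flat disc-shaped object of radius rho survives openings up
#' to rho and vanishes at rho + 1, so its mass drops at that step.
#'
#' @param field a [gray_field()] or numeric matrix.
#' @param max_radius largest structuring-element radius (integer >= 1).
#' @return An object of class `granulometric_profile`: `radii` (0:max_radius),
#'   `sums` (total intensity of the opened image), and `derivative`
#'   (first differences, indexed by the upper radius of each step).
#' @export
granulometric_profile <- function(field, max_radius) {
  check_scalar_number(max_radius, "max_radius", positive = TRUE, integer = TRUE)
  mat <- if (is_gray_field(field)) field$intensities else field
  radii <- 0:max_radius
  sums <- numeric(length(radii))
  sums[1] <- sum(mat)
  for (r in seq_len(max_radius)) sums[r + 1] <- sum(gray_open(mat, r))
  structure(
    list(radii = radii, sums = sums, derivative = diff(sums)),
    class = "granulometric_profile"
  )
}

#' @export
print.granulometric_profile <- function(x, ...) {
  cat(sprintf("<granulometric_profile> radii 0..%d\n", max(x$radii)))
  print(data.frame(radius = x$radii, sum = x$sums,
                   derivative = c(NA, x$derivative)), row.names = FALSE)
  invisible(x)
}

# Prominence of local minima of a 1-D signal: depth of each minimum relative
# to the lower of the two highest barriers separating it from deeper minima
# (the standard peak-prominence definition applied to the negated signal).
minima_prominence <- function(y) {
  n <- length(y)
  # interior minima only: an endpoint is a boundary effect, not a trough
  is_min <- vapply(seq_len(n), function(i) {
    if (i == 1 || i == n) return(FALSE)
    y[i] < y[i - 1] && y[i] <= y[i + 1]  # plateau tie resolves to its left edge
  }, logical(1))
  idx <- which(is_min)
  prom <- vapply(idx, function(i) {
    lo <- y[i]
    # walk left until a lower value; barrier = max in between
    lbar <- Inf
    if (i > 1) {
      seg <- y[seq_len(i - 1)]
      lower <- which(seg < lo)
      lbar <- if (length(lower)) max(seg[(max(lower) + 1):(i - 1)], lo)
              else max(seg)
    }
    rbar <- Inf
    if (i < n) {
      seg <- y[(i + 1):n]
      lower <- which(seg < lo)
      rbar <- if (length(lower)) max(seg[seq_len(min(lower) - 1)], lo)
              else max(seg)
    }
    min(lbar, rbar) - lo
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Detect major troughs in a granulometric derivative
#'
#' Local minima of the first-difference curve whose prominence is at least a
#' fraction of the derivative's total range.  Trough radii are reported on
#' the upper-radius convention of the profile's derivative, so a flat disc of
#' radius rho produces a trough at rho + 1.
#'
#' @param profile a [granulometric_profile()].
#' @param prominence minimum prominence; default 5% of the derivative range.
#' @return Increasing integer vector of trough radii (possibly empty).
#' @export
detect_troughs <- function(profile, prominence = NULL) {
  if (!inherits(profile, "granulometric_profile"))
    stopf("'profile' must be a granulometric_profile")
  d <- profile$derivative
  if (length(d) < 3) stopf("profile needs at least 3 radii to detect troughs")
  rng <- diff(range(d))
  if (rng == 0) return(integer(0))
  if (is.null(prominence)) prominence <- 0.05 * rng
  mp <- minima_prominence(d)
  keep <- mp$prominence >= prominence
  sort(profile$radii[-1][mp$index[keep]])
}

#' Extract one size class of objects
#'
#' Difference of openings: `open(field, radius) - open(field, radius + 1)`,
#' which isolates structures that survive an opening at `radius` but not at
#' `radius + 1` — i.e. objects of that disc size.
#'
#' @param field a [gray_field()] or matrix.
#' @param radius integer size-class radius (>= 1).
#' @return A [gray_field()] of the extracted (non-negative) intensities.
#' @export
extract_size_class <- function(field, radius) {
  check_scalar_number(radius, "radius", positive = TRUE, integer = TRUE)
  mat <- if (is_gray_field(field)) field$intensities else field
  out <- gray_open(mat, radius) - gray_open(mat, radius + 1)
  out <- pmax(round(out), 0)
  gray_field(matrix(out, nrow(mat), ncol(mat)), "full")
}

#' Rolling-ball style background subtraction
#'
#' Estimates the background as the grayscale opening with a disc of
#' `ball_radius` and subtracts it — a documented flat-disc approximation of
#' the ImageJ rolling-ball algorithm (exact parity with ImageJ's paraboloid
#' is a non-goal).  Output is non-negative and bounded by the input.
#'
#' @param field a [gray_field()] or matrix.
#' @param ball_radius disc radius in pixels (default 50, ImageJ's default).
#' @return A [gray_field()] of the background-subtracted intensities.
#' @export
rolling_ball_background <- function(field, ball_radius = 50) {
  check_scalar_number(ball_radius, "ball_radius", positive = TRUE,
                      integer = TRUE)
  mat <- if (is_gray_field(field)) field$intensities else field
  bg <- gray_open(mat, ball_radius)
  out <- pmax(round(mat - bg), 0)
  gray_field(matrix(out, nrow(mat), ncol(mat)), "full")
}

#' Maximum-entropy (Kapur) threshold
#'
#' Chooses the threshold t that maximizes the summed Shannon entropies of the
#' background (intensities <= t) and foreground (> t) portions of the
#' normalized 256-bin histogram.  Ties resolve to the smallest t.
#'
#' @param field a [gray_field()] or matrix of 8-bit intensities.
#' @return Integer threshold in 0..254; foreground is `intensities > t`.
#' @export
max_entropy_threshold <- function(field) {
  mat <- if (is_gray_field(field)) field$intensities else field
  v <- as.vector(mat)
  if (length(unique(v)) < 2) stopf("constant image: no threshold exists")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  cp <- cumsum(p)
  # entropy accumulators: sum of p log p up to each bin
  plogp <- ifelse(p > 0, p * log(p), 0)
  cplogp <- cumsum(plogp)
  total <- cplogp[256]
  best_t <- NA_integer_
  best_h <- -Inf
  for (t in 0:254) {
    Pb <- cp[t + 1]
    Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) next
    Hb <- log(Pb) - cplogp[t + 1] / Pb
    Hf <- log(Pf) - (total - cplogp[t + 1]) / Pf
    H <- Hb + Hf
    if (H > best_h + 1e-12) {
      best_h <- H
      best_t <- t
    }
  }
  best_t
}

#' Segmentation pipeline: background subtraction, MaxEntropy, close
#'
#' The reference aggregate-segmentation pipeline: rolling-ball style
#' background subtraction, maximum-entropy auto-thresholding, then a binary
#' close with edge padding (the lattice border counts as foreground during
#' the closing erosion, so border-touching objects survive).
#'
#' @param field a [gray_field()] or matrix.
#' @param ball_radius background-subtraction disc radius (default 50).
#' @param close_radius closing disc radius (default 1, a 3x3-cross disc);
#'   0 skips the close.
#' @return Logical matrix: the estimated aggregate mask.
#' @export
segment_pipeline <- function(field, ball_radius = 50, close_radius = 1) {
  sub <- rolling_ball_background(field, ball_radius)
  t <- max_entropy_threshold(sub)
  est <- sub$intensities > t
  binary_close(est, close_radius)
}

#' Truth/estimate bivariate similarity (TET and TEE)
#'
#' TET = |T intersect E| / |T| measures how much of the ground truth the
#' estimate covers; TEE = |T intersect E| / |E| measures how specific the
#' estimate is.  Both lie in [0, 1].  An empty estimate has TEE = 1 by
#' convention (nothing claimed, nothing wrong); an empty truth is an error.
#'
#' @param truth logical matrix of ground-truth foreground.
#' @param estimate logical matrix of estimated foreground, same shape.
#' @return An object of class `similarity_result`: `tet`, `tee`, `t_count`,
#'   `e_count`, `overlap_count`.
#' @export
tet_tee <- function(truth, estimate) {
  if (!is.logical(truth) || !is.logical(estimate) ||
      !identical(dim(truth), dim(estimate)))
    stopf("'truth' and 'estimate' must be logical matrices of the same shape")
  t_count <- sum(truth)
  if (t_count == 0) stopf("empty truth mask: TET is undefined")
  e_count <- sum(estimate)
  overlap <- sum(truth & estimate)
  structure(
    list(
      tet = overlap / t_count,
      tee = if (e_count == 0) 1 else overlap / e_count,
      t_count = t_count, e_count = e_count, overlap_count = overlap
    ),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> TET = %.3f, TEE = %.3f (|T| = %d, |E| = %d, |T&E| = %d)\n",
              x$tet, x$tee, x$t_count, x$e_count, x$overlap_count))
  invisible(x)
}

# Two-threshold Otsu by exhaustive search over (t1, t2) with cumulative
# sums, maximizing between-class variance (equivalently minimizing
# within-class variance).
otsu_two_thresholds <- function(h) {
  p <- h / sum(h)
  lev <- 0:255
  w <- cumsum(p)
  m <- cumsum(p * lev)
  mt <- m[256]
  best <- c(-Inf, NA, NA)
  for (t1 in 0:253) {
    w0 <- w[t1 + 1]
    if (w0 <= 0) next
    m0 <- m[t1 + 1] / w0
    for (t2 in (t1 + 1):254) {
      w1 <- w[t2 + 1] - w[t1 + 1]
      w2 <- 1 - w[t2 + 1]
      if (w1 <= 0 || w2 <= 0) next
      m1 <- (m[t2 + 1] - m[t1 + 1]) / w1
      m2 <- (mt - m[t2 + 1]) / w2
      bcv <- w0 * (m0 - mt)^2 + w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2
      if (bcv > best[1]) best <- c(bcv, t1, t2)
    }
  }
  if (!is.finite(best[1])) stopf("fewer than 3 occupied intensity levels")
  as.integer(best[2:3])
}

#' Three-class Otsu masking for experimental images
#'
#' Finds the two thresholds t1 < t2 minimizing intra-class intensity variance
#' over three classes, assigns the lower two classes (the background and the
#' ambiguous middle class) to zero, and keeps original intensities above t2.
#' The returned field's mask is its nonzero pixels, ready for K computation
#' with the thresholded-image convention (zero pixels outside the study
#' region).
#'
#' @param field a [gray_field()] or matrix of 8-bit intensities.
#' @return A [gray_field()] with `mask = "nonzero"`.
#' @export
three_class_otsu <- function(field) {
  mat <- if (is_gray_field(field)) field$intensities else field
  if (length(unique(as.vector(mat))) < 3)
    stopf("three-class Otsu needs at least 3 distinct intensities")
  h <- tabulate(as.vector(mat) + 1L, nbins = 256L)
  t <- otsu_two_thresholds(h)
  out <- mat
  out[out <= t[2]] <- 0
  gray_field(matrix(out, nrow(mat), ncol(mat)), "nonzero")
}

#' Ensemble-average K-tilde profiles across stacks
#'
#' Arithmetic mean of K-tilde (and K) per radius across profiles from stacks
#' of the same cell; all profiles must share radii and edge method.
#'
#' @param profiles list of [k_profile()] objects.
#' @return A `k_profile` whose values are the per-radius means (its `n` and
#'   `omega_area` are the means of the inputs').
#' @export
ensemble_average <- function(profiles) {
  if (!length(profiles)) stopf("'profiles' must be a non-empty list")
  if (!all(vapply(profiles, inherits, logical(1), "k_profile")))
    stopf("all elements must be k_profile objects")
  r0 <- profiles[[1]]$radii
  m0 <- profiles[[1]]$edge_method
  for (p in profiles) {
    if (!isTRUE(all.equal(p$radii, r0)))
      stopf("profiles have mismatched radii and cannot be ensemble averaged")
    if (!identical(p$edge_method, m0))
      stopf("profiles have mismatched edge methods")
  }
  as_mat <- function(name)
    matrix(unlist(lapply(profiles, `[[`, name)), nrow = length(r0))
  kt <- rowMeans(as_mat("ktilde_values"))
  kv <- rowMeans(as_mat("k_values"))
  new_k_profile(r0, kv, kt,
                mean(vapply(profiles, `[[`, numeric(1), "n")),
                mean(vapply(profiles, `[[`, numeric(1), "omega_area")), m0)
}

#' Per-construct summary: mean and SEM
#'
#' @param per_cell numeric vector of per-cell (ensemble-averaged) K-tilde
#'   values.
#' @return List with `mean` and `sem` (= sd / sqrt(m); 0 when m = 1 is not
#'   defined, so a single cell yields `sem = NA`).
#' @export
construct_summary <- function(per_cell) {
  if (!is.numeric(per_cell) || !length(per_cell))
    stopf("'per_cell' must be a non-empty numeric vector")
  m <- length(per_cell)
  list(mean = mean(per_cell),
       sem = if (m > 1) sd(per_cell) / sqrt(m) else NA_real_)
}
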