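# Helper: paint flat discs of given radii/amplitude onto a zero field.
paint_discs <- function(shape, centres, radius, amplitude) {
  x <- matrix(0, shape[1], shape[2])
  off <- disc_kernel(radius)$offsets
  for (k in seq_len(nrow(centres)))
    x[cbind(centres[k, 1] + off[, 1], centres[k, 2] + off[, 2])] <- amplitude
  x
}

test_that("granulometric sums are nonincreasing with zero derivative on a constant image", {
  prof <- granulometric_profile(gray_field(matrix(5, 24, 24)), 4)
  expect_equal(prof$radii, 0:4)
  expect_true(all(prof$derivative == 0))
  expect_equal(prof$sums, rep(5 * 576, 5))
  # anti-extensivity on an arbitrary image
  f <- simulate_csr(c(32, 32), density = 3, seed = 14)
  p2 <- granulometric_profile(f, 5)
  expect_true(all(diff(p2$sums) <= 0))
  expect_true(all(p2$derivative <= 0))
  expect_equal(p2$sums[1], total_particles(f))
})

test_that("a single flat disc vanishes at the opening that exceeds it", {
  x <- paint_discs(c(40, 40), cbind(20, 20), radius = 5, amplitude = 10)
  prof <- granulometric_profile(gray_field(x), 8)
  # essentially unchanged while the structuring element fits inside the disc
  # (pixelated discs are not perfectly nested, so openings at intermediate
  # radii may trim a few rim pixels and restore them at the matching radius)
  expect_true(all(prof$sums[1:6] >= 0.85 * sum(x)))  # radii 0..5
  expect_equal(prof$sums[6], sum(x))                 # SE radius 5 = the object
  # gone once the SE is larger than the object
  expect_lt(prof$sums[7] / sum(x), 0.05)
  # dominant trough at the 5 -> 6 step
  tr <- detect_troughs(prof)
  expect_true(6 %in% tr)
  expect_equal(prof$radii[-1][which.min(prof$derivative)], 6)
})

test_that("detect_troughs finds prominent local minima in order", {
  p <- structure(list(radii = 0:5, sums = c(100, 99, 90, 89, 81, 80),
                      derivative = c(-1, -9, -1, -8, -1)),
                 class = "granulometric_profile")
  expect_equal(detect_troughs(p), c(2, 4))
  # monotone derivative has no interior trough
  mono <- structure(list(radii = 0:4, sums = c(100, 90, 81, 73, 66),
                         derivative = c(-10, -9, -8, -7)),
                    class = "granulometric_profile")
  expect_equal(detect_troughs(mono), integer(0))
  # prominence threshold suppresses minor dips: the -9 dip has prominence 8,
  # the -8 dip only 7
  expect_equal(detect_troughs(p, prominence = 7.5), 2)
})

test_that("extract_size_class isolates objects of one disc size", {
  centres <- rbind(c(15, 15), c(40, 40))
  x <- paint_discs(c(56, 56), centres, radius = 8, amplitude = 10) +
       paint_discs(c(56, 56), cbind(15, 40), radius = 2, amplitude = 10)
  f <- gray_field(pmin(x, 255))
  # radius-8 class: the two big discs, not the small one
  cls8 <- extract_size_class(f, 8)
  truth8 <- paint_discs(c(56, 56), centres, 8, 1) > 0
  sim <- tet_tee(truth8, cls8$intensities > 0)
  expect_gte(sim$tet, 0.9)
  small_region <- paint_discs(c(56, 56), cbind(15, 40), 2, 1) > 0
  expect_equal(sum(cls8$intensities[small_region]), 0)
  # an image with only radius-2 objects has an empty radius-8 class
  f2 <- gray_field(paint_discs(c(56, 56), cbind(28, 28), 2, 10))
  expect_true(all(extract_size_class(f2, 8)$intensities == 0))
  # anti-extensivity: extracted mass bounded by the opened mass
  expect_lte(sum(extract_size_class(f, 4)$intensities),
             sum(gray_open(f, 4)))
})

test_that("rolling-ball background subtraction flattens background, keeps peaks", {
  f <- gray_field(matrix(6, 30, 30))
  expect_true(all(rolling_ball_background(f, 5)$intensities == 0))
  # constant + small peak: peak preserved within 5%
  x <- matrix(20, 40, 40)
  x[20:21, 20:21] <- 120
  out <- rolling_ball_background(gray_field(x), 6)
  expect_equal(out$intensities[20, 20], 100, tolerance = 0.05)
  expect_true(all(out$intensities <= x))
  expect_true(all(out$intensities >= 0))
})

test_that("max-entropy threshold separates a two-level histogram and matches brute force", {
  x <- matrix(c(rep(10, 128), rep(200, 128)), 16, 16)
  t <- max_entropy_threshold(gray_field(x))
  expect_gte(t, 10); expect_lt(t, 200)
  expect_equal(sum(x > t), 128)
  # oracle identity: exhaustive search over thresholds with direct entropies
  brute_me <- function(v) {
    h <- tabulate(v + 1L, nbins = 256L); p <- h / sum(h)
    best <- -Inf; bt <- NA
    for (t in 0:254) {
      pb <- p[1:(t + 1)]; pf <- p[(t + 2):256]
      Pb <- sum(pb); Pf <- sum(pf)
      if (Pb <= 0 || Pf <= 0) next
      hb <- -sum(ifelse(pb > 0, pb / Pb * log(pb / Pb), 0))
      hf <- -sum(ifelse(pf > 0, pf / Pf * log(pf / Pf), 0))
      if (hb + hf > best + 1e-12) { best <- hb + hf; bt <- t }
    }
    bt
  }
  for (seed in 1:10) {
    set.seed(seed)
    v <- sample(0:255, 400, replace = TRUE,
                prob = dgamma(1:256, shape = sample(1:4, 1), rate = 0.05))
    m <- matrix(v, 20, 20)
    expect_equal(max_entropy_threshold(gray_field(m)), brute_me(v),
                 label = sprintf("seed %d", seed))
  }
  # invariant to transposition; constant image errors
  m <- matrix(sample(0:255, 144, TRUE), 12, 12)
  expect_equal(max_entropy_threshold(m), max_entropy_threshold(t(m)))
  expect_error(max_entropy_threshold(matrix(7, 5, 5)), "constant")
})

test_that("segmentation pipeline recovers high-SBR aggregates", {
  sp <- cluster_spec(c(128, 128), n_clusters = 8, sbr = 10,
                     background_density = 2)
  sim <- simulate_clusters(sp, seed = 17)
  img <- apply_poisson_noise(apply_psf(sim$field), seed = 18)
  est <- segment_pipeline(img, ball_radius = 15, close_radius = 1)
  res <- tet_tee(sim$truth, est)
  expect_gte(res$tet, 0.8)
  # close with radius 0 leaves the threshold mask unchanged
  sub <- rolling_ball_background(img, 15)
  t <- max_entropy_threshold(sub)
  expect_identical(segment_pipeline(img, ball_radius = 15, close_radius = 0),
                   sub$intensities > t)
})

test_that("no-signal CSR fields yield a near-empty estimate", {
  f <- simulate_csr(c(96, 96), density = 2, seed = 23)
  est <- segment_pipeline(f, ball_radius = 15, close_radius = 1)
  expect_lt(mean(est), 0.2)
  truth <- matrix(FALSE, 96, 96); truth[40:50, 40:50] <- TRUE
  res <- tet_tee(truth, est & FALSE)   # empty estimate
  expect_equal(res$tee, 1)
})

test_that("tet_tee obeys its contracts", {
  truth <- matrix(FALSE, 10, 10); truth[2:4, 2:4] <- TRUE
  res <- tet_tee(truth, truth)
  expect_equal(res$tet, 1); expect_equal(res$tee, 1)
  disjoint <- matrix(FALSE, 10, 10); disjoint[8:9, 8:9] <- TRUE
  res2 <- tet_tee(truth, disjoint)
  expect_equal(res2$tet, 0); expect_equal(res2$tee, 0)
  empty <- matrix(FALSE, 10, 10)
  res3 <- tet_tee(truth, empty)
  expect_equal(res3$tee, 1); expect_equal(res3$tet, 0)
  expect_error(tet_tee(empty, truth), "empty truth")
  expect_error(tet_tee(truth, matrix(FALSE, 5, 5)), "same shape")
  half <- truth; half[2, ] <- FALSE
  res4 <- tet_tee(truth, half)
  expect_equal(res4$overlap_count, sum(half))
  expect_lte(res4$overlap_count, min(res4$t_count, res4$e_count))
})

test_that("three-class Otsu keeps only the top class and matches brute force", {
  v <- c(rep(10, 100), rep(100, 80), rep(200, 76))
  x <- matrix(v, 16, 16)
  out <- three_class_otsu(gray_field(x))
  expect_true(all(out$intensities %in% c(0, 200)))
  expect_equal(sum(out$intensities > 0), 76)
  expect_identical(out$mask, out$intensities > 0)
  # thresholds equal an exhaustive direct minimization of within-class variance
  brute_otsu2 <- function(v) {
    best <- Inf; bt <- c(NA, NA)
    for (t1 in 0:253) for (t2 in (t1 + 1):254) {
      g <- ifelse(v <= t1, 0L, ifelse(v <= t2, 1L, 2L))
      wcv <- 0; ok <- TRUE
      for (cls in 0:2) {
        vc <- v[g == cls]
        if (!length(vc)) { ok <- FALSE; break }
        wcv <- wcv + length(vc) / length(v) * mean((vc - mean(vc))^2)
      }
      if (ok && wcv < best - 1e-12) { best <- wcv; bt <- c(t1, t2) }
    }
    bt
  }
  for (seed in 1:5) {
    set.seed(seed + 40)
    v <- c(rpois(60, 15), rpois(60, 80), rpois(60, 180))
    v <- pmin(v, 255)
    expect_equal(grayK:::otsu_two_thresholds(tabulate(v + 1L, 256L)),
                 as.integer(brute_otsu2(v)), label = sprintf("seed %d", seed))
  }
  expect_error(three_class_otsu(matrix(c(1, 2), 4, 4)), "3 distinct")
})

test_that("granulometry-first segmentation beats direct segmentation at low SBR", {
  # Four-size-class fields at low SBR, high SNR; paired comparison of the
  # mean TET against the radius-8 ground truth over 12 seeds.  Extracting
  # the radius-8 size class before segmenting removes the other classes and
  # the diffuse pool, which is what rescues the threshold at low contrast.
  deltas <- vapply(1:12, function(s) {
    sim <- simulate_size_classes(sbr = 0.5, background_density = 10,
                                 seed = 600 + s)
    img <- apply_psf(sim$field)
    t8 <- sim$class_truth[["8"]]
    direct <- segment_pipeline(img, ball_radius = 15, close_radius = 1)
    granulo <- segment_pipeline(extract_size_class(img, 8),
                                ball_radius = 15, close_radius = 1)
    tet_tee(t8, granulo)$tet - tet_tee(t8, direct)$tet
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("simulate_size_classes realizes uniform per-class contrast", {
  sim <- simulate_size_classes(sbr = 3, background_density = 2, seed = 5)
  expect_length(sim$class_truth, 4)
  bg_mean <- mean(sim$field$intensities[!sim$truth])
  for (r in names(sim$class_truth)) {
    cls <- sim$class_truth[[r]]
    expect_equal(mean(sim$field$intensities[cls]) / bg_mean, 4,
                 tolerance = 0.15, label = sprintf("class %s contrast", r))
  }
  sim2 <- simulate_size_classes(sbr = 3, background_density = 2, seed = 5)
  expect_identical(sim$field$intensities, sim2$field$intensities)
})
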