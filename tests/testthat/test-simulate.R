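test_that("simulate_csr places exactly n particles, reproducibly", {
  f <- simulate_csr(c(256, 256), density = 1, seed = 4)
  expect_equal(total_particles(f), 65536)
  expect_equal(mean(f$intensities), 1.0)
  f2 <- simulate_csr(c(256, 256), density = 1, seed = 4)
  expect_identical(f$intensities, f2$intensities)
  f3 <- simulate_csr(c(256, 256), density = 1, seed = 5)
  expect_false(identical(f$intensities, f3$intensities))
  # masked placement stays on the mask
  mask <- matrix(FALSE, 30, 30); mask[5:25, 5:25] <- TRUE
  g <- simulate_csr(c(30, 30), n = 1000, mask = mask, seed = 1)
  expect_equal(sum(g$intensities[!mask]), 0)
  expect_equal(total_particles(g), 1000)
})

test_that("saturation is enforced and clipping warns", {
  expect_error(simulate_csr(c(1, 1), n = 300, seed = 1), "saturat|hold")
  one <- matrix(TRUE, 1, 1)
  f <- simulate_csr(c(1, 1), n = 255, mask = one, seed = 1)
  expect_equal(f$intensities[1, 1], 255)
  # forcing mass beyond saturation on a tiny mask warns and clips
  two <- matrix(TRUE, 1, 2)
  expect_warning(f2 <- simulate_csr(c(1, 2), n = 509, mask = two, seed = 1),
                 "clip")
  expect_lte(max(f2$intensities), 255)
})

test_that("per-pixel occupancy matches the multinomial/Poisson law", {
  # density 8 on 64x64: occupancy ~ Binomial(n, 1/|Omega|) ~ Poisson(8)
  f <- simulate_csr(c(64, 64), density = 8, seed = 9)
  counts <- as.vector(f$intensities)
  brk <- c(-Inf, 3:13, Inf)
  obs <- table(cut(counts, brk))
  p <- diff(pbinom(brk, size = 8 * 4096, prob = 1 / 4096))
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("cluster_spec derives the free member of (N_agg, SBR, ADR)", {
  disc_px <- disc_kernel(8)$pixel_count
  npix <- 256^2
  sp <- cluster_spec(n_clusters = 10, sbr = 3, background_density = 1)
  expect_equal(sp$adr, 3 * 10 * disc_px / npix)
  sp2 <- cluster_spec(n_clusters = 10, adr = sp$adr, background_density = 1)
  expect_equal(sp2$sbr, 3)
  sp3 <- cluster_spec(adr = sp$adr, sbr = 3, background_density = 1)
  expect_equal(sp3$n_clusters, 10L)
  expect_error(cluster_spec(background_density = 1), "exactly two")
  expect_error(cluster_spec(n_clusters = 2, sbr = 3, adr = 0.1,
                            background_density = 1), "exactly two")
  expect_error(cluster_spec(n_clusters = 4, sbr = 300,
                            background_density = 2), "saturation")
  # ADR = 0 is pure CSR
  sp0 <- cluster_spec(n_clusters = 0, adr = 0, background_density = 1)
  expect_equal(sp0$sbr, 0)
})

test_that("simulate_clusters realizes the requested ADR and SBR", {
  sp <- cluster_spec(n_clusters = 20, sbr = 3, background_density = 2)
  sim <- simulate_clusters(sp, seed = 13)
  expect_s3_class(sim$field, "gray_field")
  expect_true(any(sim$truth))
  # generator self-consistency: n >= 1e5 so the realized ratio is within 1%
  n_bg <- round(2 * 256^2)
  n_agg <- round(sp$adr * n_bg)
  expect_gte(n_bg + n_agg, 1e5)
  expect_equal(total_particles(sim$field), n_bg + n_agg)
  # mean intensity inside truth ~ background * (1 + SBR), outside ~ background
  inside <- mean(sim$field$intensities[sim$truth])
  outside <- mean(sim$field$intensities[!sim$truth])
  expect_equal(inside / outside, 1 + sp$sbr, tolerance = 0.05)
  # determinism
  sim2 <- simulate_clusters(sp, seed = 13)
  expect_identical(sim$field$intensities, sim2$field$intensities)
  expect_identical(sim$truth, sim2$truth)
})

test_that("ADR = 0 cluster spec degenerates to pure CSR", {
  sp <- cluster_spec(n_clusters = 0, adr = 0, background_density = 1)
  sim <- simulate_clusters(sp, seed = 3)
  expect_false(any(sim$truth))
  expect_equal(total_particles(sim$field), 256^2)
})

test_that("no-diffuse-pool clusters put every particle inside the discs", {
  sp <- cluster_spec(n_clusters = 10, cluster_radius = 8,
                     background_density = 0, aggregate_density = 0.01)
  expect_identical(sp$adr, Inf)
  sim <- simulate_clusters(sp, seed = 77)
  expect_equal(total_particles(sim$field), round(0.01 * 256^2))
  expect_equal(sum(sim$field$intensities[!sim$truth]), 0)
  expect_error(cluster_spec(n_clusters = 10, background_density = 0),
               "aggregate_density")
  expect_error(cluster_spec(n_clusters = 10, sbr = 2, background_density = 1,
                            aggregate_density = 0.5), "only meaningful")
})

test_that("flat deposition writes the signal as an exact pedestal", {
  sim <- simulate_size_classes(radii = c(3, 6), n_per_class = 4, sbr = 10,
                               background_density = 0.5, seed = 9,
                               allocation = "equal_mass", deposition = "flat")
  # pedestal value inside the largest class is sbr * background (rounded),
  # up to the nominal/realized union-area ratio; background rides on top
  cls6 <- sim$class_truth[["6"]]
  inside <- sim$field$intensities[cls6 & !sim$class_truth[["3"]]]
  ped <- min(inside)   # min strips the background contribution
  expect_gte(ped, 4)
  expect_lte(ped, 7)
  # smaller class is proportionally brighter (equal mass)
  cls3 <- sim$class_truth[["3"]] & !cls6
  expect_gt(min(sim$field$intensities[cls3]), ped)
})

test_that("Fig-8B regime: contrast inside aggregates is 1 + SBR", {
  # density 10 total with ADR 0.05, SBR 3 => background 10/1.05 per pixel
  sp <- cluster_spec(adr = 0.05, sbr = 3, background_density = 10 / 1.05)
  sim <- simulate_clusters(sp, seed = 31)
  inside <- mean(sim$field$intensities[sim$truth])
  outside <- mean(sim$field$intensities[!sim$truth])
  expect_equal(inside / outside, 4, tolerance = 0.1)
})

test_that("PSF kernel is normalized, mass-conserving and symmetric", {
  spec <- microscope_spec(psf_diameter = 3, psf_sigma = 1)
  k <- grayK:::gaussian_psf_kernel(3, 1)
  expect_equal(sum(k), 1)
  # constant field unchanged
  f <- gray_field(matrix(7, 20, 20))
  expect_identical(apply_psf(f, spec)$intensities, f$intensities)
  # single particle of 255: mass conserved within per-pixel rounding.
  # Analytic oracle: unnormalized weights exp(0), 4 exp(-1/2), 4 exp(-1);
  # rounding each of the 9 responses gives 52 + 4*32 + 4*19 = 256.
  w <- c(1, rep(exp(-0.5), 4), rep(exp(-1), 4))
  expected <- sum(round(255 * w / sum(w)))
  x <- matrix(0, 21, 21); x[11, 11] <- 255
  blurred <- apply_psf(gray_field(x), spec)
  expect_equal(sum(blurred$intensities), expected)
  expect_lte(abs(sum(blurred$intensities) - 255), 4.5)
  # delta response symmetric under rotation
  expect_identical(blurred$intensities,
                   rotate_field(blurred)$intensities)
  expect_error(microscope_spec(psf_diameter = 4), "odd")
})

test_that("Poisson noise has the right law and respects zeros/saturation", {
  z <- apply_poisson_noise(gray_field(matrix(0, 10, 10)), seed = 1)
  expect_true(all(z$intensities == 0))
  f <- gray_field(matrix(9, 120, 120))  # 14400 pixels of lambda = 9
  noisy <- apply_poisson_noise(f, seed = 2)
  expect_lt(abs(mean(noisy$intensities) - 9), 3 * 3 / sqrt(14400))
  expect_lt(abs(var(as.vector(noisy$intensities)) - 9), 1)
  sat <- apply_poisson_noise(gray_field(matrix(255, 50, 50)), seed = 3)
  expect_lte(max(sat$intensities), 255)
  expect_identical(noisy$intensities,
                   apply_poisson_noise(f, seed = 2)$intensities)
})

test_that("snr_estimate follows S / sqrt(S + B)", {
  expect_equal(snr_estimate(4, 0), 2)
  b <- 16 / 9
  expect_equal(snr_estimate(3 * b, b), 2)
})

test_that("decimated CSR masks out the holes and keeps particles outside", {
  spec <- decimation_spec(n_decimations = 12, decimation_radius = 20)
  f <- simulate_decimated_csr(c(256, 256), density = 1, spec = spec, seed = 6)
  expect_equal(sum(f$intensities[!f$mask]), 0)
  # masked-out area: 12 non-overlapping discs of radius 20
  disc_px <- disc_kernel(20)$pixel_count
  expect_equal(sum(!f$mask), 12 * disc_px)
  # holes lie fully inside the lattice: no masked-out pixel on the border
  border <- rbind(f$mask[c(1, 256), ], t(f$mask[, c(1, 256)]))
  expect_true(all(border))
  # zero decimations -> plain CSR on a full mask
  f0 <- simulate_decimated_csr(c(64, 64), density = 1,
                               spec = decimation_spec(0), seed = 6)
  expect_true(all(f0$mask))
  expect_equal(total_particles(f0), 4096)
  # determinism
  f2 <- simulate_decimated_csr(c(256, 256), density = 1, spec = spec, seed = 6)
  expect_identical(f$intensities, f2$intensities)
  expect_identical(f$mask, f2$mask)
})

test_that("infeasible decimation placement raises a domain error", {
  spec <- decimation_spec(n_decimations = 40, decimation_radius = 20)
  expect_error(
    simulate_decimated_csr(c(128, 128), density = 1, spec = spec, seed = 1,
                           max_attempts = 200),
    "failed to place")
})
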