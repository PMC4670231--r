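# Independent brute-force oracles used to validate the filter-based
# implementation.  These deliberately share no code with the package
# internals: discs are enumerated point by point and the K sums are direct
# double sums over pixel pairs.

# All lattice offsets within Euclidean distance r of the origin, by direct
# enumeration over a bounding square.
brute_disc_offsets <- function(r) {
  g <- -ceiling(r):ceiling(r)
  out <- list()
  for (a in g) for (b in g) if (a * a + b * b <= r * r)
    out[[length(out) + 1]] <- c(a, b)
  do.call(rbind, out)
}

# Clipped disc area at 1-based pixel (i, j) by point-in-circle testing.
brute_disc_area <- function(mask, i, j, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0
  for (a in -ceiling(r):ceiling(r)) for (b in -ceiling(r):ceiling(r)) {
    if (a * a + b * b > r * r) next
    ii <- i + a; jj <- j + b
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj])
      cnt <- cnt + 1
  }
  cnt
}

# Direct double-sum grayscale K: for every mask pixel x with P_x > 0,
# c_x * P_x * (P_x - 1 + sum of P_y over mask pixels y != x within r).
brute_gray_k <- function(field, r, method = "full_field") {
  P <- field$intensities
  mask <- field$mask
  n <- sum(P)
  omega <- sum(mask)
  idx <- which(mask & P > 0, arr.ind = TRUE)
  disc_px <- nrow(brute_disc_offsets(r))
  total <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    A <- brute_disc_area(mask, i, j, r)
    cx <- if (method == "full_field") pi * r^2 / A
          else if (A >= disc_px) 1
          else if (method == "ideal_border") pi * r^2 / A
          else disc_px / A
    inner <- 0
    for (m in seq_len(nrow(idx))) {
      if (m == k) next
      i2 <- idx[m, 1]; j2 <- idx[m, 2]
      if ((i - i2)^2 + (j - j2)^2 <= r^2) inner <- inner + P[i2, j2]
    }
    total <- total + cx * P[i, j] * (P[i, j] - 1 + inner)
  }
  omega / (n * (n - 1)) * total
}

# Classic point-pattern K (binary events) with Besag correction, computed
# over the point set of nonzero pixels via pairwise distances.
brute_point_k <- function(field, r, method = "full_field") {
  mask <- field$mask
  pts <- which(field$mask & field$intensities > 0, arr.ind = TRUE)
  n <- nrow(pts)
  omega <- sum(mask)
  disc_px <- nrow(brute_disc_offsets(r))
  total <- 0
  for (k in seq_len(n)) {
    A <- brute_disc_area(mask, pts[k, 1], pts[k, 2], r)
    cx <- if (method == "full_field") pi * r^2 / A
          else if (A >= disc_px) 1
          else if (method == "ideal_border") pi * r^2 / A
          else disc_px / A
    d2 <- (pts[, 1] - pts[k, 1])^2 + (pts[, 2] - pts[k, 2])^2
    total <- cx * (sum(d2 <= r^2) - 1) + total
  }
  omega / (n * (n - 1)) * total
}

# Random small integer field for property tests.
random_small_field <- function(seed, max_dim = 16, max_intensity = 255,
                               with_holes = FALSE) {
  set.seed(seed)
  nr <- sample(4:max_dim, 1)
  nc <- sample(4:max_dim, 1)
  x <- matrix(sample(0:max_intensity, nr * nc, replace = TRUE,
                     prob = c(0.5, rep(0.5 / max_intensity, max_intensity))),
              nr, nc)
  mask <- if (with_holes) matrix(runif(nr * nc) > 0.2, nr, nc)
          else matrix(TRUE, nr, nc)
  if (sum(x[mask]) < 2) x[mask][1:2] <- 1
  gray_field(x, mask)
}
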