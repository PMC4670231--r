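# Internal helpers: argument checks and reproducible seeding.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be positive", name)
  if (integer && x != round(x)) stopf("'%s' must be a whole number", name)
  invisible(x)
}

# Evaluate `expr` under a deterministic RNG state without disturbing the
# caller's random stream.
with_seed <- function(seed, expr) {
  check_scalar_number(seed, "seed", integer = TRUE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based derivation of a per-replicate seed from (seed, i), so that
# replicate i is reproducible independently of how many replicates ran
# before it.  Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((abs(as.numeric(seed)) %% m + as.numeric(i) * 48271) %% m)
}

# Order-independent numeric signature of a logical mask; used to guard that a
# CSR reference and a field share the same study-region geometry.  Not a
# cryptographic hash: a 53-bit-safe polynomial accumulator over the indices
# of TRUE pixels plus the lattice dimensions.
mask_signature <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  idx <- which(mask)
  m <- 4294967296 # 2^32
  w <- (idx * 2654435761) %% m
  h <- (sum(w) + sum(idx)) %% m
  sprintf("%dx%d:%d:%.0f", nrow(mask), ncol(mask), length(idx), h)
}
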