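# File interfaces.  This build has no TIFF/PNG codec available, so images
# travel as portable graymaps (PGM, ASCII "P2" or binary "P5") and CSV
# matrices; both are lossless for 8-bit grayscale.  Profiles and references
# are written as CSV with a JSON provenance sidecar.

#' Read a grayscale image into a gray_field
#'
#' Supports portable graymaps (`.pgm`, ASCII P2 or binary P5) and CSV
#' matrices of integer intensities.  Images deeper than 8 bits are rejected
#' unless `allow_rescale = TRUE`, in which case intensities are right-shifted
#' to 8 bits with a warning — comparing K-tilde across images of different
#' bit depth is invalid, so the conversion is never silent.
#'
#' @param path file path.
#' @param mask_policy `"full"` or `"nonzero"` (see [gray_field()]).
#' @param allow_rescale permit lossy conversion of >8-bit images.
#' @return A [gray_field()].
#' @export
read_gray_image <- function(path, mask_policy = "full",
                            allow_rescale = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  mat <- switch(ext,
    pgm = read_pgm(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    stopf("unsupported image format '.%s' (use .pgm or .csv)", ext)
  )
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(mat < 0) || any(mat != round(mat)))
    stopf("%s does not decode to non-negative integer intensities", path)
  if (max(mat) > 255) {
    if (!allow_rescale)
      stopf(paste0("%s has intensities above 255 (not 8-bit); images being ",
                   "compared must share a bit depth - pass allow_rescale = ",
                   "TRUE to force a lossy conversion"), path)
    bits <- ceiling(log2(max(mat) + 1))
    mat <- floor(mat / 2^(bits - 8))
    warning(sprintf("rescaled %d-bit intensities to 8 bits; K-tilde is not comparable with unrescaled images",
                    bits), call. = FALSE)
  }
  gray_field(mat, mask = mask_policy)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with '#' comments allowed
  while (length(tokens) < 4) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch)) stopf("truncated PGM header in %s", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval))
    stopf("malformed PGM header in %s", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    bytes <- if (maxval < 256) 1L else 2L
    vals <- readBin(con, "integer", n = n, size = bytes, signed = FALSE,
                    endian = "big")
  } else {
    stopf("%s is not a PGM file (magic '%s')", path, magic)
  }
  if (length(vals) < n) stopf("truncated PGM data in %s", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a gray_field as an ASCII PGM image
#'
#' Writes the intensity lattice as a P2 (plain text) portable graymap.  The
#' mask is not stored in the PGM; write it separately with
#' [write_mask_pgm()] if it is not recoverable as the nonzero pixels.
#'
#' @param field a [gray_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(field, path) {
  field <- as_gray_field(field)
  mat <- field$intensities
  maxval <- 2^field$bit_depth - 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mat), nrow(mat)),
               sprintf("%d", maxval)), con)
  apply(mat, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @param mask logical matrix, written as a 0/1 PGM.
#' @export
write_mask_pgm <- function(mask, path) {
  write_pgm(gray_field(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                       bit_depth = 1L), path)
}

#' Read a 0/1 PGM back as a logical mask
#' @param path file path.
#' @return Logical matrix.
#' @export
read_mask_pgm <- function(path) {
  read_pgm(path) > 0
}

#' Write a K-tilde profile (or kest_gray fit) to CSV with JSON provenance
#'
#' The CSV holds one row per radius with columns `radius, k, ktilde` and, for
#' a [kest_gray()] fit, the empirical and Cornish-Fisher critical quantiles
#' (`q01_emp, q99_emp, q01_cf, q99_cf`).  A sidecar `<path>.json` records the
#' provenance needed to reproduce the numbers: seeds, replicate counts, edge
#' method and mask signatures.
#'
#' @param x a [k_profile()] or [kest_gray()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kprofile_csv <- function(x, path) {
  if (inherits(x, "gray_kest")) {
    df <- kest_frame(x)
    prov <- list(
      edge_method = x$edge_method, n = x$n, omega_area = x$omega_area,
      replicates = vapply(x$references, `[[`, integer(1), "replicates"),
      seeds = vapply(x$references, `[[`, integer(1), "seed"),
      mask_signature = x$references[[1]]$mask_signature
    )
  } else if (inherits(x, "k_profile")) {
    df <- as.data.frame(x)
    prov <- list(edge_method = x$edge_method, n = x$n,
                 omega_area = x$omega_area)
  } else stopf("'x' must be a k_profile or gray_kest")
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run configuration: JSON round-trip
#'
#' A `run_config` bundles the knobs of a reproducible run (inputs or
#' simulation spec, radii, edge method, replicates, seed, mask policy, output
#' directory) and serializes losslessly to JSON; every CLI run writes its
#' resolved config next to its outputs.
#'
#' @param input input image path(s), or `NULL` for simulation-driven runs.
#' @param radii radii in pixels.
#' @param edge_method edge-correction method.
#' @param replicates Monte-Carlo replicates.
#' @param seed integer seed.
#' @param mask_policy `"full"`, `"nonzero"` or a mask file path.
#' @param out_dir output directory.
#' @param extra named list of extra generator parameters.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, radii = 2:15,
                       edge_method = "full_field", replicates = 1000,
                       seed = 1L, mask_policy = "full", out_dir = ".",
                       extra = list()) {
  structure(
    list(input = input, radii = as.numeric(radii),
         edge_method = check_edge_method(edge_method),
         replicates = as.integer(replicates), seed = as.integer(seed),
         mask_policy = mask_policy, out_dir = out_dir, extra = extra),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) stopf("'config' must be a run_config")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(input = x$input, radii = x$radii, edge_method = x$edge_method,
             replicates = x$replicates, seed = x$seed,
             mask_policy = x$mask_policy, out_dir = x$out_dir,
             extra = if (is.null(x$extra)) list() else as.list(x$extra))
}
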