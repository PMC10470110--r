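# The 5codes base-3 packing: five SNP dosages in {0,1,2} per byte, since
# 3^5 = 243 <= 256. The first SNP of a block is the 3^0 digit. Missing calls
# are not representable in the key space; they are carried in a sparse index
# set and corrected after multiplication.

.POW3 <- c(1L, 3L, 9L, 27L, 81L)

# all 243 dosage 5-vectors, row k+1 = decode of key k
.DECODE243 <- local({
  k <- 0:242
  m <- vapply(1:5, function(t) (k %/% .POW3[t]) %% 3L, integer(243))
  storage.mode(m) <- "double"
  m
})

#' Encode five dosages as a base-3 key
#'
#' `key = m1 + 3 m2 + 9 m3 + 27 m4 + 81 m5`, a bijection from `{0,1,2}^5`
#' onto `0..242`.
#'
#' @param m numeric vector of length 5 with entries in `{0,1,2}`, or a matrix
#'   with 5 columns (one key per row).
#' @return Integer key(s) in `0..242`.
#' @export
encode_key <- function(m) {
  if (is.matrix(m)) {
    if (ncol(m) != 5L) stop("key vectors have length 5", call. = FALSE)
    if (length(m) && !all(m %in% 0:2)) {
      stop("dosages must be 0, 1 or 2", call. = FALSE)
    }
    return(as.integer(m %*% .POW3))
  }
  if (length(m) != 5L) stop("key vectors have length 5", call. = FALSE)
  if (!all(m %in% 0:2)) stop("dosages must be 0, 1 or 2", call. = FALSE)
  as.integer(sum(m * .POW3))
}

#' Decode a base-3 key into five dosages
#'
#' Exact inverse of [encode_key()] on `0..242`.
#'
#' @param key integer vector of keys in `0..242`.
#' @return For a single key, an integer 5-vector; for several, a matrix with
#'   one row per key.
#' @export
decode_key <- function(key) {
  if (!all(key %in% 0:242)) stop("keys lie in 0..242", call. = FALSE)
  out <- .DECODE243[as.integer(key) + 1L, , drop = FALSE]
  storage.mode(out) <- "integer"
  if (length(key) == 1L) out <- drop(out)
  out
}

#' Pack a dosage matrix into the 5codes format
#'
#' In `by-snp` orientation, row `i`, block `b` of `keys` encodes SNPs
#' `5(b-1)+1 .. 5b` of individual `i` (packing M); in `by-individual`
#' orientation the roles are swapped (packing M'). Trailing slots of the last
#' block are padded with dosage 0, so centered contributions from pads vanish.
#' The missing index set is carried through unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param orientation `"by-snp"` (packs M) or `"by-individual"` (packs M').
#' @return An object of class `fivecodes_matrix` with fields `keys` (integer
#'   matrix with entries in `0..242`), `n_individuals`, `n_snps`, `missing`
#'   and `orientation`.
#' @export
encode_matrix <- function(g, orientation = c("by-snp", "by-individual")) {
  stopifnot(inherits(g, "genotype_matrix"))
  orientation <- match.arg(orientation)
  d <- g$dosages
  if (orientation == "by-individual") d <- t(d)
  nr <- nrow(d)
  nc <- ncol(d)
  nb <- as.integer(ceiling(nc / 5))
  pad <- 5L * nb - nc
  if (pad > 0L) d <- cbind(d, matrix(0L, nr, pad))
  keys <- matrix(0L, nr, max(nb, 0L))
  for (b in seq_len(nb)) {
    cols <- (5L * (b - 1L) + 1L):(5L * b)
    keys[, b] <- as.integer(d[, cols, drop = FALSE] %*% .POW3)
  }
  structure(
    list(n_individuals = nrow(g$dosages), n_snps = ncol(g$dosages),
         keys = keys, missing = g$missing, orientation = orientation,
         snp_ids = g$snp_ids, individual_ids = g$individual_ids),
    class = "fivecodes_matrix"
  )
}

#' Pack the transposed dosage matrix
#'
#' Stores M' explicitly (five contiguous individuals per byte) so transposed
#' products need no on-the-fly transpose. Equivalent to [encode_matrix()] with
#' `orientation = "by-individual"`.
#'
#' @param g a [genotype_matrix()].
#' @return A `fivecodes_matrix` in by-individual orientation.
#' @export
transpose_packed <- function(g) encode_matrix(g, "by-individual")

#' @exportS3Method base::print
print.fivecodes_matrix <- function(x, ...) {
  cat(sprintf("fivecodes_matrix (%s): %d individuals x %d SNPs, %d key bytes\n",
              x$orientation, x$n_individuals, x$n_snps, length(x$keys)))
  invisible(x)
}

#' Recover the dosage matrix from a 5codes packing
#'
#' @param fc a `fivecodes_matrix`.
#' @return The [genotype_matrix()] it encodes (pad slots dropped).
#' @export
decode_matrix <- function(fc) {
  stopifnot(inherits(fc, "fivecodes_matrix"))
  nr <- nrow(fc$keys)
  full <- matrix(0L, nr, 5L * ncol(fc$keys))
  for (b in seq_len(ncol(fc$keys))) {
    cols <- (5L * (b - 1L) + 1L):(5L * b)
    dec <- .DECODE243[fc$keys[, b] + 1L, , drop = FALSE]
    storage.mode(dec) <- "integer"
    full[, cols] <- dec
  }
  if (fc$orientation == "by-snp") {
    d <- full[, seq_len(fc$n_snps), drop = FALSE]
  } else {
    d <- t(full[, seq_len(fc$n_individuals), drop = FALSE])
  }
  genotype_matrix(d, missing = fc$missing, snp_ids = fc$snp_ids,
                  individual_ids = fc$individual_ids)
}

#' Lookup table of dot products for one 5-SNP block
#'
#' Entry `k` holds `decode_key(k)' lambda5`, optionally centered by
#' `- 2 p5' lambda5` so that the table stores the centered values
#' `z' lambda5` directly.
#'
#' @param lambda5 numeric 5-vector (five rows of one trait-matrix column).
#' @param p5 numeric 5-vector of allele frequencies (used when centered).
#' @param centered logical; subtract `2 * p5' lambda5` from every entry.
#' @return Numeric vector of length 243.
#' @export
build_lookup_table <- function(lambda5, p5 = NULL, centered = FALSE) {
  stopifnot(length(lambda5) == 5L)
  v <- as.numeric(.DECODE243 %*% lambda5)
  if (centered) {
    stopifnot(length(p5) == 5L)
    v <- v - 2 * sum(p5 * lambda5)
  }
  v
}

#' Storage size of a 5codes packing, in bytes
#'
#' One byte per 5 SNPs (1.6 bits per SNP): `n_individuals * ceiling(n_snps/5)`
#' in by-snp orientation, `n_snps * ceiling(n_individuals/5)` for the stored
#' transpose.
#'
#' @param n_individuals,n_snps dimensions.
#' @param orientation packing orientation.
#' @return Byte count.
#' @export
fivecodes_nbytes <- function(n_individuals, n_snps,
                             orientation = c("by-snp", "by-individual")) {
  orientation <- match.arg(orientation)
  if (orientation == "by-snp") n_individuals * ceiling(n_snps / 5)
  else n_snps * ceiling(n_individuals / 5)
}

#' Storage size of the 2-bit SNP-major packing, in bytes
#'
#' The PLINK 1 payload size: `n_snps * ceiling(n_individuals / 4)`
#' (2 bits per SNP).
#'
#' @param n_individuals,n_snps dimensions.
#' @return Byte count.
#' @export
twobit_nbytes <- function(n_individuals, n_snps) {
  n_snps * ceiling(n_individuals / 4)
}

# --- on-disk container -------------------------------------------------------

.FIVECODES_MAGIC <- charToRaw("5COD")

#' Write a 5codes matrix to its little-endian container
#'
#' Layout: magic `"5COD"`, version byte (1), orientation byte (0 = by-snp,
#' 1 = by-individual), `n_individuals` and `n_snps` as 32-bit little-endian
#' integers, the key bytes row-major, a 32-bit missing-pair count, then the
#' 1-based `(individual, snp)` missing pairs as 32-bit integers.
#'
#' @param fc a `fivecodes_matrix`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fivecodes <- function(fc, path) {
  stopifnot(inherits(fc, "fivecodes_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.FIVECODES_MAGIC, con)
  writeBin(as.raw(c(1L, if (fc$orientation == "by-snp") 0L else 1L)), con)
  writeBin(as.integer(c(fc$n_individuals, fc$n_snps)), con,
           size = 4L, endian = "little")
  writeBin(as.raw(t(fc$keys)), con)
  writeBin(nrow(fc$missing), con, size = 4L, endian = "little")
  if (nrow(fc$missing)) {
    writeBin(as.integer(t(fc$missing)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a 5codes container written by [write_fivecodes()]
#'
#' @param path input path.
#' @return A `fivecodes_matrix`.
#' @export
read_fivecodes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .FIVECODES_MAGIC)) {
    stop("unsupported format: not a 5codes container", call. = FALSE)
  }
  hdr <- as.integer(readBin(con, "raw", 2L))
  if (hdr[1L] != 1L) stop("unsupported 5codes container version", call. = FALSE)
  orientation <- if (hdr[2L] == 0L) "by-snp" else "by-individual"
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n_g <- dims[1L]
  n_s <- dims[2L]
  nr <- if (orientation == "by-snp") n_g else n_s
  nb <- as.integer(ceiling((if (orientation == "by-snp") n_s else n_g) / 5))
  keys <- matrix(as.integer(readBin(con, "raw", nr * nb)),
                 nrow = nr, ncol = nb, byrow = TRUE)
  nmiss <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  missing <- if (nmiss > 0L) {
    matrix(readBin(con, "integer", 2L * nmiss, size = 4L, endian = "little"),
           ncol = 2L, byrow = TRUE)
  } else matrix(integer(), 0L, 2L)
  if (any(keys > 242L)) stop("corrupt 5codes container: key out of range",
                             call. = FALSE)
  structure(
    list(n_individuals = n_g, n_snps = n_s, keys = keys, missing = missing,
         orientation = orientation,
         snp_ids = if (n_s) paste0("snp", seq_len(n_s)) else character(),
         individual_ids = if (n_g) paste0("id", seq_len(n_g)) else character()),
    class = "fivecodes_matrix"
  )
}
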