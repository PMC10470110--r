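# PLINK 1 binary (.bed/.bim/.fam) input/output and dosage derivation.
#
# The .bed payload is SNP-major: ceiling(n_individuals / 4) bytes per SNP, the
# first individual of each byte in the two least-significant bits. 2-bit codes:
# 0 = homozygous, 1 = missing, 2 = heterozygous, 3 = alternate homozygous,
# so the counted allele is the one whose homozygote is code 3.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))
.BED_SNP_MAJOR <- as.raw(0x01)

# byte value (0..255) -> its four 2-bit codes, lowest bits first
.byte_codes <- local({
  b <- 0:255
  cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
})

.CODE_DOSAGE <- c(0L, 0L, 1L, 2L) # bed code -> dosage (code 1 = missing -> 0)
.DOSAGE_CODE <- c(0L, 2L, 3L)     # dosage -> bed code

#' Packed 2-bit genotype matrix (PLINK 1 bed payload)
#'
#' Container holding the SNP-major 2-bit payload exactly as stored on disk,
#' including missing codes. Use [unpack_genotypes()] to obtain dosages.
#'
#' @param data raw vector of length `n_snps * ceiling(n_individuals / 4)`,
#'   SNP blocks contiguous.
#' @param n_individuals,n_snps dimensions.
#' @param snp_ids,individual_ids optional identifier vectors.
#' @param bim,fam optional 6-column data frames passed through to
#'   [write_bed()]; only the id columns are ever interpreted.
#' @return An object of class `packed_bed`.
#' @export
packed_bed <- function(data, n_individuals, n_snps, snp_ids = NULL,
                       individual_ids = NULL, bim = NULL, fam = NULL) {
  if (!is.raw(data)) stop("`data` must be a raw vector", call. = FALSE)
  n_individuals <- as.integer(n_individuals)
  n_snps <- as.integer(n_snps)
  bps <- as.integer(ceiling(n_individuals / 4))
  if (length(data) != n_snps * bps) {
    stop(sprintf("corrupt payload: expected %d bytes, got %d",
                 n_snps * bps, length(data)), call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- if (n_snps) paste0("snp", seq_len(n_snps)) else character()
  if (is.null(individual_ids)) {
    individual_ids <- if (n_individuals) paste0("id", seq_len(n_individuals)) else character()
  }
  if (length(snp_ids) != n_snps || length(individual_ids) != n_individuals) {
    stop("id list lengths do not match matrix dimensions", call. = FALSE)
  }
  npad <- (4L - n_individuals %% 4L) %% 4L
  if (npad > 0L && n_snps > 0L) {
    last <- as.integer(data[seq(bps, length(data), by = bps)])
    if (any(last %/% 4L^(4L - npad) != 0L)) {
      stop("pad bit-pairs in the last byte of a SNP block are not zero",
           call. = FALSE)
    }
  }
  structure(
    list(data = data, n_individuals = n_individuals, n_snps = n_snps,
         snp_ids = as.character(snp_ids),
         individual_ids = as.character(individual_ids),
         bim = bim, fam = fam),
    class = "packed_bed"
  )
}

#' @exportS3Method base::print
print.packed_bed <- function(x, ...) {
  cat(sprintf("packed_bed: %d individuals x %d SNPs (%d payload bytes)\n",
              x$n_individuals, x$n_snps, length(x$data)))
  invisible(x)
}

.bed_paths <- function(bed_path, bim_path, fam_path) {
  prefix <- sub("\\.bed$", "", bed_path)
  if (!grepl("\\.bed$", bed_path)) bed_path <- paste0(prefix, ".bed")
  if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
  if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  list(bed = bed_path, bim = bim_path, fam = fam_path)
}

#' Read a PLINK 1 binary genotype trio
#'
#' Reads `.bed`/`.bim`/`.fam` files bit-exactly into a [packed_bed()] object.
#' Only the SNP-major layout (mode byte `0x01`) is supported; individual-major
#' files are rejected.
#'
#' @param bed_path path to the `.bed` file, or the fileset prefix.
#' @param bim_path,fam_path optional explicit paths; derived from `bed_path`
#'   when `NULL`.
#' @return A `packed_bed` object whose `bim`/`fam` tables are carried through
#'   untouched (only the id columns are consumed).
#' @export
read_bed <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  paths <- .bed_paths(bed_path, bim_path, fam_path)
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  read_tsv6 <- function(path) {
    if (file.size(path) == 0) {
      return(data.frame(V1 = character(), V2 = character(), V3 = character(),
                        V4 = character(), V5 = character(), V6 = character()))
    }
    read.table(path, header = FALSE, colClasses = "character")
  }
  fam <- read_tsv6(paths$fam)
  bim <- read_tsv6(paths$bim)
  n_g <- nrow(fam)
  n_s <- nrow(bim)
  raw <- readBin(paths$bed, what = "raw", n = file.size(paths$bed))
  if (length(raw) < 3L || !identical(raw[1:2], .BED_MAGIC)) {
    stop("unsupported format: missing PLINK 1 .bed magic bytes", call. = FALSE)
  }
  if (!identical(raw[3L], .BED_SNP_MAJOR)) {
    stop("unsupported format: only SNP-major (mode 0x01) .bed files are supported",
         call. = FALSE)
  }
  payload <- raw[-(1:3)]
  expected <- n_s * ceiling(n_g / 4)
  if (length(payload) != expected) {
    stop(sprintf("corrupt file: payload has %d bytes, expected %d",
                 length(payload), expected), call. = FALSE)
  }
  packed_bed(payload, n_g, n_s,
             snp_ids = bim[[2L]], individual_ids = fam[[2L]],
             bim = bim, fam = fam)
}

#' Write a PLINK 1 binary genotype trio
#'
#' @param packed a [packed_bed()] object.
#' @param bed_path output `.bed` path or fileset prefix.
#' @param bim_path,fam_path optional explicit paths.
#' @return Invisibly, the list of paths written.
#' @export
write_bed <- function(packed, bed_path, bim_path = NULL, fam_path = NULL) {
  stopifnot(inherits(packed, "packed_bed"))
  paths <- .bed_paths(bed_path, bim_path, fam_path)
  con <- file(paths$bed, "wb")
  on.exit(close(con))
  writeBin(c(.BED_MAGIC, .BED_SNP_MAJOR, packed$data), con)
  bim <- packed$bim
  if (is.null(bim)) {
    ns <- packed$n_snps
    bim <- data.frame(V1 = rep("1", ns), V2 = packed$snp_ids,
                      V3 = rep("0", ns), V4 = as.character(seq_len(ns)),
                      V5 = rep("A", ns), V6 = rep("B", ns))
  }
  fam <- packed$fam
  if (is.null(fam)) {
    ng <- packed$n_individuals
    fam <- data.frame(V1 = packed$individual_ids, V2 = packed$individual_ids,
                      V3 = rep("0", ng), V4 = rep("0", ng),
                      V5 = rep("0", ng), V6 = rep("-9", ng))
  }
  write.table(bim, paths$bim, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(fam, paths$fam, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Dosage genotype matrix with explicit missing index
#'
#' Dosages count the allele whose homozygote carries bed code 3 (the
#' "alternate" homozygote). Missing calls are stored as dosage 0 together with
#' their `(individual, snp)` positions.
#'
#' @param dosages integer matrix (individuals x SNPs) with entries in `{0,1,2}`.
#' @param missing two-column integer matrix of 1-based `(individual, snp)`
#'   positions, or `NULL` for none. Dosages at missing positions must be 0.
#' @param snp_ids,individual_ids optional identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, missing = NULL, snp_ids = NULL,
                            individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (length(dosages) && !all(dosages %in% 0:2)) {
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  }
  if (is.null(missing)) {
    missing <- matrix(integer(), 0L, 2L)
  } else {
    missing <- matrix(as.integer(missing), ncol = 2L)
    if (nrow(missing)) {
      ord <- order(missing[, 2L], missing[, 1L])
      missing <- missing[ord, , drop = FALSE]
      if (any(dosages[missing] != 0L)) {
        stop("dosage at a missing position must be 0", call. = FALSE)
      }
    }
  }
  dimnames(missing) <- NULL
  n_g <- nrow(dosages)
  n_s <- ncol(dosages)
  if (is.null(snp_ids)) snp_ids <- if (n_s) paste0("snp", seq_len(n_s)) else character()
  if (is.null(individual_ids)) {
    individual_ids <- if (n_g) paste0("id", seq_len(n_g)) else character()
  }
  dimnames(dosages) <- NULL
  structure(
    list(dosages = dosages, missing = missing,
         snp_ids = as.character(snp_ids),
         individual_ids = as.character(individual_ids)),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, %d missing calls\n",
              nrow(x$dosages), ncol(x$dosages), nrow(x$missing)))
  invisible(x)
}

#' Unpack 2-bit codes into a dosage matrix
#'
#' Code 0 maps to dosage 0, code 2 to 1, code 3 to 2; code 1 marks a missing
#' call, stored as dosage 0 with its position recorded.
#'
#' @param packed a [packed_bed()] object.
#' @return A [genotype_matrix()].
#' @export
unpack_genotypes <- function(packed) {
  stopifnot(inherits(packed, "packed_bed"))
  n_g <- packed$n_individuals
  n_s <- packed$n_snps
  bps <- as.integer(ceiling(n_g / 4))
  if (n_s == 0L || n_g == 0L) {
    return(genotype_matrix(matrix(integer(), n_g, n_s),
                           snp_ids = packed$snp_ids,
                           individual_ids = packed$individual_ids))
  }
  codes4 <- .byte_codes[as.integer(packed$data) + 1L, , drop = FALSE]
  codes <- matrix(t(codes4), nrow = 4L * bps)[seq_len(n_g), , drop = FALSE]
  dosages <- matrix(.CODE_DOSAGE[codes + 1L], n_g, n_s)
  miss <- which(codes == 1L, arr.ind = TRUE)
  dimnames(miss) <- NULL
  genotype_matrix(dosages, missing = miss,
                  snp_ids = packed$snp_ids,
                  individual_ids = packed$individual_ids)
}

#' Pack a dosage matrix back into 2-bit codes
#'
#' Inverse of [unpack_genotypes()]: dosages 0/1/2 become codes 0/2/3 and
#' recorded missing positions become code 1. Pad bit-pairs are zero.
#'
#' @param g a [genotype_matrix()].
#' @return A [packed_bed()] object.
#' @export
pack_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_g <- nrow(g$dosages)
  n_s <- ncol(g$dosages)
  bps <- as.integer(ceiling(n_g / 4))
  codes <- matrix(.DOSAGE_CODE[g$dosages + 1L], n_g, n_s)
  if (nrow(g$missing)) codes[g$missing] <- 1L
  if (n_s == 0L) {
    return(packed_bed(raw(), n_g, n_s, snp_ids = g$snp_ids,
                      individual_ids = g$individual_ids))
  }
  pad <- 4L * bps - n_g
  if (pad > 0L) codes <- rbind(codes, matrix(0L, pad, n_s))
  cm <- matrix(codes, nrow = 4L)
  bytes <- as.raw(cm[1L, ] + 4L * cm[2L, ] + 16L * cm[3L, ] + 64L * cm[4L, ])
  packed_bed(bytes, n_g, n_s, snp_ids = g$snp_ids,
             individual_ids = g$individual_ids)
}

#' Observed allele frequencies from a dosage matrix
#'
#' For SNP `j`, `p_j` is the sum of non-missing dosages divided by twice the
#' number of non-missing calls. A SNP with every call missing gets `p_j = 0`
#' with a warning; monomorphic SNPs are retained (filtering is the caller's
#' job).
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
compute_allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_g <- nrow(g$dosages)
  n_s <- ncol(g$dosages)
  nmiss <- if (nrow(g$missing)) tabulate(g$missing[, 2L], n_s) else integer(n_s)
  denom <- 2 * (n_g - nmiss)
  p <- numeric(n_s)
  ok <- denom > 0
  p[ok] <- colSums(g$dosages)[ok] / denom[ok]
  if (any(!ok)) {
    warning(sprintf("%d SNP(s) with all calls missing; frequency set to 0",
                    sum(!ok)))
  }
  names(p) <- g$snp_ids
  p
}
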