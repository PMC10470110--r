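# Products of the genotype matrix M (and its centered version Z = M - 2 1 p')
# with narrow real matrices, computed through 243-entry lookup tables on the
# 5codes packing, directly on 2-bit codes, or densely as the reference oracle.
#
# Missing calls are packed as dosage 0. Two correction policies are exposed:
#   mean_impute (default): a missing entry contributes 0 to Z, i.e. the
#     -2 p_j lambda term the packed path implicitly adds is removed afterwards
#     by a sparse rank-structured correction;
#   zero_dosage: the literal packed value stands (dosage 0, so z = -2 p_j).

.MISSING_POLICIES <- c("mean_impute", "zero_dosage")

.chunk_blocks <- function(nb, chunks) {
  chunks <- max(1L, min(as.integer(chunks), nb))
  if (chunks == 1L) return(list(seq_len(nb)))
  rem <- nb %% chunks
  sizes <- rep.int(nb %/% chunks, chunks) +
    c(rep.int(1L, rem), rep.int(0L, chunks - rem))
  unname(split(seq_len(nb), rep.int(seq_len(chunks), sizes)))
}

# core table-lookup multiply: keys (nr x nb), lam ((<=5*nb) x k) zero-padded by
# the caller to 5*nb rows. Centering constants (per column x block) may be
# folded into the tables via `center2` = 2 * p' lambda per (block, column).
.lookup_product <- function(keys, lam_pad, center2 = NULL, chunks = 1L) {
  nr <- nrow(keys)
  nb <- ncol(keys)
  k <- ncol(lam_pad)
  out <- matrix(0, nr, k)
  if (nr == 0L || nb == 0L) return(out)
  groups <- .chunk_blocks(nb, chunks)
  # linear indices into the stacked tables; kept as a plain vector so that a
  # two-block matrix is not mistaken for (row, col) subscript pairs
  lin <- as.vector(keys + 1L) +
    rep.int((seq_len(nb) - 1L) * 243L, rep.int(nr, nb))
  for (c in seq_len(k)) {
    tab <- .DECODE243 %*% matrix(lam_pad[, c], nrow = 5L) # 243 x nb
    if (!is.null(center2)) tab <- sweep(tab, 2L, center2[, c], "-")
    vals <- matrix(tab[lin], nr, nb)
    acc <- numeric(nr)
    for (g in groups) {
      acc <- acc + rowSums(vals[, g, drop = FALSE])
    }
    out[, c] <- acc
  }
  out
}

.pad_rows <- function(lam, n_real, nb) {
  lam <- as.matrix(lam)
  if (nrow(lam) != n_real) stop("dimension error: trait matrix rows", call. = FALSE)
  pad <- 5L * nb - n_real
  if (pad > 0L) lam <- rbind(lam, matrix(0, pad, ncol(lam)))
  lam
}

.missing_indicator <- function(missing, n_g, n_s) {
  Matrix::sparseMatrix(i = missing[, 1L], j = missing[, 2L], x = 1,
                       dims = c(n_g, n_s))
}

#' Uncentered product M Lambda via lookup tables
#'
#' For each trait-matrix column, one 243-entry table per 5-SNP block is built
#' (`decode' lambda5`) and the product accumulates table lookups over blocks.
#' Missing calls enter as dosage 0 (no correction; see [z_times()] for the
#' centered, corrected product).
#'
#' @param fc a `fivecodes_matrix` in by-snp orientation.
#' @param lam numeric matrix with `fc$n_snps` rows and small width.
#' @param chunks number of contiguous block groups accumulated separately and
#'   summed once at the end, in fixed order (parallel-reduction contract).
#' @return Numeric matrix, individuals x traits.
#' @export
m_times <- function(fc, lam, chunks = 1L) {
  stopifnot(inherits(fc, "fivecodes_matrix"))
  if (fc$orientation != "by-snp") {
    stop("orientation error: m_times needs a by-snp packing", call. = FALSE)
  }
  lam_pad <- .pad_rows(lam, fc$n_snps, ncol(fc$keys))
  .lookup_product(fc$keys, lam_pad, chunks = chunks)
}

#' Transposed uncentered product M' Lambda~
#'
#' Uses the explicitly stored by-individual packing of M'; the lookup
#' machinery is identical to [m_times()] with individuals in the key digits.
#'
#' @param fcT a `fivecodes_matrix` in by-individual orientation (packs M').
#' @param lamT numeric matrix with `fcT$n_individuals` rows.
#' @param chunks reduction chunk count, as in [m_times()].
#' @return Numeric matrix, SNPs x traits.
#' @export
mt_times <- function(fcT, lamT, chunks = 1L) {
  stopifnot(inherits(fcT, "fivecodes_matrix"))
  if (fcT$orientation != "by-individual") {
    stop("orientation error: mt_times needs a by-individual packing", call. = FALSE)
  }
  lam_pad <- .pad_rows(lamT, fcT$n_individuals, ncol(fcT$keys))
  .lookup_product(fcT$keys, lam_pad, chunks = chunks)
}

#' Centered product Z Lambda = (M - 2 1 p') Lambda
#'
#' The centering is folded into the lookup tables (entry `k` stores
#' `decode(k)' lambda5 - 2 p5' lambda5`), which avoids a separate rank-one
#' subtraction and reduces accumulation error. Missing entries are then
#' corrected according to `missing_policy`.
#'
#' @param fc a `fivecodes_matrix` in by-snp orientation.
#' @param p allele-frequency vector of length `fc$n_snps`.
#' @param lam numeric matrix with `fc$n_snps` rows.
#' @param missing_policy `"mean_impute"` (missing contributes 0 to Z; default)
#'   or `"zero_dosage"` (missing keeps the packed dosage 0, i.e. z = -2 p_j).
#' @param chunks reduction chunk count.
#' @return Numeric matrix, individuals x traits.
#' @export
z_times <- function(fc, p, lam, missing_policy = .MISSING_POLICIES,
                    chunks = 1L) {
  stopifnot(inherits(fc, "fivecodes_matrix"))
  if (fc$orientation != "by-snp") {
    stop("orientation error: z_times needs a by-snp packing", call. = FALSE)
  }
  missing_policy <- match.arg(missing_policy)
  if (length(p) != fc$n_snps) stop("dimension error: length(p) != n_snps", call. = FALSE)
  nb <- ncol(fc$keys)
  lam_pad <- .pad_rows(lam, fc$n_snps, nb)
  p_pad <- c(as.numeric(p), numeric(5L * nb - fc$n_snps))
  # 2 * p5' lambda5 per (block, column), folded into the tables
  pm <- matrix(p_pad, nrow = 5L)
  center2 <- matrix(0, nb, ncol(lam_pad))
  for (c in seq_len(ncol(lam_pad))) {
    center2[, c] <- 2 * colSums(pm * matrix(lam_pad[, c], nrow = 5L))
  }
  out <- .lookup_product(fc$keys, lam_pad, center2 = center2, chunks = chunks)
  if (missing_policy == "mean_impute" && nrow(fc$missing)) {
    S <- .missing_indicator(fc$missing, fc$n_individuals, fc$n_snps)
    out <- out + 2 * as.matrix(S %*% (as.numeric(p) * as.matrix(lam)))
  }
  out
}

#' Transposed centered product Z' Lambda~
#'
#' Computed as `M' Lambda~ - 2 p (1' Lambda~)`: for the transposed product the
#' centering term depends on the output row's allele frequency, so it is a
#' rank-one subtraction rather than a table constant.
#'
#' @param fcT a `fivecodes_matrix` in by-individual orientation.
#' @param p allele-frequency vector of length `fcT$n_snps`.
#' @param lamT numeric matrix with `fcT$n_individuals` rows.
#' @param missing_policy as in [z_times()].
#' @param chunks reduction chunk count.
#' @return Numeric matrix, SNPs x traits.
#' @export
zt_times <- function(fcT, p, lamT, missing_policy = .MISSING_POLICIES,
                     chunks = 1L) {
  stopifnot(inherits(fcT, "fivecodes_matrix"))
  missing_policy <- match.arg(missing_policy)
  if (length(p) != fcT$n_snps) stop("dimension error: length(p) != n_snps", call. = FALSE)
  lamT <- as.matrix(lamT)
  out <- mt_times(fcT, lamT, chunks = chunks)
  out <- out - 2 * outer(as.numeric(p), colSums(lamT))
  if (missing_policy == "mean_impute" && nrow(fcT$missing)) {
    S <- .missing_indicator(fcT$missing, fcT$n_individuals, fcT$n_snps)
    out <- out + 2 * (as.numeric(p) * as.matrix(Matrix::crossprod(S, lamT)))
  }
  out
}

#' Products directly on the 2-bit packed representation
#'
#' Streams the PLINK payload one SNP at a time, extracting the four 2-bit
#' codes of each byte through a 256-entry table and multiplying the resulting
#' dosages immediately; the full matrix is never inflated. Code 1 is treated
#' as missing. Mathematical contract identical to [m_times()]/[z_times()] and
#' their transposed variants.
#'
#' @param pb a [packed_bed()] object.
#' @param lam trait matrix: `n_snps` rows when `transposed = FALSE`
#'   (computes M Lambda / Z Lambda), `n_individuals` rows when
#'   `transposed = TRUE` (computes M' Lambda~ / Z' Lambda~).
#' @param transposed logical.
#' @param p allele frequencies (required when `centered = TRUE`).
#' @param centered logical; compute the Z product.
#' @param missing_policy as in [z_times()].
#' @return Numeric matrix of the requested product.
#' @export
packed_bed_times <- function(pb, lam, transposed = FALSE, p = NULL,
                             centered = FALSE,
                             missing_policy = .MISSING_POLICIES) {
  stopifnot(inherits(pb, "packed_bed"))
  missing_policy <- match.arg(missing_policy)
  n_g <- pb$n_individuals
  n_s <- pb$n_snps
  lam <- as.matrix(lam)
  k <- ncol(lam)
  if (centered && length(p) != n_s) {
    stop("dimension error: length(p) != n_snps", call. = FALSE)
  }
  if (nrow(lam) != (if (transposed) n_g else n_s)) {
    stop("dimension error: trait matrix rows", call. = FALSE)
  }
  bps <- as.integer(ceiling(n_g / 4))
  bm <- matrix(as.integer(pb$data), bps, max(n_s, 0L))
  out <- if (transposed) matrix(0, n_s, k) else matrix(0, n_g, k)
  idx <- seq_len(n_g)
  for (j in seq_len(n_s)) {
    cj <- .byte_codes[bm[, j] + 1L, , drop = FALSE]
    v <- as.vector(t(cj))[idx]
    z <- as.numeric(.CODE_DOSAGE[v + 1L])
    miss <- v == 1L
    if (centered) {
      z <- z - 2 * p[j]
      if (missing_policy == "mean_impute" && any(miss)) z[miss] <- 0
    }
    if (transposed) {
      out[j, ] <- colSums(z * lam)
    } else {
      out <- out + tcrossprod(z, lam[j, ])
    }
  }
  out
}

#' Dense reference multiply (the oracle for every packed path)
#'
#' Literally materializes M (or Z) in double precision and calls `%*%`.
#' Intended for desk-scale verification, not production use.
#'
#' @param g a [genotype_matrix()].
#' @param p allele frequencies (needed for the centered modes).
#' @param lam trait matrix; `n_snps` rows for modes `"M"`/`"Z"`,
#'   `n_individuals` rows for `"Mt"`/`"Zt"`.
#' @param mode `"M"`, `"Z"`, `"Mt"` or `"Zt"`.
#' @param missing_policy as in [z_times()].
#' @return Dense numeric matrix.
#' @export
reference_dense_multiply <- function(g, p = NULL, lam,
                                     mode = c("M", "Z", "Mt", "Zt"),
                                     missing_policy = .MISSING_POLICIES) {
  stopifnot(inherits(g, "genotype_matrix"))
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  lam <- as.matrix(lam)
  X <- matrix(as.numeric(g$dosages), nrow(g$dosages), ncol(g$dosages))
  if (mode %in% c("Z", "Zt")) {
    stopifnot(length(p) == ncol(X))
    X <- sweep(X, 2L, 2 * as.numeric(p))
    if (nrow(g$missing)) {
      X[g$missing] <- if (missing_policy == "mean_impute") 0 else {
        -2 * as.numeric(p)[g$missing[, 2L]]
      }
    }
  }
  if (mode %in% c("Mt", "Zt")) crossprod(X, lam) else X %*% lam
}

#' Genomic relationship matrix G = Z Z' / m
#'
#' Z is centered at `2 p` with missing calls mean-imputed (z = 0), and
#' `m = 2 * sum(p_j (1 - p_j))` is the usual scaling so that G averages near
#' 1 on the diagonal under Hardy-Weinberg proportions.
#'
#' @param fc by-snp packing (used for dimension checks).
#' @param fcT by-individual packing of M', which drives the computation.
#' @param p allele frequencies.
#' @return Dense symmetric `n_individuals x n_individuals` matrix.
#' @export
compute_grm <- function(fc, fcT, p) {
  stopifnot(inherits(fc, "fivecodes_matrix"), inherits(fcT, "fivecodes_matrix"))
  if (fc$n_individuals != fcT$n_individuals || fc$n_snps != fcT$n_snps) {
    stop("dimension error: packings disagree", call. = FALSE)
  }
  m <- 2 * sum(p * (1 - p))
  if (m <= 0) stop("degenerate panel: no polymorphic SNP (m = 0)", call. = FALSE)
  Zt <- zt_times(fcT, p, diag(fcT$n_individuals), missing_policy = "mean_impute")
  G <- crossprod(Zt) / m
  dimnames(G) <- list(fc$individual_ids, fc$individual_ids)
  G
}
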