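# Pedigree algebra: the numerator relationship matrix A (tabular method, desk
# scale), inbreeding coefficients, and Henderson's rules for the sparse A^-1,
# partitioned into non-genotyped (n) and genotyped (g) blocks.

#' Pedigree frame
#'
#' Animal/sire/dam triples with a genotyped mask. Unknown parents are coded
#' `0` or `NA`. Parents must be animals of the pedigree; a pedigree listing an
#' animal before one of its parents is reordered internally (with a warning),
#' and cycles are an error.
#'
#' @param animal vector of unique animal ids.
#' @param sire,dam parent ids (0/`NA` = unknown).
#' @param genotyped logical mask, one entry per animal (default all `FALSE`).
#' @return An object of class `pedigree_frame` with integer parent indices
#'   (`sire_idx`/`dam_idx`, 0 = unknown) and a topological `order` permutation.
#' @export
pedigree_frame <- function(animal, sire, dam, genotyped = NULL) {
  n <- length(animal)
  if (anyDuplicated(animal)) stop("duplicate animal ids", call. = FALSE)
  if (length(sire) != n || length(dam) != n) {
    stop("animal, sire and dam must have equal length", call. = FALSE)
  }
  if (is.null(genotyped)) genotyped <- rep(FALSE, n)
  if (length(genotyped) != n) {
    stop("genotyped mask length must equal the number of animals", call. = FALSE)
  }
  to_idx <- function(par) {
    unknown <- is.na(par) | par == 0
    idx <- match(par, animal)
    idx[unknown] <- 0L
    if (any(is.na(idx))) {
      stop("pedigree error: parent id not in the animal list", call. = FALSE)
    }
    as.integer(idx)
  }
  sire_idx <- to_idx(sire)
  dam_idx <- to_idx(dam)
  if (any(sire_idx == seq_len(n)) || any(dam_idx == seq_len(n))) {
    stop("pedigree error: animal is its own parent", call. = FALSE)
  }
  # Kahn topological sort on parent -> offspring edges
  indeg <- (sire_idx > 0L) + (dam_idx > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (par in c(sire_idx[i], dam_idx[i])) {
      if (par > 0L) children[[par]] <- c(children[[par]], i)
    }
  }
  ord <- integer(0)
  queue <- which(indeg == 0L)
  deg <- indeg
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n) stop("pedigree error: cycle detected", call. = FALSE)
  already <- all(sire_idx < seq_len(n)) && all(dam_idx < seq_len(n))
  if (already) {
    ord <- seq_len(n)
  } else {
    warning("pedigree not in parent-before-offspring order; reordered internally")
  }
  structure(
    list(animal = animal, sire = sire, dam = dam,
         sire_idx = sire_idx, dam_idx = dam_idx,
         genotyped = as.logical(genotyped), order = ord, n = n),
    class = "pedigree_frame"
  )
}

#' @exportS3Method base::print
print.pedigree_frame <- function(x, ...) {
  cat(sprintf("pedigree_frame: %d animals (%d genotyped, %d founders)\n",
              x$n, sum(x$genotyped), sum(x$sire_idx == 0L & x$dam_idx == 0L)))
  invisible(x)
}

#' Numerator relationship matrix by the tabular method
#'
#' Recursive construction of the full dense A: for animal `i` with parents
#' `s`, `d` (processed in topological order),
#' `A[i, j] = (A[s, j] + A[d, j]) / 2` for earlier `j` and
#' `A[i, i] = 1 + A[s, d] / 2`, unknown parents contributing 0. O(n^2) memory,
#' intended for desk-scale pedigrees; refuses more than 2000 animals.
#'
#' @param ped a [pedigree_frame()].
#' @return Dense symmetric matrix in the input animal order.
#' @export
tabular_a <- function(ped) {
  stopifnot(inherits(ped, "pedigree_frame"))
  n <- ped$n
  if (n > 2000L) {
    stop("tabular_a is O(n^2) and capped at 2000 animals", call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (pos in seq_len(n)) {
    i <- ped$order[pos]
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    if (pos > 1L) {
      prev <- ped$order[seq_len(pos - 1L)]
      as_ <- if (s > 0L) A[s, prev] else numeric(pos - 1L)
      ad_ <- if (d > 0L) A[d, prev] else numeric(pos - 1L)
      val <- (as_ + ad_) / 2
      A[i, prev] <- val
      A[prev, i] <- val
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients
#'
#' `F_i = A(sire_i, dam_i) / 2`, zero for animals with an unknown parent.
#' Computed from the tabular relationship matrix (desk scale).
#'
#' @param ped a [pedigree_frame()].
#' @return Numeric vector of length `n`.
#' @export
inbreeding_coefficients <- function(ped) {
  A <- tabular_a(ped)
  f <- numeric(ped$n)
  both <- ped$sire_idx > 0L & ped$dam_idx > 0L
  if (any(both)) {
    f[both] <- A[cbind(ped$sire_idx[both], ped$dam_idx[both])] / 2
  }
  f
}

#' Sparse inverse of the pedigree relationship matrix (Henderson's rules)
#'
#' For animal `i` with Mendelian sampling variance `d_i`
#' (`1/2 - (F_s + F_d)/4` with both parents known, `3/4 - F_par/4` with one,
#' `1` with none) and `alpha_i = 1/d_i`, adds `alpha_i` at `(i,i)`,
#' `-alpha_i/2` between `i` and each known parent and `alpha_i/4` among the
#' known parents. With `use_inbreeding = FALSE` all `F` are taken as 0, giving
#' the classical alphas 2, 4/3 and 1.
#'
#' The inverse is partitioned by the genotyped mask into the blocks `Ann`,
#' `Ang`, `Agn`, `Agg` (superscript blocks of A^-1), and the Cholesky factor
#' of `Ann` is computed once for use by [agg_inverse_times()].
#'
#' @param ped a [pedigree_frame()].
#' @param use_inbreeding logical; use exact `alpha` from computed inbreeding.
#' @return An object of class `sparse_a_inverse`.
#' @export
build_a_inverse <- function(ped, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "pedigree_frame"))
  n <- ped$n
  f <- if (use_inbreeding) inbreeding_coefficients(ped) else numeric(n)
  s <- ped$sire_idx
  d <- ped$dam_idx
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], 0)
  nk <- (s > 0L) + (d > 0L)
  mend <- ifelse(nk == 2L, 0.5 - 0.25 * (fs + fd),
                 ifelse(nk == 1L, 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / mend
  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  for (pcol in list(s, d)) {
    has <- pcol > 0L
    if (any(has)) {
      add(idx[has], pcol[has], -alpha[has] / 2)
      add(pcol[has], idx[has], -alpha[has] / 2)
    }
  }
  for (q in list(s, d)) {
    for (r in list(s, d)) {
      has <- q > 0L & r > 0L
      if (any(has)) add(q[has], r[has], alpha[has] / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  n_idx <- which(!ped$genotyped)
  g_idx <- which(ped$genotyped)
  Ann <- Ainv[n_idx, n_idx, drop = FALSE]
  Ang <- Ainv[n_idx, g_idx, drop = FALSE]
  Agn <- Ainv[g_idx, n_idx, drop = FALSE]
  Agg <- Ainv[g_idx, g_idx, drop = FALSE]
  chol_nn <- if (length(n_idx)) {
    Matrix::Cholesky(Matrix::forceSymmetric(Ann), LDL = FALSE, perm = TRUE)
  } else NULL
  structure(
    list(Ainv = Ainv, Ann = Ann, Ang = Ang, Agn = Agn, Agg = Agg,
         n_idx = n_idx, g_idx = g_idx, inbreeding = f, chol_nn = chol_nn,
         animal = ped$animal),
    class = "sparse_a_inverse"
  )
}

#' @exportS3Method base::print
print.sparse_a_inverse <- function(x, ...) {
  cat(sprintf("sparse_a_inverse: %d animals (%d genotyped), %d non-zeros\n",
              nrow(x$Ainv), length(x$g_idx), Matrix::nnzero(x$Ainv)))
  invisible(x)
}

#' Apply the inverse of the genotyped-block relationship submatrix
#'
#' Evaluates `inv(A_gg) v` through the partitioned identity
#' `inv(A_gg) = Agg - Agn inv(Ann) Ang` (superscripts denote blocks of the
#' sparse A^-1), using forward/backward substitution with the precomputed
#' Cholesky factor of `Ann`. Neither `A_gg` nor its inverse is ever formed
#' densely.
#'
#' @param ainv a [build_a_inverse()] result.
#' @param v numeric vector over genotyped animals.
#' @return Numeric vector `inv(A_gg) %*% v`.
#' @export
agg_inverse_times <- function(ainv, v) {
  stopifnot(inherits(ainv, "sparse_a_inverse"))
  if (length(v) != length(ainv$g_idx)) {
    stop("dimension error: v must span the genotyped animals", call. = FALSE)
  }
  if (!length(ainv$n_idx)) return(as.numeric(ainv$Agg %*% v))
  t1 <- ainv$Ang %*% v
  t2 <- Matrix::solve(ainv$chol_nn, t1, system = "A")
  as.numeric(ainv$Agg %*% v - ainv$Agn %*% t2)
}
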