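# Single-step SNP BLUP: the joint precision matrix Sigma^-1 of
# (u_n, u_g, g), the Henderson mixed model equations for (b, u_n, u_g, g),
# and a matrix-free preconditioned conjugate gradient solver.
#
# Sigma^-1 = sigma_u^-2 *
#   [ Ann , Ang                         , 0
#     Agn , Agg + (1/w - 1) inv(A_gg)   , -(1/w) inv(A_gg) Z
#     0   , -(1/w) Z' inv(A_gg)         , (1/w) Z' inv(A_gg) Z + m/(1-w) I ]
# with Ann/Ang/Agn/Agg the blocks of the sparse pedigree inverse,
# m = 2 sum_j p_j (1 - p_j), and w in (0,1) the residual polygenic proportion.

#' Single-step SNP BLUP model container
#'
#' Bundles records, incidence matrices, the packed genotype kernels and the
#' variance parameters of the observation model
#' `y = X b + W_n u_n + W_g u_g + e`, where the genetic effect of a genotyped
#' animal decomposes as `u_g = a_g + Z g` (residual polygenic plus SNP
#' effects). The residual is homogeneous univariate, `var(e) = I sigma2_e`.
#'
#' @param y numeric record vector.
#' @param X fixed-effect incidence matrix (records x levels).
#' @param W_n,W_g 0/1 incidence matrices relating records to non-genotyped and
#'   genotyped animals; each record maps to exactly one animal overall.
#' @param fc,fcT by-snp and by-individual 5codes packings of the genotyped
#'   dosage matrix.
#' @param p allele frequencies used to center Z.
#' @param w residual polygenic proportion, strictly in (0, 1).
#' @param sigma2_u,sigma2_e additive-genetic and residual variances.
#' @param missing_policy missing-call policy for the Z products.
#' @return An object of class `ss_model`; `m = 2 sum p (1 - p)` is stored.
#' @export
ss_model <- function(y, X, W_n, W_g, fc, fcT, p, w, sigma2_u, sigma2_e,
                     missing_policy = c("mean_impute", "zero_dosage")) {
  missing_policy <- match.arg(missing_policy)
  if (!(w > 0 && w < 1)) stop("parameter error: w must lie in (0, 1)", call. = FALSE)
  if (sigma2_u <= 0 || sigma2_e <= 0) {
    stop("parameter error: variances must be positive", call. = FALSE)
  }
  X <- as(as(X, "CsparseMatrix"), "generalMatrix")
  W_n <- as(as(W_n, "CsparseMatrix"), "generalMatrix")
  W_g <- as(as(W_g, "CsparseMatrix"), "generalMatrix")
  nrec <- length(y)
  if (nrow(X) != nrec || nrow(W_n) != nrec || nrow(W_g) != nrec) {
    stop("dimension error: incidence rows must match records", call. = FALSE)
  }
  rs <- Matrix::rowSums(W_n) + Matrix::rowSums(W_g)
  if (any(rs != 1)) {
    stop("each record must map to exactly one animal", call. = FALSE)
  }
  stopifnot(inherits(fc, "fivecodes_matrix"), fc$orientation == "by-snp",
            inherits(fcT, "fivecodes_matrix"),
            fcT$orientation == "by-individual")
  if (ncol(W_g) != fc$n_individuals || length(p) != fc$n_snps) {
    stop("dimension error: genotype side inconsistent", call. = FALSE)
  }
  m <- 2 * sum(p * (1 - p))
  if (m <= 0) stop("degenerate panel: m = 2 sum p(1-p) must be positive", call. = FALSE)
  structure(
    list(y = as.numeric(y), X = X, W_n = W_n, W_g = W_g,
         fc = fc, fcT = fcT, p = as.numeric(p), m = m, w = w,
         sigma2_u = sigma2_u, sigma2_e = sigma2_e,
         missing_policy = missing_policy,
         n_fixed = ncol(X), n_nong = ncol(W_n), n_geno = ncol(W_g),
         n_snps = fc$n_snps),
    class = "ss_model"
  )
}

#' @exportS3Method base::print
print.ss_model <- function(x, ...) {
  cat(sprintf(paste0("ss_model: %d records, %d fixed, %d + %d animals ",
                     "(non-genotyped + genotyped), %d SNPs, w = %g\n"),
              length(x$y), x$n_fixed, x$n_nong, x$n_geno, x$n_snps, x$w))
  invisible(x)
}

.split_theta <- function(model, theta, with_fixed = TRUE) {
  sizes <- c(if (with_fixed) model$n_fixed else NULL,
             model$n_nong, model$n_geno, model$n_snps)
  stopifnot(length(theta) == sum(sizes))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(i) theta[starts[i]:ends[i]])
}

#' Matrix-free product with the joint precision matrix Sigma^-1
#'
#' Evaluates the three block-rows of `Sigma^-1 (v_n, v_g, v_snp)` without
#' assembling the matrix: sparse products for the pedigree blocks,
#' [agg_inverse_times()] for each `inv(A_gg)` application and
#' [z_times()]/[zt_times()] for each application of Z or Z'.
#'
#' @param model an [ss_model()].
#' @param ainv a [build_a_inverse()] result whose genotyped block matches the
#'   model's genotyped animals.
#' @param v numeric vector of length `n_nong + n_geno + n_snps`.
#' @return Numeric vector of the same length.
#' @export
sigma_inverse_times <- function(model, ainv, v) {
  stopifnot(inherits(model, "ss_model"), inherits(ainv, "sparse_a_inverse"))
  if (length(ainv$n_idx) != model$n_nong || length(ainv$g_idx) != model$n_geno) {
    stop("dimension error: pedigree blocks do not match the model", call. = FALSE)
  }
  parts <- .split_theta(model, v, with_fixed = FALSE)
  v_n <- parts[[1L]]; v_g <- parts[[2L]]; v_s <- parts[[3L]]
  iw <- 1 / model$w
  t1 <- agg_inverse_times(ainv, v_g)
  Zv <- as.numeric(z_times(model$fc, model$p, matrix(v_s, ncol = 1L),
                           missing_policy = model$missing_policy))
  t2 <- agg_inverse_times(ainv, Zv)
  r_n <- as.numeric(ainv$Ann %*% v_n + ainv$Ang %*% v_g)
  r_g <- as.numeric(ainv$Agn %*% v_n + ainv$Agg %*% v_g) +
    (iw - 1) * t1 - iw * t2
  zt1 <- as.numeric(zt_times(model$fcT, model$p, matrix(t1, ncol = 1L),
                             missing_policy = model$missing_policy))
  zt2 <- as.numeric(zt_times(model$fcT, model$p, matrix(t2, ncol = 1L),
                             missing_policy = model$missing_policy))
  r_s <- -iw * zt1 + iw * zt2 + model$m / (1 - model$w) * v_s
  c(r_n, r_g, r_s) / model$sigma2_u
}

#' Matrix-free product with the mixed-model coefficient matrix
#'
#' With `T = [X | W_n | W_g | 0]`, returns
#' `T' T theta + sigma2_e * blockdiag(0, Sigma^-1) theta` — the Henderson MME
#' multiplied through by `sigma2_e` so no record term carries `1/sigma2_e`.
#'
#' @param model an [ss_model()].
#' @param ainv a [build_a_inverse()] result.
#' @param theta numeric vector `(b, u_n, u_g, g)`.
#' @return Numeric vector of the same length.
#' @export
mme_operator_times <- function(model, ainv, theta) {
  parts <- .split_theta(model, theta)
  b <- parts[[1L]]; u_n <- parts[[2L]]; u_g <- parts[[3L]]; g <- parts[[4L]]
  eta <- as.numeric(model$X %*% b + model$W_n %*% u_n + model$W_g %*% u_g)
  sv <- sigma_inverse_times(model, ainv, c(u_n, u_g, g))
  se2 <- model$sigma2_e
  c(as.numeric(Matrix::crossprod(model$X, eta)),
    as.numeric(Matrix::crossprod(model$W_n, eta)) +
      se2 * sv[seq_len(model$n_nong)],
    as.numeric(Matrix::crossprod(model$W_g, eta)) +
      se2 * sv[model$n_nong + seq_len(model$n_geno)],
    se2 * sv[model$n_nong + model$n_geno + seq_len(model$n_snps)])
}

#' Preconditioned conjugate gradient with diagonal preconditioner
#'
#' Standard PCG for a symmetric positive (semi)definite operator given as a
#' function. Convergence is monitored by the squared relative residual
#' `||r||^2 / ||rhs||^2 < tol` (default `1e-13`); the history of that quantity
#' is recorded per iteration.
#'
#' @param operator function mapping a vector to the matrix-vector product.
#' @param rhs right-hand side.
#' @param preconditioner positive diagonal (numeric vector), or `NULL` for
#'   the identity.
#' @param tol convergence threshold on the squared relative residual.
#' @param max_iter iteration cap.
#' @return List with `x`, `iterations`, `residual_history`, `converged`.
#' @export
pcg_solve <- function(operator, rhs, preconditioner = NULL, tol = 1e-13,
                      max_iter = 5000L) {
  n <- length(rhs)
  if (is.null(preconditioner)) preconditioner <- rep(1, n)
  if (any(preconditioner <= 0)) {
    stop("preconditioner must be a positive diagonal", call. = FALSE)
  }
  x <- numeric(n)
  bnorm2 <- sum(rhs^2)
  if (bnorm2 == 0) {
    return(structure(list(x = x, iterations = 0L,
                          residual_history = numeric(0), converged = TRUE),
                     class = "pcg_result"))
  }
  r <- rhs
  z <- r / preconditioner
  pvec <- z
  rho <- sum(r * z)
  hist <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    q <- operator(pvec)
    denom <- sum(pvec * q)
    if (!is.finite(denom) || denom <= 0) {
      stop(sprintf("divergence error at iteration %d: operator not positive",
                   it), call. = FALSE)
    }
    alpha <- rho / denom
    x <- x + alpha * pvec
    r <- r - alpha * q
    res <- sum(r^2) / bnorm2
    if (!is.finite(res)) {
      stop(sprintf("divergence error at iteration %d: non-finite residual", it),
           call. = FALSE)
    }
    hist <- c(hist, res)
    if (res < tol) {
      converged <- TRUE
      break
    }
    z <- r / preconditioner
    rho_new <- sum(r * z)
    pvec <- z + (rho_new / rho) * pvec
    rho <- rho_new
  }
  structure(list(x = x, iterations = it, residual_history = hist,
                 converged = converged),
            class = "pcg_result")
}

#' @exportS3Method base::print
print.pcg_result <- function(x, ...) {
  cat(sprintf("pcg_result: %d iterations, %s (final squared rel. residual %.3e)\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              if (length(x$residual_history)) tail(x$residual_history, 1L) else 0))
  invisible(x)
}

#' Solve the single-step SNP BLUP equations matrix-free
#'
#' Builds the right-hand side `T' y`, a diagonal preconditioner (exact
#' diagonal of `T' T` plus the cheap diagonals of the `sigma2_e * Sigma^-1`
#' blocks: `diag(Ann)`, `diag(Agg)` and `m/(1-w)` for the SNP block — the
#' expensive diagonal of `(1/w) Z' inv(A_gg) Z` is omitted, which affects only
#' convergence speed, never the solution), and runs [pcg_solve()] with
#' [mme_operator_times()].
#'
#' @param model an [ss_model()].
#' @param ainv a [build_a_inverse()] result.
#' @param tol squared relative residual threshold (default `1e-13`).
#' @param max_iter iteration cap.
#' @return An object of class `ss_fit` with solution blocks `b`, `u_n`, `u_g`
#'   (total breeding values of genotyped animals), `g` (SNP effects), the
#'   combined breeding-value vector `u` in pedigree order, and the PCG
#'   diagnostics.
#' @export
solve_ssSNPBLUP <- function(model, ainv, tol = 1e-13, max_iter = 5000L) {
  stopifnot(inherits(model, "ss_model"), inherits(ainv, "sparse_a_inverse"))
  rhs <- c(as.numeric(Matrix::crossprod(model$X, model$y)),
           as.numeric(Matrix::crossprod(model$W_n, model$y)),
           as.numeric(Matrix::crossprod(model$W_g, model$y)),
           numeric(model$n_snps))
  ru <- model$sigma2_e / model$sigma2_u
  pc <- c(pmax(Matrix::colSums(model$X^2), 1e-8),
          Matrix::colSums(model$W_n^2) + ru * Matrix::diag(ainv$Ann),
          Matrix::colSums(model$W_g^2) + ru * Matrix::diag(ainv$Agg),
          rep(ru * model$m / (1 - model$w), model$n_snps))
  res <- pcg_solve(function(v) mme_operator_times(model, ainv, v),
                   rhs, preconditioner = pc, tol = tol, max_iter = max_iter)
  parts <- .split_theta(model, res$x)
  u <- numeric(model$n_nong + model$n_geno)
  u[ainv$n_idx] <- parts[[2L]]
  u[ainv$g_idx] <- parts[[3L]]
  structure(
    list(b = parts[[1L]], u_n = parts[[2L]], u_g = parts[[3L]],
         g = parts[[4L]], u = u, iterations = res$iterations,
         residual_history = res$residual_history, converged = res$converged),
    class = "ss_fit"
  )
}

#' @exportS3Method base::print
print.ss_fit <- function(x, ...) {
  cat(sprintf(paste0("ss_fit: %d fixed, %d + %d breeding values, %d SNP ",
                     "effects; %d PCG iterations (%s)\n"),
              length(x$b), length(x$u_n), length(x$u_g), length(x$g),
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Assemble an [ss_model()] from a simulated study
#'
#' Convenience wrapper: packs the study's genotypes both ways, recomputes the
#' observed allele frequencies, and carries over the study's variance
#' parameters.
#'
#' @param study a [simulate_study()] result.
#' @return An `ss_model`.
#' @export
ss_model_from_study <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  cfg <- study$config
  fc <- encode_matrix(study$genotypes, "by-snp")
  fcT <- transpose_packed(study$genotypes)
  ss_model(y = study$y, X = study$X, W_n = study$W_n, W_g = study$W_g,
           fc = fc, fcT = fcT, p = study$freq,
           w = cfg$w, sigma2_u = cfg$sigma2_u, sigma2_e = cfg$sigma2_e)
}
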