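# Dense oracles assembled from first principles (tabular relationship matrix,
# plain dense inverses and products), independent of the matrix-free paths.

# centered, mean-imputed dense Z built directly from dosages
dense_Z <- function(g, p, missing_policy = "mean_impute") {
  Z <- sweep(matrix(as.numeric(g$dosages), nrow(g$dosages)), 2L,
             2 * as.numeric(p))
  if (nrow(g$missing)) {
    Z[g$missing] <- if (missing_policy == "mean_impute") 0 else
      -2 * as.numeric(p)[g$missing[, 2L]]
  }
  Z
}

# dense joint precision of (u_n, u_g, g) from the tabular A
dense_sigma_inverse <- function(ped, g, p, w, sigma2_u) {
  A <- tabular_a(ped)
  nidx <- which(!ped$genotyped)
  gidx <- which(ped$genotyped)
  Ainv <- solve(A)
  Agg_inv <- solve(A[gidx, gidx, drop = FALSE])
  Z <- dense_Z(g, p)
  m <- 2 * sum(p * (1 - p))
  nn <- length(nidx)
  ns <- ncol(Z)
  S12 <- Ainv[nidx, gidx, drop = FALSE]
  S22 <- Ainv[gidx, gidx, drop = FALSE] + (1 / w - 1) * Agg_inv
  S23 <- -(1 / w) * Agg_inv %*% Z
  S33 <- (1 / w) * t(Z) %*% Agg_inv %*% Z + m / (1 - w) * diag(ns)
  rbind(
    cbind(Ainv[nidx, nidx, drop = FALSE], S12, matrix(0, nn, ns)),
    cbind(t(S12), S22, S23),
    cbind(matrix(0, ns, nn), t(S23), S33)
  ) / sigma2_u
}

# dense coefficient matrix and direct solve of the scaled MME
dense_mme <- function(study) {
  cfg <- study$config
  ns <- ncol(study$genotypes$dosages)
  Td <- cbind(as.matrix(study$X), as.matrix(study$W_n), as.matrix(study$W_g),
              matrix(0, length(study$y), ns))
  C <- crossprod(Td)
  Sig <- dense_sigma_inverse(study$pedigree, study$genotypes, study$freq,
                             cfg$w, cfg$sigma2_u)
  ridx <- (ncol(study$X) + 1):ncol(Td)
  C[ridx, ridx] <- C[ridx, ridx] + cfg$sigma2_e * Sig
  list(C = C, rhs = as.numeric(crossprod(Td, study$y)),
       theta = as.numeric(solve(C, crossprod(Td, study$y))))
}
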