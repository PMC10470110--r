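# Seeded synthetic data: multi-generation pedigrees, gene-dropped genotypes,
# phenotypes from the single-step observation model, and normal trait
# matrices. Everything is deterministic given the config seed; genotypes are
# gene-dropped (not sampled independently per animal) so pedigree and genomic
# relationships are mutually consistent.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's own
#' checks: a 5-generation pedigree (80 founders + 4 generations of 80, i.e.
#' 400 animals), 1000 SNPs with founder frequencies uniform on
#' `[0.05, 0.5]`, half of the animals (the youngest) genotyped, 1% missing
#' calls, residual polygenic proportion `w = 0.2`, unit variances, and a
#' trait-matrix width of 10.
#'
#' @param n_founders number of founder animals (>= 2).
#' @param n_generations number of non-founder generations.
#' @param offspring_per_mating offspring per mating pair;
#'   `floor(n_founders/2)` matings are formed per generation.
#' @param n_snps number of SNPs.
#' @param maf_range founder allele-frequency interval, within `(0, 0.5]`.
#' @param genotyped_fraction fraction of animals (the youngest) genotyped.
#' @param missing_rate per-call missing probability.
#' @param w residual polygenic proportion in (0, 1).
#' @param sigma2_u,sigma2_e additive-genetic and residual variances.
#' @param k trait-matrix width.
#' @param n_batches number of fixed-effect levels (1 = single mean; more adds
#'   a batch effect with cell-means coding).
#' @param seed integer seed; every generator call is reseeded from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_founders = 80L, n_generations = 4L,
                              offspring_per_mating = 2L, n_snps = 1000L,
                              maf_range = c(0.05, 0.5),
                              genotyped_fraction = 0.5, missing_rate = 0.01,
                              w = 0.2, sigma2_u = 1, sigma2_e = 1, k = 10L,
                              n_batches = 1L, seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 0, offspring_per_mating >= 1,
            n_snps >= 1, length(maf_range) == 2L, maf_range[1] > 0,
            maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
            genotyped_fraction > 0, genotyped_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            w > 0, w < 1, sigma2_u > 0, sigma2_e > 0, k >= 1, n_batches >= 1)
  structure(
    list(n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         offspring_per_mating = as.integer(offspring_per_mating),
         n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
         genotyped_fraction = genotyped_fraction,
         missing_rate = missing_rate, w = w,
         sigma2_u = sigma2_u, sigma2_e = sigma2_e, k = as.integer(k),
         n_batches = as.integer(n_batches), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

.sample_from <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]

#' Simulate a multi-generation pedigree
#'
#' Founders have unknown parents and alternating sexes. Each later generation
#' is formed by `floor(n_founders/2)` seeded random matings of males and
#' females of the previous generation, each producing
#' `offspring_per_mating` offspring. Animals are numbered in birth order, so
#' the pedigree is topological by construction. The youngest
#' `genotyped_fraction` of animals carry the genotyped flag.
#'
#' @param config a [simulation_config()].
#' @return A [pedigree_frame()].
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  animal <- seq_len(nf)
  sire <- dam <- rep(0L, nf)
  sex <- rep_len(c(1L, 2L), nf) # 1 = male, 2 = female
  prev <- animal
  prev_sex <- sex
  for (gen in seq_len(config$n_generations)) {
    males <- prev[prev_sex == 1L]
    females <- prev[prev_sex == 2L]
    nm <- max(1L, nf %/% 2L)
    sires <- .sample_from(males, nm)
    dams <- .sample_from(females, nm)
    noff <- nm * config$offspring_per_mating
    off <- max(animal) + seq_len(noff)
    animal <- c(animal, off)
    sire <- c(sire, rep(sires, each = config$offspring_per_mating))
    dam <- c(dam, rep(dams, each = config$offspring_per_mating))
    off_sex <- rep_len(c(1L, 2L), noff)
    sex <- c(sex, off_sex)
    prev <- off
    prev_sex <- off_sex
  }
  n <- length(animal)
  n_geno <- as.integer(ceiling(config$genotyped_fraction * n))
  genotyped <- rep(FALSE, n)
  genotyped[(n - n_geno + 1L):n] <- TRUE
  pedigree_frame(animal, sire, dam, genotyped = genotyped)
}

#' Gene-drop genotypes down a pedigree
#'
#' Per SNP, founder alleles are Bernoulli draws at a frequency sampled
#' uniformly from `maf_range`; every non-founder inherits one uniformly chosen
#' allele from each parent (Mendelian gene dropping). Missing calls are
#' injected at `missing_rate` over the genotyped subset and stored as dosage 0
#' plus an index entry.
#'
#' @param ped a [pedigree_frame()] (animals in birth order).
#' @param config a [simulation_config()].
#' @return List with `genotypes` (a [genotype_matrix()] over the genotyped
#'   subset), `freq` (observed frequencies) and `founder_freq` (the sampled
#'   founder frequencies).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree_frame"), inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  n <- ped$n
  ns <- config$n_snps
  q <- runif(ns, config$maf_range[1], config$maf_range[2])
  H1 <- matrix(0L, n, ns) # paternal gamete
  H2 <- matrix(0L, n, ns) # maternal gamete
  founders <- which(ped$sire_idx == 0L & ped$dam_idx == 0L)
  nf <- length(founders)
  pf <- rep(q, each = nf)
  H1[founders, ] <- matrix(rbinom(nf * ns, 1L, pf), nf, ns)
  H2[founders, ] <- matrix(rbinom(nf * ns, 1L, pf), nf, ns)
  for (i in ped$order) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    if (s == 0L && d == 0L) next
    H1[i, ] <- if (s > 0L) {
      ifelse(runif(ns) < 0.5, H1[s, ], H2[s, ])
    } else rbinom(ns, 1L, q)
    H2[i, ] <- if (d > 0L) {
      ifelse(runif(ns) < 0.5, H1[d, ], H2[d, ])
    } else rbinom(ns, 1L, q)
  }
  gidx <- which(ped$genotyped)
  dos <- H1[gidx, , drop = FALSE] + H2[gidx, , drop = FALSE]
  miss <- matrix(integer(), 0L, 2L)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(dos)) < config$missing_rate,
                   nrow(dos), ncol(dos))
    if (any(mask)) {
      miss <- which(mask, arr.ind = TRUE)
      dimnames(miss) <- NULL
      dos[mask] <- 0L
    }
  }
  g <- genotype_matrix(dos, missing = miss,
                       individual_ids = as.character(ped$animal[gidx]))
  list(genotypes = g, freq = compute_allele_frequencies(g), founder_freq = q)
}

#' Simulate phenotypes from the single-step observation model
#'
#' SNP effects `g ~ N(0, (1-w) sigma2_u / m)` with `m = 2 sum p(1-p)` from the
#' observed frequencies; polygenic values over all animals from the Cholesky
#' factor of the tabular relationship matrix, scaled to variance
#' `w * sigma2_u` (O(n^3), capped at 2000 animals; the identity shortcut is
#' used when all animals are founders); total genotyped values
#' `u_g = a_g + Z g` with Z mean-imputed; one record per animal,
#' `y = X b + u + e`, `e ~ N(0, sigma2_e)`.
#'
#' @param ped a [pedigree_frame()].
#' @param geno a [simulate_genotypes()] result for `ped`.
#' @param config a [simulation_config()].
#' @return An object of class `simulated_study` bundling the pedigree,
#'   genotypes, frequencies, true effects (`true_g`, `true_a`, `true_u`,
#'   `true_b`), records `y` with incidences `X`, `W_n`, `W_g`, and a trait
#'   matrix `lam` of width `k`.
#' @export
simulate_phenotypes <- function(ped, geno, config) {
  stopifnot(inherits(ped, "pedigree_frame"), inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n <- ped$n
  p <- geno$freq
  ns <- length(p)
  m <- 2 * sum(p * (1 - p))
  g_eff <- rnorm(ns, 0, sqrt((1 - config$w) * config$sigma2_u / m))
  all_founders <- all(ped$sire_idx == 0L & ped$dam_idx == 0L)
  a <- if (all_founders) {
    rnorm(n, 0, sqrt(config$w * config$sigma2_u))
  } else {
    A <- tabular_a(ped)
    U <- chol(A)
    sqrt(config$w * config$sigma2_u) * as.numeric(crossprod(U, rnorm(n)))
  }
  gidx <- which(ped$genotyped)
  Z <- sweep(matrix(as.numeric(geno$genotypes$dosages),
                    nrow(geno$genotypes$dosages)), 2L, 2 * p)
  if (nrow(geno$genotypes$missing)) Z[geno$genotypes$missing] <- 0
  u <- a
  u[gidx] <- u[gidx] + as.numeric(Z %*% g_eff)
  batch <- rep_len(seq_len(config$n_batches), n)
  X <- Matrix::sparseMatrix(i = seq_len(n), j = batch, x = 1,
                            dims = c(n, config$n_batches))
  true_b <- 10 + (seq_len(config$n_batches) - 1)
  e <- rnorm(n, 0, sqrt(config$sigma2_e))
  y <- as.numeric(X %*% true_b) + u + e
  W <- Matrix::Diagonal(n)
  n_idx <- which(!ped$genotyped)
  structure(
    list(config = config, pedigree = ped, genotypes = geno$genotypes,
         freq = p, founder_freq = geno$founder_freq,
         true_g = g_eff, true_a = a, true_u = u, true_b = true_b,
         y = y, X = X,
         W_n = W[, n_idx, drop = FALSE], W_g = W[, gidx, drop = FALSE],
         lam = simulate_trait_matrix(ns, config$k, seed = config$seed + 3L)),
    class = "simulated_study"
  )
}

#' @exportS3Method base::print
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("simulated_study: %d animals (%d genotyped), %d SNPs, ",
                     "%d records, seed %d\n"),
              x$pedigree$n, sum(x$pedigree$genotyped),
              ncol(x$genotypes$dosages), length(x$y), x$config$seed))
  invisible(x)
}

#' Standard-normal trait matrix
#'
#' i.i.d. `N(0, 1)` entries; the default width of 10 columns matches the
#' width the multiplication engine is calibrated against.
#'
#' @param n_rows number of rows.
#' @param k width (default 10).
#' @param seed optional seed applied before drawing.
#' @return Numeric `n_rows x k` matrix.
#' @export
simulate_trait_matrix <- function(n_rows, k = 10L, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n_rows * k), n_rows, k)
}

#' Run the full generator
#'
#' Pedigree, gene-dropped genotypes and phenotypes in one call; bit-identical
#' across runs for a fixed config.
#'
#' @param config a [simulation_config()].
#' @return A `simulated_study`.
#' @export
simulate_study <- function(config = simulation_config()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  simulate_phenotypes(ped, geno, config)
}
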