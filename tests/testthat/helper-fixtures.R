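# Fixtures built in code, independent of the package's own generator where
# the generator itself is under test.

# random dosage matrix with optional missing calls (dosage zeroed at missing)
rand_genotype_matrix <- function(n_g, n_s, missing_rate = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_g * n_s, replace = TRUE), n_g, n_s)
  miss <- NULL
  if (missing_rate > 0) {
    mask <- matrix(runif(n_g * n_s) < missing_rate, n_g, n_s)
    if (any(mask)) {
      miss <- which(mask, arr.ind = TRUE)
      dimnames(miss) <- NULL
      d[mask] <- 0L
    }
  }
  genotype_matrix(d, missing = miss)
}

# random valid pedigree: parents drawn from earlier animals or unknown
rand_pedigree <- function(n, seed = 1, p_unknown = 0.25,
                          genotyped_fraction = 0.5) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) > p_unknown) {
      sire[i] <- sample.int(i - 1L, 1L)
      dam[i] <- sample.int(i - 1L, 1L)
      if (dam[i] == sire[i]) dam[i] <- 0L
    }
  }
  genotyped <- rep(FALSE, n)
  genotyped[sample.int(n, ceiling(genotyped_fraction * n))] <- TRUE
  pedigree_frame(seq_len(n), sire, dam, genotyped = genotyped)
}

rel_err <- function(x, ref) {
  denom <- max(abs(ref))
  if (denom == 0) max(abs(x)) else max(abs(x - ref)) / denom
}
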