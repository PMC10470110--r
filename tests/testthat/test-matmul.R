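test_that("all packed paths agree with the dense reference across random instances", {
  cases <- expand.grid(seed = 1:12, miss = c(0, 0.02, 0.2))
  worst <- 0
  for (i in seq_len(nrow(cases))) {
    set.seed(1000 + i)
    n_g <- sample(1:200, 1)
    n_s <- sample(1:200, 1)
    k <- sample(1:10, 1)
    g <- rand_genotype_matrix(n_g, n_s, missing_rate = cases$miss[i],
                              seed = cases$seed[i] * 31 + i)
    # tiny instances can have an all-missing SNP; p = 0 there is the intended
    # behaviour and is itself tested elsewhere
    p <- suppressWarnings(compute_allele_frequencies(g))
    pb <- pack_genotypes(g)
    fc <- encode_matrix(g)
    fcT <- transpose_packed(g)
    lam <- matrix(rnorm(n_s * k), n_s, k)
    lamT <- matrix(rnorm(n_g * k), n_g, k)

    errs <- c(
      rel_err(m_times(fc, lam), reference_dense_multiply(g, lam = lam, mode = "M")),
      rel_err(mt_times(fcT, lamT), reference_dense_multiply(g, lam = lamT, mode = "Mt")),
      rel_err(z_times(fc, p, lam), reference_dense_multiply(g, p, lam, "Z")),
      rel_err(zt_times(fcT, p, lamT), reference_dense_multiply(g, p, lamT, "Zt")),
      rel_err(z_times(fc, p, lam, "zero_dosage"),
              reference_dense_multiply(g, p, lam, "Z", "zero_dosage")),
      rel_err(packed_bed_times(pb, lam, FALSE, p, centered = TRUE),
              reference_dense_multiply(g, p, lam, "Z")),
      rel_err(packed_bed_times(pb, lamT, TRUE, p, centered = TRUE),
              reference_dense_multiply(g, p, lamT, "Zt")),
      rel_err(packed_bed_times(pb, lam), reference_dense_multiply(g, lam = lam, mode = "M"))
    )
    worst <- max(worst, errs)
  }
  expect_lt(worst, 1e-10)
})

test_that("trivial trait matrices give the expected closed forms", {
  g <- rand_genotype_matrix(50, 23, seed = 8)
  p <- compute_allele_frequencies(g)
  fc <- encode_matrix(g)
  fcT <- transpose_packed(g)

  expect_equal(m_times(fc, matrix(0, 23, 4)), matrix(0, 50, 4))
  expect_equal(zt_times(fcT, p, matrix(0, 50, 2)), matrix(0, 23, 2))
  # column of ones -> row sums of M / column dosage sums of M
  expect_equal(as.numeric(m_times(fc, matrix(1, 23, 1))), rowSums(g$dosages))
  expect_equal(as.numeric(mt_times(fcT, matrix(1, 50, 1))), colSums(g$dosages))
  # with observed p and no missing, columns of Z Lambda sum to zero
  lam <- matrix(rnorm(23 * 3), 23, 3)
  expect_equal(colSums(z_times(fc, p, lam)), rep(0, 3), tolerance = 1e-12)
})

test_that("the two missing policies differ by exactly the correction term", {
  g <- rand_genotype_matrix(10, 8, seed = 21)
  d <- g$dosages
  d[3, 5] <- 0L
  g <- genotype_matrix(d, missing = rbind(c(3L, 5L)))
  p <- compute_allele_frequencies(g)
  fc <- encode_matrix(g)
  lam <- matrix(rnorm(8 * 3), 8, 3)
  mi <- z_times(fc, p, lam, "mean_impute")
  zd <- z_times(fc, p, lam, "zero_dosage")
  diff <- mi - zd
  expect_equal(diff[3, ], 2 * p[5] * lam[5, ], ignore_attr = TRUE)
  expect_equal(diff[-3, ], matrix(0, 9, 3))
})

test_that("an all-missing SNP row of Z' Lambda~ is zero under mean imputation", {
  g <- rand_genotype_matrix(12, 6, seed = 22)
  d <- g$dosages
  d[, 4] <- 0L
  g <- genotype_matrix(d, missing = cbind(1:12, 4L))
  suppressWarnings(p <- compute_allele_frequencies(g))
  fcT <- transpose_packed(g)
  lamT <- matrix(rnorm(12 * 3), 12, 3)
  out <- zt_times(fcT, p, lamT, "mean_impute")
  expect_equal(out[4, ], rep(0, 3))
})

test_that("the products are linear in the trait matrix", {
  g <- rand_genotype_matrix(40, 31, missing_rate = 0.05, seed = 13)
  p <- compute_allele_frequencies(g)
  fc <- encode_matrix(g)
  set.seed(14)
  l1 <- matrix(rnorm(31 * 2), 31, 2)
  l2 <- matrix(rnorm(31 * 2), 31, 2)
  expect_equal(z_times(fc, p, l1 + l2), z_times(fc, p, l1) + z_times(fc, p, l2),
               tolerance = 1e-12)
  expect_equal(m_times(fc, 3.5 * l1), 3.5 * m_times(fc, l1), tolerance = 1e-12)
})

test_that("chunked reduction matches single-chunk execution", {
  g <- rand_genotype_matrix(60, 97, missing_rate = 0.02, seed = 15)
  p <- compute_allele_frequencies(g)
  fc <- encode_matrix(g)
  fcT <- transpose_packed(g)
  lam <- matrix(rnorm(97 * 4), 97, 4)
  lamT <- matrix(rnorm(60 * 4), 60, 4)
  one <- z_times(fc, p, lam, chunks = 1)
  oneT <- zt_times(fcT, p, lamT, chunks = 1)
  for (ch in c(2, 3, 7, 50)) {
    expect_equal(z_times(fc, p, lam, chunks = ch), one, tolerance = 1e-12)
    expect_equal(zt_times(fcT, p, lamT, chunks = ch), oneT, tolerance = 1e-12)
  }
})

test_that("shape and orientation errors are caught", {
  g <- rand_genotype_matrix(6, 10, seed = 16)
  p <- compute_allele_frequencies(g)
  fc <- encode_matrix(g)
  fcT <- transpose_packed(g)
  expect_error(m_times(fc, matrix(0, 9, 1)), "dimension")
  expect_error(m_times(fcT, matrix(0, 6, 1)), "orientation")
  expect_error(mt_times(fc, matrix(0, 10, 1)), "orientation")
  expect_error(z_times(fc, p[-1], matrix(0, 10, 1)), "dimension")
})

test_that("a single byte multiplies to the hand-computed dosage sum", {
  pb <- packed_bed(as.raw(0xE4), 4, 1)
  out <- packed_bed_times(pb, matrix(1, 1, 1))
  expect_equal(sum(out), 3) # dosages 0,0,1,2 (code 1 missing -> 0)
})

test_that("the GRM matches its definition and is a PSD Gram matrix", {
  g <- genotype_matrix(matrix(c(0L, 2L), 1, 2))
  p <- c(0.5, 0.5)
  G <- compute_grm(encode_matrix(g), transpose_packed(g), p)
  expect_equal(as.numeric(G), 2) # Z = (-1, 1), m = 1

  g <- rand_genotype_matrix(25, 60, missing_rate = 0.05, seed = 17)
  p <- compute_allele_frequencies(g)
  G <- compute_grm(encode_matrix(g), transpose_packed(g), p)
  Z <- dense_Z(g, p)
  expect_equal(unname(G), Z %*% t(Z) / (2 * sum(p * (1 - p))), tolerance = 1e-10)
  expect_equal(unname(G), unname(t(G)), tolerance = 1e-12)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  gm <- genotype_matrix(matrix(2L, 3, 2)) # monomorphic panel: m = 0
  expect_error(compute_grm(encode_matrix(gm), transpose_packed(gm), c(1, 1)),
               "degenerate")
})
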