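# desk-scale study shared across the solver tests
small_study <- function(seed = 7) {
  simulate_study(simulation_config(n_founders = 40, n_generations = 3,
                                   n_snps = 200, seed = seed))
}

test_that("the matrix-free Sigma-inverse equals its dense assembly", {
  st <- small_study()
  model <- ss_model_from_study(st)
  ainv <- build_a_inverse(st$pedigree)
  Sig <- dense_sigma_inverse(st$pedigree, st$genotypes, st$freq,
                             st$config$w, st$config$sigma2_u)
  n <- ncol(Sig)
  set.seed(1)
  for (rep in 1:3) {
    v <- rnorm(n)
    expect_equal(sigma_inverse_times(model, ainv, v), as.numeric(Sig %*% v),
                 tolerance = 1e-8)
  }
  expect_equal(sigma_inverse_times(model, ainv, rep(0, n)), rep(0, n))
  # the assembled precision matrix is positive definite for w in (0,1)
  expect_gt(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("the matrix-free MME operator equals the dense coefficient matrix", {
  st <- small_study()
  model <- ss_model_from_study(st)
  ainv <- build_a_inverse(st$pedigree)
  oracle <- dense_mme(st)
  n <- ncol(oracle$C)
  set.seed(2)
  theta <- rnorm(n)
  expect_equal(mme_operator_times(model, ainv, theta),
               as.numeric(oracle$C %*% theta), tolerance = 1e-8)
  expect_equal(mme_operator_times(model, ainv, rep(0, n)), rep(0, n))
  # doubling sigma2_e doubles only the Sigma-inverse contribution
  st2 <- st
  st2$config$sigma2_e <- 2 * st$config$sigma2_e
  model2 <- ss_model_from_study(st2)
  d <- mme_operator_times(model2, ainv, theta) -
    mme_operator_times(model, ainv, theta)
  sv <- sigma_inverse_times(model, ainv, theta[-seq_len(model$n_fixed)])
  expect_equal(d, st$config$sigma2_e * c(rep(0, model$n_fixed), sv),
               tolerance = 1e-10)
})

test_that("PCG reproduces closed-form and identity solutions", {
  # identity operator: one iteration, solution equals the rhs
  rhs <- c(3, -1, 2)
  res <- pcg_solve(identity, rhs)
  expect_equal(res$x, rhs)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)

  # [[4,1],[1,3]] x = (1,2) has the exact solution (1/11, 7/11)
  op <- function(v) as.numeric(rbind(c(4, 1), c(1, 3)) %*% v)
  res <- pcg_solve(op, c(1, 2))
  expect_equal(res$x, c(1 / 11, 7 / 11), tolerance = 1e-10)

  # zero rhs short-circuits
  res <- pcg_solve(op, c(0, 0))
  expect_equal(res$x, c(0, 0))
  expect_equal(res$iterations, 0L)

  # indefinite operator raises a divergence error with the iteration index
  expect_error(pcg_solve(function(v) -v, c(1, 1)), "iteration 1")
})

test_that("the matrix-free ssSNPBLUP solution matches a dense direct solve", {
  st <- small_study()
  model <- ss_model_from_study(st)
  ainv <- build_a_inverse(st$pedigree)
  fit <- solve_ssSNPBLUP(model, ainv, tol = 1e-13)
  expect_true(fit$converged)
  oracle <- dense_mme(st)
  splits <- rep(1:4, c(model$n_fixed, model$n_nong, model$n_geno, model$n_snps))
  blocks <- split(oracle$theta, splits)
  expect_lt(rel_err(fit$b, blocks[[1]]), 1e-5)
  expect_lt(rel_err(fit$u_n, blocks[[2]]), 1e-5)
  expect_lt(rel_err(fit$u_g, blocks[[3]]), 1e-5)
  expect_lt(rel_err(fit$g, blocks[[4]]), 1e-5)
  # squared relative residual is recorded and ends below the first entry
  expect_lt(tail(fit$residual_history, 1), fit$residual_history[1])
  expect_lt(tail(fit$residual_history, 1), 1e-13)

  # zero records give the zero solution
  st0 <- st
  st0$y <- rep(0, length(st$y))
  fit0 <- solve_ssSNPBLUP(ss_model_from_study(st0), ainv)
  expect_equal(c(fit0$b, fit0$u, fit0$g), rep(0, length(oracle$theta)))
})

test_that("loosening the stopping tolerance leaves the solution stable", {
  # a squared relative residual of 1e-10 is a relative residual of 1e-5; the
  # solution perturbation it admits is that times the (preconditioned)
  # condition number, so block-scale agreement to ~1e-3 is what the stopping
  # rule guarantees here
  st <- small_study(seed = 8)
  model <- ss_model_from_study(st)
  ainv <- build_a_inverse(st$pedigree)
  tight <- solve_ssSNPBLUP(model, ainv, tol = 1e-13)
  loose <- solve_ssSNPBLUP(model, ainv, tol = 1e-10)
  for (bl in c("b", "u_n", "u_g", "g")) {
    expect_lt(max(abs(tight[[bl]] - loose[[bl]])) / max(abs(tight[[bl]])), 1e-3)
  }
})

test_that("estimated breeding values track the simulated truth", {
  st <- simulate_study(simulation_config(n_founders = 80, n_generations = 4,
                                         n_snps = 300, seed = 11))
  expect_equal(sum(st$pedigree$genotyped), 200) # 200 genotyped of 400
  model <- ss_model_from_study(st)
  ainv <- build_a_inverse(st$pedigree)
  fit <- solve_ssSNPBLUP(model, ainv)
  r_true <- cor(fit$u, st$true_u)

  set.seed(99)
  stp <- st
  stp$y <- sample(st$y)
  fitp <- solve_ssSNPBLUP(ss_model_from_study(stp), ainv)
  r_perm <- cor(fitp$u, st$true_u)
  expect_gt(r_true, 0)
  expect_gt(r_true, r_perm)
})

test_that("model construction validates its inputs", {
  st <- small_study()
  cfg <- st$config
  fc <- encode_matrix(st$genotypes)
  fcT <- transpose_packed(st$genotypes)
  build <- function(w = cfg$w, s2u = cfg$sigma2_u, s2e = cfg$sigma2_e,
                    W_n = st$W_n) {
    ss_model(st$y, st$X, W_n, st$W_g, fc, fcT, st$freq, w, s2u, s2e)
  }
  expect_s3_class(build(), "ss_model")
  expect_error(build(w = 1), "parameter error")
  expect_error(build(w = 0), "parameter error")
  expect_error(build(s2e = 0), "parameter error")
  expect_error(build(W_n = st$W_n * 2), "exactly one animal")
})
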