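quick_settings <- function(seed = 1, ...) {
  mcmc_settings(n_iter = 4000, burn_in = 1000, thin = 2, seed = seed, ...)
}

test_that("chains are bitwise reproducible from the seed", {
  ds <- make_prior_comparison_dataset(0.25, seed = 2, n = 120, n_markers = 8)
  X <- matrix(1, 120, 1, dimnames = list(NULL, "(Intercept)"))
  st <- mcmc_settings(n_iter = 600, burn_in = 100, thin = 2, seed = 99)
  a1 <- run_bayes_a(X, ds$genotypes$values, ds$phenotypes$bc, st)
  a2 <- run_bayes_a(X, ds$genotypes$values, ds$phenotypes$bc, st)
  expect_identical(a1$alpha_samples, a2$alpha_samples)
  expect_identical(a1$sigma2e_samples, a2$sigma2e_samples)
  c1 <- run_bayes_cpi(X, ds$genotypes$values, ds$phenotypes$bc, st)
  c2 <- run_bayes_cpi(X, ds$genotypes$values, ds$phenotypes$bc, st)
  expect_identical(c1$alpha_samples, c2$alpha_samples)
  expect_identical(c1$pi_samples, c2$pi_samples)
})

test_that("with no markers the fixed-effect posterior centers on OLS", {
  set.seed(5)
  n <- 150
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  y <- drop(X %*% c(3, 1.5)) + rnorm(n)
  M <- matrix(numeric(0), n, 0)
  post <- run_bayes_a(X, M, y, quick_settings(seed = 6))
  ols <- ols_oracle(X, y)
  mc_se <- apply(post$fixed_samples, 2, sd) / sqrt(post$n_kept / 10)
  expect_lt(abs(mean(post$fixed_samples[, 1]) - ols$beta[1]),
            3 * mc_se[1] + 0.02)
  expect_lt(abs(mean(post$fixed_samples[, 2]) - ols$beta[2]),
            3 * mc_se[2] + 0.02)
  # a zero-marker model has a deterministic D of zero
  expect_equal(post$D_mean, 0)
})

test_that("single-SNP posterior matches the conjugate closed form", {
  set.seed(8)
  n <- 80
  g <- rbinom(n, 2, 0.5)
  y <- 5 + 0.8 * g + rnorm(n, sd = 1)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  s2e <- 1; s2a <- 0.5
  post <- run_bayes_a(X, matrix(g, dimnames = list(NULL, "g")), y,
                      quick_settings(seed = 9, fix_sigma2_e = s2e,
                                     fix_sigma2_alpha = s2a))
  # closed form: flat prior on the intercept, N(0, s2a) on the effect
  W <- cbind(X, g)
  prec <- crossprod(W) / s2e + diag(c(0, 1 / s2a))
  Vpost <- solve(prec)
  mpost <- drop(Vpost %*% crossprod(W, y)) / s2e
  mc_se <- post$summary$sd / sqrt(post$n_kept / 10)
  expect_lt(abs(post$summary$mean - mpost[2]), 3 * mc_se + 0.01)
  expect_equal(post$summary$sd, sqrt(Vpost[2, 2]), tolerance = 0.15)
})

test_that("spike-and-slab with pi fixed at 0 matches the ridge closed form", {
  set.seed(12)
  n <- 100
  M <- matrix(rbinom(3 * n, 2, 0.4), n, dimnames = list(NULL, c("g1", "g2", "g3")))
  y <- 4 + drop(M %*% c(0.6, 0, -0.6)) + rnorm(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  s2e <- 1; s2a <- 0.4
  post <- run_bayes_cpi(X, M, y,
                        quick_settings(seed = 13, fix_sigma2_e = s2e,
                                       fix_sigma2_alpha = s2a, pi_fixed = 0))
  expect_true(all(post$summary$pp_nonnull == 1))
  W <- cbind(X, M)
  prec <- crossprod(W) / s2e + diag(c(0, rep(1 / s2a, 3)))
  mpost <- drop(solve(prec, crossprod(W, y))) / s2e
  mc_se <- post$summary$sd / sqrt(post$n_kept / 10)
  expect_true(all(abs(post$summary$mean - mpost[-1]) < 3 * mc_se + 0.02))
})

test_that("pi behaves like its posterior should: prior without data, high under
           the null, near-prior for weak small-sample data", {
  n <- 100
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  set.seed(21)
  y <- rnorm(n, 10)

  # no markers: pi keeps its Uniform(0,1) prior (mean 1/2)
  post0 <- run_bayes_cpi(X, matrix(numeric(0), n, 0), y,
                         quick_settings(seed = 22))
  expect_lt(abs(post0$pi_posterior_mean - 0.5), 0.05)

  # all-null markers at decent n: posterior shifts toward exclusion
  dsn <- make_prior_comparison_dataset(0, seed = 23)
  Xn <- matrix(1, 500, 1)
  postn <- run_bayes_cpi(Xn, dsn$genotypes$values, dsn$phenotypes$bc,
                         quick_settings(seed = 24))
  expect_gt(postn$pi_posterior_mean, 0.5)

  # tiny sample drowned in noise: pi cannot move far from its prior mean
  dsw <- make_prior_comparison_dataset(0.25, seed = 25, n = 30, resid_sd = 25)
  Xw <- matrix(1, 30, 1)
  postw <- run_bayes_cpi(Xw, dsw$genotypes$values, dsw$phenotypes$bc,
                         quick_settings(seed = 26))
  expect_lt(abs(postw$pi_posterior_mean - 0.5), 0.15)
})

test_that("posterior means are shrunken relative to OLS", {
  ds <- make_prior_comparison_dataset(0.25, seed = 31)
  X <- matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)"))
  ols <- ols_oracle(cbind(X, ds$genotypes$values), ds$phenotypes$bc)
  ols_abs <- sum(abs(ols$beta[-1]))
  posta <- run_bayes_a(X, ds$genotypes$values, ds$phenotypes$bc,
                       quick_settings(seed = 32))
  postc <- run_bayes_cpi(X, ds$genotypes$values, ds$phenotypes$bc,
                         quick_settings(seed = 33))
  expect_lte(sum(abs(posta$summary$mean)), ols_abs + 1e-8)
  expect_lte(sum(abs(postc$summary$mean)), ols_abs + 1e-8)
})

test_that("PP tables use strict thresholds and nest across levels", {
  ds <- make_prior_comparison_dataset(0.25, seed = 41, n = 200, n_markers = 10)
  X <- matrix(1, 200, 1)
  post <- run_bayes_a(X, ds$genotypes$values, ds$phenotypes$bc,
                      quick_settings(seed = 42))
  tab <- pp_sign_table(post)
  sets <- tab$snps
  expect_true(all(sets[["pp>0.8"]] %in% sets[["pp>0.7"]]))
  expect_true(all(sets[["pp>0.7"]] %in% sets[["pp>0.5"]]))
  # a marker split exactly 50/50 between signs is listed nowhere
  post_tie <- post
  post_tie$summary$pp_positive[1] <- 0.5
  post_tie$summary$pp_negative[1] <- 0.5
  tie_tab <- pp_sign_table(post_tie)
  expect_false(post_tie$summary$snp_id[1] %in% tie_tab$snps[["pp>0.5"]])

  postc <- run_bayes_cpi(X, ds$genotypes$values, ds$phenotypes$bc,
                         quick_settings(seed = 43))
  itab <- pp_inclusion_table(postc)
  expect_true(all(itab$snps[["pp>0.2"]] %in% itab$snps[["pp>0.1"]]))
  expect_true(all(itab$snps[["pp>0.1"]] %in% itab$snps[["pp>0"]]))
  # boundary: pp exactly at the threshold is excluded
  postb <- postc
  postb$summary$pp_nonnull[] <- 0.2
  expect_equal(pp_inclusion_table(postb, 0.2)$table$n_snps, 0L)
  expect_error(pp_inclusion_table(postc, thresholds = 1), "\\[0, 1\\)")
  expect_error(pp_inclusion_table(post, 0.1), "Bayes Cpi")
})

test_that("sampler validates inputs and reports divergence", {
  X <- matrix(1, 10, 1)
  M <- matrix(rbinom(10, 2, 0.5), 10, 1)
  expect_error(run_bayes_a(X, M, c(rnorm(9), NA), quick_settings()),
               "non-finite")
  Mna <- M; Mna[1] <- NA
  expect_error(run_bayes_a(X, Mna, rnorm(10), quick_settings()), "missing")
})
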