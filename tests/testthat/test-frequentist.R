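test_that("design builder codes factors, nesting, covariates and SNP terms", {
  ph <- pheno_fixture(paste0("a", 1:8), bc = 1:8,
                      breed = rep(c("B1", "B2"), each = 4),
                      place = rep(c("p1", "p2", "p1", "p2"), each = 2))
  d1 <- build_design(ph, model_spec("breed"))
  expect_equal(colnames(d1$X), c("(Intercept)", "breedB2"))

  # 2 breeds x 2 places: nested place carries combos minus breeds = 2 df
  # after the QR removes the dummy aliased with the breed main effect
  d2 <- build_design(ph, model_spec(c("breed", "place(breed)")))
  expect_equal(sum(d2$term_map$term == "place(breed)"), 2)
  expect_length(d2$dropped_columns, 1)

  # farmer identical to place: aliased dummies dropped, earlier columns win
  ph$farmer <- ph$place
  d3 <- build_design(ph, model_spec(c("place", "farmer")))
  expect_equal(d3$dropped_columns, "farmerp2")
  expect_true("placep2" %in% colnames(d3$X))

  # adding a SNP term appends exactly one numeric column
  g <- geno_fixture(matrix(rep(0:1, 4), 8, 1,
                           dimnames = list(paste0("a", 1:8), "s1")))
  d4 <- build_design(ph, model_spec("breed", snp_terms = "s1"), g)
  expect_equal(ncol(d4$X) - ncol(d1$X), 1)
  expect_equal(d4$term_map$type[d4$term_map$column == "s1"], "snp")

  expect_error(build_design(ph, model_spec("nosuchterm")), "absent column")
  expect_error(model_spec("place(breed)"), "nesting parent")
})

test_that("rows with missing covariates are dropped and counted", {
  ph <- pheno_fixture(paste0("a", 1:6), bc = 1:6,
                      lactation = c(1, 2, NA, 1, 2, 3), yield = 5)
  d <- build_design(ph, model_spec(c("lactation", "yield")))
  expect_equal(d$n_dropped_rows, 1)
  expect_equal(nrow(d$X), 5)
  expect_false("a3" %in% d$rows_used)
})

test_that("fit_ols matches toy closed forms and the normal-equations oracle", {
  x <- c(1, 2, 3, 4)
  fit <- fit_ols(matrix(x, dimnames = list(NULL, "x")), 2 * x)
  expect_equal(fit$coefficients$estimate, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(9)
  for (r in 1:8) {
    n <- sample(8:50, 1)
    k <- sample(2:min(6, n - 2), 1)
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    oracle <- ols_oracle(X, y)
    expect_equal(fit$coefficients$estimate, unname(oracle$beta),
                 tolerance = 1e-10)
    expect_equal(fit$coefficients$se, unname(oracle$se), tolerance = 1e-10)
    expect_equal(unname(fit$vcov), unname(oracle$vcov), tolerance = 1e-10)
    expect_equal(fit$residual_df, oracle$df)
  }

  # shuffled response carries no signal
  set.seed(10)
  X <- cbind(1, rnorm(200)); colnames(X) <- c("(Intercept)", "x")
  y <- X[, 2] * 2 + rnorm(200, sd = 0.1)
  expect_lt(fit_ols(X, sample(y))$r_squared, 0.05)
  expect_error(fit_ols(X[1:2, ], y[1:2]), "zero residual degrees")
})

test_that("model hierarchy is nested, selects by strict P < 0.3, and survives
           an empty selection", {
  sim <- small_study(seed = 7)
  st <- sim$study
  h <- run_model_hierarchy(st, unit = "combined",
                           fixed_terms = c("breed", "place(breed)"))
  expect_gte(h$r_squared[["all_snp"]], h$r_squared[["base"]])
  expect_true(all(c("s1", "s3") %in% h$selected_snps))
  expect_gte(h$r_squared[["selected"]], h$r_squared[["base"]])

  # boundary: P exactly at the threshold is excluded
  fake <- h$fits$all_snp
  fake$coefficients$p[fake$coefficients$term == "s2"] <- 0.30
  fake$coefficients$p[fake$coefficients$term == "s4"] <- 0.29
  sel <- select_snps(fake, p_include = 0.30)
  expect_false("s2" %in% sel)
  expect_true("s4" %in% sel)

  # a response of pure noise against one weak SNP can select nothing;
  # the hierarchy reports that instead of failing
  null_sim <- small_study(seed = 1, n_per_breed = 40L,
                          beta = c(s1 = 0, s2 = 0, s3 = 0, s4 = 0))
  nst <- null_sim$study
  set.seed(3)
  nst$phenotypes$bc <- abs(rnorm(nrow(nst$phenotypes), 10, 0.01))
  hn <- run_model_hierarchy(nst, unit = "B1", fixed_terms = "place")
  if (hn$no_snp_selected) {
    expect_null(hn$fits$selected)
    res <- gene_effects(hn)
    expect_true(res$no_snp_selected)
    expect_equal(nrow(report_gene_effects(res)), 0)
  } else {
    succeed("selection non-empty for this draw; empty path covered elsewhere")
  }
})

test_that("substitution effects recommend the allele that raises BC", {
  sim <- small_study(seed = 19)
  st <- sim$study
  st$genotypes$counted_allele[] <- c("T", "G", "C", "A")
  st$genotypes$other_allele[] <- c("C", "A", "T", "G")
  h <- run_model_hierarchy(st, unit = "combined",
                           fixed_terms = c("breed", "place(breed)"))
  eff <- substitution_effects(h$fits$selected, genotypes = st$genotypes)
  freq <- allele_frequency(st$genotypes)
  for (i in seq_len(nrow(eff))) {
    s <- eff$snp_id[i]
    if (eff$beta[i] > 0) {
      expect_equal(eff$recommended_allele[i],
                   unname(st$genotypes$counted_allele[s]))
      expect_equal(eff$recommended_freq[i], unname(freq[s]))
    } else {
      expect_equal(eff$recommended_allele[i],
                   unname(st$genotypes$other_allele[s]))
      expect_equal(eff$recommended_freq[i], 1 - unname(freq[s]))
    }
  }
  # the simulated causal signs are recovered in the recommendation
  expect_gt(eff$beta[eff$snp_id == "s1"], 0)
  expect_lt(eff$beta[eff$snp_id == "s3"], 0)
})

test_that("gene F-test reduces to t^2 for one SNP and detects strong genes", {
  sim <- small_study(seed = 23)
  h <- run_model_hierarchy(sim$study, unit = "combined",
                           fixed_terms = c("breed", "place(breed)"))
  fit <- h$fits$selected
  s <- h$selected_snps[1]
  co <- fit$coefficients[fit$coefficients$term == s, ]
  ft <- gene_f_test(fit, s)
  expect_equal(ft$f, co$t^2, tolerance = 1e-10)
  expect_equal(ft$p, co$p, tolerance = 1e-10)

  ft_all <- gene_f_test(fit, h$selected_snps)
  expect_lt(ft_all$p, 0.01)   # strong simulated signal
  expect_error(gene_f_test(fit, character()), "no retained SNP")
})

test_that("D contrast matches worked examples and its defining identities", {
  # printed worked examples: one- and three-SNP genes
  expect_equal(total_effect_D(0.55)$D, 1.10)
  expect_equal(total_effect_D(c(0.91, -2.48, 0.93))$D, 8.64)
  expect_equal(total_effect_D(c(0, 0, 0))$D, 0)

  # SE collapses to 2*SE(beta) for a single effect, any sign
  V <- matrix(0.49^2, 1, 1)
  expect_equal(total_effect_D(0.55, V)$se, 2 * 0.49, tolerance = 1e-12)
  expect_equal(total_effect_D(-0.55, V)$se, 2 * 0.49, tolerance = 1e-12)
})

test_that("D equals the predicted gap between extreme homozygotes exactly", {
  sim <- small_study(seed = 29)
  h <- run_model_hierarchy(sim$study, unit = "combined",
                           fixed_terms = c("breed", "place(breed)"))
  fit <- h$fits$selected
  eff <- substitution_effects(fit)
  D <- total_effect_D(eff$beta)$D
  # prediction difference: favorable homozygote carries 2 copies wherever
  # beta > 0 and 0 copies elsewhere; unfavorable is the mirror image
  g_fav <- ifelse(eff$beta >= 0, 2, 0)
  g_unf <- 2 - g_fav
  pred_gap <- sum(eff$beta * (g_fav - g_unf))
  expect_equal(D, pred_gap, tolerance = 1e-12)
})

test_that("flipping the counted allele leaves D, gene F and R2 unchanged", {
  sim <- small_study(seed = 31)
  st <- sim$study
  h1 <- run_model_hierarchy(st, unit = "combined",
                            fixed_terms = c("breed", "place(breed)"))
  r1 <- gene_effects(h1)

  st2 <- st
  st2$genotypes$values[, "s1"] <- 2L - st2$genotypes$values[, "s1"]
  h2 <- run_model_hierarchy(st2, unit = "combined",
                            fixed_terms = c("breed", "place(breed)"))
  r2 <- gene_effects(h2)

  expect_setequal(h1$selected_snps, h2$selected_snps)
  expect_equal(h1$r_squared[["selected"]], h2$r_squared[["selected"]],
               tolerance = 1e-10)
  expect_equal(r1$total$D, r2$total$D, tolerance = 1e-10)
  expect_equal(r1$total$se, r2$total$se, tolerance = 1e-10)
  expect_equal(r1$per_gene$f, r2$per_gene$f, tolerance = 1e-10)
})

test_that("with vanishing noise the fitted effects equal the simulated truth", {
  freqs <- c(s1 = 0.5, s2 = 0.3)
  beta <- c(s1 = 1.25, s2 = -0.75)
  spec <- sim_spec(breeds = data.frame(breed = "B1", n = 200L, mean = 5),
                   snp_freqs = freqs, beta = beta, n_places = 2L,
                   place_sd = 1e-9, farmer_sd = 1e-9, lactation_slope = 0,
                   yield_slope = 0, resid_sd = 1e-9, seed = 17)
  sim <- simulate_study(spec)
  h <- run_model_hierarchy(sim$study, unit = "B1", fixed_terms = "place")
  eff <- substitution_effects(h$fits$selected)
  expect_equal(eff$beta[match(c("s1", "s2"), eff$snp_id)],
               unname(beta), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(adjust_fdr(0.02), 0.02)
  expect_equal(adjust_fdr(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
})
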