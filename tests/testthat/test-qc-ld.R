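test_that("call-rate filter keeps the 0.90 boundary inclusive and is idempotent", {
  v <- matrix(1L, 10, 3, dimnames = list(paste0("a", 1:10),
                                         c("s1", "s2", "s3")))
  v[1, 2] <- NA          # s2 typed in 9/10 -> call rate exactly 0.90
  v[1:2, 3] <- NA        # s3 at 0.80
  g <- geno_fixture(v)
  qc <- call_rate_filter(g, rep("B1", 10), threshold = 0.90)
  expect_setequal(qc$retained_per_breed$B1, c("s1", "s2"))
  expect_equal(unname(qc$call_rates["s2", "B1"]), 0.9)

  # second pass on the filtered matrix changes nothing
  g2 <- bcassoc:::subset_genotypes(g, snps = qc$retained_per_breed$B1)
  qc2 <- call_rate_filter(g2, rep("B1", 10), threshold = 0.90)
  expect_setequal(qc2$retained_per_breed$B1, qc$retained_per_breed$B1)
})

test_that("combined retention requires passing in every breed", {
  set.seed(1)
  v <- matrix(1L, 100, 2, dimnames = list(paste0("a", 1:100), c("s1", "s2")))
  breeds <- rep(c("B1", "B2", "B3", "B4", "B5"), each = 20)
  v[breeds == "B5", "s2"][1:3] <- NA   # 0.85 in one breed, 1.0 elsewhere
  g <- geno_fixture(v)
  qc <- call_rate_filter(g, breeds, threshold = 0.90)
  expect_true(all(vapply(qc$retained_per_breed[1:4],
                         function(s) "s2" %in% s, logical(1))))
  expect_false("s2" %in% qc$retained_per_breed$B5)
  expect_equal(qc$retained_combined, "s1")
  expect_error(call_rate_filter(g, factor(breeds, levels = c(unique(breeds),
                                                             "EMPTY"))),
               "zero animals")
})

test_that("allele frequencies are counted-allele fractions of typed animals", {
  v <- matrix(c(0L, 1L, 2L, 2L, 2L, 2L, NA, NA, NA), 3,
              dimnames = list(paste0("a", 1:3), c("s1", "s2", "s3")))
  g <- geno_fixture(v)
  f <- allele_frequency(g)
  expect_equal(unname(f["s1"]), 0.5)
  expect_equal(unname(f["s2"]), 1.0)
  expect_true(is.na(f["s3"]))
  expect_equal(attr(f, "undefined"), "s3")

  # estimate is consistent at simulation scale
  gs <- simulate_genotypes(c(x = 0.88), 100, seed = 31)
  se <- sqrt(0.88 * 0.12 / (2 * 100))
  expect_lt(abs(unname(allele_frequency(gs)["x"]) - 0.88), 3 * se)
})

test_that("imputation fills every hole from breed allele frequencies", {
  v <- matrix(2L, 6, 2, dimnames = list(paste0("a", 1:6), c("s1", "s2")))
  v[3, 1] <- NA   # fixed SNP: the imputed value must be 2
  g <- geno_fixture(v)
  gi <- impute_missing(g, seed = 1)
  expect_false(anyNA(gi$values))
  expect_equal(gi$values[3, 1], 2L)
  expect_equal(nrow(attr(gi, "imputed")), 1)

  # without missingness the matrix is untouched
  gfull <- geno_fixture(matrix(1L, 4, 2))
  expect_identical(impute_missing(gfull)$values, gfull$values)

  # imputed draws average to 2 * frequency across replicates
  set.seed(2)
  v2 <- matrix(rbinom(400, 2, 0.5), 200, 2,
               dimnames = list(paste0("a", 1:200), c("s1", "s2")))
  vals <- vapply(1:50, function(r) {
    vm <- v2; vm[1, 1] <- NA
    impute_missing(geno_fixture(vm), seed = r)$values[1, 1]
  }, integer(1))
  expect_lt(abs(mean(vals) - 1.0), 3 * sqrt(0.5 / 50))
})

test_that("EM r2 equals the phased haplotype-count oracle when phase is known", {
  # individuals built from known haplotype pairs, no double heterozygotes
  hap <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
  pairs <- rbind(c("AB", "AB"), c("AB", "AB"), c("AB", "Ab"), c("Ab", "Ab"),
                 c("aB", "ab"), c("ab", "ab"), c("ab", "ab"), c("AB", "aB"),
                 c("Ab", "ab"), c("aB", "aB"))
  geno <- t(apply(pairs, 1, function(pr) hap[pr[1], ] + hap[pr[2], ]))
  colnames(geno) <- c("x", "y")
  g <- geno_fixture(geno)
  counts <- table(factor(pairs, levels = rownames(hap)))
  expect_equal(as.numeric(ld_r2(g, "x", "y")),
               hap_count_r2(as.numeric(counts)), tolerance = 1e-10)
})

test_that("EM r2 resolves double-heterozygote phase like a likelihood oracle", {
  # simulate phased haplotypes with real LD, keep ambiguous genotypes in
  set.seed(77)
  n <- 4000
  pA <- 0.6; pB <- 0.5; D <- 0.12
  hap_p <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
             aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
  hap <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
  draw <- sample(rownames(hap), 2 * n, replace = TRUE, prob = hap_p)
  h1 <- hap[draw[1:n], , drop = FALSE]
  h2 <- hap[draw[(n + 1):(2 * n)], , drop = FALSE]
  geno <- h1 + h2
  colnames(geno) <- c("x", "y")
  # oracle: r2 from the directly counted (phased) haplotypes
  truth <- hap_count_r2(as.numeric(table(factor(draw, rownames(hap)))))
  est <- as.numeric(ld_r2(geno_fixture(geno), "x", "y"))
  # the EM works from genotypes only, so it cannot match the phased counts
  # exactly; at n = 4000 the discrepancy is small in absolute terms
  expect_lt(abs(est - truth), 0.02)
})

test_that("r2 is 1 for duplicated SNP, ~0 for independent SNP, NA if monomorphic", {
  g <- simulate_genotypes(c(a = 0.4, b = 0.4), 10000, seed = 41)
  gdup <- geno_fixture(cbind(g$values, c = g$values[, "a"]))
  expect_equal(as.numeric(ld_r2(gdup, "a", "c")), 1, tolerance = 1e-9)
  expect_lt(as.numeric(ld_r2(gdup, "a", "b")), 0.01)

  mono <- geno_fixture(cbind(g$values[, "a", drop = FALSE],
                             m = rep(2L, 10000)))
  expect_true(is.na(ld_r2(mono, "a", "m")))
})

test_that("r2 is invariant to flipping the counted allele at either locus", {
  g <- simulate_genotypes(c(a = 0.3, b = 0.35), 800, seed = 55)
  v <- g$values
  r_orig <- as.numeric(ld_r2(geno_fixture(v), "a", "b"))
  vflip <- v; vflip[, "a"] <- 2L - vflip[, "a"]
  expect_equal(as.numeric(ld_r2(geno_fixture(vflip), "a", "b")), r_orig,
               tolerance = 1e-9)
  vflip2 <- vflip; vflip2[, "b"] <- 2L - vflip2[, "b"]
  expect_equal(as.numeric(ld_r2(geno_fixture(vflip2), "a", "b")), r_orig,
               tolerance = 1e-9)
})

test_that("ld_matrix restricts to within-gene pairs and flags strong LD", {
  p <- panel_fixture()
  v <- simulate_genotypes(c(0.4, 0.5, 0.6), 200, seed = 61)$values
  colnames(v) <- c("BCO2.1", "BCO2.5", "BCMO1.3")
  v <- cbind(v, "BCMO1.4" = v[, "BCMO1.3"])   # duplicate inside BCMO1
  ld <- ld_matrix(geno_fixture(v), panel = p)
  expect_setequal(paste(ld$snp_a, ld$snp_b),
                  c("BCO2.1 BCO2.5", "BCMO1.3 BCMO1.4"))
  expect_true(ld$strong[ld$snp_a == "BCMO1.3"])
  expect_false(ld$strong[ld$snp_a == "BCO2.1"])
})
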