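# Small in-code fixtures shared across tests.

panel_fixture <- function() read_panel(bca_panel_file())

# genotype matrix from a plain integer matrix with ids filled in
geno_fixture <- function(values, counted = NULL, other = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("a", seq_len(nrow(values)))
  }
  genotype_matrix(values, counted_allele = counted, other_allele = other)
}

# minimal phenotype table matching a genotype matrix's animals
pheno_fixture <- function(ids, bc, breed = "B1", species = "cattle",
                          place = "p1", farmer = "f1", batch = NA,
                          lactation = NA, yield = NA) {
  df <- data.frame(animal_id = ids, species = species, breed = breed,
                   bc = bc, place = place, farmer = farmer,
                   batch = batch, lactation = lactation, yield = yield,
                   stringsAsFactors = FALSE)
  bcassoc:::validate_phenotypes(df)
}

# a small multi-breed study with a few causal SNP, used by several suites
small_study <- function(seed = 42, n_per_breed = 80L,
                        beta = c(s1 = 1.5, s2 = 0, s3 = -1.2, s4 = 0)) {
  freqs <- c(s1 = 0.5, s2 = 0.3, s3 = 0.6, s4 = 0.4)
  spec <- sim_spec(
    breeds = data.frame(breed = c("B1", "B2"), n = rep(n_per_breed, 2),
                        mean = c(5, 4)),
    species = "cattle", snp_freqs = freqs, beta = beta[names(freqs)],
    n_places = 3L, n_farmers_per_place = 2L, place_sd = 0.5,
    farmer_sd = 0.3, resid_sd = 1.5, seed = seed)
  simulate_study(spec)
}

# closed-form OLS via normal equations, the independent oracle for fit_ols
ols_oracle <- function(X, y) {
  XtX_inv <- solve(crossprod(X))
  beta <- drop(XtX_inv %*% crossprod(X, y))
  resid <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  list(beta = beta, se = sqrt(diag(sigma2 * XtX_inv)), sigma2 = sigma2,
       vcov = sigma2 * XtX_inv, df = df)
}

# r2 from directly counted (phased) haplotype frequencies
hap_count_r2 <- function(hap_counts) {
  p <- hap_counts / sum(hap_counts)   # order AB, Ab, aB, ab
  pa <- p[1] + p[2]
  pb <- p[1] + p[3]
  D <- p[1] - pa * pb
  unname(D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}
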