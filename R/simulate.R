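#' Specification for a synthetic multi-breed study
#'
#' Describes a study to simulate: breeds with their sample sizes and
#' population mean beta-carotene levels, a nested place/farmer management
#' structure with fixed effects drawn once per level, an optional two-period
#' batch shift (buffalo collections happened in two periods), lactation and
#' yield covariate slopes, and per-SNP counted-allele frequencies and true
#' substitution effects.
#'
#' Defaults produced by [default_sim_spec()] mirror the published study
#' design: per-breed sample sizes and mean concentrations on the scale of the
#' reported breed summary, and allele frequencies / effect sizes transcribed
#' from the reported per-SNP results. The residual standard deviation
#' (default 2.5 ug/100 mL) and the place/farmer effect SDs are package
#' choices discussed in the methods vignette.
#'
#' @param breeds data.frame with columns `breed`, `n`, `mean` (ug/100 mL).
#' @param species `"cattle"` or `"buffalo"`.
#' @param snp_freqs named numeric, per-SNP counted-allele frequency in (0,1).
#' @param beta named numeric, true substitution effect per copy of the
#'   counted allele (ug/100 mL); names must match `snp_freqs`.
#' @param n_places places per breed; `n_farmers_per_place` farmers nested in
#'   each place.
#' @param place_sd,farmer_sd SDs of the place and farmer(place) fixed effects
#'   (drawn once per level, then treated as fixed).
#' @param batch_effect shift added to collection batch 2 (ug/100 mL);
#'   `NULL` disables the batch structure (cattle default).
#' @param lactation_slope,yield_slope covariate coefficients; covariates are
#'   centered during generation so breed means stay interpretable.
#' @param resid_sd residual SD (ug/100 mL), must be > 0.
#' @param missing_rate per-cell genotype missingness rate.
#' @param seed master seed; independent named streams are derived from it for
#'   genotypes, level effects, covariates and noise.
#' @return list of class `bca_sim_spec`.
#' @export
sim_spec <- function(breeds, species = c("cattle", "buffalo"),
                     snp_freqs, beta = NULL,
                     n_places = 5L, n_farmers_per_place = 4L,
                     place_sd = 0.8, farmer_sd = 0.5,
                     batch_effect = NULL,
                     lactation_slope = 0.15, yield_slope = 0.1,
                     resid_sd = 2.5, missing_rate = 0, seed = 1L) {
  species <- match.arg(species)
  stopifnot(is.data.frame(breeds),
            all(c("breed", "n", "mean") %in% names(breeds)))
  if (any(breeds$n < 1)) bca_stop("each breed needs n >= 1")
  if (any(snp_freqs <= 0 | snp_freqs >= 1)) {
    bca_stop("snp_freqs must lie strictly in (0, 1)")
  }
  if (is.null(names(snp_freqs))) {
    names(snp_freqs) <- paste0("snp", seq_along(snp_freqs))
  }
  beta <- beta %||% stats::setNames(rep(0, length(snp_freqs)), names(snp_freqs))
  if (is.null(names(beta))) names(beta) <- names(snp_freqs)
  stopifnot(identical(sort(names(beta)), sort(names(snp_freqs))))
  beta <- beta[names(snp_freqs)]
  if (resid_sd <= 0) bca_stop("resid_sd must be > 0")
  structure(list(breeds = breeds, species = species, snp_freqs = snp_freqs,
                 beta = beta, n_places = as.integer(n_places),
                 n_farmers_per_place = as.integer(n_farmers_per_place),
                 place_sd = place_sd, farmer_sd = farmer_sd,
                 batch_effect = batch_effect,
                 lactation_slope = lactation_slope, yield_slope = yield_slope,
                 resid_sd = resid_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "bca_sim_spec")
}

#' Study-shaped default simulation specification
#'
#' Builds a [sim_spec()] whose breed sample sizes and mean beta-carotene
#' concentrations match the published breed summary, and whose SNP
#' frequencies and substitution effects are the values reported for the
#' combined within-species analysis (counted-allele frequency recovered from
#' the recommended-allele frequency and the effect sign).
#'
#' @param species `"cattle"` or `"buffalo"`.
#' @param seed master seed stored in the spec.
#' @param ... further arguments passed to [sim_spec()] to override defaults.
#' @return a `bca_sim_spec`.
#' @export
default_sim_spec <- function(species = c("cattle", "buffalo"), seed = 1L, ...) {
  species <- match.arg(species)
  breeds <- if (species == "cattle") {
    data.frame(breed = c("Holstein cross", "Jersey cross", "Sahiwal",
                         "Tharparkar", "Gir"),
               n = c(492L, 512L, 392L, 481L, 414L),
               mean = c(6.16, 3.90, 4.34, 4.04, 3.50))
  } else {
    data.frame(breed = c("Jafarabadi", "Murrah", "Pandharpuri", "Mehsana",
                         "Surti"),
               n = c(458L, 470L, 412L, 489L, 413L),
               mean = c(5.50, 4.71, 3.35, 4.31, 3.61))
  }
  rep_eff <- reported_effects()
  rows <- rep_eff[rep_eff$species == species & rep_eff$breed == "Combined", ]
  beta <- stats::setNames(rows$beta, rows$snp_id)
  # printed frequencies refer to the recommended allele; the counted allele
  # is the recommended one iff the printed effect is positive
  freq <- ifelse(rows$beta > 0, rows$recommended_freq,
                 1 - rows$recommended_freq)
  # keep frequencies strictly inside (0,1) for binomial sampling
  freq <- pmin(pmax(freq, 0.005), 0.995)
  names(freq) <- rows$snp_id
  batch <- if (species == "buffalo") 0.5 else NULL
  sim_spec(breeds = breeds, species = species, snp_freqs = freq, beta = beta,
           batch_effect = batch, seed = seed, ...)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each animal's count of the counted allele at SNP `j` is an independent
#' Binomial(2, `freqs[j]`) draw; loci are unlinked.
#'
#' @param freqs per-SNP counted-allele frequencies, strictly in (0,1).
#' @param n number of animals.
#' @param seed optional integer seed (stream-local).
#' @param missing_rate per-cell probability of setting the call to `NA`.
#' @param animal_ids optional row labels.
#' @return a `bca_genotypes`.
#' @export
simulate_genotypes <- function(freqs, n, seed = NULL, missing_rate = 0,
                               animal_ids = NULL) {
  if (any(freqs <= 0 | freqs >= 1)) {
    bca_stop("allele frequencies must lie strictly in (0, 1)")
  }
  if (is.null(names(freqs))) names(freqs) <- paste0("snp", seq_along(freqs))
  p <- length(freqs)
  v <- local_seed(seed, {
    m <- vapply(freqs, function(f) stats::rbinom(n, 2L, f), integer(n))
    m <- matrix(m, nrow = n, dimnames = list(NULL, names(freqs)))
    if (missing_rate > 0) {
      m[stats::runif(length(m)) < missing_rate] <- NA_integer_
    }
    m
  })
  rownames(v) <- animal_ids %||% sprintf("animal%04d", seq_len(n))
  genotype_matrix(v)
}

#' Simulate phenotypes for a genotyped population
#'
#' Generates beta-carotene observations as
#' breed mean + place + farmer(place) + batch + centered covariate terms +
#' sum of SNP contributions + Gaussian noise, truncated at zero (a
#' concentration cannot be negative; with the default residual SD the
#' truncated mass is small). SNP contributions are expressed as deviations
#' from the population mean genotype, so that the specified breed means stay
#' the expected breed means. All realized components are returned in the
#' truth object.
#'
#' @param genotypes a `bca_genotypes` with `sum(spec$breeds$n)` animals and
#'   the SNP named in the spec.
#' @param spec a `bca_sim_spec`.
#' @return list with `phenotypes` (a `bca_phenotypes`) and `truth` (class
#'   `bca_sim_truth`: `beta`, `true_D = 2 * sum(|beta|)`, realized place /
#'   farmer / batch effects, and the noiseless genetic values).
#' @export
simulate_phenotypes <- function(genotypes, spec) {
  stopifnot(inherits(genotypes, "bca_genotypes"),
            inherits(spec, "bca_sim_spec"))
  n <- sum(spec$breeds$n)
  if (nrow(genotypes$values) != n) {
    bca_stop("genotype matrix has ", nrow(genotypes$values),
             " animals but spec expects ", n)
  }
  snps <- names(spec$snp_freqs)
  if (!all(snps %in% colnames(genotypes$values))) {
    bca_stop("genotypes lack SNP named in the spec")
  }
  g <- genotypes$values[, snps, drop = FALSE]
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    # phenotype generation needs complete genotypes; treat unobserved calls
    # as the population expectation
    for (j in seq_along(snps)) {
      g[is.na(g[, j]), j] <- 2 * spec$snp_freqs[j]
    }
  }

  breed <- rep(spec$breeds$breed, spec$breeds$n)
  breed_mean <- rep(spec$breeds$mean, spec$breeds$n)

  place_lab <- unlist(lapply(spec$breeds$breed, function(b) {
    paste0(b, ".place", seq_len(spec$n_places))
  }))
  farmer_lab <- unlist(lapply(place_lab, function(pl) {
    paste0(pl, ".farmer", seq_len(spec$n_farmers_per_place))
  }))
  place_eff <- local_seed(derive_seed(spec$seed, "places"),
                          stats::setNames(stats::rnorm(length(place_lab), 0,
                                                       spec$place_sd),
                                          place_lab))
  farmer_eff <- local_seed(derive_seed(spec$seed, "farmers"),
                           stats::setNames(stats::rnorm(length(farmer_lab), 0,
                                                        spec$farmer_sd),
                                           farmer_lab))

  cov <- local_seed(derive_seed(spec$seed, "covariates"), {
    place <- unlist(lapply(seq_len(nrow(spec$breeds)), function(i) {
      sample(paste0(spec$breeds$breed[i], ".place",
                    seq_len(spec$n_places)),
             spec$breeds$n[i], replace = TRUE)
    }))
    farmer <- paste0(place, ".farmer",
                     sample.int(spec$n_farmers_per_place, n, replace = TRUE))
    lact <- sample(1:5, n, replace = TRUE)
    yield <- pmax(0.5, stats::rnorm(n, 5, 1.5))
    batch <- if (!is.null(spec$batch_effect)) {
      sample(c("batch1", "batch2"), n, replace = TRUE)
    } else {
      rep(NA_character_, n)
    }
    list(place = place, farmer = farmer, lact = lact, yield = yield,
         batch = batch)
  })

  genetic <- drop(sweep(g, 2, 2 * spec$snp_freqs) %*% spec$beta)
  batch_term <- if (!is.null(spec$batch_effect)) {
    ifelse(cov$batch == "batch2", spec$batch_effect, 0)
  } else {
    rep(0, n)
  }
  noise <- local_seed(derive_seed(spec$seed, "noise"),
                      stats::rnorm(n, 0, spec$resid_sd))

  mu <- breed_mean + place_eff[cov$place] + farmer_eff[cov$farmer] +
    batch_term +
    spec$lactation_slope * (cov$lact - mean(cov$lact)) +
    spec$yield_slope * (cov$yield - mean(cov$yield)) +
    genetic
  bc <- pmax(0, mu + noise)

  ph <- data.frame(animal_id = rownames(genotypes$values),
                   species = spec$species, breed = breed, bc = bc,
                   place = cov$place, farmer = cov$farmer, batch = cov$batch,
                   lactation = cov$lact, yield = cov$yield,
                   stringsAsFactors = FALSE)
  ph <- validate_phenotypes(ph)
  truth <- structure(list(beta = spec$beta, snp_freqs = spec$snp_freqs,
                          true_D = 2 * sum(abs(spec$beta)),
                          place_effects = place_eff,
                          farmer_effects = farmer_eff,
                          batch_effect = spec$batch_effect,
                          genetic_values = genetic,
                          expected_mean = mu),
                     class = "bca_sim_truth")
  list(phenotypes = ph, truth = truth)
}

#' Simulate a complete study
#'
#' Convenience wrapper: draws genotypes from the spec's allele frequencies,
#' generates phenotypes, and assembles the study object.
#'
#' @param spec a `bca_sim_spec`.
#' @param panel optional `bca_panel` carried into the study.
#' @return list with `study` (a `bca_study`) and `truth`.
#' @export
simulate_study <- function(spec, panel = NULL) {
  stopifnot(inherits(spec, "bca_sim_spec"))
  n <- sum(spec$breeds$n)
  g <- simulate_genotypes(spec$snp_freqs, n,
                          seed = derive_seed(spec$seed, "genotypes"),
                          missing_rate = spec$missing_rate)
  sim <- simulate_phenotypes(g, spec)
  study <- assemble_study(g, sim$phenotypes, panel = panel)
  list(study = study, truth = sim$truth)
}

#' Simulate a prior-comparison dataset (500 observations, 20 markers)
#'
#' Generates the small benchmark design used to compare shrinkage priors:
#' 500 animals genotyped at 20 unlinked markers with allele frequencies drawn
#' from Uniform(0.1, 0.9). With `causal_fraction = 0` no marker affects the
#' phenotype; with `causal_fraction = 0.25` exactly 5 markers carry effects
#' of equal magnitude (`effect_size`, default half the residual SD) and
#' alternating sign. The phenotype is a constant mean plus marker effects
#' plus Gaussian noise.
#'
#' @param causal_fraction 0 or 0.25.
#' @param seed master integer seed.
#' @param n,n_markers design size (defaults 500 and 20).
#' @param resid_sd residual SD (default 1).
#' @param effect_size magnitude of each causal effect; default
#'   `0.5 * resid_sd`.
#' @param mu phenotype mean (default 10, comfortably above zero).
#' @return list with `genotypes`, `phenotypes`, `truth` (including
#'   `true_D = 2 * sum(|beta|)`).
#' @export
make_prior_comparison_dataset <- function(causal_fraction, seed = 1L,
                                          n = 500L, n_markers = 20L,
                                          resid_sd = 1, effect_size = NULL,
                                          mu = 10) {
  if (!causal_fraction %in% c(0, 0.25)) {
    bca_stop("causal_fraction must be 0 or 0.25")
  }
  effect_size <- effect_size %||% (0.5 * resid_sd)
  freqs <- local_seed(derive_seed(seed, "freqs"),
                      stats::runif(n_markers, 0.1, 0.9))
  names(freqs) <- sprintf("M%02d", seq_len(n_markers))
  g <- simulate_genotypes(freqs, n, seed = derive_seed(seed, "genotypes"))
  beta <- stats::setNames(rep(0, n_markers), names(freqs))
  if (causal_fraction > 0) {
    k <- round(causal_fraction * n_markers)
    idx <- local_seed(derive_seed(seed, "effects"),
                      sort(sample.int(n_markers, k)))
    beta[idx] <- effect_size * (-1)^(seq_len(k) - 1)
  }
  noise <- local_seed(derive_seed(seed, "noise"), stats::rnorm(n, 0, resid_sd))
  bc <- pmax(0, mu + drop(g$values %*% beta) + noise)
  ph <- validate_phenotypes(
    data.frame(animal_id = rownames(g$values), species = "cattle",
               breed = "sim", bc = bc, place = "place1", farmer = "farmer1",
               batch = NA_character_, lactation = NA_real_, yield = NA_real_,
               stringsAsFactors = FALSE))
  truth <- structure(list(beta = beta, snp_freqs = freqs,
                          true_D = 2 * sum(abs(beta)),
                          resid_sd = resid_sd, mu = mu),
                     class = "bca_sim_truth")
  list(genotypes = g, phenotypes = ph, truth = truth)
}
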