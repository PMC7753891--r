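#' Run call-rate QC and imputation on a study
#'
#' Applies the per-breed call-rate filter (combined mode restricts to SNP
#' passing in every breed) and then fills remaining sporadic missingness by
#' breed-wise binomial imputation.
#'
#' @param study a `bca_study`.
#' @param config an [analysis_config()].
#' @param combined use the across-breed retained set (for pooled analyses).
#' @return the study with filtered, fully imputed genotypes; the QC report is
#'   attached as `attr(, "qc")`.
#' @export
qc_impute <- function(study, config = analysis_config(), combined = FALSE) {
  stopifnot(inherits(study, "bca_study"))
  breeds <- study$phenotypes$breed
  qc <- call_rate_filter(study$genotypes, breeds,
                         threshold = config$call_rate_min, combined = TRUE)
  keep <- if (combined) {
    qc$retained_combined
  } else {
    unique(unlist(qc$retained_per_breed))
  }
  if (length(keep) == 0) bca_stop("no SNP pass the call-rate filter")
  g <- subset_genotypes(study$genotypes, snps = keep)
  g <- impute_missing(g, breeds = breeds,
                      seed = derive_seed(config$seed, "impute"))
  study$genotypes <- g
  attr(study, "qc") <- qc
  study
}

#' Staged model hierarchy for one breed or the pooled species
#'
#' Fits the sequence of fixed-effects models used to assess the SNP panel:
#' (1) the base model with management effects only; (2) the base model plus
#' all QC-passing SNP as 0/1/2 covariates; (3) the base model plus only the
#' protein-changing (nonsynonymous/stop) SNP; (4) the final model keeping the
#' SNP whose two-sided P-value in model 2 is strictly below `p_include`
#' (default 0.30). When no SNP clears the screen the hierarchy stops after
#' model 3 with an explicit empty selection rather than an error.
#'
#' @param study a `bca_study` with complete (imputed) genotypes.
#' @param unit `"combined"` for the pooled multi-breed model, otherwise a
#'   breed label.
#' @param config an [analysis_config()].
#' @param fixed_terms optional override of [default_model_terms()].
#' @param selection `"joint"` takes selection P-values from the all-SNP model
#'   (SNP adjusted for each other); `"marginal"` screens each SNP in its own
#'   single-SNP model.
#' @return object of class `bca_hierarchy`: named fits (`base`, `all_snp`,
#'   `coding`, `selected`), `r_squared`, `selected_snps`, `unit`,
#'   `fixed_terms`, `no_snp_selected`.
#' @export
run_model_hierarchy <- function(study, unit = "combined",
                                config = analysis_config(),
                                fixed_terms = NULL,
                                selection = c("joint", "marginal")) {
  stopifnot(inherits(study, "bca_study"))
  selection <- match.arg(selection)
  combined <- identical(unit, "combined")
  if (!combined) study <- subset_study(study, unit)
  if (anyNA(study$genotypes$values)) {
    bca_stop("genotypes contain missing values; run qc_impute first")
  }
  fixed_terms <- fixed_terms %||% default_model_terms(study, combined = combined)
  snps <- colnames(study$genotypes$values)

  fit_with <- function(snp_set) {
    sp <- model_spec(fixed_terms, snp_terms = snp_set)
    fit_ols(build_design(study$phenotypes, sp, genotypes = study$genotypes))
  }

  base_fit <- fit_with(character())
  all_fit <- fit_with(snps)

  coding_fit <- NULL
  if (!is.null(study$panel)) {
    coding <- intersect(snps,
                        study$panel$snp_id[is_coding_change(study$panel)])
    if (length(coding)) coding_fit <- fit_with(coding)
  }

  screen_p <- if (selection == "joint") {
    sc <- snp_coefficients(all_fit)
    stats::setNames(sc$p, sc$term)
  } else {
    vapply(snps, function(s) {
      sc <- snp_coefficients(fit_with(s))
      sc$p[1]
    }, numeric(1))
  }
  selected <- names(screen_p)[!is.na(screen_p) & screen_p < config$p_include]
  sel_fit <- if (length(selected)) fit_with(selected)

  fits <- list(base = base_fit, all_snp = all_fit, coding = coding_fit,
               selected = sel_fit)
  r2 <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$r_squared,
               numeric(1))
  structure(list(fits = fits, r_squared = r2, selected_snps = selected,
                 screen_p = screen_p, unit = unit, fixed_terms = fixed_terms,
                 no_snp_selected = length(selected) == 0,
                 study = study, config = config),
            class = "bca_hierarchy")
}

#' @export
print.bca_hierarchy <- function(x, ...) {
  cat("Model hierarchy for", x$unit, "\n")
  lbl <- c(base = "base fixed effects", all_snp = "+ all SNP",
           coding = "+ nonsynonymous/stop SNP", selected = "+ selected SNP")
  for (nm in names(x$fits)) {
    r2 <- x$r_squared[[nm]]
    cat(sprintf("  %-28s R2 = %s\n", lbl[[nm]],
                ifelse(is.na(r2), "(not fitted)", format(round(r2, 3)))))
  }
  if (x$no_snp_selected) {
    cat("  no SNP passed the selection screen\n")
  } else {
    cat("  selected:", paste(x$selected_snps, collapse = ", "), "\n")
  }
  invisible(x)
}

#' SNP passing the inclusion screen
#'
#' SNP whose two-sided P-value is strictly below the threshold (a P-value of
#' exactly 0.30 is excluded), in model order.
#'
#' @param fit a `bca_fit` containing SNP terms.
#' @param p_include threshold, default 0.30.
#' @return character vector of snp ids (possibly empty).
#' @export
select_snps <- function(fit, p_include = 0.30) {
  sc <- snp_coefficients(fit)
  sc$term[!is.na(sc$p) & sc$p < p_include]
}

#' Allele substitution effects and recommended alleles
#'
#' Reads the per-SNP coefficients off the final model. The recommended allele
#' at a SNP is the one whose additional copy increases the predicted
#' beta-carotene level: the counted allele when the coefficient is positive,
#' the other allele when negative (an exactly zero estimate is a tie,
#' resolved to the counted allele and flagged). The recommended-allele
#' frequency is derived from the counted-allele frequency.
#'
#' @param fit the final `bca_fit`.
#' @param genotypes a `bca_genotypes` supplying allele labels and
#'   frequencies (frequencies can be overridden via `frequencies`).
#' @param frequencies optional named counted-allele frequencies.
#' @return data.frame: `snp_id`, `beta`, `se`, `p`, `recommended_allele`,
#'   `recommended_freq`, `tie`.
#' @export
substitution_effects <- function(fit, genotypes = NULL, frequencies = NULL) {
  sc <- snp_coefficients(fit)
  if (nrow(sc) == 0) {
    return(data.frame(snp_id = character(), beta = numeric(), se = numeric(),
                      p = numeric(), recommended_allele = character(),
                      recommended_freq = numeric(), tie = logical()))
  }
  snp <- sc$term
  counted <- other <- stats::setNames(rep(NA_character_, length(snp)), snp)
  if (!is.null(genotypes)) {
    counted[snp] <- genotypes$counted_allele[snp]
    other[snp] <- genotypes$other_allele[snp]
  }
  freq <- frequencies %||%
    (if (!is.null(genotypes)) allele_frequency(genotypes) else NULL)
  cfreq <- if (is.null(freq)) rep(NA_real_, length(snp)) else unname(freq[snp])
  tie <- sc$estimate == 0
  rec_allele <- ifelse(sc$estimate >= 0, counted[snp], other[snp])
  rec_freq <- ifelse(sc$estimate >= 0, cfreq, 1 - cfreq)
  data.frame(snp_id = snp, beta = sc$estimate, se = sc$se, p = sc$p,
             recommended_allele = unname(rec_allele),
             recommended_freq = unname(rec_freq), tie = tie,
             stringsAsFactors = FALSE)
}

#' Gene-wise joint F-test
#'
#' Wald F-test that all retained SNP coefficients belonging to one gene are
#' simultaneously zero, against the final model. For a single-SNP gene this
#' reduces to the square of that SNP's t-statistic.
#'
#' @param fit the final `bca_fit`.
#' @param snps snp ids of the gene present in the fit.
#' @return list with `f`, `df1`, `df2`, `p`.
#' @export
gene_f_test <- function(fit, snps) {
  stopifnot(inherits(fit, "bca_fit"))
  if (length(snps) == 0) bca_stop("gene has no retained SNP; test undefined")
  miss <- setdiff(snps, fit$coefficients$term)
  if (length(miss)) {
    bca_stop("SNP not in fitted model: ", paste(miss, collapse = ", "))
  }
  b <- fit$coefficients$estimate[match(snps, fit$coefficients$term)]
  V <- fit$vcov[snps, snps, drop = FALSE]
  q <- length(snps)
  f <- drop(t(b) %*% solve(V, b)) / q
  p <- stats::pf(f, q, fit$residual_df, lower.tail = FALSE)
  list(f = f, df1 = q, df2 = fit$residual_df, p = p)
}

#' Extreme-genotype contrast D = 2 * sum(|beta|)
#'
#' The predicted difference in beta-carotene between a hypothetical animal
#' homozygous for the favorable allele at every locus and one homozygous for
#' the unfavorable allele everywhere. Estimated by plugging in the fitted
#' substitution effects. When a coefficient covariance is supplied, the
#' standard error treats the estimated signs as fixed — D-hat is then the
#' linear contrast `c'beta` with `c_j = 2 * sign(beta_j)` — and a two-sided
#' t-based P-value is reported on `df` degrees of freedom.
#'
#' @param beta numeric vector of substitution effects (one per SNP).
#' @param vcov optional covariance matrix of `beta`.
#' @param df residual degrees of freedom for the P-value (default `Inf`, a
#'   normal approximation).
#' @return list with `D`, `se` (NA without `vcov`), `p`.
#' @export
total_effect_D <- function(beta, vcov = NULL, df = Inf) {
  if (length(beta) == 0) bca_stop("at least one effect is required")
  D <- 2 * sum(abs(beta))
  se <- p <- NA_real_
  if (!is.null(vcov)) {
    cc <- 2 * ifelse(beta >= 0, 1, -1)
    se <- sqrt(drop(t(cc) %*% vcov %*% cc))
    p <- 2 * stats::pt(-abs(D / se), df)
  }
  list(D = D, se = se, p = p)
}

#' Per-gene association results from a fitted hierarchy
#'
#' Combines substitution effects, gene-wise F-tests and the per-gene and
#' overall D contrasts into the report structure of the final analysis.
#' Without a panel all SNP are grouped under one pseudo-gene `"(all)"`.
#'
#' @param hierarchy a `bca_hierarchy` whose final model was fitted.
#' @return object of class `bca_assoc_result`: `per_snp` (effects table with
#'   gene), `per_gene` (gene, n_snps, F, F P-value, D, SE, P), `total`
#'   (D across all retained SNP), `unit`, `r_squared`.
#' @export
gene_effects <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "bca_hierarchy"))
  if (hierarchy$no_snp_selected) {
    res <- structure(list(per_snp = NULL, per_gene = NULL, total = NULL,
                          unit = hierarchy$unit,
                          r_squared = hierarchy$r_squared,
                          no_snp_selected = TRUE),
                     class = "bca_assoc_result")
    return(res)
  }
  fit <- hierarchy$fits$selected
  study <- hierarchy$study
  eff <- substitution_effects(fit, genotypes = study$genotypes)
  gene <- if (!is.null(study$panel)) {
    study$panel$gene[match(eff$snp_id, study$panel$snp_id)]
  } else {
    rep("(all)", nrow(eff))
  }
  gene[is.na(gene)] <- "(all)"
  eff <- cbind(gene = gene, eff, stringsAsFactors = FALSE)

  per_gene <- do.call(rbind, lapply(split(eff, eff$gene), function(gdf) {
    ft <- gene_f_test(fit, gdf$snp_id)
    dd <- total_effect_D(gdf$beta,
                         vcov = fit$vcov[gdf$snp_id, gdf$snp_id, drop = FALSE],
                         df = fit$residual_df)
    data.frame(gene = gdf$gene[1], n_snps = nrow(gdf), f = ft$f, f_p = ft$p,
               D = dd$D, D_se = dd$se, D_p = dd$p, stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  tot <- total_effect_D(eff$beta,
                        vcov = fit$vcov[eff$snp_id, eff$snp_id, drop = FALSE],
                        df = fit$residual_df)
  structure(list(per_snp = eff, per_gene = per_gene, total = tot,
                 unit = hierarchy$unit, r_squared = hierarchy$r_squared,
                 no_snp_selected = FALSE),
            class = "bca_assoc_result")
}

#' @export
print.bca_assoc_result <- function(x, ...) {
  cat("Association results for", x$unit, "\n")
  if (isTRUE(x$no_snp_selected)) {
    cat("  no SNP passed the selection screen; no effects to report\n")
    return(invisible(x))
  }
  print(x$per_gene, row.names = FALSE)
  cat(sprintf("  total D = %.3f (SE %.3f, P = %.3g)\n",
              x$total$D, x$total$se, x$total$p))
  invisible(x)
}

#' Optional multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment, reported alongside the nominal
#' P-values for reference. SNP selection in [run_model_hierarchy()] always
#' uses nominal P-values: with a small pre-filtered candidate panel a
#' multiplicity correction mostly discards information, so the adjustment is
#' advisory.
#'
#' @param p numeric vector of P-values.
#' @param method passed to [stats::p.adjust()]; default `"BH"`.
#' @return adjusted P-values.
#' @export
adjust_fdr <- function(p, method = "BH") {
  stats::p.adjust(p, method = method)
}

#' Transcription of the published per-SNP substitution effects
#'
#' Loads the packaged table of reported allele-substitution effects,
#' recommended alleles and gene-level summaries for each breed and the
#' combined within-species analyses. These printed values serve as worked
#' examples for the D contrast and as realistic defaults for the simulator.
#' Gene-level cells that were not legible in the source table are `NA`.
#'
#' @return data.frame with columns `species`, `breed`, `gene`, `snp_id`,
#'   `beta`, `se`, `p_value`, `recommended_allele`, `recommended_freq`,
#'   `gene_effect`, `gene_se`, `gene_p`.
#' @export
reported_effects <- function() {
  path <- system.file("extdata", "reported_effects.tsv", package = "bcassoc",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
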