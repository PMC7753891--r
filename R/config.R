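#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults follow the
#' study design: SNP are kept when their within-breed call rate is at least
#' 0.90 (combined analyses additionally require this in every breed of the
#' species); SNP enter the final substitution-effect model when their
#' two-sided P-value in the all-SNP model is strictly below 0.30; pairs with
#' LD r-squared strictly above 0.6 are flagged as in strong LD.
#'
#' @param call_rate_min minimum per-breed call rate (inclusive), in (0, 1].
#' @param p_include selection threshold for the final model (strict `<`).
#' @param ld_strong_r2 strong-LD threshold on r-squared (strict `>`).
#' @param alpha nominal significance level used in reports.
#' @param mcmc an [mcmc_settings()] object for the Bayesian stages.
#' @param seed master integer seed; every stochastic step derives its own
#'   stream from it via [derive_seed()].
#' @return list of class `bca_config`.
#' @export
analysis_config <- function(call_rate_min = 0.90, p_include = 0.30,
                            ld_strong_r2 = 0.6, alpha = 0.05,
                            mcmc = mcmc_settings(), seed = 1L) {
  for (nm in c("call_rate_min", "p_include", "ld_strong_r2", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      bca_stop(nm, " must be a single number in (0, 1]")
    }
  }
  stopifnot(inherits(mcmc, "bca_mcmc_settings"))
  structure(list(call_rate_min = call_rate_min, p_include = p_include,
                 ld_strong_r2 = ld_strong_r2, alpha = alpha, mcmc = mcmc,
                 seed = as.integer(seed)),
            class = "bca_config")
}

#' MCMC settings for the Bayesian regressions
#'
#' Defaults give a 50,000-iteration single chain with 5,000 burn-in and
#' thinning of 10. The scaled-inverse-chi-square prior on marker-effect
#' variances has `nu_alpha` degrees of freedom; its scale, when left `NULL`,
#' is derived at run time from the phenotypic variance so that markers are a
#' priori expected to explain `var_fraction` of it (the usual convention in
#' genomic prediction; see the methods vignette). The residual-variance prior
#' scale defaults analogously to the remaining fraction.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before summarizing.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed for the sampler.
#' @param nu_alpha,s2_alpha df and scale of the marker-variance prior.
#' @param nu_e,s2_e df and scale of the residual-variance prior.
#' @param var_fraction a priori fraction of phenotypic variance attributed
#'   to markers when deriving `s2_alpha`/`s2_e`.
#' @param fix_sigma2_e,fix_sigma2_alpha optional fixed values; when given the
#'   corresponding variance is not sampled (used for conjugate checks).
#' @param pi_fixed optional fixed mixture proportion for the spike-and-slab
#'   sampler; `NULL` (default) treats it as unknown with a Uniform(0,1) prior.
#' @return list of class `bca_mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 50000L, burn_in = 5000L, thin = 10L,
                          seed = 1L, nu_alpha = 4, s2_alpha = NULL,
                          nu_e = 4, s2_e = NULL, var_fraction = 0.5,
                          fix_sigma2_e = NULL, fix_sigma2_alpha = NULL,
                          pi_fixed = NULL) {
  if (burn_in >= n_iter) bca_stop("burn_in must be smaller than n_iter")
  if (nu_alpha <= 0 || nu_e <= 0) bca_stop("prior df must be positive")
  if (thin < 1) bca_stop("thin must be >= 1")
  if (!is.null(pi_fixed) && (pi_fixed < 0 || pi_fixed > 1)) {
    bca_stop("pi_fixed must lie in [0, 1]")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 nu_alpha = nu_alpha, s2_alpha = s2_alpha,
                 nu_e = nu_e, s2_e = s2_e, var_fraction = var_fraction,
                 fix_sigma2_e = fix_sigma2_e,
                 fix_sigma2_alpha = fix_sigma2_alpha,
                 pi_fixed = pi_fixed),
            class = "bca_mcmc_settings")
}
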