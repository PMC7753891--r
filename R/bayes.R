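#' Bayes A: Gibbs sampler with locus-specific effect variances
#'
#' Whole-genome regression `y = X b + M alpha + e` in which the non-SNP
#' effects `b` have flat priors, each marker effect `alpha_j` is normal with
#' its own variance, and each variance has a scaled-inverse-chi-square prior
#' — marginally the effects are i.i.d. scaled-t variables, so every marker is
#' assumed to have some effect. Single-site Gibbs updates are used for the
#' marker effects; the fixed-effect block is drawn jointly from its
#' multivariate-normal full conditional (stabler than scalar updates when
#' the design has many nested management dummies).
#'
#' @param X numeric fixed-effect design matrix (full rank, with intercept).
#' @param M numeric marker dosage matrix (columns = SNP, entries 0/1/2, no
#'   missing values).
#' @param y numeric response (finite).
#' @param settings an [mcmc_settings()].
#' @return object of class `bca_posterior`; see [posterior_summary fields:
#'   per-SNP posterior means/SDs and sign posterior probabilities, thinned
#'   post-burn-in chains for marker effects, fixed effects and variances, and
#'   posterior samples of the total contrast `D = 2 * sum(|alpha|)`].
#' @export
run_bayes_a <- function(X, M, y, settings = mcmc_settings()) {
  gibbs_wgr(X, M, y, settings, prior = "a")
}

#' Bayes C-pi: spike-and-slab Gibbs sampler with unknown pi
#'
#' As [run_bayes_a()], but each marker effect is exactly zero with
#' probability `pi` or drawn from a normal with a variance common to all
#' included markers. The inclusion indicator of each marker is sampled from
#' its conditional Bernoulli with the effect integrated out, and `pi` itself
#' is treated as unknown with a Uniform(0,1) prior, so its full conditional
#' is Beta(#excluded + 1, #included + 1). The posterior mean of the
#' indicator is the marker's posterior probability of association.
#'
#' @inheritParams run_bayes_a
#' @return a `bca_posterior` with, additionally, per-SNP inclusion
#'   probabilities (`pp_nonnull`) and the `pi` chain.
#' @export
run_bayes_cpi <- function(X, M, y, settings = mcmc_settings()) {
  gibbs_wgr(X, M, y, settings, prior = "cpi")
}

# Shared Gibbs machinery for both priors.
gibbs_wgr <- function(X, M, y, settings, prior = c("a", "cpi")) {
  prior <- match.arg(prior)
  stopifnot(inherits(settings, "bca_mcmc_settings"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  M <- as.matrix(M); storage.mode(M) <- "double"
  y <- as.numeric(y)
  if (any(!is.finite(y))) bca_stop("response contains non-finite values")
  if (anyNA(M)) bca_stop("marker matrix contains missing values; impute first")
  n <- length(y)
  k <- ncol(X)
  p <- ncol(M)
  snp_ids <- if (p == 0) character(0)
             else colnames(M) %||% paste0("snp", seq_len(p))

  vary <- stats::var(y)
  r <- settings$var_fraction
  pbar <- if (p > 0) colMeans(M) / 2 else numeric()
  sum2pq <- sum(2 * pbar * (1 - pbar))
  s2a <- settings$s2_alpha %||% {
    tgt <- r * vary / max(sum2pq, 1e-8)
    tgt * max(settings$nu_alpha - 2, 0.5) / settings$nu_alpha
  }
  s2e <- settings$s2_e %||%
    ((1 - r) * vary * max(settings$nu_e - 2, 0.5) / settings$nu_e)

  XtX <- crossprod(X)
  Rx <- chol(XtX)
  mtm <- if (p > 0) colSums(M^2) else numeric()

  n_keep <- length(seq(settings$burn_in + 1L, settings$n_iter,
                       by = settings$thin))
  alpha_s <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, snp_ids))
  delta_s <- if (prior == "cpi") matrix(NA_real_, n_keep, p,
                                        dimnames = list(NULL, snp_ids))
  fixed_s <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, colnames(X)))
  s2e_s <- numeric(n_keep)
  pi_s <- if (prior == "cpi") numeric(n_keep)

  local_seed(settings$seed, {
    b <- qr.coef(qr(X), y)
    alpha <- rep(0, p)
    delta <- rep(1L, p)
    sigma2e <- settings$fix_sigma2_e %||% (vary / 2)
    sigma2j <- rep(settings$fix_sigma2_alpha %||% s2a, max(p, 1))
    sigma2a <- settings$fix_sigma2_alpha %||% s2a
    pi_cur <- settings$pi_fixed %||% 0.5
    e <- y - drop(X %*% b)
    keep_i <- 0L

    for (it in seq_len(settings$n_iter)) {
      # fixed effects jointly: b | rest ~ N((X'X)^-1 X'w, sigma2e (X'X)^-1)
      w <- e + drop(X %*% b)
      bhat <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, w)))
      b_new <- drop(bhat + sqrt(sigma2e) *
                      backsolve(Rx, stats::rnorm(k)))
      e <- w - drop(X %*% b_new)
      b <- b_new

      if (p > 0) {
        if (prior == "a") {
          for (j in seq_len(p)) {
            xj <- M[, j]
            e <- e + xj * alpha[j]
            rhs <- sum(xj * e)
            C <- mtm[j] + sigma2e / sigma2j[j]
            aj <- stats::rnorm(1, rhs / C, sqrt(sigma2e / C))
            e <- e - xj * aj
            alpha[j] <- aj
          }
          if (is.null(settings$fix_sigma2_alpha)) {
            sigma2j <- (settings$nu_alpha * s2a + alpha^2) /
              stats::rchisq(p, settings$nu_alpha + 1)
          }
        } else {
          logit_excl <- log(pi_cur) - log1p(-pi_cur)  # +-Inf at pi = 0 or 1
          for (j in seq_len(p)) {
            xj <- M[, j]
            e <- e + xj * alpha[j]
            rhs <- sum(xj * e)
            v <- mtm[j] * sigma2a + sigma2e
            log_bf <- 0.5 * log(sigma2e / v) +
              rhs^2 * sigma2a / (2 * sigma2e * v)
            p_incl <- if (pi_cur <= 0) 1 else if (pi_cur >= 1) 0 else
              1 / (1 + exp(logit_excl - log_bf))
            if (stats::runif(1) < p_incl) {
              C <- mtm[j] + sigma2e / sigma2a
              aj <- stats::rnorm(1, rhs / C, sqrt(sigma2e / C))
              delta[j] <- 1L
            } else {
              aj <- 0
              delta[j] <- 0L
            }
            e <- e - xj * aj
            alpha[j] <- aj
          }
          n_in <- sum(delta)
          if (is.null(settings$fix_sigma2_alpha)) {
            sigma2a <- (settings$nu_alpha * s2a + sum(alpha^2)) /
              stats::rchisq(1, settings$nu_alpha + n_in)
          }
          if (is.null(settings$pi_fixed)) {
            pi_cur <- stats::rbeta(1, p - n_in + 1, n_in + 1)
          }
        }
      } else if (prior == "cpi" && is.null(settings$pi_fixed)) {
        pi_cur <- stats::rbeta(1, 1, 1)  # no markers: prior is untouched
      }

      if (is.null(settings$fix_sigma2_e)) {
        sigma2e <- (settings$nu_e * s2e + sum(e^2)) /
          stats::rchisq(1, settings$nu_e + n)
      }
      if (!is.finite(sigma2e) || sigma2e > 1e12) {
        bca_stop("residual variance diverged at iteration ", it)
      }

      if (it > settings$burn_in &&
          (it - settings$burn_in - 1L) %% settings$thin == 0L) {
        keep_i <- keep_i + 1L
        if (p > 0) alpha_s[keep_i, ] <- alpha
        if (prior == "cpi" && p > 0) delta_s[keep_i, ] <- delta
        fixed_s[keep_i, ] <- b
        s2e_s[keep_i] <- sigma2e
        if (prior == "cpi") pi_s[keep_i] <- pi_cur
      }
    }
  })

  summary <- data.frame(
    snp_id = snp_ids,
    mean = if (p > 0) colMeans(alpha_s) else numeric(),
    sd = if (p > 0) apply(alpha_s, 2, stats::sd) else numeric(),
    pp_positive = if (p > 0) colMeans(alpha_s > 0) else numeric(),
    pp_negative = if (p > 0) colMeans(alpha_s < 0) else numeric(),
    pp_nonnull = if (prior == "cpi" && p > 0) colMeans(delta_s)
                 else rep(NA_real_, p),
    stringsAsFactors = FALSE)
  D_samples <- if (p > 0) 2 * rowSums(abs(alpha_s)) else rep(0, n_keep)
  structure(list(prior = prior, summary = summary,
                 alpha_samples = alpha_s, delta_samples = delta_s,
                 fixed_samples = fixed_s, sigma2e_samples = s2e_s,
                 pi_samples = pi_s,
                 pi_posterior_mean = if (prior == "cpi") mean(pi_s),
                 D_samples = D_samples, D_mean = mean(D_samples),
                 D_sd = stats::sd(D_samples),
                 n_kept = n_keep, snp_ids = snp_ids, settings = settings),
            class = "bca_posterior")
}

#' @export
print.bca_posterior <- function(x, ...) {
  cat("Posterior (", ifelse(x$prior == "a", "Bayes A", "Bayes Cpi"), "): ",
      length(x$snp_ids), " SNP, ", x$n_kept, " kept samples\n", sep = "")
  cat(sprintf("  D posterior mean %.3f (SD %.3f)\n", x$D_mean, x$D_sd))
  if (x$prior == "cpi") {
    cat(sprintf("  pi posterior mean %.3f\n", x$pi_posterior_mean))
  }
  invisible(x)
}

#' Sign-based posterior-probability table
#'
#' Lists, for each threshold, the SNP whose posterior probability of having a
#' positive (or negative) effect exceeds the threshold (strict `>`), and
#' summarizes the posterior of the total contrast `D = 2 * sum(|alpha|)`
#' restricted to the listed SNP, computed sample by sample.
#'
#' @param posterior a `bca_posterior`.
#' @param thresholds default `c(0.8, 0.7, 0.5)`.
#' @return list of class `bca_pp_table`: `table` (threshold, n_snps, D_mean,
#'   D_sd) and `snps` (SNP ids listed at each threshold).
#' @export
pp_sign_table <- function(posterior, thresholds = c(0.8, 0.7, 0.5)) {
  stopifnot(inherits(posterior, "bca_posterior"))
  s <- posterior$summary
  pp <- pmax(s$pp_positive, s$pp_negative)
  pp_threshold_table(posterior, pp, thresholds, label = "sign")
}

#' Inclusion-based posterior-probability table
#'
#' For a spike-and-slab posterior: lists SNP whose posterior probability of a
#' non-null effect (posterior mean of the inclusion indicator) exceeds each
#' threshold (strict `>`), with the posterior of D over the listed set. At
#' threshold 0 every SNP with any included sample is listed.
#'
#' @param posterior a `bca_posterior` from [run_bayes_cpi()].
#' @param thresholds default `c(0, 0.1, 0.2)`; small breeds whose `pi`
#'   posterior stays near its prior are better summarized with
#'   `c(0.4, 0.5)`. Must lie in `[0, 1)`.
#' @return a `bca_pp_table`.
#' @export
pp_inclusion_table <- function(posterior, thresholds = c(0, 0.1, 0.2)) {
  stopifnot(inherits(posterior, "bca_posterior"))
  if (posterior$prior != "cpi") {
    bca_stop("inclusion probabilities require a Bayes Cpi posterior")
  }
  if (any(thresholds < 0 | thresholds >= 1)) {
    bca_stop("thresholds must lie in [0, 1)")
  }
  pp_threshold_table(posterior, posterior$summary$pp_nonnull, thresholds,
                     label = "inclusion")
}

pp_threshold_table <- function(posterior, pp, thresholds, label) {
  snps <- lapply(thresholds, function(th) posterior$snp_ids[pp > th])
  names(snps) <- paste0("pp>", thresholds)
  rows <- lapply(seq_along(thresholds), function(i) {
    set <- snps[[i]]
    if (length(set)) {
      d <- 2 * rowSums(abs(posterior$alpha_samples[, set, drop = FALSE]))
      data.frame(threshold = thresholds[i], n_snps = length(set),
                 D_mean = mean(d), D_sd = stats::sd(d))
    } else {
      data.frame(threshold = thresholds[i], n_snps = 0L,
                 D_mean = 0, D_sd = 0)
    }
  })
  structure(list(table = do.call(rbind, rows), snps = snps, kind = label),
            class = "bca_pp_table")
}

#' @export
print.bca_pp_table <- function(x, ...) {
  cat("Posterior-probability table (", x$kind, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Bayesian analysis of a fitted hierarchy
#'
#' Runs a whole-genome regression on the SNP retained by the frequentist
#' screen (nominal P < 0.3), with the hierarchy's management terms as flat-
#' prior fixed effects — the screened markers are the ones worth the heavier
#' machinery, and a prior that lets effects be exactly zero then reports how
#' many of them survive.
#'
#' @param hierarchy a `bca_hierarchy` with a non-empty selection.
#' @param prior `"a"` or `"cpi"`.
#' @param settings an [mcmc_settings()].
#' @param snps optional explicit SNP set overriding the screen.
#' @return a `bca_posterior`.
#' @export
bayes_assoc <- function(hierarchy, prior = c("a", "cpi"),
                        settings = mcmc_settings(), snps = NULL) {
  stopifnot(inherits(hierarchy, "bca_hierarchy"))
  prior <- match.arg(prior)
  snps <- snps %||% hierarchy$selected_snps
  if (length(snps) == 0) bca_stop("no SNP selected; nothing to analyze")
  study <- hierarchy$study
  sp <- model_spec(hierarchy$fixed_terms)
  des <- build_design(study$phenotypes, sp)
  M <- study$genotypes$values[des$rows_used, snps, drop = FALSE]
  fun <- if (prior == "a") run_bayes_a else run_bayes_cpi
  fun(des$X, M, des$y, settings)
}
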