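#' Pairwise LD r-squared from unphased genotypes
#'
#' Estimates two-locus haplotype frequencies from unphased 0/1/2 genotype
#' pairs by expectation-maximization and returns
#' \eqn{r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))} with
#' \eqn{D = f(AB) - p_A p_B}. Only the double-heterozygote class is phase
#' ambiguous; its expected split between the two haplotype resolutions is
#' recomputed each E-step from the current frequencies. The EM starts at
#' linkage equilibrium and stops when no haplotype frequency moves by more
#' than `tol` (default 1e-8) or after `max_iter` iterations.
#'
#' `method = "composite"` instead returns the squared Pearson correlation of
#' the genotype dosages — a fast approximation that does not resolve phase.
#'
#' @param genotypes a `bca_genotypes`.
#' @param snp_a,snp_b SNP ids (columns of the genotype matrix).
#' @param method `"em"` (default) or `"composite"`.
#' @param max_iter,tol EM controls.
#' @return r-squared in `[0, 1]`, or `NA` when either locus is monomorphic
#'   (LD is then undefined). For the EM method the result carries attributes
#'   `D`, `hap_freq` (AB, Ab, aB, ab) and `iterations`.
#' @export
ld_r2 <- function(genotypes, snp_a, snp_b, method = c("em", "composite"),
                  max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(genotypes, "bca_genotypes"))
  method <- match.arg(method)
  ga <- genotypes$values[, snp_a]
  gb <- genotypes$values[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (length(ga) == 0) return(NA_real_)
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  if (method == "composite") {
    return(stats::cor(ga, gb)^2)
  }
  em_r2(ga, gb, max_iter = max_iter, tol = tol)
}

# Two-locus EM on the 3x3 genotype table. A/B denote counted alleles.
em_r2 <- function(ga, gb, max_iter = 100L, tol = 1e-8) {
  n <- length(ga)
  cnt <- table(factor(ga, levels = 0:2), factor(gb, levels = 0:2))
  n_dh <- cnt["1", "1"]
  # phase-unambiguous haplotype counts
  base <- c(
    AB = 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"],
    Ab = 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"],
    aB = 2 * cnt["0", "2"] + cnt["1", "2"] + cnt["0", "1"],
    ab = 2 * cnt["0", "0"] + cnt["1", "0"] + cnt["0", "1"]
  )
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  p <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
         ab = (1 - pa) * (1 - pb))
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- p["AB"] * p["ab"]
    trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt_new <- base + n_dh * c(w, 1 - w, 1 - w, w)
    p_new <- cnt_new / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol || it >= max_iter) break
  }
  D <- unname(p["AB"] - pa * pb)
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  r2 <- min(max(unname(r2), 0), 1)
  attr(r2, "D") <- D
  attr(r2, "hap_freq") <- p
  attr(r2, "iterations") <- it
  r2
}

#' All pairwise LD within genes (or across the whole panel)
#'
#' @param genotypes a `bca_genotypes`.
#' @param panel optional `bca_panel`; when given and `within_genes = TRUE`,
#'   only pairs belonging to the same gene are evaluated (the usual usage for
#'   a candidate-gene panel).
#' @param within_genes restrict pairs to shared genes (needs `panel`).
#' @param strong_r2 threshold above which (strict `>`) a pair is flagged as
#'   in strong LD; default 0.6.
#' @param method passed to [ld_r2()].
#' @return data.frame of class `bca_ld` with columns `snp_a`, `snp_b`,
#'   `gene` (NA without a panel), `r2`, `strong`.
#' @export
ld_matrix <- function(genotypes, panel = NULL, within_genes = !is.null(panel),
                      strong_r2 = 0.6, method = "em") {
  stopifnot(inherits(genotypes, "bca_genotypes"))
  snps <- colnames(genotypes$values)
  gene <- if (!is.null(panel)) {
    panel$gene[match(snps, panel$snp_id)]
  } else {
    rep(NA_character_, length(snps))
  }
  pairs <- utils::combn(seq_along(snps), 2)
  keep <- rep(TRUE, ncol(pairs))
  if (within_genes) {
    if (is.null(panel)) bca_stop("within_genes = TRUE requires a panel")
    keep <- !is.na(gene[pairs[1, ]]) & gene[pairs[1, ]] == gene[pairs[2, ]]
  }
  pairs <- pairs[, keep, drop = FALSE]
  r2 <- vapply(seq_len(ncol(pairs)), function(k) {
    as.numeric(ld_r2(genotypes, snps[pairs[1, k]], snps[pairs[2, k]],
                     method = method))
  }, numeric(1))
  out <- data.frame(snp_a = snps[pairs[1, ]], snp_b = snps[pairs[2, ]],
                    gene = gene[pairs[1, ]], r2 = r2,
                    strong = !is.na(r2) & r2 > strong_r2,
                    stringsAsFactors = FALSE)
  class(out) <- c("bca_ld", "data.frame")
  out
}
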