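#' Call-rate filtering of a genotype matrix
#'
#' Computes per-SNP call rates within each breed and retains, per breed, the
#' SNP whose call rate is at least `threshold` (the boundary is inclusive:
#' 9/10 typed animals at threshold 0.90 is kept). In combined mode a SNP is
#' retained for the pooled within-species analysis only when it passes in
#' every breed.
#'
#' @param genotypes a `bca_genotypes`.
#' @param breeds character vector of breed labels, one per animal (in row
#'   order of the genotype matrix, or named by animal id).
#' @param threshold minimum call rate, default 0.90.
#' @param combined also compute the across-breed retained set (default TRUE).
#' @return list of class `bca_qc` with `call_rates` (SNP x breed matrix),
#'   `retained_per_breed` (named list of snp-id vectors),
#'   `retained_combined` (snp ids, or NULL when `combined = FALSE`) and
#'   `threshold`.
#' @export
call_rate_filter <- function(genotypes, breeds, threshold = 0.90,
                             combined = TRUE) {
  stopifnot(inherits(genotypes, "bca_genotypes"))
  v <- genotypes$values
  breeds <- align_breeds(breeds, rownames(v))
  tab <- table(breeds)
  if (any(tab == 0)) {
    bca_stop("breed(s) with zero animals: ",
             paste(names(tab)[tab == 0], collapse = ", "))
  }
  lev <- names(tab)
  call_rates <- sapply(lev, function(b) {
    colMeans(!is.na(v[breeds == b, , drop = FALSE]))
  })
  call_rates <- matrix(call_rates, nrow = ncol(v),
                       dimnames = list(colnames(v), lev))
  retained <- lapply(lev, function(b) {
    rownames(call_rates)[call_rates[, b] >= threshold]
  })
  names(retained) <- lev
  comb <- if (combined) {
    rownames(call_rates)[apply(call_rates >= threshold, 1, all)]
  }
  structure(list(call_rates = call_rates, retained_per_breed = retained,
                 retained_combined = comb, threshold = threshold),
            class = "bca_qc")
}

align_breeds <- function(breeds, animal_ids) {
  if (!is.null(names(breeds))) {
    miss <- setdiff(animal_ids, names(breeds))
    if (length(miss)) bca_stop("no breed assigned to animal(s): ",
                               paste(utils::head(miss, 5), collapse = ", "))
    breeds <- breeds[animal_ids]
  }
  if (length(breeds) != length(animal_ids)) {
    bca_stop("breeds must have one entry per animal")
  }
  b <- as.character(breeds)
  if (is.factor(breeds)) factor(b, levels = levels(breeds)) else factor(b)
}

#' @export
print.bca_qc <- function(x, ...) {
  cat("Call-rate QC at threshold", x$threshold, "\n")
  for (b in names(x$retained_per_breed)) {
    cat("  ", b, ": ", length(x$retained_per_breed[[b]]), "/",
        nrow(x$call_rates), " SNP retained\n", sep = "")
  }
  if (!is.null(x$retained_combined)) {
    cat("  combined: ", length(x$retained_combined), " SNP\n", sep = "")
  }
  invisible(x)
}

#' Counted-allele frequencies
#'
#' Frequency of the counted allele per SNP among non-missing genotypes:
#' sum of allele counts over twice the number of typed animals. SNP with no
#' typed animal get `NA` and are flagged in the `"undefined"` attribute.
#'
#' @param genotypes a `bca_genotypes`.
#' @param animals optional subset of animals (ids or logical/integer index),
#'   e.g. one breed.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequency <- function(genotypes, animals = NULL) {
  stopifnot(inherits(genotypes, "bca_genotypes"))
  v <- genotypes$values
  if (!is.null(animals)) v <- v[animals, , drop = FALSE]
  n_typed <- colSums(!is.na(v))
  freq <- colSums(v, na.rm = TRUE) / (2 * n_typed)
  freq[n_typed == 0] <- NA_real_
  attr(freq, "undefined") <- colnames(v)[n_typed == 0]
  freq
}

#' Impute sporadic missing genotypes
#'
#' Fills missing cells with independent draws from Binomial(2, p-hat), where
#' p-hat is the counted-allele frequency estimated from the typed animals —
#' breed by breed when breed labels are given. Intended for the sporadic
#' missingness that survives the call-rate filter; it ignores linkage, which
#' is acceptable for a sparse candidate-gene panel of mostly unlinked loci.
#'
#' @param genotypes a `bca_genotypes` (after filtering).
#' @param breeds optional per-animal breed labels; when given, frequencies
#'   are estimated within breed.
#' @param seed optional integer seed (stream-local; the caller's RNG state is
#'   untouched).
#' @return a `bca_genotypes` with no missing values; the imputation log is in
#'   `attr(, "imputed")` (data.frame of animal, snp, breed, value).
#' @export
impute_missing <- function(genotypes, breeds = NULL, seed = NULL) {
  stopifnot(inherits(genotypes, "bca_genotypes"))
  v <- genotypes$values
  if (!anyNA(v)) {
    out <- genotypes
    attr(out, "imputed") <- data.frame(animal = character(), snp = character(),
                                       breed = character(), value = integer())
    return(out)
  }
  grp <- if (is.null(breeds)) {
    factor(rep("(all)", nrow(v)))
  } else {
    align_breeds(breeds, rownames(v))
  }
  log_rows <- list()
  local_seed(seed, {
    for (b in levels(grp)) {
      rows <- which(grp == b)
      sub <- v[rows, , drop = FALSE]
      na_cols <- which(colSums(is.na(sub)) > 0)
      for (j in na_cols) {
        typed <- sub[, j][!is.na(sub[, j])]
        if (length(typed) == 0) {
          bca_stop("SNP '", colnames(v)[j], "' has no typed animal in breed '",
                   b, "'; run call_rate_filter first")
        }
        p <- sum(typed) / (2 * length(typed))
        miss <- rows[is.na(v[rows, j])]
        v[miss, j] <- stats::rbinom(length(miss), 2L, p)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(animal = rownames(v)[miss], snp = colnames(v)[j],
                     breed = b, value = v[miss, j],
                     stringsAsFactors = FALSE)
      }
    }
  })
  out <- genotype_matrix(v, genotypes$counted_allele, genotypes$other_allele)
  attr(out, "imputed") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(animal = character(), snp = character(),
               breed = character(), value = integer())
  }
  out
}
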