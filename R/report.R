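#' Publication-shaped report tables
#'
#' These helpers flatten the pipeline's result objects into plain data.frames
#' shaped like the study's report tables: model-hierarchy R-squared per
#' analysis unit, per-gene substitution effects with the D contrast, and
#' posterior-probability tables from the Bayesian stage.
#'
#' @param hierarchies a `bca_hierarchy` or a list of them.
#' @return a data.frame, one row per model in the hierarchy.
#' @export
report_hierarchy <- function(hierarchies) {
  if (inherits(hierarchies, "bca_hierarchy")) hierarchies <- list(hierarchies)
  lbl <- c(base = "fixed effects", all_snp = "all SNP",
           coding = "nonsynonymous/stop SNP", selected = "selected SNP")
  do.call(rbind, lapply(hierarchies, function(h) {
    n_snp <- c(base = 0L,
               all_snp = ncol(h$study$genotypes$values),
               coding = if (is.null(h$fits$coding)) NA_integer_ else
                 sum(h$fits$coding$term_map$type == "snp"),
               selected = length(h$selected_snps))
    data.frame(unit = h$unit, model = unname(lbl), n_snps = unname(n_snp),
               r_squared = unname(h$r_squared), stringsAsFactors = FALSE)
  }))
}

#' @rdname report_hierarchy
#' @param result a `bca_assoc_result` from [gene_effects()].
#' @export
report_gene_effects <- function(result) {
  stopifnot(inherits(result, "bca_assoc_result"))
  empty <- data.frame(unit = character(), gene = character(),
                      snp_id = character(), beta = numeric(), se = numeric(),
                      p = numeric(), recommended_allele = character(),
                      recommended_freq = numeric(), gene_D = numeric(),
                      gene_D_se = numeric(), gene_f_p = numeric(),
                      total_D = numeric(), total_D_se = numeric(),
                      stringsAsFactors = FALSE)
  if (isTRUE(result$no_snp_selected)) return(empty)
  snp <- result$per_snp
  g <- result$per_gene[match(snp$gene, result$per_gene$gene), ]
  data.frame(unit = result$unit, gene = snp$gene, snp_id = snp$snp_id,
             beta = snp$beta, se = snp$se, p = snp$p,
             recommended_allele = snp$recommended_allele,
             recommended_freq = snp$recommended_freq,
             gene_D = g$D, gene_D_se = g$D_se, gene_f_p = g$f_p,
             total_D = result$total$D, total_D_se = result$total$se,
             stringsAsFactors = FALSE)
}

#' @rdname report_hierarchy
#' @param pp a `bca_pp_table`.
#' @export
report_pp <- function(pp) {
  stopifnot(inherits(pp, "bca_pp_table"))
  tab <- pp$table
  tab$snps <- vapply(pp$snps, paste, character(1), collapse = ",")
  tab
}

#' @rdname report_hierarchy
#' @param qc a `bca_qc`.
#' @export
report_qc <- function(qc) {
  stopifnot(inherits(qc, "bca_qc"))
  cr <- qc$call_rates
  out <- data.frame(snp_id = rep(rownames(cr), ncol(cr)),
                    breed = rep(colnames(cr), each = nrow(cr)),
                    call_rate = as.vector(cr), stringsAsFactors = FALSE)
  out$retained <- out$call_rate >= qc$threshold
  out
}

#' Write a report table as TSV
#'
#' Writes the table twice: once with numeric columns rounded for display
#' (default 3 decimals, matching typical journal precision) and once at full
#' precision with a `_full.tsv` suffix.
#'
#' @param df data.frame to write.
#' @param path output path ending in `.tsv`.
#' @param digits display rounding.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, digits = 3) {
  full <- sub("\\.tsv$", "_full.tsv", path)
  utils::write.table(df, full, sep = "\t", row.names = FALSE, quote = FALSE)
  shown <- df
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = digits)
  utils::write.table(shown, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
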