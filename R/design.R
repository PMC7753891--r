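#' Model specification for the fixed-effects analysis
#'
#' Fixed terms use a small nesting grammar: a bare name (`"farmer"`,
#' `"place"`, `"batch"`, `"breed"`, `"lactation"`, `"yield"`) or
#' `"child(parent)"` / `"child(a x b)"` for effects nested in one or more
#' parent factors, e.g. `"place(breed)"` or `"farmer(place x breed)"`.
#' `lactation` and `yield` are numeric covariates; everything else is
#' categorical with treatment (reference-level) coding. Nesting parents must
#' themselves appear in the specification.
#'
#' @param fixed_terms character vector of fixed-effect terms, in order.
#' @param snp_terms snp ids appended as 0/1/2 numeric covariates.
#' @param response response column, default `"bc"`.
#' @return list of class `bca_model_spec`.
#' @export
model_spec <- function(fixed_terms, snp_terms = character(),
                       response = "bc") {
  parsed <- lapply(fixed_terms, parse_term)
  vars <- vapply(parsed, `[[`, character(1), "var")
  nest_vars <- unique(unlist(lapply(parsed, `[[`, "nest")))
  orphan <- setdiff(nest_vars, vars)
  if (length(orphan)) {
    bca_stop("nesting parent(s) not in the model: ",
             paste(orphan, collapse = ", "))
  }
  structure(list(fixed_terms = fixed_terms, parsed = parsed,
                 snp_terms = snp_terms, response = response),
            class = "bca_model_spec")
}

parse_term <- function(term) {
  m <- regmatches(term, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*(\\(([^)]*)\\))?$",
                                term))[[1]]
  if (length(m) == 0 || m[1] != term) bca_stop("cannot parse model term: ", term)
  nest <- character()
  if (nzchar(m[3])) {
    nest <- trimws(strsplit(m[4], "(?i)\\s*(x|×)\\s*", perl = TRUE)[[1]])
    nest <- nest[nzchar(nest)]
  }
  list(term = term, var = m[2], nest = nest,
       numeric = m[2] %in% c("lactation", "yield"))
}

#' Build a design matrix for the fixed-effects model
#'
#' Assembles intercept, treatment-coded categorical dummies (nested terms are
#' coded through the interaction of the child with its parents), numeric
#' covariates, and SNP dosage columns. Rows with a missing value in any used
#' variable are dropped and counted. Exactly collinear columns (e.g. farmer
#' dummies aliased with place) are removed deterministically by a
#' column-pivoted QR in which earlier columns take precedence; the removal is
#' recorded in `dropped_columns`.
#'
#' @param phenotypes a `bca_phenotypes` (or any data.frame with the needed
#'   columns).
#' @param spec a `bca_model_spec`.
#' @param genotypes optional `bca_genotypes` supplying the SNP dosage columns
#'   named in `spec$snp_terms`.
#' @return list of class `bca_design`: full-rank matrix `X`, response `y`,
#'   `term_map` (data.frame: column, term, type), `dropped_columns`,
#'   `n_dropped_rows`, `rows_used` (animal ids).
#' @export
build_design <- function(phenotypes, spec, genotypes = NULL) {
  stopifnot(inherits(spec, "bca_model_spec"))
  df <- as.data.frame(phenotypes)
  used_vars <- unique(unlist(lapply(spec$parsed, function(p) c(p$var, p$nest))))
  miss_col <- setdiff(c(spec$response, used_vars), names(df))
  if (length(miss_col)) {
    bca_stop("model term references absent column(s): ",
             paste(miss_col, collapse = ", "))
  }
  if (length(spec$snp_terms)) {
    if (is.null(genotypes)) bca_stop("snp_terms given but no genotypes")
    miss_snp <- setdiff(spec$snp_terms, colnames(genotypes$values))
    if (length(miss_snp)) {
      bca_stop("SNP not in genotype matrix: ", paste(miss_snp, collapse = ", "))
    }
    gmat <- genotypes$values[df$animal_id, spec$snp_terms, drop = FALSE]
    if (anyNA(gmat)) {
      bca_stop("missing genotypes in SNP terms; impute first (impute_missing)")
    }
  } else {
    gmat <- NULL
  }

  keep <- stats::complete.cases(df[, c(spec$response, used_vars), drop = FALSE])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!is.null(gmat)) gmat <- gmat[keep, , drop = FALSE]

  blocks <- list(`(Intercept)` = matrix(1, nrow(df), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  map <- data.frame(column = "(Intercept)", term = "(Intercept)",
                    type = "intercept", stringsAsFactors = FALSE)
  for (p in spec$parsed) {
    if (p$numeric) {
      b <- matrix(as.numeric(df[[p$var]]), ncol = 1,
                  dimnames = list(NULL, p$var))
    } else {
      f <- if (length(p$nest)) {
        interaction(c(df[p$nest], df[p$var]), drop = TRUE, sep = ":")
      } else {
        factor(df[[p$var]])
      }
      f <- droplevels(f)
      if (nlevels(f) < 2) next  # constant factor carries no information
      b <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(b) <- paste0(p$term, levels(f)[-1])
    }
    blocks[[p$term]] <- b
    map <- rbind(map, data.frame(column = colnames(b), term = p$term,
                                 type = "fixed", stringsAsFactors = FALSE))
  }
  if (!is.null(gmat)) {
    storage.mode(gmat) <- "double"
    blocks[["(snps)"]] <- gmat
    map <- rbind(map, data.frame(column = colnames(gmat),
                                 term = colnames(gmat), type = "snp",
                                 stringsAsFactors = FALSE))
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- map$column

  qx <- qr(X)
  kept <- sort(qx$pivot[seq_len(qx$rank)])
  dropped_cols <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
  X <- X[, kept, drop = FALSE]
  map <- map[map$column %in% colnames(X), , drop = FALSE]

  structure(list(X = X, y = as.numeric(df[[spec$response]]),
                 term_map = map, dropped_columns = dropped_cols,
                 n_dropped_rows = n_dropped,
                 rows_used = df$animal_id, spec = spec),
            class = "bca_design")
}

#' Default fixed-effect terms for a study
#'
#' Mirrors the published model choices: the pooled within-species analysis
#' uses breed with place nested in breed and farmer nested in place-by-breed
#' (buffalo additionally nest everything in the collection batch); per-breed
#' analyses use farmer and place (buffalo: plus batch), with lactation and
#' yield added as covariates when the information is available.
#'
#' @param study a `bca_study`.
#' @param combined pooled multi-breed model (TRUE) or single-breed model.
#' @return character vector of fixed terms for [model_spec()].
#' @export
default_model_terms <- function(study, combined = FALSE) {
  ph <- study$phenotypes
  species <- unique(ph$species)
  has_batch <- sum(!is.na(unique(ph$batch))) >= 2
  if (combined) {
    if (species[1] == "buffalo" && has_batch) {
      return(c("breed", "batch(breed)", "place(batch x breed)"))
    }
    return(c("breed", "place(breed)", "farmer(place x breed)"))
  }
  terms <- character()
  if (has_batch) terms <- c(terms, "batch")
  terms <- c(terms, "farmer", "place")
  if (any(!is.na(ph$lactation))) terms <- c(terms, "lactation")
  if (any(!is.na(ph$yield))) terms <- c(terms, "yield")
  terms
}
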