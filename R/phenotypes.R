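#' Read a phenotype/covariate table
#'
#' One row per animal with the milk beta-carotene concentration (`bc`, in
#' micrograms per 100 mL) and the management covariates used by the
#' fixed-effect models: breed, place, farmer nested in place, an optional
#' collection batch (buffalo data were collected in two periods), lactation
#' number and daily milk yield. Empty cells are missing.
#'
#' @param path CSV with columns `animal_id`, `species`, `breed`, `bc`,
#'   `place`, `farmer`, `batch`, `lactation`, `yield`.
#' @return data.frame of class `bca_phenotypes`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) bca_stop("phenotype file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("animal_id", "species", "breed", "bc", "place", "farmer")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    bca_stop("phenotype CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  for (opt in c("batch", "lactation", "yield")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  }
  validate_phenotypes(raw)
}

validate_phenotypes <- function(df) {
  if (anyDuplicated(df$animal_id)) {
    bca_stop("duplicated animal_id: ",
             paste(unique(df$animal_id[duplicated(df$animal_id)]), collapse = ", "))
  }
  df$bc <- as.numeric(df$bc)
  if (any(!is.finite(df$bc))) bca_stop("bc must be finite for every animal")
  if (any(df$bc < 0)) bca_stop("bc must be non-negative (micrograms/100 mL)")
  bad_sp <- !df$species %in% c("cattle", "buffalo")
  if (any(bad_sp)) {
    bca_stop("species must be 'cattle' or 'buffalo'; got: ",
             paste(unique(df$species[bad_sp]), collapse = ", "))
  }
  df$lactation <- as.numeric(df$lactation)
  df$yield <- as.numeric(df$yield)
  if (any(df$lactation < 0, na.rm = TRUE)) bca_stop("lactation must be >= 0")
  if (any(df$yield < 0, na.rm = TRUE)) bca_stop("yield must be >= 0")
  class(df) <- c("bca_phenotypes", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param phenotypes a `bca_phenotypes`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Assemble genotypes, phenotypes and panel into a study
#'
#' Inner join on animal id. Animals present in only one of the two inputs are
#' dropped and reported in the returned object; an empty intersection is an
#' error.
#'
#' @param genotypes a `bca_genotypes`.
#' @param phenotypes a `bca_phenotypes`.
#' @param panel optional `bca_panel`; also used to attach allele labels.
#' @return object of class `bca_study` with elements `genotypes`,
#'   `phenotypes` (row-aligned with the genotype matrix), `panel`, and
#'   `dropped` (list with `genotype_only` and `phenotype_only` ids).
#' @export
assemble_study <- function(genotypes, phenotypes, panel = NULL) {
  stopifnot(inherits(genotypes, "bca_genotypes"),
            inherits(phenotypes, "bca_phenotypes"))
  gid <- rownames(genotypes$values)
  pid <- phenotypes$animal_id
  common <- intersect(gid, pid)
  if (length(common) == 0) {
    bca_stop("no animals shared between genotype and phenotype tables")
  }
  dropped <- list(genotype_only = setdiff(gid, pid),
                  phenotype_only = setdiff(pid, gid))
  g <- subset_genotypes(genotypes, animals = common)
  if (!is.null(panel)) g <- attach_alleles(g, panel)
  ph <- phenotypes[match(common, phenotypes$animal_id), , drop = FALSE]
  rownames(ph) <- NULL
  structure(list(genotypes = g, phenotypes = ph, panel = panel,
                 dropped = dropped),
            class = "bca_study")
}

#' @export
print.bca_study <- function(x, ...) {
  cat("Study:", nrow(x$genotypes$values), "animals,",
      ncol(x$genotypes$values), "SNP,",
      length(unique(x$phenotypes$breed)), "breed(s)\n")
  nd <- lengths(x$dropped)
  if (any(nd > 0)) {
    cat("Dropped at join:", nd[["genotype_only"]], "genotype-only,",
        nd[["phenotype_only"]], "phenotype-only animals\n")
  }
  invisible(x)
}

#' Restrict a study to one breed
#'
#' @param study a `bca_study`.
#' @param breed breed label present in the phenotype table.
#' @return a `bca_study` for that breed only.
#' @export
subset_study <- function(study, breed) {
  stopifnot(inherits(study, "bca_study"))
  keep <- study$phenotypes$breed == breed
  if (!any(keep)) bca_stop("no animals of breed '", breed, "' in study")
  ids <- study$phenotypes$animal_id[keep]
  structure(list(genotypes = subset_genotypes(study$genotypes, animals = ids),
                 phenotypes = study$phenotypes[keep, , drop = FALSE],
                 panel = study$panel, dropped = study$dropped),
            class = "bca_study")
}
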