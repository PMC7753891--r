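#' Read a SNP panel definition table
#'
#' Parses the tab-separated panel table describing the custom genotyping
#' array: one row per assay with its genomic coordinate (1-based,
#' `chrom:g.<pos><ref>><alt>` HGVS-like notation), the panel SNP name
#' (`<gene>.<number>`), the target species, the predicted functional effect,
#' and an optional dbSNP identifier. The same physical variant may appear as
#' two distinct panel records when it was targeted in two species (shared
#' coordinates); records are keyed by `snp_id`, which must be unique.
#'
#' Coordinates are kept 1-based exactly as printed; no half-open conversion
#' is performed anywhere in the package.
#'
#' @param path path to a panel TSV with columns
#'   `coordinate`, `snp_id`, `species`, `effect`, `dbsnp` (the last may be
#'   empty). The packaged example is at
#'   `system.file("extdata", "panel_snps.tsv", package = "bcassoc")`.
#' @return a `data.frame` of class `bca_panel` with columns `snp_id`, `gene`,
#'   `species`, `chrom`, `pos`, `ref`, `alt`, `effect_class` (normalized to
#'   one of `synonymous`, `nonsynonymous`, `stop`, `upstream`, `missense`),
#'   `effect` (verbatim), `dbsnp`, `coordinate`.
#' @details The effect label `Missense` is treated as a synonym of
#'   `Nonsynonymous` for the purpose of selecting protein-changing SNP
#'   (some panel sources use one term, some the other); the combined label
#'   `Nonsynonymous/stop` is classed as `stop`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) bca_stop("panel file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           fill = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  need <- c("coordinate", "snp_id", "species", "effect")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    bca_stop("panel header is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"dbsnp" %in% names(raw)) raw$dbsnp <- NA_character_
  if (nrow(raw) == 0) {
    out <- data.frame(snp_id = character(), gene = character(),
                      species = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      effect_class = character(), effect = character(),
                      dbsnp = character(), coordinate = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("bca_panel", "data.frame")
    return(out)
  }

  dup <- raw$snp_id[duplicated(raw$snp_id)]
  if (length(dup)) {
    bca_stop("duplicate snp_id in panel: ", paste(unique(dup), collapse = ", "))
  }

  co <- parse_coordinate(raw$coordinate)
  species <- normalize_species(raw$species)
  bad_sp <- !species %in% c("B. taurus", "B. indicus", "B. bubalis")
  if (any(bad_sp)) {
    bca_stop("unrecognized species label(s): ",
             paste(unique(raw$species[bad_sp]), collapse = ", "))
  }
  gene <- sub("\\..*$", "", raw$snp_id)
  bad_id <- !grepl("^[A-Za-z0-9]+\\.[0-9]+$", raw$snp_id)
  if (any(bad_id)) {
    bca_stop("snp_id not of the form <gene>.<number> at data line(s) ",
             paste(which(bad_id), collapse = ", "))
  }

  out <- data.frame(snp_id = raw$snp_id, gene = gene, species = species,
                    chrom = co$chrom, pos = co$pos, ref = co$ref, alt = co$alt,
                    effect_class = normalize_effect(raw$effect),
                    effect = raw$effect, dbsnp = raw$dbsnp,
                    coordinate = raw$coordinate, stringsAsFactors = FALSE)
  class(out) <- c("bca_panel", "data.frame")
  out
}

# Parse "chrom:g.<pos><ref>><alt>" strings; vectorized, errors name the line.
parse_coordinate <- function(x) {
  pat <- "^([^:]+):g\\.([0-9]+)([ACGT])>([ACGT])$"
  ok <- grepl(pat, x)
  if (any(!ok)) {
    bca_stop("malformed coordinate at data line(s) ",
             paste(which(!ok), collapse = ", "), ": ",
             paste(x[!ok][seq_len(min(3, sum(!ok)))], collapse = "; "))
  }
  pos <- as.integer(sub(pat, "\\2", x))
  if (any(pos <= 0)) bca_stop("coordinate position must be > 0")
  list(chrom = sub(pat, "\\1", x), pos = pos,
       ref = sub(pat, "\\3", x), alt = sub(pat, "\\4", x))
}

normalize_species <- function(x) {
  x <- trimws(x)
  x[x %in% c("Bubalus bubalis", "B.bubalis")] <- "B. bubalis"
  x[x %in% c("Bos taurus", "B.taurus")] <- "B. taurus"
  x[x %in% c("Bos indicus", "B.indicus")] <- "B. indicus"
  x
}

normalize_effect <- function(x) {
  key <- tolower(trimws(x))
  map <- c("synonymous" = "synonymous",
           "nonsynonymous" = "nonsynonymous",
           "nonsynonymous/stop" = "stop",
           "stop" = "stop",
           "missense" = "missense",
           "upstream variant" = "upstream",
           "upstream gene variant" = "upstream")
  out <- unname(map[key])
  if (any(is.na(out))) {
    bca_stop("unrecognized effect label(s): ",
             paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Path to the packaged panel definition table
#'
#' @return path to the panel TSV shipped with the package (67 assays across
#'   the three carotenoid genes BCMO1, BCO2 and SCARB1 in B. taurus,
#'   B. indicus and B. bubalis).
#' @export
bca_panel_file <- function() {
  system.file("extdata", "panel_snps.tsv", package = "bcassoc", mustWork = TRUE)
}

#' Which panel SNP change the protein?
#'
#' @param panel a `bca_panel`.
#' @return logical vector: `TRUE` for nonsynonymous, stop and missense SNP.
#' @export
is_coding_change <- function(panel) {
  stopifnot(inherits(panel, "bca_panel"))
  panel$effect_class %in% c("nonsynonymous", "stop", "missense")
}

#' @export
print.bca_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x), "assays,",
      length(unique(x$gene)), "genes,",
      length(unique(x$species)), "species\n")
  if (nrow(x)) print(table(gene = x$gene, species = x$species))
  invisible(x)
}
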