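#' Construct a genotype matrix
#'
#' Genotypes are additive allele counts: for each SNP one allele is designated
#' the *counted* allele and each animal's value is the number of copies it
#' carries (0, 1 or 2), with `NA` for failed assays. Which homozygote is coded
#' 0 is arbitrary and only flips the sign of downstream substitution effects;
#' by convention the counted allele defaults to the panel's alternate allele
#' when allele labels are attached from a panel.
#'
#' @param values integer matrix, animals in rows (rownames = animal ids),
#'   SNP in columns (colnames = snp ids); entries in `{0, 1, 2, NA}`.
#' @param counted_allele,other_allele optional character vectors (named by
#'   snp id or in column order) giving the two allele labels per SNP;
#'   defaults are the placeholders `"A"` and `"B"`.
#' @return an object of class `bca_genotypes`.
#' @export
genotype_matrix <- function(values, counted_allele = NULL, other_allele = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("animal", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("snp", seq_len(ncol(values)))
  bad <- !(is.na(values) | values %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    bca_stop("genotype value outside {0,1,2,NA} at animal '",
             rownames(values)[idx[1]], "', SNP '", colnames(values)[idx[2]],
             "': ", values[idx[1], idx[2]])
  }
  storage.mode(values) <- "integer"
  p <- ncol(values)
  counted <- expand_alleles(counted_allele, colnames(values), "A")
  other <- expand_alleles(other_allele, colnames(values), "B")
  if (any(counted == other)) {
    bca_stop("counted_allele equals other_allele for SNP: ",
             paste(colnames(values)[counted == other], collapse = ", "))
  }
  structure(list(values = values, counted_allele = counted,
                 other_allele = other),
            class = "bca_genotypes")
}

expand_alleles <- function(x, snp_ids, default) {
  p <- length(snp_ids)
  if (is.null(x)) return(stats::setNames(rep(default, p), snp_ids))
  if (!is.null(names(x))) {
    out <- stats::setNames(rep(default, p), snp_ids)
    known <- intersect(names(x), snp_ids)
    out[known] <- x[known]
    return(out)
  }
  if (length(x) == 1) x <- rep(x, p)
  if (length(x) != p) bca_stop("allele vector length does not match SNP count")
  stats::setNames(x, snp_ids)
}

#' @export
dim.bca_genotypes <- function(x) dim(x$values)

#' @export
print.bca_genotypes <- function(x, ...) {
  v <- x$values
  cat("Genotype matrix:", nrow(v), "animals x", ncol(v), "SNP; ",
      sum(is.na(v)), "missing (",
      sprintf("%.1f%%", 100 * mean(is.na(v))), ")\n", sep = " ")
  invisible(x)
}

#' Read a genotype CSV
#'
#' Plain CSV dialect: first column `animal_id`, one further column per SNP,
#' cells `0`/`1`/`2` or `NA`/empty for missing.
#'
#' @param path path to the CSV.
#' @param panel optional `bca_panel`; when supplied, allele labels for SNP
#'   present in the panel are attached (counted = alternate, other =
#'   reference allele of the printed coordinate).
#' @return a `bca_genotypes`.
#' @export
read_genotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) bca_stop("genotype file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2 || names(raw)[1] != "animal_id") {
    bca_stop("genotype CSV must have 'animal_id' as its first column")
  }
  ids <- raw$animal_id
  m <- as.matrix(raw[, -1, drop = FALSE])
  m[m %in% c("", "NA")] <- NA_character_
  bad <- !is.na(m) & !m %in% c("0", "1", "2")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    bca_stop("invalid genotype '", m[idx[1], idx[2]], "' for animal '",
             ids[idx[1]], "' at SNP '", colnames(m)[idx[2]], "'")
  }
  vals <- matrix(as.integer(m), nrow = nrow(m),
                 dimnames = list(ids, colnames(m)))
  g <- genotype_matrix(vals)
  if (!is.null(panel)) g <- attach_alleles(g, panel)
  g
}

#' Write a genotype matrix as CSV
#'
#' Round-trips exactly with [read_genotypes()], including missingness.
#'
#' @param genotypes a `bca_genotypes`.
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "bca_genotypes"))
  df <- data.frame(animal_id = rownames(genotypes$values),
                   genotypes$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Attach allele labels from a panel
#'
#' The counted allele is set to the alternate allele of the panel coordinate
#' and the other allele to the reference; SNP absent from the panel keep
#' their current labels.
#'
#' @param genotypes a `bca_genotypes`.
#' @param panel a `bca_panel`.
#' @return the relabelled `bca_genotypes`.
#' @export
attach_alleles <- function(genotypes, panel) {
  stopifnot(inherits(genotypes, "bca_genotypes"), inherits(panel, "bca_panel"))
  snp <- colnames(genotypes$values)
  hit <- match(snp, panel$snp_id)
  has <- !is.na(hit)
  genotypes$counted_allele[has] <- panel$alt[hit[has]]
  genotypes$other_allele[has] <- panel$ref[hit[has]]
  genotypes
}

# Subset helper used throughout: keep given animals (character or logical)
# and/or SNP columns.
subset_genotypes <- function(genotypes, animals = NULL, snps = NULL) {
  v <- genotypes$values
  if (!is.null(animals)) v <- v[animals, , drop = FALSE]
  if (!is.null(snps)) v <- v[, snps, drop = FALSE]
  genotype_matrix(v,
                  counted_allele = genotypes$counted_allele[colnames(v)],
                  other_allele = genotypes$other_allele[colnames(v)])
}
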