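# Genotype input/output.
#
# Genotypes are held as an individuals x SNPs matrix of effect-allele
# dosages (0/1/2, NA for missing) in panel order, together with sample
# identifiers and a per-sample population label.  Dosage counts the
# effect allele as declared in the panel -- orientation to "risk" alleles
# happens at scoring time, never at read time.

#' Construct a genotype matrix
#'
#' @param dosage Numeric matrix, samples x SNPs, values in \{0, 1, 2\} or
#'   `NA` for missing calls.
#' @param sample_ids Character vector of sample identifiers (row order).
#' @param snp_ids Character vector of SNP identifiers (column order,
#'   panel order).
#' @param population Character vector of per-sample population labels
#'   (recycled if length 1).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, sample_ids, snp_ids,
                            population = "unlabelled") {
  dosage <- as.matrix(dosage)
  if (length(population) == 1L) population <- rep(population, length(sample_ids))
  stopifnot(
    nrow(dosage) == length(sample_ids),
    ncol(dosage) == length(snp_ids),
    length(population) == length(sample_ids)
  )
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) stop("dosages must lie in [0, 2] or be NA", call. = FALSE)
  dimnames(dosage) <- list(sample_ids, snp_ids)
  structure(
    list(dosage = dosage, sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids), population = as.character(population)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs;",
      sum(is.na(x$dosage)), "missing calls;",
      "populations:", paste(unique(x$population), collapse = ", "), "\n")
  invisible(x)
}

#' Read panel genotypes from a VCF file
#'
#' Records are matched to the panel by rsID in the `ID` column (the
#' panel predates any fixed genome build, so positions are not used).
#' The dosage is the count of panel effect alleles in the `GT` call,
#' regardless of whether the effect allele is REF or ALT; phase is
#' ignored and `./.` becomes `NA`.  Panel SNPs absent from the file
#' yield an all-missing column with a warning.  A matched record whose
#' REF/ALT do not contain both panel alleles, or that is multi-allelic,
#' is an error.
#'
#' @param path Path to a VCF (v4.x) file with a GT FORMAT field.
#' @param panel A `panel_spec`.
#' @param population Per-sample population labels (single value recycled).
#' @return A `genotype_matrix` in panel SNP order.
#' @export
read_vcf <- function(path, panel, population = "unlabelled") {
  stopifnot(inherits(panel, "panel_spec"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  samples <- colnames(gt)
  n <- length(samples)
  dosage <- matrix(NA_real_, nrow = n, ncol = nrow(panel),
                   dimnames = list(samples, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    snp <- panel$snp_id[j]
    k <- which(ids == snp)
    if (!length(k)) {
      warning("panel SNP ", snp, " absent from VCF; column set to missing",
              call. = FALSE)
      next
    }
    if (length(k) > 1L) stop("duplicate VCF record for ", snp, call. = FALSE)
    ref <- fix[k, "REF"]; alt <- fix[k, "ALT"]
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multi-allelic VCF record for ", snp, " not supported", call. = FALSE)
    }
    pair <- c(panel$effect_allele[j], panel$other_allele[j])
    if (!setequal(c(ref, alt), pair)) {
      stop("allele mismatch for ", snp, ": VCF has ", ref, "/", alt,
           ", panel expects ", pair[1], "/", pair[2], call. = FALSE)
    }
    effect_code <- if (alt == panel$effect_allele[j]) "1" else "0"
    calls <- gt[k, ]
    dosage[, j] <- vapply(calls, function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == effect_code)
    }, numeric(1), USE.NAMES = FALSE)
  }
  genotype_matrix(dosage, samples, panel$snp_id, population)
}

#' Read panel genotypes from a dosage TSV
#'
#' Expects a matrix of samples (rows) by SNPs (columns) of effect-allele
#' dosages, with a leading `sample_id` column, an optional `population`
#' column, and values in \{0, 1, 2, NA\}.  Columns are reconciled to
#' panel order.
#'
#' @inheritParams read_vcf
#' @param path Path to the TSV.
#' @return A `genotype_matrix` in panel SNP order.
#' @export
read_dosage_tsv <- function(path, panel, population = NULL) {
  stopifnot(inherits(panel, "panel_spec"))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("dosage TSV must start with a 'sample_id' column", call. = FALSE)
  }
  pop_col <- NULL
  if ("population" %in% names(df)) {
    pop_col <- df$population
    df$population <- NULL
  }
  if (is.null(population)) population <- if (is.null(pop_col)) "unlabelled" else pop_col
  samples <- as.character(df$sample_id)
  snp_cols <- setdiff(names(df), "sample_id")
  missing_snps <- setdiff(panel$snp_id, snp_cols)
  if (length(missing_snps)) {
    stop("dosage TSV missing panel SNP column(s): ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = nrow(panel),
                   dimnames = list(samples, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    col <- df[[panel$snp_id[j]]]
    bad <- !is.na(col) & !(col %in% c(0, 1, 2))
    if (any(bad)) {
      i <- which(bad)[1]
      stop("invalid dosage '", col[i], "' at row ", i, ", column ",
           panel$snp_id[j], " (must be 0, 1, 2 or NA)", call. = FALSE)
    }
    dosage[, j] <- as.numeric(col)
  }
  genotype_matrix(dosage, samples, panel$snp_id, population)
}

#' Write a dosage TSV
#'
#' Inverse of [read_dosage_tsv()]: samples are rows, SNPs columns,
#' missing calls written as `NA`.
#'
#' @param G A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(sample_id = G$sample_ids, population = G$population,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(G$dosage, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with the panel's other allele as REF
#' and the effect allele as ALT, unphased GT calls only, and record IDs
#' set to the panel rsIDs.  Positions are synthetic (panel order): panel
#' records are matched by rsID, not coordinates.
#'
#' @param G A `genotype_matrix`.
#' @param panel A `panel_spec` (defines REF/ALT per SNP).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, panel, path) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(panel, "panel_spec"))
  idx <- match(G$snp_ids, panel$snp_id)
  if (anyNA(idx)) stop("genotype matrix contains SNPs not in the panel", call. = FALSE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grspanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t")
  )
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  rows <- vapply(seq_along(G$snp_ids), function(j) {
    p <- idx[j]
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", code[as.character(d)])
    paste(c(panel$chromosome[p], j, panel$snp_id[p], panel$other_allele[p],
            panel$effect_allele[p], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a score table to TSV
#'
#' One row per sample with columns `sample_id`, `population`, `grs`,
#' `wgrs`, `n_imputed`.  Values survive a write/read round trip to full
#' printed precision.
#'
#' @param scores A `score_table` (see [score_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  out <- as.data.frame(scores)[, c("sample_id", "population", "grs", "wgrs", "n_imputed")]
  old <- options(scipen = 15, digits = 15)
  on.exit(options(old))
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores_tsv()]
#'
#' @param path Path to the TSV.
#' @return A `score_table` data frame.
#' @export
read_scores_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character", population = "character",
                                  grs = "numeric", wgrs = "numeric",
                                  n_imputed = "integer"))
  structure(df, class = c("score_table", "data.frame"))
}
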