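# Panel and frequency-table data model.
#
# A "panel" is a fixed, ordered set of biallelic SNPs, each annotated with
# its effect allele, the direction of the published association
# (susceptibility or protective), the genetic model under which the effect
# was estimated (per-allele, dominant carrier, recessive homozygote) and
# the published effect size (odds ratio or blood-pressure beta in mmHg).
# The scoring weight of a SNP is ln(OR) for odds ratios and the beta
# itself for mmHg effects; a SNP may carry no usable effect size, in which
# case it contributes to the unweighted score only.

PANEL_COLUMNS <- c(
  "snp_id", "locus", "chromosome", "effect_allele", "other_allele",
  "direction", "genetic_model", "effect_kind", "effect_value"
)

FREQ_COLUMNS <- c("population", "snp_id", "effect_allele_freq_pct", "n_individuals")

VALID_ALLELES <- c("A", "C", "G", "T")
VALID_DIRECTIONS <- c("susceptibility", "protective")
VALID_MODELS <- c("per_allele", "dominant", "recessive")
VALID_EFFECT_KINDS <- c("odds_ratio", "bp_beta", "none")

#' Derive a scoring weight from a published effect size
#'
#' Odds ratios enter the weighted score on the natural-log scale, so that
#' protective odds ratios (< 1) yield negative weights; blood-pressure
#' betas (mmHg per effect allele) are used as published.
#'
#' @param effect_kind `"odds_ratio"` or `"bp_beta"`.  `"none"` is an
#'   error: variants without an effect size are excluded from the
#'   weighted score by the caller.
#' @param effect_value Effect size on its natural scale; an odds ratio
#'   must be strictly positive.
#' @return Numeric weight.
#' @export
#' @examples
#' derive_weight("odds_ratio", 7.3)   # ln(7.3) = 1.9879
#' derive_weight("bp_beta", 0.15)
derive_weight <- function(effect_kind, effect_value) {
  effect_kind <- match.arg(effect_kind, c("odds_ratio", "bp_beta", "none"))
  if (effect_kind == "none") {
    stop("variant without an effect size has no weight; exclude it from the weighted score",
         call. = FALSE)
  }
  if (!is.numeric(effect_value) || length(effect_value) != 1L || is.na(effect_value)) {
    stop("effect_value must be a single non-missing number", call. = FALSE)
  }
  if (effect_kind == "odds_ratio") {
    if (effect_value <= 0) stop("odds ratio must be > 0", call. = FALSE)
    return(log(effect_value))
  }
  effect_value
}

#' Load a SNP panel from a TSV file
#'
#' Reads a tab-separated panel specification (one row per SNP, columns
#' `snp_id`, `locus`, `chromosome`, `effect_allele`, `other_allele`,
#' `direction`, `genetic_model`, `effect_kind`, `effect_value`), validates
#' it, and attaches the derived scoring weight ([derive_weight()]).  Row
#' order is preserved and defines the panel order used throughout.
#'
#' @param path Path to the panel TSV.
#' @return A `panel_spec`: a data frame with the columns above plus
#'   `weight` (`NA` where `effect_kind` is `"none"`), and attribute `M`,
#'   the number of variants.
#' @export
#' @examples
#' panel <- load_panel(grspanel_example("panel.tsv"))
#' nrow(panel)                 # 20
#' sum(!is.na(panel$weight))   # 19
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), PANEL_COLUMNS)) {
    stop("panel file header must be exactly: ",
         paste(PANEL_COLUMNS, collapse = ", "), call. = FALSE)
  }
  df$effect_value <- suppressWarnings(as.numeric(df$effect_value))
  validate_panel_fields(df)
  df$weight <- NA_real_
  has_w <- df$effect_kind != "none"
  df$weight[has_w] <- mapply(derive_weight, df$effect_kind[has_w], df$effect_value[has_w])
  new_panel_spec(df)
}

new_panel_spec <- function(df) {
  rownames(df) <- NULL
  structure(df, M = nrow(df), class = c("panel_spec", "data.frame"))
}

validate_panel_fields <- function(df) {
  if (anyDuplicated(df$snp_id)) {
    dup <- unique(df$snp_id[duplicated(df$snp_id)])
    stop("duplicate rsID in panel: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  check_tokens <- function(x, valid, what) {
    bad <- setdiff(unique(x), valid)
    if (length(bad)) {
      stop("unknown ", what, " token: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_tokens(df$effect_allele, VALID_ALLELES, "effect_allele")
  check_tokens(df$other_allele, VALID_ALLELES, "other_allele")
  check_tokens(df$direction, VALID_DIRECTIONS, "direction")
  check_tokens(df$genetic_model, VALID_MODELS, "genetic_model")
  check_tokens(df$effect_kind, VALID_EFFECT_KINDS, "effect_kind")
  same <- df$effect_allele == df$other_allele
  if (any(same)) {
    stop("effect and other allele identical for: ",
         paste(df$snp_id[same], collapse = ", "), call. = FALSE)
  }
  no_val <- df$effect_kind != "none" & is.na(df$effect_value)
  if (any(no_val)) {
    stop("missing effect_value for weighted variant: ",
         paste(df$snp_id[no_val], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Write a panel to TSV
#'
#' Inverse of [load_panel()]; the derived `weight` column is not written
#' (it is re-derived on load).
#'
#' @param panel A `panel_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_spec"))
  out <- as.data.frame(panel)[, PANEL_COLUMNS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a per-population effect-allele frequency table from TSV
#'
#' Reads a tab-separated table with columns `population`, `snp_id`,
#' `effect_allele_freq_pct` (a percentage in (0, 100)) and
#' `n_individuals`, and stores frequencies as proportions.  When a panel
#' is supplied, every panel SNP must be present for every declared
#' population.
#'
#' @param path Path to the frequency TSV.
#' @param panel Optional `panel_spec` used to check completeness.
#' @return A `freq_table`: data frame with columns `population`,
#'   `snp_id`, `effect_allele_freq` (proportion) and `n_individuals`.
#' @export
#' @examples
#' panel <- load_panel(grspanel_example("panel.tsv"))
#' freqs <- load_frequencies(grspanel_example("frequencies.tsv"), panel)
#' subset(freqs, snp_id == "rs5186")
load_frequencies <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("frequency file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df), FREQ_COLUMNS)) {
    stop("frequency file header must be exactly: ",
         paste(FREQ_COLUMNS, collapse = ", "), call. = FALSE)
  }
  pct <- as.numeric(df$effect_allele_freq_pct)
  if (any(is.na(pct)) || any(pct <= 0) || any(pct >= 100)) {
    stop("effect_allele_freq_pct must be a percentage strictly inside (0, 100)",
         call. = FALSE)
  }
  out <- data.frame(
    population = as.character(df$population),
    snp_id = as.character(df$snp_id),
    effect_allele_freq = pct / 100,
    n_individuals = as.integer(df$n_individuals),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out[, c("population", "snp_id")])) {
    stop("duplicate (population, snp_id) row in frequency table", call. = FALSE)
  }
  if (!is.null(panel)) {
    for (pop in unique(out$population)) {
      missing <- setdiff(panel$snp_id, out$snp_id[out$population == pop])
      if (length(missing)) {
        stop("frequency table incomplete for population ", pop, ": missing ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(out, class = c("freq_table", "data.frame"))
}

#' Write a frequency table to TSV
#'
#' Inverse of [load_frequencies()]; proportions are written back as
#' percentages.
#'
#' @param freqs A `freq_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(freqs, path) {
  stopifnot(inherits(freqs, "freq_table"))
  out <- data.frame(
    population = freqs$population,
    snp_id = freqs$snp_id,
    effect_allele_freq_pct = freqs$effect_allele_freq * 100,
    n_individuals = freqs$n_individuals,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Frequencies for one population, in panel order.
freq_vector <- function(freqs, population, panel) {
  rows <- freqs[freqs$population == population, ]
  if (!nrow(rows)) {
    stop("no frequencies for population '", population, "'", call. = FALSE)
  }
  idx <- match(panel$snp_id, rows$snp_id)
  if (anyNA(idx)) {
    stop("frequency table missing panel SNPs for population '", population, "'",
         call. = FALSE)
  }
  setNames(rows$effect_allele_freq[idx], panel$snp_id)
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("SNP panel:", nrow(x), "variants,",
      sum(!is.na(x$weight)), "with scoring weights\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
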