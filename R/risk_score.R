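# Unweighted and weighted genetic risk scores.
#
# The unweighted score (GRS) counts risk alleles: effect-allele dosages
# are used as-is for susceptibility alleles and flipped (2 - dosage) for
# protective alleles, then summed over the panel.  The weighted score
# (wGRS) multiplies each SNP's signed weight (ln OR or mmHg beta) by its
# effect-allele exposure -- the dosage for per-allele SNPs, a carrier
# indicator for dominant SNPs, a homozygote indicator for recessive
# SNPs -- with no allele flipping: protective SNPs carry negative
# weights and so contribute negatively.  Missing dosages are imputed by
# their expectation 2p from the population effect-allele frequency
# before scoring.

#' Orient an effect-allele dosage to the risk scale
#'
#' Susceptibility alleles keep their dosage; protective alleles are
#' recoded so that effect-allele homozygotes score 0 and other-allele
#' homozygotes score 2.
#'
#' @param dosage Dosage values (no missing entries: impute first).
#' @param direction `"susceptibility"` or `"protective"` (recycled).
#' @return Risk-oriented counts on the same scale.
#' @export
#' @examples
#' orient_dosage(2, "protective")  # 0
orient_dosage <- function(dosage, direction) {
  if (anyNA(dosage)) {
    stop("missing dosage: impute before orienting", call. = FALSE)
  }
  direction <- match.arg(direction, c("susceptibility", "protective"),
                         several.ok = TRUE)
  ifelse(rep_len(direction, length(dosage)) == "protective", 2 - dosage, dosage)
}

#' Impute missing dosages by their population expectation
#'
#' Each missing entry of a dosage column is replaced by `2 * p`, the
#' expected effect-allele count at population frequency `p`; non-missing
#' entries are untouched.  Fractional dosages are deliberate: they
#' contribute fractionally to the scores.
#'
#' @param dosage Dosage vector with possible `NA`s.
#' @param p Effect-allele frequency in \[0, 1\] (`NA` is an error: an
#'   all-missing SNP has no usable frequency).
#' @return The filled vector.
#' @export
#' @examples
#' impute_missing(c(0, NA, 2), 0.2622)
impute_missing <- function(dosage, p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("imputation frequency must be a single value in [0, 1]", call. = FALSE)
  }
  dosage[is.na(dosage)] <- 2 * p
  dosage
}

#' Unweighted genetic risk score for one sample
#'
#' Arithmetic sum of risk-oriented allele counts over the full panel;
#' fractional imputed dosages contribute fractionally.
#'
#' @param oriented Risk-oriented counts, one per panel SNP, no missing
#'   values.
#' @param M Expected panel size (length check).
#' @return The score, in \[0, 2M\].
#' @export
grs <- function(oriented, M = length(oriented)) {
  if (length(oriented) != M) {
    stop("expected ", M, " oriented counts, got ", length(oriented), call. = FALSE)
  }
  if (anyNA(oriented)) stop("missing oriented count", call. = FALSE)
  sum(oriented)
}

# Effect-allele exposure X for the weighted score, honouring the genetic
# model.  Fractional (imputed) dosages map to the indicator expectation
# under HWE at frequency d/2 for dominant/recessive SNPs, preserving the
# score expectation instead of rounding.
weight_exposure <- function(dosage, genetic_model) {
  whole <- dosage == floor(dosage)
  switch(genetic_model,
    per_allele = dosage,
    dominant = ifelse(whole, as.numeric(dosage >= 1),
                      1 - (1 - dosage / 2)^2),
    recessive = ifelse(whole, as.numeric(dosage == 2),
                       (dosage / 2)^2),
    stop("unknown genetic model: ", genetic_model, call. = FALSE)
  )
}

#' Weighted genetic risk score for one sample
#'
#' Sum over the weighted panel variants of weight times effect-allele
#' exposure: the dosage for per-allele SNPs, a carrier indicator for
#' dominant SNPs and a homozygote indicator for recessive SNPs.
#' Weights are signed (protective variants contribute negatively); a
#' variant without a weight is skipped only if `effect_kind` is
#' `"none"` -- encountering an `NA` weight on any other variant is an
#' error.
#'
#' @param dosages Effect-allele dosages in panel order, no missing
#'   values (impute first); fractional imputed values allowed.
#' @param panel A `panel_spec`.
#' @return The weighted score.
#' @export
wgrs <- function(dosages, panel) {
  stopifnot(inherits(panel, "panel_spec"))
  if (length(dosages) != nrow(panel)) {
    stop("expected ", nrow(panel), " dosages, got ", length(dosages), call. = FALSE)
  }
  if (anyNA(dosages)) stop("missing dosage: impute before scoring", call. = FALSE)
  use <- panel$effect_kind != "none"
  if (anyNA(panel$weight[use])) {
    stop("weighted variant without a weight: ",
         paste(panel$snp_id[use & is.na(panel$weight)], collapse = ", "),
         call. = FALSE)
  }
  x <- vapply(which(use), function(j) {
    weight_exposure(dosages[j], panel$genetic_model[j])
  }, numeric(1))
  sum(panel$weight[use] * x)
}

#' Score a cohort: per-sample GRS and wGRS
#'
#' Imputes missing dosages with the effect-allele frequency of each
#' sample's own population -- observed from the genotypes by default, or
#' taken from a supplied frequency table -- then computes the unweighted
#' and weighted scores for every sample.
#'
#' @param G A `genotype_matrix`.
#' @param panel A `panel_spec` in the same SNP order.
#' @param freqs Optional `freq_table` supplying imputation frequencies;
#'   by default frequencies observed in the data per population are
#'   used.
#' @return A `score_table`: data frame with `sample_id`, `population`,
#'   `grs`, `wgrs`, `n_imputed`.
#' @export
score_cohort <- function(G, panel, freqs = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(panel, "panel_spec"))
  if (!identical(G$snp_ids, panel$snp_id)) {
    idx <- match(panel$snp_id, G$snp_ids)
    if (anyNA(idx)) stop("genotype matrix does not cover the panel", call. = FALSE)
    G$dosage <- G$dosage[, idx, drop = FALSE]
    G$snp_ids <- panel$snp_id
  }
  pops <- unique(G$population)
  imp_freq <- lapply(pops, function(pop) {
    if (is.null(freqs)) {
      af <- allele_freq(G, pop)
      if (any(!af$defined)) {
        stop("all-missing SNP(s) in population ", pop,
             ": no imputation frequency (",
             paste(af$snp_id[!af$defined], collapse = ", "), ")", call. = FALSE)
      }
      setNames(af$freq, af$snp_id)
    } else {
      freq_vector(freqs, pop, panel)
    }
  })
  names(imp_freq) <- pops
  n <- length(G$sample_ids)
  out <- data.frame(
    sample_id = G$sample_ids, population = G$population,
    grs = NA_real_, wgrs = NA_real_, n_imputed = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    d <- G$dosage[i, ]
    miss <- is.na(d)
    p <- imp_freq[[G$population[i]]]
    if (any(miss)) d[miss] <- 2 * p[miss]
    out$grs[i] <- grs(orient_dosage(d, panel$direction), nrow(panel))
    out$wgrs[i] <- wgrs(d, panel)
    out$n_imputed[i] <- sum(miss)
  }
  structure(out, class = c("score_table", "data.frame"))
}

#' Quintile partition of pooled scores
#'
#' Cut points are the 20/40/60/80th percentiles of the pooled score
#' distribution; boundary values are assigned to the lower bin, so
#' integer cut points read as "score <= c" for the bottom bin and
#' "score >= c" for the top bin.  Population shares per quintile are
#' compared with a 5x2 chi-square.
#'
#' @param scores Pooled numeric scores (n >= 5).
#' @param population Population label per score.
#' @return List with `quintile` (1-5 per sample), `cutpoints`, `shares`
#'   (population x quintile proportions within population), `counts`,
#'   `chi2`, `p`.
#' @export
quintile_partition <- function(scores, population) {
  stopifnot(length(scores) == length(population))
  if (length(scores) < 5L) stop("need at least 5 pooled scores", call. = FALSE)
  cut_points <- quantile(scores, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  if (length(unique(cut_points)) < 4L || diff(range(scores)) == 0) {
    stop("degenerate quintile partition: ties at the cut points", call. = FALSE)
  }
  q <- findInterval(scores, cut_points, left.open = TRUE) + 1L
  counts <- table(population = population, quintile = factor(q, levels = 1:5))
  shares <- prop.table(counts, margin = 1)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(quintile = q, cutpoints = cut_points, shares = shares, counts = counts,
       chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

# Adjusted Fisher-Pearson standardised skewness and excess kurtosis with
# their large-sample standard errors.
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

se_skewness <- function(n) {
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

sample_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g2 <- mean((x - m)^4) / s2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

se_kurtosis <- function(n) {
  2 * se_skewness(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

#' Distribution summary of a score vector
#'
#' @param x Numeric vector (n >= 8 for the standard errors to be
#'   meaningful).
#' @return Data frame with `n`, `mean`, `sd`, `median`, `q25`, `q75`,
#'   `skewness`, `se_skewness`, `kurtosis` (excess), `se_kurtosis`.
#' @export
distribution_summary <- function(x) {
  n <- length(x)
  data.frame(
    n = n, mean = mean(x), sd = sd(x), median = median(x),
    q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75)),
    skewness = sample_skewness(x), se_skewness = se_skewness(n),
    kurtosis = sample_kurtosis(x), se_kurtosis = se_kurtosis(n)
  )
}

#' Summarise and compare two score distributions
#'
#' Per-population distribution summaries plus the two-sided two-sample
#' Mann-Whitney U test and Kolmogorov-Smirnov test on the scores.
#'
#' @param scores1,scores2 Numeric score vectors, each of length >= 8.
#' @param labels Length-2 character vector naming the two groups.
#' @return List with `summary` (two-row data frame), `mann_whitney_p`,
#'   `ks_p`, `ks_statistic`.
#' @export
summarize_and_compare <- function(scores1, scores2, labels = c("pop1", "pop2")) {
  if (length(scores1) < 8L || length(scores2) < 8L) {
    stop("need at least 8 observations per group", call. = FALSE)
  }
  smry <- rbind(distribution_summary(scores1), distribution_summary(scores2))
  smry <- cbind(data.frame(population = labels, stringsAsFactors = FALSE), smry)
  mw <- suppressWarnings(wilcox.test(scores1, scores2, exact = FALSE))
  ks <- suppressWarnings(ks.test(scores1, scores2))
  list(summary = smry,
       mann_whitney_p = unname(mw$p.value),
       ks_p = unname(ks$p.value),
       ks_statistic = unname(ks$statistic))
}
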