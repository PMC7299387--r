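# Two-population synthetic cohort generator.
#
# Genotypes are drawn per SNP independently (the shipped panel shows no
# pairwise LD worth modelling and most SNPs sit on different
# chromosomes) under Hardy-Weinberg genotype probabilities, optionally
# inflated for excess homozygosity by an inbreeding coefficient F:
# P(hom effect) = p^2 + Fpq, P(het) = 2pq(1 - F), P(hom other) =
# q^2 + Fpq.  Missingness is MCAR.  Phenotypes follow a linear model of
# blood pressure on the genetic score and covariates; antihypertensive
# treatment is assigned by a logistic function of latent pressure, and
# measured pressure is the latent value minus the standard 10/5 mmHg
# treatment effect, so that the +10/+5 adjustment recovers the latent
# scale in expectation.

#' Simulation configuration for a two-population study
#'
#' Defaults emulate the shipped study conditions: cohorts of 1167 (HG)
#' and 1176 (HR) individuals at the shipped per-population effect-allele
#' frequencies, HWE (F = 0), 2.2% missing genotype calls (a 97.8% call
#' rate), the published cohort age/sex/BMI distributions, and blood
#' pressure linked linearly to the unweighted score.
#'
#' @param populations Named list of per-population settings; each entry
#'   may set `n`, `freq` (named per-SNP effect-allele frequencies), `f`
#'   (inbreeding coefficient), `missing_rate`, `age_mean`, `age_sd`,
#'   `prop_male`, `bmi_mean`, `bmi_sd`.
#' @param phenotype List of phenotype-model settings: `score` (`"grs"`
#'   or `"wgrs"`), `sbp_intercept`, `sbp_slope` (mmHg per unit score),
#'   `dbp_intercept`, `dbp_slope`, `age_slope_sbp`, `age_slope_dbp`,
#'   `male_slope_sbp`, `male_slope_dbp`, `bmi_slope_sbp`,
#'   `bmi_slope_dbp`, `sbp_sd`, `dbp_sd` (residual SDs),
#'   `treat_midpoint`, `treat_scale` (logistic treatment assignment on
#'   latent SBP; `treat_scale = 0` disables treatment), and `enabled`.
#' @param seed Integer seed; every build from the same config is
#'   reproducible.
#' @param panel A `panel_spec`; defaults to the shipped panel.
#' @param freqs A `freq_table` supplying default per-population
#'   frequencies; defaults to the shipped table.
#' @return A `sim_config` list.
#' @export
sim_config <- function(populations = NULL, phenotype = NULL, seed = 20200617L,
                       panel = load_panel(grspanel_example("panel.tsv")),
                       freqs = load_frequencies(grspanel_example("frequencies.tsv"),
                                                panel)) {
  defaults <- list(
    HG = list(n = 1167L, f = 0, missing_rate = 0.022,
              age_mean = 47.31, age_sd = 17.02, prop_male = 0.46,
              bmi_mean = 26.10, bmi_sd = 4.88),
    HR = list(n = 1176L, f = 0, missing_rate = 0.022,
              age_mean = 40.98, age_sd = 12.84, prop_male = 0.41,
              bmi_mean = 26.55, bmi_sd = 6.54)
  )
  if (is.null(populations)) populations <- defaults
  labels <- names(populations)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("populations must be a named list", call. = FALSE)
  }
  populations <- lapply(seq_along(populations), function(i) {
    pop <- populations[[i]]
    label <- labels[i]
    base <- if (label %in% names(defaults)) defaults[[label]] else defaults$HG
    pop <- utils::modifyList(base, pop)
    if (is.null(pop$freq)) {
      pop$freq <- freq_vector(freqs, label, panel)
    }
    stopifnot(pop$n > 0, pop$f >= 0, pop$f < 1,
              pop$missing_rate >= 0, pop$missing_rate < 1,
              all(pop$freq > 0 & pop$freq < 1))
    pop
  })
  names(populations) <- labels
  phen_defaults <- list(
    enabled = TRUE, score = "grs",
    sbp_intercept = 65, sbp_slope = 0.401,
    dbp_intercept = 50, dbp_slope = 0.149,
    age_slope_sbp = 0.683, age_slope_dbp = 0.291,
    male_slope_sbp = 5.415, male_slope_dbp = 1.966,
    bmi_slope_sbp = 1.143, bmi_slope_dbp = 0.551,
    sbp_sd = 15, dbp_sd = 10,
    treat_midpoint = 150, treat_scale = 8
  )
  phenotype <- if (is.null(phenotype)) phen_defaults else
    utils::modifyList(phen_defaults, phenotype)
  structure(list(populations = populations, phenotype = phenotype,
                 seed = as.integer(seed), panel = panel),
            class = "sim_config")
}

#' Simulate panel genotypes for one population
#'
#' Independent per-SNP draws with genotype probabilities
#' `p^2 + Fpq` / `2pq(1 - F)` / `q^2 + Fpq`, then MCAR missingness.
#'
#' @param freq Named vector of effect-allele frequencies (panel order).
#' @param n Number of individuals.
#' @param f Inbreeding coefficient in \[0, 1\].
#' @param missing_rate MCAR missingness rate in \[0, 1).
#' @param population Population label for the result.
#' @param seed Optional seed set before drawing.
#' @return A `genotype_matrix`.
#' @export
sim_genotypes <- function(freq, n, f = 0, missing_rate = 0,
                          population = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(freq >= 0 & freq <= 1), f >= 0, f <= 1,
            missing_rate >= 0, missing_rate < 1)
  M <- length(freq)
  dosage <- vapply(freq, function(p) {
    q <- 1 - p
    probs <- c(q^2 + f * p * q, 2 * p * q * (1 - f), p^2 + f * p * q)
    sample(0:2, n, replace = TRUE, prob = probs)
  }, numeric(n))
  if (n == 1L) dosage <- matrix(dosage, nrow = 1)
  if (missing_rate > 0) {
    dosage[runif(n * M) < missing_rate] <- NA_real_
  }
  ids <- sprintf("%s_%05d", population, seq_len(n))
  snp_ids <- if (is.null(names(freq))) sprintf("snp%02d", seq_len(M)) else names(freq)
  genotype_matrix(dosage, ids, snp_ids, population)
}

#' Simulate phenotypes for scored genotypes
#'
#' Age and BMI are drawn from normals truncated below (at 18 years and
#' 15 kg/m^2), sex is Bernoulli.  Latent blood pressure is linear in
#' the genetic score, age, sex and BMI plus normal noise; treatment is
#' assigned with probability `plogis((latent SBP - midpoint)/scale)`;
#' measured pressure subtracts the 10/5 mmHg treatment effect from the
#' latent value.
#'
#' @param scores A `score_table` for the population being simulated.
#' @param pop_config One population entry of a [sim_config()].
#' @param phenotype The phenotype block of a [sim_config()].
#' @param seed Optional seed set before drawing.
#' @return A `cohort_table` with per-sample covariates, measured BP and
#'   treatment flag.
#' @export
sim_phenotypes <- function(scores, pop_config, phenotype, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(scores)
  rtnorm <- function(n, mean, sd, lower) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  age <- rtnorm(n, pop_config$age_mean, pop_config$age_sd, 18)
  bmi <- rtnorm(n, pop_config$bmi_mean, pop_config$bmi_sd, 15)
  male <- rbinom(n, 1, pop_config$prop_male)
  s <- scores[[phenotype$score]]
  ph <- phenotype
  sbp_latent <- ph$sbp_intercept + ph$sbp_slope * s + ph$age_slope_sbp * age +
    ph$male_slope_sbp * male + ph$bmi_slope_sbp * bmi + rnorm(n, 0, ph$sbp_sd)
  dbp_latent <- ph$dbp_intercept + ph$dbp_slope * s + ph$age_slope_dbp * age +
    ph$male_slope_dbp * male + ph$bmi_slope_dbp * bmi + rnorm(n, 0, ph$dbp_sd)
  treated <- if (ph$treat_scale > 0) {
    runif(n) < plogis((sbp_latent - ph$treat_midpoint) / ph$treat_scale)
  } else {
    rep(FALSE, n)
  }
  sbp <- sbp_latent - 10 * treated
  dbp <- dbp_latent - 5 * treated
  # keep the SBP > DBP ordering the phenotype model implies
  dbp <- pmin(dbp, sbp - 1)
  cohort_table(
    sample_id = scores$sample_id, population = scores$population,
    age = age, sex = ifelse(male == 1, "male", "female"), bmi = bmi,
    sbp = sbp, dbp = dbp, on_antihypertensive = treated
  )
}

#' Build a complete synthetic two-population study
#'
#' Simulates genotypes for every configured population, scores them
#' ([score_cohort()]), simulates phenotypes when enabled, and returns
#' the combined dataset.  Fully reproducible from the config's seed.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (combined `genotype_matrix`), `scores`
#'   (`score_table`), `cohort` (`cohort_table` or `NULL` when
#'   phenotypes are disabled) and `config`.
#' @export
build_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- names(config$populations)
  if (anyDuplicated(labels)) stop("duplicate population labels", call. = FALSE)
  set.seed(config$seed)
  panel <- config$panel
  parts <- lapply(labels, function(label) {
    pop <- config$populations[[label]]
    G <- sim_genotypes(pop$freq, pop$n, pop$f, pop$missing_rate, label)
    scores <- score_cohort(G, panel)
    cohort <- if (isTRUE(config$phenotype$enabled)) {
      sim_phenotypes(scores, pop, config$phenotype)
    }
    list(G = G, scores = scores, cohort = cohort)
  })
  dosage <- do.call(rbind, lapply(parts, function(p) p$G$dosage))
  sample_ids <- unlist(lapply(parts, function(p) p$G$sample_ids))
  population <- unlist(lapply(parts, function(p) p$G$population))
  genotypes <- genotype_matrix(dosage, sample_ids, panel$snp_id, population)
  scores <- do.call(rbind, lapply(parts, function(p) p$scores))
  class(scores) <- c("score_table", "data.frame")
  cohort <- if (isTRUE(config$phenotype$enabled)) {
    out <- do.call(rbind, lapply(parts, function(p) p$cohort))
    class(out) <- c("cohort_table", "data.frame")
    out
  }
  list(genotypes = genotypes, scores = scores, cohort = cohort, config = config)
}

#' Serialize a synthetic study to disk
#'
#' Writes the genotypes as VCF, the scores and phenotypes as TSV, and
#' the generating configuration as a JSON sidecar for provenance.
#'
#' @param study Result of [build_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    scores = file.path(dir, "scores.tsv"),
    config = file.path(dir, "sim_config.json")
  )
  write_vcf(study$genotypes, study$config$panel, paths["genotypes"])
  write_scores_tsv(study$scores, paths["scores"])
  cfg <- study$config
  cfg$panel <- NULL
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(study$cohort)) {
    paths["cohort"] <- file.path(dir, "phenotypes.tsv")
    write.table(as.data.frame(study$cohort), paths["cohort"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
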