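# Phenotype derivation and score-phenotype regression.
#
# Continuous outcomes are systolic/diastolic blood pressure, with a
# +10/+5 mmHg constant added for individuals under antihypertensive
# treatment to approximate their untreated pressure.  The binary
# outcome is hypertension under the IDF consensus definition
# (SBP >= 130 mmHg, DBP >= 85 mmHg, or medication).  Non-normal
# continuous variables may be normalised by the two-step rank-based
# inverse-normal transformation before fitting.

#' Build a cohort phenotype table
#'
#' @param sample_id Sample identifiers.
#' @param population Population label per sample.
#' @param age Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param bmi Body mass index, kg/m^2 (> 0).
#' @param sbp,dbp Measured systolic/diastolic blood pressure, mmHg.
#' @param on_antihypertensive Logical: current antihypertensive
#'   medication.
#' @return A `cohort_table` data frame.
#' @export
cohort_table <- function(sample_id, population, age = NA_real_, sex = NA_character_,
                         bmi = NA_real_, sbp = NA_real_, dbp = NA_real_,
                         on_antihypertensive = NA) {
  out <- data.frame(
    sample_id = as.character(sample_id), population = as.character(population),
    age = age, sex = sex, bmi = bmi, sbp = sbp, dbp = dbp,
    on_antihypertensive = as.logical(on_antihypertensive),
    stringsAsFactors = FALSE
  )
  bad_bp <- !is.na(out$sbp) & !is.na(out$dbp) & out$sbp <= out$dbp
  if (any(bad_bp)) stop("SBP must exceed DBP", call. = FALSE)
  if (any(!is.na(out$age) & out$age <= 0)) stop("age must be > 0", call. = FALSE)
  if (any(!is.na(out$bmi) & out$bmi <= 0)) stop("BMI must be > 0", call. = FALSE)
  if (any(!is.na(out$sex) & !out$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  structure(out, class = c("cohort_table", "data.frame"))
}

#' Two-step rank-based inverse-normal transformation
#'
#' Step 1 maps values to fractional ranks in (0, 1) as
#' `rank / (n + 1)`, with mid-ranks for ties; step 2 takes standard
#' normal quantiles of those probabilities and rescales them to the
#' input's mean and standard deviation.  The map is monotone, preserves
#' ranks exactly, and restores approximate normality of skewed inputs.
#'
#' @param x Numeric vector, n >= 3, non-constant.
#' @return Transformed vector with the input's mean and SD.
#' @export
templeton_transform <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  if (sd(x) == 0) stop("constant vector cannot be transformed", call. = FALSE)
  z <- qnorm(rank(x, ties.method = "average") / (n + 1))
  mean(x) + (z - mean(z)) * sd(x) / sd(z)
}

#' Adjust measured blood pressure for antihypertensive treatment
#'
#' Adds a constant 10 mmHg to systolic and 5 mmHg to diastolic values of
#' treated individuals, approximating untreated pressure for
#' continuous-outcome models; untreated values pass through unchanged.
#'
#' @param sbp,dbp Measured pressures, mmHg.
#' @param on_antihypertensive Logical treatment flag (recycled).
#' @return List with adjusted `sbp` and `dbp`.
#' @export
#' @examples
#' adjust_bp_for_treatment(130, 80, TRUE)  # 140 / 85
adjust_bp_for_treatment <- function(sbp, dbp, on_antihypertensive) {
  treated <- rep_len(as.logical(on_antihypertensive), length(sbp))
  list(sbp = sbp + 10 * treated, dbp = dbp + 5 * treated)
}

#' Hypertension status under the IDF consensus definition
#'
#' True iff systolic pressure >= 130 mmHg, diastolic pressure >= 85
#' mmHg, or the individual is on antihypertensive medication (inclusive
#' thresholds).
#'
#' @inheritParams adjust_bp_for_treatment
#' @return Logical vector.
#' @export
#' @examples
#' hypertension_status(129, 84, FALSE)  # FALSE
#' hypertension_status(110, 70, TRUE)   # TRUE
hypertension_status <- function(sbp, dbp, on_antihypertensive) {
  sbp >= 130 | dbp >= 85 | rep_len(as.logical(on_antihypertensive), length(sbp))
}

# Tidy one fitted model into the report layout.
tidy_model <- function(fit, model_label, outcome, logistic, data) {
  cf <- summary(fit)$coefficients
  est <- cf[, 1]
  se <- cf[, 2]
  if (logistic) {
    z <- qnorm(0.975)
    out <- data.frame(
      model = model_label, outcome = outcome, predictor = rownames(cf),
      estimate = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
      p = cf[, 4], std_beta = NA_real_, r_squared = NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    tq <- qt(0.975, df = fit$df.residual)
    sd_y <- sd(fit$model[[1]])
    std_beta <- vapply(rownames(cf), function(v) {
      if (v == "(Intercept)") return(NA_real_)
      x <- fit$model[[v]]
      if (is.null(x)) return(NA_real_)
      cf[v, 1] * sd(as.numeric(x)) / sd_y
    }, numeric(1))
    out <- data.frame(
      model = model_label, outcome = outcome, predictor = rownames(cf),
      estimate = est, ci_low = est - tq * se, ci_high = est + tq * se,
      p = cf[, 4], std_beta = std_beta,
      r_squared = summary(fit)$r.squared,
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Fit score-phenotype association models
#'
#' Model 1 regresses the outcome on the score alone; Model 2 adds sex
#' (male = 1), age and BMI.  Hypertension (derived with
#' [hypertension_status()] from measured pressure and medication) is fit
#' by logistic regression reporting odds ratios per unit score with
#' Wald 95% intervals; systolic/diastolic pressure are fit by linear
#' regression on treatment-adjusted values
#' ([adjust_bp_for_treatment()]), reporting coefficients, 95% CIs,
#' standardised betas and R^2.  With `transform = "templeton"` the
#' score and the continuous covariates and outcome are normalised by
#' [templeton_transform()] before fitting (binary variables are left
#' alone).  Complete cases only.
#'
#' @param cohort A `cohort_table`.
#' @param scores A `score_table` for the same samples.
#' @param score_kind `"grs"` or `"wgrs"`.
#' @param outcome `"hypertension"`, `"sbp"` or `"dbp"`.
#' @param transform `"none"` (raw scales) or `"templeton"`.
#' @return Data frame with both models' rows: `model`, `outcome`,
#'   `predictor`, `estimate` (OR for the logistic fit), `ci_low`,
#'   `ci_high`, `p`, `std_beta`, `r_squared`.
#' @export
fit_association_models <- function(cohort, scores,
                                   score_kind = c("grs", "wgrs"),
                                   outcome = c("hypertension", "sbp", "dbp"),
                                   transform = c("none", "templeton")) {
  score_kind <- match.arg(score_kind)
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  df <- merge(as.data.frame(cohort), as.data.frame(scores)[, c("sample_id", score_kind)],
              by = "sample_id")
  df$score <- df[[score_kind]]
  df$male <- as.numeric(df$sex == "male")
  logistic <- outcome == "hypertension"
  if (logistic) {
    df$y <- as.numeric(hypertension_status(df$sbp, df$dbp, df$on_antihypertensive))
  } else {
    adj <- adjust_bp_for_treatment(df$sbp, df$dbp, df$on_antihypertensive)
    df$y <- if (outcome == "sbp") adj$sbp else adj$dbp
  }
  df <- df[complete.cases(df[, c("y", "score", "male", "age", "bmi")]), ]
  if (!nrow(df)) stop("no complete cases", call. = FALSE)
  if (transform == "templeton") {
    df$score <- templeton_transform(df$score)
    df$age <- templeton_transform(df$age)
    df$bmi <- templeton_transform(df$bmi)
    if (!logistic) df$y <- templeton_transform(df$y)
  }
  fit_one <- function(formula, label) {
    if (logistic) {
      fit <- glm(formula, data = df, family = binomial())
      if (!fit$converged || any(fitted(fit) > 1 - 1e-10) || any(fitted(fit) < 1e-10)) {
        stop("logistic fit did not converge (possible separation) for ",
             label, call. = FALSE)
      }
    } else {
      fit <- lm(formula, data = df)
    }
    tidy_model(fit, label, outcome, logistic, df)
  }
  rbind(
    fit_one(y ~ score, "model1"),
    fit_one(y ~ score + male + age + bmi, "model2")
  )
}
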