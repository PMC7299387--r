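---
title: "Methods: panel risk scores and two-population comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel risk scores and two-population comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grspanel)
```

## Scope and model

`grspanel` compares the genetic load for essential hypertension of two
populations over a fixed 20-SNP panel.  The shipped panel records, for
each SNP, the published effect allele, whether that allele is a
susceptibility or a protective one, the genetic model under which its
effect was estimated (per-allele for 18 SNPs, dominant carrier for
rs4961, recessive homozygote for rs5186), and the published effect
size — an odds ratio for hypertension or a beta in mmHg of blood
pressure.  One SNP (rs2266782) has no usable published effect size; it
participates in the unweighted score only, so the weighted score runs
over 19 variants.

Two scores are computed per individual.  The unweighted score sums
risk-oriented allele counts: a susceptibility-allele dosage is used
as-is, a protective-allele dosage is flipped to `2 - dosage`, so every
SNP contributes 0–2 *risk* alleles and the score lies in `[0, 2M]`.
The weighted score uses **signed** weights on unflipped effect-allele
exposures: `ln(OR)` for odds ratios (negative for protective ORs < 1),
betas as published (negative for protective effects), multiplied by
the effect-allele dosage (per-allele), a carrier indicator (dominant)
or a homozygote indicator (recessive).

The signed-weight convention — rather than flipping protective alleles
and using `|ln(OR)|` — is a genuine design choice: both appear in the
applied literature.  We chose the signed form because it keeps Eq-style
weights exactly as published and, under simulation from the shipped
frequency tables, it reproduces the weighted-score medians in the
neighbourhood of 1.4–1.5 that the shipped study context reports, which
the flip-and-absolute convention does not (it shifts the scale upward
by the sum of the flipped baseline contributions).

## Missing genotypes

Missing calls are never zero-filled.  Scoring imputes each missing
dosage by its expectation `2p`, with `p` the effect-allele frequency of
the *sample's own population* — observed from the cohort by default, or
taken from a supplied frequency table.  Using the pooled frequency
instead would leak the between-population frequency difference into
individual scores; the per-population choice keeps the imputed
contribution neutral for each cohort's mean (verified by a
property-style test under MCAR missingness at the 1% level).

A fractional imputed dosage `d` interacts with the dominant/recessive
codings: we map it to the indicator *expectation* under HWE at
frequency `d/2` (carrier probability `1 - (1 - d/2)^2`, homozygote
probability `(d/2)^2`) rather than rounding, which preserves the score
expectation and is deterministic.

## Population-genetic statistics

*Allele frequencies* are computed from non-missing calls only.  *HWE*
is tested by the 1-df chi-square of observed genotype counts against
`p²/2pq/q²` expectations, no continuity correction; monomorphic SNPs
are flagged undefined rather than scored.  The exact
(enumeration-based) HWE test is deliberately out of scope: at cohort
sizes above a thousand the chi-square is the field's standard screen.

*Between-population comparison* is a Pearson 1-df chi-square on the
2×2 effect/other allele-count table (counts `2N`, no Yates
correction).  When only a published percentage table is available,
counts are reconstructed as `round(pct/100 * 2N)`; reconstruction from
rounded percentages reproduces the strongly significant comparisons
robustly, but p-values near 0.05 can differ in the second decimal from
values computed on the raw data, because per-SNP missingness in the
original genotyping is unknowable from the table.

*LD* is estimated from unphased dosages by the standard two-locus EM:
double heterozygotes are split between cis and trans phases in
proportion to the current haplotype-frequency product, iterating until
the log-likelihood moves by less than `1e-9` (or 100 iterations —
convergence on the panel's data is typically < 20).  With no double
heterozygotes the first M-step equals direct haplotype counting, which
the tests exploit as a brute-force oracle.  `r² = D²/(p₁q₁p₂q₂)`; a
monomorphic member makes the pair undefined and flagged, not zero.

*Multiple testing* uses the spectral effective number of tests,
`Meff = 1 + (M − 1)(1 − Var(λ)/M)` on the eigenvalues of the
inter-marker **signed** correlation matrix, and a Bonferroni-style
corrected threshold `0.05/Meff`.  Two open choices were resolved as
follows.  The matrix fed to the correction is the genotype correlation
(pairwise complete, undefined pairs set to 0), not the unsigned `r²`
map: the spectral-decomposition method is defined on a correlation
matrix and the `r²` map has no sign.  And the correction is `α/Meff`
rather than the Šidák form `1 − (1 − α)^{1/Meff}`, because for
`Meff = 20` the former gives the conventional rounded threshold 0.0025
(the Šidák form gives 0.00256).  Limits are exact: identity input
gives `Meff = M`, an all-ones matrix gives `Meff = 1`.  Significance
after correction is a *strict* inequality.

The HWE screen can drop SNPs (at p < 0.05 in a designated reference
population, mirroring assay-stage QC).  In the default pipeline the
screen is reported but exclusion is opt-in (`hwe_exclude`): the
shipped panel is already post-QC, so on clean data a flagged SNP is an
expected false positive of the 0.05 screen (about one per 20-SNP run),
and silently dropping it would make default runs non-comparable.  A
separate two-SNP assay fixture (`assay_snps_synthetic.tsv`, synthetic)
exists purely to exercise the exclusion path with simulated excess
homozygosity.

## Distribution comparison

Score distributions are summarised by mean ± SD, median and quartiles,
adjusted Fisher–Pearson skewness and excess kurtosis with their
textbook standard errors (`SE_skew = sqrt(6n(n−1)/((n−2)(n+1)(n+3))`,
which is 0.07 at n ≈ 1176), and compared by the two-sided two-sample
Mann–Whitney and Kolmogorov–Smirnov tests.  The quintile partition
pools both populations, cuts at the pooled 20/40/60/80th percentiles,
and assigns boundary ties *downward*, so that on an integer-valued
score the bottom and top bins read naturally as "score ≤ c" and
"score ≥ c".  Pooled (rather than per-population) cut points are the
choice that makes the two populations' shares directly comparable.

## Phenotypes and association models

Hypertension follows the IDF consensus definition: SBP ≥ 130 mmHg,
DBP ≥ 85 mmHg or current antihypertensive medication, inclusive
thresholds.  For continuous-outcome models, measured pressures of
treated individuals get the standard +10/+5 mmHg constant added to
approximate untreated pressure.

Model 1 regresses the outcome on the score alone; Model 2 adds sex
(male = 1), age and BMI.  Logistic fits report odds ratios per unit
score with Wald 95% intervals; linear fits report coefficients,
t-based 95% intervals, standardised betas
(`coef × SD(x)/SD(y)`) and R².  Non-normal continuous variables can be
normalised first by the two-step rank-based inverse-normal
transformation: mid-ranks mapped to `(0,1)` as `rank/(n+1)` (this
denominator avoids infinite quantiles and is deterministic under
ties), standard-normal quantiles, then rescaling to the input's mean
and SD.  The transformation preserves ranks exactly and mean/SD to
float precision.  Because it is ambiguous which fits should use
transformed scales when results are reported in mmHg, the pipeline
emits both raw-scale and transformed fits, labelled.

## What the simulator emulates — and what it does not

The generator draws each SNP independently with genotype probabilities
`p² + Fpq / 2pq(1−F) / q² + Fpq` (inbreeding coefficient `F`,
default 0 = HWE), applies MCAR missingness (default 2.2%, i.e. a
97.8% call rate), and simulates phenotypes from a linear model of
latent blood pressure on the score, age, sex and BMI with normal
noise; treatment is assigned by a logistic function of latent SBP and
measured pressure subtracts the 10/5 mmHg treatment effect, so the
adjustment step recovers the latent scale exactly.  Default cohort
settings are the study conditions: n = 1167 (HG) and 1176 (HR) at the
shipped frequency columns; age 47.31 ± 17.02 vs 40.98 ± 12.84 years,
46% vs 41% male, BMI 26.10 ± 4.88 vs 26.55 ± 6.54 kg/m² (truncated
below at 18 years and 15 kg/m²); SBP slope 0.401 and DBP slope
0.149 mmHg per risk allele with residual SDs 15/10 mmHg, intercepts 65
and 50 mmHg chosen to put cohort means in a realistic 125–130 /
75–80 mmHg range; treatment probability `plogis((SBP − 150)/8)`.

SNPs are simulated in linkage equilibrium: the panel's LD map shows no
pair near the pruning threshold and most SNPs sit on different
chromosomes.  The simulator does **not** model population structure,
endogamy, admixture or genotyping batch effects.  A real cohort's
score variance therefore exceeds the HWE-independence prediction
(binomial variance sums, about SD 2.7 on the unweighted score at these
frequencies, versus ~3.0 reported for comparable real cohorts), and
quintile tail shares of real data are fatter than simulated ones.
Consequently the test suite asserts *means, medians, gaps and
directions* — quantities robust to that extra variance — and
explicitly does not assert SDs, ranges or exact tail shares.  `F` is
exposed as a sensitivity knob for excess homozygosity, not as a claim
about any population's structure.

## Problem sizes and determinism

All stochastic tests fix their seeds.  Study-scale checks use the full
cohort sizes (1167/1176); replicated checks average 50 simulated
cohorts, except the HG weighted-score median, which averages 300
because that comparison sits within ~0.004 of its tolerance edge and
needs the Monte Carlo error an order of magnitude below the band.
Parameter-recovery coverage uses 200 replicate cohorts; the null
calibration of the allele chi-square uses 2000 replicate 2×2 tables.
`build_study()` is byte-reproducible from its config and seed,
including serialization.

## Known limitations

- Panel SNPs are matched by rsID, not genomic coordinates; there is no
  strand-flip or reference-genome harmonisation.  The panel's alleles
  are authoritative, and a VCF whose REF/ALT do not match them is an
  error, not a silent flip.
- Multi-allelic VCF records are rejected rather than decomposed.
- The weighted score assumes published effect sizes transfer to both
  populations; no re-estimation or shrinkage (LDpred-style) is
  attempted.
- No gene–gene or gene–environment interactions; association models
  are main-effects only.
- The EM LD estimator assumes random union of haplotypes within the
  population in which it is run; applied across a pooled stratified
  sample it would absorb structure into apparent LD.
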