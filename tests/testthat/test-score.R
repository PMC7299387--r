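test_that("dosage orientation flips protective alleles around the heterozygote", {
  expect_equal(orient_dosage(2, "susceptibility"), 2)
  expect_equal(orient_dosage(2, "protective"), 0)
  expect_equal(orient_dosage(1, "protective"), 1)
  expect_equal(orient_dosage(c(0, 1, 2), c("protective", "protective", "protective")),
               c(2, 1, 0))
  expect_error(orient_dosage(NA, "susceptibility"), "impute")
})

test_that("expected-value imputation fills missing entries with 2p", {
  expect_equal(impute_missing(c(NA_real_), 0.5), 1.0)
  expect_equal(impute_missing(c(NA_real_), 0.2622), 0.5244)
  x <- c(0, 1, 2)
  expect_identical(impute_missing(x, 0.3), x)  # no-missing identity
  expect_equal(impute_missing(c(0, NA, 2), 0.25), c(0, 0.5, 2))
  expect_error(impute_missing(c(NA_real_), NA_real_), "\\[0, 1\\]")
})

test_that("unweighted score is the oriented allele sum over the panel", {
  expect_equal(grs(rep(2, 20)), 40)
  expect_equal(grs(rep(1, 20)), 20)
  expect_equal(grs(c(1, 0.5244, 2), M = 3), 3.5244)
  expect_error(grs(rep(1, 19), M = 20), "expected 20")
})

test_that("weighted score honours genetic models and signed weights", {
  panel <- shipped_panel()
  base <- rep(0, 20)  # zero effect alleles everywhere
  expect_equal(wgrs(base, panel), 0)

  # recessive rs5186: only the homozygote scores, at ln(7.3)
  d <- base
  i5186 <- which(panel$snp_id == "rs5186")
  d[i5186] <- 2
  expect_equal(wgrs(d, panel), log(7.3), tolerance = 1e-12)
  expect_equal(wgrs(d, panel), 1.988, tolerance = 1e-3)
  d[i5186] <- 1  # heterozygote does not score under recessive coding
  expect_equal(wgrs(d, panel), 0)

  # dominant rs4961: the heterozygote carrier scores the full ln(1.60)
  d <- base
  i4961 <- which(panel$snp_id == "rs4961")
  d[i4961] <- 1
  expect_equal(wgrs(d, panel), log(1.60), tolerance = 1e-12)
  expect_equal(wgrs(d, panel), 0.470, tolerance = 1e-3)
  d[i4961] <- 2  # homozygote scores the same indicator
  expect_equal(wgrs(d, panel), log(1.60), tolerance = 1e-12)

  # protective per-allele SNPs contribute negatively
  d <- base
  i13333226 <- which(panel$snp_id == "rs13333226")
  d[i13333226] <- 2
  expect_equal(wgrs(d, panel), 2 * log(0.87), tolerance = 1e-12)

  # the effect-size-free SNP never contributes
  d <- base
  d[panel$snp_id == "rs2266782"] <- 2
  expect_equal(wgrs(d, panel), 0)
})

test_that("fractional imputed dosages enter dominant/recessive terms as HWE expectations", {
  panel <- shipped_panel()
  d <- rep(0, 20)
  i5186 <- which(panel$snp_id == "rs5186")
  p <- 0.2622
  d[i5186] <- 2 * p  # imputed
  expect_equal(wgrs(d, panel), log(7.3) * p^2, tolerance = 1e-12)
  d <- rep(0, 20)
  i4961 <- which(panel$snp_id == "rs4961")
  q <- 0.1839
  d[i4961] <- 2 * q
  expect_equal(wgrs(d, panel), log(1.60) * (1 - (1 - q)^2), tolerance = 1e-12)
})

test_that("cohort scoring matches hand computation on a toy matrix", {
  panel <- toy_panel()  # s1 susc per-allele ln2, s2 prot per-allele ln0.5, s3 dom ln1.5
  G <- genotype_matrix(rbind(c(1, 2, 0), c(2, 0, 1)), c("a", "b"),
                       panel$snp_id, "P")
  sc <- score_cohort(G, panel)
  # GRS: oriented sums; s2 protective flips
  expect_equal(sc$grs, c(1 + (2 - 2) + 0, 2 + (2 - 0) + 1))
  # wGRS: signed weights, dominant indicator for s3
  expect_equal(sc$wgrs, c(1 * log(2) + 2 * log(0.5) + 0,
                          2 * log(2) + 0 * log(0.5) + log(1.5)))
  expect_equal(sc$n_imputed, c(0L, 0L))
})

test_that("an all-missing sample scores at the population expectation", {
  panel <- shipped_panel()
  freqs <- shipped_freqs(panel)
  set.seed(21)
  p <- pop_freq_vec(freqs, "HR", panel)
  G <- sim_genotypes(p, 50, population = "HR")
  G$dosage[1, ] <- NA_real_
  sc <- score_cohort(G, panel)
  expect_equal(sc$n_imputed[1], 20L)
  obs <- allele_freq(G, "HR")$freq
  expect_equal(sc$grs[1], expected_mean_grs(panel, obs), tolerance = 1e-10)
  # with an external frequency table, the fill uses the table instead
  sc2 <- score_cohort(G, panel, freqs = freqs)
  expect_equal(sc2$grs[1], expected_mean_grs(panel, p), tolerance = 1e-10)
})

test_that("GRS conservation under direction flip: score + flipped score = 2M", {
  panel <- shipped_panel()
  flipped <- panel
  flipped$direction <- ifelse(panel$direction == "protective",
                              "susceptibility", "protective")
  set.seed(31)
  freqs <- shipped_freqs(panel)
  G <- sim_genotypes(pop_freq_vec(freqs, "HG", panel), 30, population = "HG")
  s1 <- score_cohort(G, panel)$grs
  s2 <- score_cohort(G, flipped)$grs
  expect_equal(s1 + s2, rep(40, 30))
})

test_that("wGRS is invariant to panel row order", {
  panel <- shipped_panel()
  set.seed(32)
  freqs <- shipped_freqs(panel)
  G <- sim_genotypes(pop_freq_vec(freqs, "HG", panel), 25,
                     missing_rate = 0.05, population = "HG")
  sc <- score_cohort(G, panel, freqs = freqs)
  perm <- sample(nrow(panel))
  panel_perm <- structure(as.data.frame(panel)[perm, ], M = nrow(panel),
                          class = c("panel_spec", "data.frame"))
  sc_perm <- score_cohort(G, panel_perm, freqs = freqs)
  expect_equal(sc_perm$wgrs, sc$wgrs, tolerance = 1e-12)
  expect_equal(sc_perm$grs, sc$grs, tolerance = 1e-12)
})

test_that("cohort mean GRS matches the closed-form expectation and survives MCAR missingness", {
  panel <- shipped_panel()
  freqs <- shipped_freqs(panel)
  p <- pop_freq_vec(freqs, "HR", panel)
  mu <- expected_mean_grs(panel, p)  # 18.30 for the HR column
  expect_equal(mu, 18.2982, tolerance = 1e-4)
  set.seed(41)
  G <- sim_genotypes(p, 5000, population = "HR")
  sc <- score_cohort(G, panel, freqs = freqs)
  se <- sd(sc$grs) / sqrt(5000)
  expect_lt(abs(mean(sc$grs) - mu), 3 * se)

  # imputation neutrality: heavy MCAR missingness leaves the mean within 1%
  set.seed(42)
  Gm <- sim_genotypes(p, 5000, missing_rate = 0.2, population = "HR")
  scm <- score_cohort(Gm, panel, freqs = freqs)
  expect_lt(abs(mean(scm$grs) - mu) / mu, 0.01)

  # closed-form mean for the weighted score
  use <- !is.na(panel$weight)
  ex <- ifelse(panel$genetic_model == "per_allele", 2 * p,
               ifelse(panel$genetic_model == "dominant", 1 - (1 - p)^2, p^2))
  mu_w <- sum(panel$weight[use] * ex[use])
  se_w <- sd(sc$wgrs) / sqrt(5000)
  expect_lt(abs(mean(sc$wgrs) - mu_w), 3 * se_w)
})

test_that("quintile partition assigns ties downward and detects shifts", {
  scores <- 1:100
  pop <- rep(c("A", "B"), 50)
  qp <- quintile_partition(scores, pop)
  expect_true(all(abs(qp$shares - 0.2) < 1e-12))
  expect_equal(qp$p, 1)
  expect_equal(as.integer(table(qp$quintile)), rep(20L, 5))

  # integer scores tied with a cut point land in the lower bin
  s2 <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  qp_t <- quintile_partition(s2, rep(c("A", "B"), 5))
  expect_equal(qp_t$cutpoints[1], 2)
  expect_true(all(qp_t$quintile[s2 == 2] == 1L))

  # a +1 SD shift over-represents the shifted group in the top quintile
  set.seed(51)
  a <- rnorm(1000, 1); b <- rnorm(1000, 0)
  qp2 <- quintile_partition(c(a, b), rep(c("A", "B"), each = 1000))
  expect_gt(qp2$shares["A", 5], qp2$shares["B", 5])
  expect_lt(qp2$shares["A", 1], qp2$shares["B", 1])

  expect_error(quintile_partition(rep(1, 100), rep("A", 100)), "degenerate")
})

test_that("distribution summaries report the textbook skewness/kurtosis SEs", {
  set.seed(61)
  x <- rnorm(1176)
  s <- distribution_summary(x)
  expect_equal(round(s$se_skewness, 2), 0.07)
  expect_equal(round(s$se_kurtosis, 2), 0.14)
  expect_true(s$q25 <= s$median && s$median <= s$q75)
  # a symmetric sample has near-zero skewness; a lognormal one is skewed
  expect_lt(abs(s$skewness), 3 * s$se_skewness)
  expect_gt(distribution_summary(exp(rnorm(1176)))$skewness, 1)
})

test_that("distribution comparison separates shifted populations", {
  set.seed(71)
  x <- rnorm(500)
  cmp0 <- summarize_and_compare(x, x)
  expect_equal(cmp0$ks_statistic, 0)
  expect_gt(cmp0$mann_whitney_p, 0.99)

  panel <- shipped_panel()
  freqs <- shipped_freqs(panel)
  set.seed(72)
  g_hg <- score_cohort(sim_genotypes(pop_freq_vec(freqs, "HG", panel), 1167,
                                     population = "HG"), panel)$grs
  g_hr <- score_cohort(sim_genotypes(pop_freq_vec(freqs, "HR", panel), 1176,
                                     population = "HR"), panel)$grs
  cmp <- summarize_and_compare(g_hg, g_hr, c("HG", "HR"))
  expect_gt(cmp$summary$mean[1], cmp$summary$mean[2])
  expect_lt(cmp$mann_whitney_p, 0.001)
})
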