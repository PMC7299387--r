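test_that("allele frequencies exclude missing calls and flag all-missing SNPs", {
  G <- genotype_matrix(rbind(c(0, 2, NA), c(1, 2, NA), c(2, 2, NA)),
                       c("a", "b", "c"), c("s1", "s2", "s3"))
  af <- allele_freq(G)
  expect_equal(af$freq[1], 0.5)   # {0,1,2} -> 3/6
  expect_equal(af$freq[2], 1.0)
  expect_true(is.na(af$freq[3]))
  expect_false(af$defined[3])

  # missing calls drop out of numerator and denominator, never zero-fill
  G2 <- genotype_matrix(rbind(c(2), c(NA), c(0)), c("a", "b", "c"), "s1")
  expect_equal(allele_freq(G2)$freq, 0.5)
  expect_equal(allele_freq(G2)$n_called, 2L)
})

test_that("simulated cohort frequencies recover the fixture values", {
  panel <- shipped_panel()
  freqs <- shipped_freqs(panel)
  p <- pop_freq_vec(freqs, "HR", panel)
  set.seed(101)
  G <- sim_genotypes(p, 1176, population = "HR")
  af <- allele_freq(G)
  se <- sqrt(p * (1 - p) / (2 * 1176))
  expect_true(all(abs(af$freq - p) < 3 * se))
})

test_that("HWE chi-square matches hand computation and flags monomorphic SNPs", {
  h0 <- hwe_chisq(25, 50, 25)
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p, 1)
  h1 <- hwe_chisq(30, 40, 30)
  expect_equal(h1$chi2, 4.0)
  expect_equal(h1$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(h1$p, 4), 0.0455)
  mono <- hwe_chisq(0, 0, 50)
  expect_false(mono$defined)
  expect_true(is.na(mono$p))
})

test_that("excess-homozygosity assay SNPs are flagged for HWE exclusion", {
  assay <- load_panel(grspanel_example("assay_snps_synthetic.tsv"))
  expect_equal(nrow(assay), 2L)
  set.seed(77)
  G <- sim_genotypes(setNames(c(0.3, 0.35), assay$snp_id), 1000,
                     f = 0.3, population = "HG")
  screen <- hwe_screen(G, population = "HG", alpha = 0.05)
  expect_true(all(screen$p < 0.05))
  expect_true(all(screen$exclude))
  # an HWE-true panel of the same size is mostly retained
  set.seed(78)
  G0 <- sim_genotypes(setNames(c(0.3, 0.35), assay$snp_id), 1000,
                      f = 0, population = "HG")
  expect_true(all(hwe_screen(G0, "HG")$p > 0.05))
})

test_that("allele-count reconstruction from printed percentages", {
  expect_equal(reconstruct_counts(26.22, 1167), c(effect = 612, other = 1722))
  expect_equal(reconstruct_counts(13.41, 1176), c(effect = 315, other = 2037))
  expect_equal(reconstruct_counts(50.0, 100), c(effect = 100, other = 100))
  expect_error(reconstruct_counts(0, 100), "strictly inside")
  expect_error(reconstruct_counts(100, 100), "strictly inside")
})

test_that("two-population allele chi-square behaves as a Pearson 1-df test", {
  # rs5186 counts reconstructed from the shipped table
  cmp <- compare_freqs(reconstruct_counts(26.22, 1167),
                       reconstruct_counts(13.41, 1176))
  expect_lt(cmp$p, 0.001)
  # symmetric under population swap
  swapped <- compare_freqs(reconstruct_counts(13.41, 1176),
                           reconstruct_counts(26.22, 1167))
  expect_equal(cmp$chi2, swapped$chi2)
  expect_equal(cmp$p, swapped$p)
  # identical counts: no difference
  same <- compare_freqs(c(50, 150), c(50, 150))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # rs5049 reconstruction (oracle value frozen from an independent
  # chi-square on counts 312/2022 vs 266/2086)
  r5049 <- compare_freqs(reconstruct_counts(13.38, 1167),
                         reconstruct_counts(11.29, 1176))
  expect_equal(r5049$p, 0.0322, tolerance = 1e-2)
  expect_lt(r5049$p, 0.05)
  expect_error(compare_freqs(c(0, 100), c(0, 50)), "zero margin")
})

test_that("allele chi-square holds its type-I error under the null", {
  set.seed(2020)
  n <- 1000
  reps <- 2000
  p <- 0.3
  rejections <- mean(replicate(reps, {
    k1 <- rbinom(1, 2 * n, p)
    k2 <- rbinom(1, 2 * n, p)
    compare_freqs(c(k1, 2 * n - k1), c(k2, 2 * n - k2))$p < 0.05
  }))
  expect_gte(rejections, 0.04)
  expect_lte(rejections, 0.06)
})

test_that("EM haplotype frequencies match direct counting when phase is unambiguous", {
  # genotype pairs with no double heterozygotes: phase fully determined
  d1 <- c(0, 0, 2, 2, 1, 0, 2, 1, 0, 2)
  d2 <- c(0, 2, 0, 2, 0, 1, 1, 2, 0, 2)
  count_haps <- function(d1, d2) {
    # brute-force: deduce each individual's two haplotypes
    haps <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
    for (i in seq_along(d1)) {
      a <- c(rep("A", d1[i]), rep("a", 2 - d1[i]))
      b <- c(rep("B", d2[i]), rep("b", 2 - d2[i]))
      if (d1[i] == 1 && d2[i] == 1) stop("ambiguous")
      # when one locus is homozygous the pairing is irrelevant
      h1 <- paste0(ifelse(a[1] == "A", "A", "a"), ifelse(b[1] == "B", "B", "b"))
      h2 <- paste0(ifelse(a[2] == "A", "A", "a"), ifelse(b[2] == "B", "B", "b"))
      haps[h1] <- haps[h1] + 1
      haps[h2] <- haps[h2] + 1
    }
    haps / sum(haps)
  }
  expected <- count_haps(d1, d2)
  est <- em_r2(d1, d2)
  expect_true(est$converged)
  expect_equal(est$hap_freqs, expected, tolerance = 1e-6)
})

test_that("EM recovers known haplotype frequencies from collapsed phased data", {
  set.seed(303)
  # truth: D = 0.08 at p1 = 0.5, p2 = 0.4
  h <- c(AB = 0.28, Ab = 0.22, aB = 0.12, ab = 0.38)
  n <- 4000
  hap_draw <- sample(names(h), 2 * n, replace = TRUE, prob = h)
  h1 <- hap_draw[seq_len(n)]; h2 <- hap_draw[n + seq_len(n)]
  d1 <- (substr(h1, 1, 1) == "A") + (substr(h2, 1, 1) == "A")
  d2 <- (substr(h1, 2, 2) == "B") + (substr(h2, 2, 2) == "B")
  est <- em_r2(d1, d2)
  se <- sqrt(h * (1 - h) / (2 * n))
  expect_true(all(abs(est$hap_freqs - h) < 2 * se))
  # r2 against the truth implied by D
  r2_true <- 0.08^2 / (0.5 * 0.5 * 0.4 * 0.6)
  expect_equal(est$r2, r2_true, tolerance = 0.15)
})

test_that("EM r2 limits: perfect LD, independence, monomorphic pairs", {
  set.seed(99)
  d <- rbinom(500, 2, 0.5)
  expect_equal(em_r2(d, d)$r2, 1, tolerance = 1e-9)
  a <- rbinom(10000, 2, 0.5)
  b <- rbinom(10000, 2, 0.5)
  expect_lt(em_r2(a, b)$r2, 0.01)
  mono <- em_r2(rep(0, 100), rbinom(100, 2, 0.5))
  expect_false(mono$defined)
  expect_true(is.na(mono$r2))
})

test_that("LD matrix is symmetric with unit diagonal and a prune flag", {
  set.seed(5)
  G <- genotype_matrix(cbind(rbinom(300, 2, 0.4), rbinom(300, 2, 0.6)),
                       sprintf("i%03d", 1:300), c("s1", "s2"))
  ld <- ld_matrix(G)
  expect_equal(ld$r2, t(ld$r2))
  expect_equal(unname(diag(ld$r2)), c(1, 1))
  expect_false(ld$prune)

  # a duplicated SNP column forces r2 = 1 >= 0.8
  Gdup <- genotype_matrix(cbind(G$dosage, G$dosage[, 1]),
                          G$sample_ids, c("s1", "s2", "s1b"))
  expect_true(ld_matrix(Gdup)$prune)

  # an independent panel at study scale stays below the prune threshold
  panel <- shipped_panel()
  freqs <- shipped_freqs(panel)
  set.seed(6)
  Gp <- sim_genotypes(pop_freq_vec(freqs, "HG", panel), 400, population = "HG")
  expect_false(ld_matrix(Gp)$prune)
})

test_that("spectral Meff has the identity and perfect-correlation limits", {
  id20 <- meff(diag(20))
  expect_equal(id20$meff, 20)
  expect_equal(id20$corrected_alpha_rounded, 0.0025)
  expect_equal(meff(matrix(1, 1, 1))$meff, 1)
  ones <- meff(matrix(1, 7, 7))
  expect_equal(ones$meff, 1)
  expect_equal(ones$corrected_alpha, 0.05)
  expect_error(meff(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("Meff stays within [1, M] and eigenvalues sum to M", {
  set.seed(42)
  for (M in c(3, 8, 20)) {
    X <- matrix(rnorm(60 * M), 60, M)
    X[, 1] <- X[, 2] + rnorm(60, sd = 0.3)  # induce some correlation
    r <- cor(X)
    res <- meff(r)
    expect_equal(sum(res$eigenvalues), M, tolerance = 1e-8)
    expect_gte(res$meff, 1)
    expect_lte(res$meff, M)
  }
})

test_that("corrected-significance flags use a strict inequality", {
  res <- significant_after_correction(c(0.001, 0.0025, 0.5, 0.0024), 0.0025)
  expect_equal(res$flags, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$count, 2L)
  expect_equal(significant_after_correction(rep(0.5, 10), 0.0025)$count, 0L)
})
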