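# Allele-frequency estimation and comparison, Hardy-Weinberg testing,
# EM haplotype-frequency LD, and the spectral effective-number-of-tests
# (Meff / SNP spectral decomposition) multiple-testing correction.

#' Per-SNP effect-allele frequencies from genotypes
#'
#' Frequency = (heterozygotes + 2 x effect-homozygotes) / (2 x
#' non-missing individuals); missing calls are excluded from both the
#' numerator and the denominator, never zero-filled.  An all-missing SNP
#' gets `NA` frequency and `defined = FALSE`.
#'
#' @param G A `genotype_matrix`.
#' @param population Optional label: restrict to samples of that
#'   population.
#' @return Data frame with columns `snp_id`, `n_called`, `n_effect`
#'   (effect-allele count), `freq`, `defined`.
#' @export
allele_freq <- function(G, population = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  if (!is.null(population)) {
    keep <- G$population == population
    if (!any(keep)) stop("no samples with population '", population, "'", call. = FALSE)
    d <- d[keep, , drop = FALSE]
  }
  n_called <- colSums(!is.na(d))
  n_effect <- colSums(d, na.rm = TRUE)
  freq <- ifelse(n_called > 0, n_effect / (2 * n_called), NA_real_)
  data.frame(
    snp_id = G$snp_ids, n_called = as.integer(n_called),
    n_effect = as.numeric(n_effect), freq = freq, defined = n_called > 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square of observed genotype counts against
#' the p^2 / 2pq / q^2 expectation, without continuity correction; the
#' p-value is the upper tail.  A monomorphic SNP has no defined test and
#' is flagged rather than scored.
#'
#' @param n_aa Count of effect-allele homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of other-allele homozygotes.
#' @return List with `chi2`, `p`, `defined`.
#' @export
#' @examples
#' hwe_chisq(25, 50, 25)  # exact HWE proportions: chi2 = 0, p = 1
hwe_chisq <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n <= 0) stop("no genotypes", call. = FALSE)
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = NA_real_, p = NA_real_, defined = FALSE))
  }
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  observed <- c(n_aa, n_ab, n_bb)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), defined = TRUE)
}

#' Hardy-Weinberg screen of a genotype matrix
#'
#' Applies [hwe_chisq()] per SNP within one population and flags SNPs
#' whose HWE p-value falls below `alpha` for exclusion from downstream
#' analysis.
#'
#' @param G A `genotype_matrix`.
#' @param population Population in which HWE is assessed (assay-quality
#'   screens are run in a designated reference population).
#' @param alpha Exclusion threshold on the HWE p-value (default 0.05).
#' @return Data frame with per-SNP genotype counts, `chi2`, `p`,
#'   `defined` and `exclude`.
#' @export
hwe_screen <- function(G, population = NULL, alpha = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  if (!is.null(population)) {
    keep <- G$population == population
    if (!any(keep)) stop("no samples with population '", population, "'", call. = FALSE)
    d <- d[keep, , drop = FALSE]
  }
  res <- lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    counts <- c(sum(x == 2), sum(x == 1), sum(x == 0))
    if (sum(counts) == 0) {
      return(data.frame(n_aa = 0L, n_ab = 0L, n_bb = 0L,
                        chi2 = NA_real_, p = NA_real_, defined = FALSE))
    }
    h <- hwe_chisq(counts[1], counts[2], counts[3])
    data.frame(n_aa = counts[1], n_ab = counts[2], n_bb = counts[3],
               chi2 = h$chi2, p = h$p, defined = h$defined)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(snp_id = G$snp_ids, stringsAsFactors = FALSE), out)
  out$exclude <- out$defined & !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Reconstruct allele counts from a printed frequency percentage
#'
#' Recovers the effect/other allele counts behind a rounded percentage:
#' effect = `round(freq_pct/100 * 2n)`, other = `2n - effect`.  Used to
#' reproduce published two-population comparisons from frequency tables
#' alone.
#'
#' @param freq_pct Effect-allele frequency as a percentage in (0, 100).
#' @param n_individuals Number of genotyped individuals.
#' @return Named numeric vector `c(effect = ..., other = ...)`.
#' @export
#' @examples
#' reconstruct_counts(26.22, 1167)  # c(effect = 612, other = 1722)
reconstruct_counts <- function(freq_pct, n_individuals) {
  if (freq_pct <= 0 || freq_pct >= 100) {
    stop("freq_pct must be strictly inside (0, 100)", call. = FALSE)
  }
  total <- 2 * n_individuals
  effect <- round(freq_pct / 100 * total)
  c(effect = effect, other = total - effect)
}

#' Compare effect-allele counts between two populations
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' of effect/other allele counts.  Symmetric in the two populations.
#'
#' @param counts1,counts2 Length-2 vectors `c(effect, other)` of allele
#'   counts for each population.
#' @return List with `freq1`, `freq2`, `chi2`, `p` and the 2x2 `table`.
#' @export
compare_freqs <- function(counts1, counts2) {
  stopifnot(length(counts1) == 2L, length(counts2) == 2L)
  tab <- rbind(pop1 = counts1, pop2 = counts2)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    stop("degenerate 2x2 table: zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(
    freq1 = counts1[1] / sum(counts1),
    freq2 = counts2[1] / sum(counts2),
    chi2 = unname(ct$statistic),
    p = unname(ct$p.value),
    table = tab
  )
}

#' Two-population allele-frequency comparison for a whole panel
#'
#' Builds per-SNP 2x2 allele-count tables from a frequency table
#' ([reconstruct_counts()]) or from genotypes ([allele_freq()]), runs
#' [compare_freqs()] per SNP, and flags nominal (p < 0.05) and
#' corrected significance.
#'
#' @param freqs A `freq_table` with exactly the two populations, or
#'   `NULL` to use genotypes.
#' @param G A `genotype_matrix` with two populations (used when `freqs`
#'   is `NULL`).
#' @param panel A `panel_spec`.
#' @param populations Length-2 character vector ordering the comparison.
#' @param corrected_alpha Corrected significance threshold (see
#'   [meff()]).
#' @return Data frame, one row per panel SNP: frequencies (proportions),
#'   `chi2`, `p`, `significant_nominal`, `significant_corrected`.
#' @export
compare_panel_freqs <- function(panel, populations, freqs = NULL, G = NULL,
                                corrected_alpha = 0.05) {
  stopifnot(inherits(panel, "panel_spec"), length(populations) == 2L)
  get_counts <- function(pop) {
    if (!is.null(freqs)) {
      rows <- freqs[freqs$population == pop, ]
      idx <- match(panel$snp_id, rows$snp_id)
      if (anyNA(idx)) stop("frequency table incomplete for ", pop, call. = FALSE)
      t(mapply(function(f, n) reconstruct_counts(f * 100, n),
               rows$effect_allele_freq[idx], rows$n_individuals[idx]))
    } else {
      af <- allele_freq(G, pop)
      cbind(effect = af$n_effect, other = 2 * af$n_called - af$n_effect)
    }
  }
  c1 <- get_counts(populations[1])
  c2 <- get_counts(populations[2])
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    cmp <- compare_freqs(c1[i, ], c2[i, ])
    data.frame(snp_id = panel$snp_id[i], direction = panel$direction[i],
               freq_pop1 = cmp$freq1, freq_pop2 = cmp$freq2,
               chi2 = cmp$chi2, p = cmp$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant_nominal <- out$p < 0.05
  out$significant_corrected <- out$p < corrected_alpha
  attr(out, "populations") <- populations
  out
}

#' EM estimation of two-locus haplotype frequencies and LD
#'
#' Estimates the four haplotype frequencies of two biallelic SNPs from
#' unphased dosages by expectation-maximisation: double heterozygotes
#' are split between the cis and trans phase configurations in
#' proportion to the current haplotype-frequency estimates, iterating
#' until the log-likelihood changes by less than `tol` (default 1e-9) or
#' `max_iter` iterations.  Complete-case pairs only.
#'
#' @param d1,d2 Effect-allele dosage vectors (0/1/2, NA allowed) of the
#'   two SNPs over the same samples.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Iteration cap.
#' @return List with `hap_freqs` (named `AB`, `Ab`, `aB`, `ab`, where
#'   `A`/`B` are the effect alleles), `D`, `Dprime`, `r2`, `p1`, `p2`,
#'   `n`, `iterations`, `converged`, `defined`.  A pair with a
#'   monomorphic member has `defined = FALSE` and `NA` statistics.
#' @export
em_r2 <- function(d1, d2, tol = 1e-9, max_iter = 100L) {
  keep <- !is.na(d1) & !is.na(d2)
  x <- d1[keep]; y <- d2[keep]
  n <- length(x)
  if (n == 0L) stop("no complete-case pairs", call. = FALSE)
  p1 <- mean(x) / 2; p2 <- mean(y) / 2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    return(list(hap_freqs = c(AB = NA, Ab = NA, aB = NA, ab = NA),
                D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                p1 = p1, p2 = p2, n = n, iterations = 0L,
                converged = FALSE, defined = FALSE))
  }
  # 3x3 genotype count table; cell (i, j) = count with dosages (i-1, j-1)
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(x == i & y == j)
  # haplotype freqs: h = (AB, Ab, aB, ab); initialise at linkage equilibrium
  h <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  loglik <- function(h) {
    # genotype class probabilities under random union of haplotypes
    pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
    probs <- matrix(c(
      pab^2,           2 * pab * paB,               paB^2,
      2 * pab * pAb,   2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
      pAb^2,           2 * pAB * pAb,               pAB^2
    ), 3, 3, byrow = TRUE)
    sum(tab[tab > 0] * log(probs[tab > 0]))
  }
  ll <- loglik(h)
  iter <- 0L
  converged <- FALSE
  n_dh <- tab[2, 2]  # double heterozygotes: phase-ambiguous
  repeat {
    iter <- iter + 1L
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    # expected haplotype counts over 2n gametes
    cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + n_dh * w
    cAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + n_dh * (1 - w)
    caB <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + n_dh * (1 - w)
    cab <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2] + n_dh * w
    h <- c(cAB, cAb, caB, cab) / (2 * n)
    ll_new <- loglik(h)
    if (abs(ll_new - ll) < tol) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
    if (iter >= max_iter) break
  }
  D <- h[1] - p1 * p2
  dmax <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2) else min(p1 * p2, (1 - p1) * (1 - p2))
  list(
    hap_freqs = setNames(h, c("AB", "Ab", "aB", "ab")),
    D = D,
    Dprime = if (dmax > 0) abs(D) / dmax else NA_real_,
    r2 = D^2 / (p1 * (1 - p1) * p2 * (1 - p2)),
    p1 = p1, p2 = p2, n = n, iterations = iter,
    converged = converged, defined = TRUE
  )
}

#' Pairwise LD (r-squared) matrix for a panel
#'
#' Runs [em_r2()] on every SNP pair of a genotype matrix (optionally
#' within one population) and reports whether any off-diagonal pair
#' reaches the pruning threshold.
#'
#' @param G A `genotype_matrix` with at least two SNPs.
#' @param population Optional population restriction.
#' @param prune_threshold r-squared above which a pair would warrant
#'   pruning (default 0.8).
#' @return List with `r2` (symmetric matrix, unit diagonal), `defined`
#'   (logical matrix of estimable pairs), `max_r2` (largest defined
#'   off-diagonal value) and `prune` (flag: any pair >= threshold).
#' @export
ld_matrix <- function(G, population = NULL, prune_threshold = 0.8) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  if (!is.null(population)) d <- d[G$population == population, , drop = FALSE]
  M <- ncol(d)
  if (M < 2L) stop("need at least two SNPs", call. = FALSE)
  r2 <- diag(1, M)
  defined <- matrix(TRUE, M, M)
  for (i in seq_len(M - 1)) {
    for (j in seq(i + 1, M)) {
      est <- em_r2(d[, i], d[, j])
      r2[i, j] <- r2[j, i] <- if (est$defined) est$r2 else NA_real_
      defined[i, j] <- defined[j, i] <- est$defined
    }
  }
  dimnames(r2) <- dimnames(defined) <- list(G$snp_ids, G$snp_ids)
  off <- r2[upper.tri(r2)]
  max_r2 <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  list(r2 = r2, defined = defined, max_r2 = max_r2,
       prune = isTRUE(max_r2 >= prune_threshold))
}

#' Signed genotype-correlation matrix
#'
#' Pairwise-complete Pearson correlation of effect-allele dosages, the
#' input expected by the spectral [meff()] correction (which is defined
#' on a signed correlation matrix, unlike the unsigned r-squared LD
#' map).  Pairs with undefined correlation fall back to 0.
#'
#' @param G A `genotype_matrix`.
#' @param population Optional population restriction.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
genotype_cor <- function(G, population = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  if (!is.null(population)) d <- d[G$population == population, , drop = FALSE]
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(G$snp_ids, G$snp_ids)
  r
}

#' Effective number of independent tests (spectral Meff)
#'
#' From the eigenvalue spectrum of the inter-marker correlation matrix:
#' `Meff = 1 + (M - 1) * (1 - Var(lambda) / M)` with `Var` the sample
#' variance of the eigenvalues.  Completely correlated markers give
#' Meff = 1, completely independent markers Meff = M.  The corrected
#' significance threshold is `alpha / Meff` (Bonferroni-style on the
#' effective test count).
#'
#' @param corr Symmetric correlation matrix with unit diagonal (e.g.
#'   [genotype_cor()], or an identity for markers treated as unlinked).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `meff_result` list: `eigenvalues`, `M`, `meff`,
#'   `corrected_alpha` (raw) and `corrected_alpha_rounded` (4 decimals).
#' @export
#' @examples
#' meff(diag(20))$corrected_alpha_rounded  # 0.0025
meff <- function(corr, alpha = 0.05) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || !isSymmetric(unname(corr), tol = 1e-8)) {
    stop("meff requires a symmetric square matrix", call. = FALSE)
  }
  if (any(abs(diag(corr) - 1) > 1e-8)) {
    stop("meff requires a unit diagonal", call. = FALSE)
  }
  M <- nrow(corr)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  m_eff <- if (M == 1L) 1 else 1 + (M - 1) * (1 - var(lambda) / M)
  m_eff <- min(max(m_eff, 1), M)
  structure(
    list(eigenvalues = lambda, M = M, meff = m_eff,
         corrected_alpha = alpha / m_eff,
         corrected_alpha_rounded = round(alpha / m_eff, 4)),
    class = "meff_result"
  )
}

#' @export
print.meff_result <- function(x, ...) {
  cat("Meff =", format(x$meff), "of", x$M, "markers; corrected alpha =",
      format(x$corrected_alpha_rounded), "\n")
  invisible(x)
}

#' Flag p-values significant after multiple-test correction
#'
#' Strict inequality: a p-value exactly equal to the corrected threshold
#' is not significant.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param corrected_alpha Corrected threshold (e.g. from [meff()]).
#' @return List with logical `flags` and integer `count`.
#' @export
significant_after_correction <- function(p_values, corrected_alpha) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  flags <- !is.na(p_values) & p_values < corrected_alpha
  list(flags = flags, count = sum(flags))
}
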