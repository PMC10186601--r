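#' Count APOE epsilon alleles from diploid genotype calls
#'
#' To maximize sample size, e4 and e2 are counted from their defining variant
#' alone (rs429358-C and rs7412-T respectively, over all samples with that
#' site called), while e3 — the rs429358-T/rs7412-C haplotype — is counted
#' only over samples with both sites called. Any diplotype that is not
#' heterozygous at both sites has a unique decomposition into \{e2, e3, e4\}
#' haplotypes; double heterozygotes are ambiguous and are resolved as e2/e4
#' (zero e3 haplotypes) — the parsimonious reading given that the e1
#' recombinant is vanishingly rare in Europeans — and their number is
#' reported so the alternative (e1/e3) resolution can be assessed.
#'
#' @param calls data.frame with one row per QC-passing sample and columns
#'   `rs429358_C` (count of C alleles at rs429358: 0/1/2 or NA) and
#'   `rs7412_T` (count of T alleles at rs7412: 0/1/2 or NA); an optional
#'   `population` column labels the output.
#' @return one-row data.frame with counts `x_e4`, `n_e4`, `x_e2`, `n_e2`,
#'   `x_e3`, `n_e3` and `n_ambiguous_dhet`.
#' @export
#' @examples
#' calls <- data.frame(rs429358_C = c(0, 1, NA), rs7412_T = c(0, 0, 1))
#' count_epsilon(calls)
count_epsilon <- function(calls) {
  abort_if(!all(c("rs429358_C", "rs7412_T") %in% names(calls)),
           "calls must have columns rs429358_C and rs7412_T")
  cc <- calls$rs429358_C
  tt <- calls$rs7412_T
  abort_if(!all(cc %in% c(0:2, NA)) || !all(tt %in% c(0:2, NA)),
           "dosages must be 0, 1, 2 or NA")
  pop <- if ("population" %in% names(calls) && nrow(calls) > 0L) {
    unique(as.character(calls$population))[1L]
  } else NA_character_
  both <- !is.na(cc) & !is.na(tt)
  dhet <- both & cc == 1L & tt == 1L
  e3 <- 2L - cc[both] - tt[both]
  if (any(e3 < 0L)) {
    warning("diplotype(s) implying an e1 haplotype encountered; ",
            "e3 contribution clipped at 0", call. = FALSE)
    e3 <- pmax(e3, 0L)
  }
  data.frame(population = pop,
             x_e4 = sum(cc, na.rm = TRUE), n_e4 = 2L * sum(!is.na(cc)),
             x_e2 = sum(tt, na.rm = TRUE), n_e2 = 2L * sum(!is.na(tt)),
             x_e3 = sum(e3), n_e3 = 2L * sum(both),
             n_ambiguous_dhet = sum(dhet),
             stringsAsFactors = FALSE)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile ("exact") interval for a binomial proportion; the lower
#' bound is 0 when x = 0 and the upper bound is 1 when x = n.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.90, matching the frequency
#'   plots' error bars).
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' clopper_pearson(0, 10) # upper bound 1 - 0.05^(1/10)
clopper_pearson <- function(x, n, level = 0.90) {
  abort_if(length(n) != 1 || n < 1, "n must be a positive count")
  abort_if(x < 0 || x > n, "x must lie in [0, n]")
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(ci_low = lo, ci_high = hi)
}

#' Epsilon allele frequency estimates with exact confidence intervals
#'
#' @param counts data.frame of per-population counts from [count_epsilon()]
#'   (one row per population).
#' @param level confidence level for the Clopper-Pearson interval.
#' @return data.frame with one row per population x allele: `population`,
#'   `allele`, `x`, `n`, `freq`, `ci_low`, `ci_high`.
#' @export
epsilon_frequencies <- function(counts, level = 0.90) {
  rows <- lapply(seq_len(nrow(counts)), function(r) {
    do.call(rbind, lapply(c("e2", "e3", "e4"), function(al) {
      x <- counts[[paste0("x_", al)]][r]
      n <- counts[[paste0("n_", al)]][r]
      ci <- if (n >= 1) clopper_pearson(x, n, level) else c(NA_real_, NA_real_)
      data.frame(population = counts$population[r], allele = al,
                 x = x, n = n, freq = if (n >= 1) x / n else NA_real_,
                 ci_low = ci[[1L]], ci_high = ci[[2L]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for an allele count difference
#'
#' Compares allele counts between two populations as a 2x2 table
#' (carrier vs non-carrier chromosomes); two-sidedness follows the
#' conventional probability ordering (all tables with hypergeometric
#' probability at most that of the observed table).
#'
#' @param x_a,n_a allele count and denominator in population A.
#' @param x_b,n_b allele count and denominator in population B.
#' @return the two-sided p-value.
#' @export
fisher_pairwise <- function(x_a, n_a, x_b, n_b) {
  abort_if(x_a < 0 || x_a > n_a || x_b < 0 || x_b > n_b,
           "counts must satisfy 0 <= x <= n")
  tab <- matrix(c(x_a, n_a - x_a, x_b, n_b - x_b), nrow = 2L, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @param q FDR level for the rejection flags (default 0.05).
#' @return data.frame with `p`, `p_adj` and `significant` (p_adj <= q);
#'   empty input yields an empty result.
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  abort_if(length(pvals) > 0 && !is_prob(pvals[!is.na(pvals)]),
           "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adj = adj, significant = !is.na(adj) & adj <= q)
}

#' All pairwise Fisher tests across populations and alleles, FDR-corrected
#'
#' Every unordered population pair is tested for each epsilon allele using
#' its allele-specific counts, and all resulting p-values are pooled into a
#' single family for Benjamini-Hochberg correction.
#'
#' @param counts per-population counts from [count_epsilon()].
#' @param alleles which alleles to test.
#' @param q FDR level (default 0.05).
#' @return data.frame with `pop_a`, `pop_b`, `allele`, `p`, `p_adj`,
#'   `significant`.
#' @export
pairwise_freq_tests <- function(counts, alleles = c("e2", "e3", "e4"),
                                q = 0.05) {
  abort_if(nrow(counts) < 2L, "need at least two populations")
  pairs <- utils::combn(seq_len(nrow(counts)), 2L)
  rows <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    do.call(rbind, lapply(alleles, function(al) {
      data.frame(pop_a = counts$population[i], pop_b = counts$population[j],
                 allele = al,
                 p = fisher_pairwise(counts[[paste0("x_", al)]][i],
                                     counts[[paste0("n_", al)]][i],
                                     counts[[paste0("x_", al)]][j],
                                     counts[[paste0("n_", al)]][j]),
                 stringsAsFactors = FALSE)
    }))
  }))
  adj <- bh_adjust(rows$p, q)
  rows$p_adj <- adj$p_adj
  rows$significant <- adj$significant
  rownames(rows) <- NULL
  rows
}
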