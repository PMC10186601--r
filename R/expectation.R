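#' Admixture-informed expected allele frequency
#'
#' The expected frequency in an admixed offspring population is the linear
#' combination of its parents' allele frequencies weighted by the ancestry
#' components: `fexp = kA * fA + kB * fB`.
#'
#' @param kA,kB ancestry components of parents A and B (must sum to 1
#'   within 1e-9).
#' @param fA,fB parental allele frequencies in [0, 1].
#' @return the expected offspring frequency.
#' @export
#' @examples
#' expected_frequency(kA = 0.18, fA = 0.4, kB = 0.82, fB = 0.05) # 0.113
expected_frequency <- function(kA, fA, kB, fB) {
  abort_if(abs(kA + kB - 1) > 1e-9, "ancestry components must sum to 1")
  abort_if(!is_prob(c(fA, fB)), "allele frequencies must lie in [0, 1]")
  kA * fA + kB * fB
}

#' Define one step of a demographic chain
#'
#' @param offspring offspring population label.
#' @param parent_a,parent_b parental population labels.
#' @param kA,kB ancestry components (sum to 1).
#' @return a `demographic_step` list.
#' @export
demographic_step <- function(offspring, parent_a, parent_b, kA, kB = 1 - kA) {
  abort_if(abs(kA + kB - 1) > 1e-9, "ancestry components must sum to 1")
  abort_if(offspring %in% c(parent_a, parent_b),
           "a population cannot be its own parent")
  structure(list(offspring = offspring, parent_a = parent_a,
                 parent_b = parent_b, kA = kA, kB = kB),
            class = "demographic_step")
}

#' Expected allele frequencies along a demographic chain
#'
#' Each step combines its parents' *observed* allele frequencies (not their
#' own expectations): in the two-step European model, the late farmers'
#' observed frequencies — not their admixture expectations — feed the
#' steppe-admixture step that forms the later populations.
#'
#' @param steps list of [demographic_step()] objects, ordered so that every
#'   parent appears in `observed` .
#' @param observed data.frame with columns `population`, `allele`, `freq`
#'   giving observed frequencies for every population used as a parent.
#' @return data.frame with `offspring`, `allele`, `fexp`.
#' @export
chain_expectations <- function(steps, observed) {
  abort_if(!all(c("population", "allele", "freq") %in% names(observed)),
           "observed must have columns population, allele, freq")
  get_freq <- function(pop, al, step_label) {
    hit <- observed$population == pop & observed$allele == al
    abort_if(!any(hit), "no observed frequency for parent '", pop,
             "' (allele ", al, ") required by step '", step_label, "'")
    observed$freq[which(hit)[1L]]
  }
  alleles <- unique(observed$allele)
  rows <- do.call(rbind, lapply(steps, function(st) {
    do.call(rbind, lapply(alleles, function(al) {
      data.frame(offspring = st$offspring, allele = al,
                 fexp = expected_frequency(st$kA,
                                           get_freq(st$parent_a, al, st$offspring),
                                           st$kB,
                                           get_freq(st$parent_b, al, st$offspring)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Two-sided binomial test of deviation from the admixture expectation
#'
#' Exact two-sided binomial test of the observed allele count against the
#' admixture-informed expected frequency, using the minimum-likelihood
#' ordering (the p-value sums the probabilities of all outcomes whose point
#' probability does not exceed that of the observed count).
#'
#' @param x observed allele count.
#' @param n allele denominator (the allele-specific chromosome count).
#' @param fexp expected frequency under pure admixture.
#' @return the two-sided p-value.
#' @export
#' @examples
#' binomial_deviation_test(0, 10, 0.5) # 2 * 0.5^10
binomial_deviation_test <- function(x, n, fexp) {
  abort_if(x < 0 || x > n || n < 1, "need 0 <= x <= n, n >= 1")
  abort_if(!is_prob(fexp), "fexp must lie in [0, 1]")
  # degenerate expectations: the observed count either matches the only
  # possible outcome (p = 1) or has probability zero under the null
  if (fexp == 0) return(if (x == 0) 1 else 0)
  if (fexp == 1) return(if (x == n) 1 else 0)
  as.numeric(stats::binom.test(x, n, p = fexp,
                               alternative = "two.sided")$p.value)
}

#' Deviation tests for every offspring population and allele
#'
#' @param expectations data.frame from [chain_expectations()].
#' @param counts per-population counts from [count_epsilon()]; the
#'   allele-specific denominators (single-site for e2/e4, both-site for e3)
#'   are used as n.
#' @return data.frame with `offspring`, `allele`, `x`, `n`, `f_obs`, `fexp`,
#'   `p`, and significance `stars` at 0.05 / 0.01 / 0.001.
#' @export
deviation_tests <- function(expectations, counts) {
  rows <- lapply(seq_len(nrow(expectations)), function(r) {
    pop <- expectations$offspring[r]
    al <- expectations$allele[r]
    i <- which(counts$population == pop)
    abort_if(length(i) != 1L, "no counts for offspring population '", pop, "'")
    x <- counts[[paste0("x_", al)]][i]
    n <- counts[[paste0("n_", al)]][i]
    p <- binomial_deviation_test(x, n, expectations$fexp[r])
    data.frame(offspring = pop, allele = al, x = x, n = n,
               f_obs = x / n, fexp = expectations$fexp[r], p = p,
               stars = if (p <= 0.001) "***" else if (p <= 0.01) "**"
                       else if (p <= 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
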