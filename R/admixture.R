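#' Build a SNP panel of fixed parental allele frequencies
#'
#' @param freq_a,freq_b per-site parental allele frequencies, strictly inside
#'   (0, 1) (regularize estimated frequencies with a pseudocount first).
#' @param site_id optional site labels.
#' @return a `snp_panel` list.
#' @export
snp_panel <- function(freq_a, freq_b, site_id = NULL) {
  abort_if(length(freq_a) != length(freq_b) || length(freq_a) == 0L,
           "parental frequency vectors must be non-empty and equal length")
  abort_if(any(freq_a <= 0 | freq_a >= 1 | freq_b <= 0 | freq_b >= 1),
           "panel frequencies must lie strictly in (0, 1)")
  if (is.null(site_id)) site_id <- sprintf("site%06d", seq_along(freq_a))
  structure(list(site_id = site_id, freq_a = freq_a, freq_b = freq_b),
            class = "snp_panel")
}

#' Estimate parental allele frequencies from reference genotypes
#'
#' Pseudocount-regularized frequency `(alt + c) / (2n + 2c)` per site, which
#' keeps frequencies strictly inside (0, 1) so the admixture likelihood is
#' finite at the boundary. Sites with no called parental genotypes are
#' dropped.
#'
#' @param geno site x individual dosage matrix (0/1/2, NA allowed).
#' @param pseudocount regularization constant (default 0.5).
#' @return list with `freq` and `kept` (logical index of retained sites).
#' @export
estimate_parental_freqs <- function(geno, pseudocount = 0.5) {
  abort_if(!is.matrix(geno), "geno must be a site x individual matrix")
  abort_if(pseudocount < 0, "pseudocount must be >= 0")
  ncalled <- rowSums(!is.na(geno))
  kept <- ncalled >= 1L
  if (any(!kept)) {
    message(sum(!kept), " site(s) with no called parental genotypes dropped")
  }
  alt <- rowSums(geno, na.rm = TRUE)
  freq <- (alt[kept] + pseudocount) / (2 * ncalled[kept] + 2 * pseudocount)
  list(freq = as.numeric(freq), kept = kept)
}

# Binomial log-likelihood of ancestry proportion q for one individual.
admix_loglik <- function(q, g, fa, fb) {
  p <- q * fa + (1 - q) * fb
  sum(stats::dbinom(g, 2L, p, log = TRUE))
}

#' Supervised ancestry proportion by maximum likelihood
#'
#' With the two parental allele frequency panels held fixed, the ancestry
#' proportion q of an individual maximizes the binomial likelihood
#' `prod_l Binom(g_l | 2, q*fA_l + (1-q)*fB_l)`. The per-site success
#' probability is linear in q, so the log-likelihood is concave and the
#' maximizer unique unless fA = fB at every used site; that degenerate case
#' returns q = 0.5 with a flag. Optimization is bounded scalar (golden
#' section / parabolic) to tolerance 1e-8, with boundary refinement.
#'
#' @param g genotype dosage vector (0/1/2, NA allowed) across panel sites.
#' @param panel a [snp_panel()].
#' @return list with `q_hat`, `loglik`, `n_sites_used` and `degenerate`.
#' @export
fit_q <- function(g, panel) {
  abort_if(!inherits(panel, "snp_panel"), "panel must be a snp_panel")
  abort_if(length(g) != length(panel$freq_a),
           "genotype vector must match the panel length")
  use <- !is.na(g)
  abort_if(!any(use), "at least one non-missing site is required")
  g <- as.integer(g[use])
  abort_if(!all(g %in% 0:2), "genotypes must be dosages 0, 1 or 2")
  fa <- panel$freq_a[use]
  fb <- panel$freq_b[use]
  if (all(fa == fb)) {
    return(list(q_hat = 0.5, loglik = admix_loglik(0.5, g, fa, fb),
                n_sites_used = length(g), degenerate = TRUE))
  }
  opt <- stats::optimize(admix_loglik, c(0, 1), g = g, fa = fa, fb = fb,
                         maximum = TRUE, tol = 1e-8)
  # optimize() never evaluates the exact endpoints; adopt one if it is better
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, admix_loglik(0, g, fa, fb), admix_loglik(1, g, fa, fb))
  best <- which.max(ll)
  list(q_hat = cand[best], loglik = ll[best], n_sites_used = length(g),
       degenerate = FALSE)
}

#' Site-bootstrap standard error of the ancestry proportion
#'
#' Resamples panel sites with replacement B times and refits q; the SE is
#' the standard deviation of the bootstrap replicates.
#'
#' @param g genotype dosage vector across panel sites.
#' @param panel a [snp_panel()].
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return list with `bootstrap_se` and the replicate vector `q_boot`.
#' @export
bootstrap_q <- function(g, panel, B = 100L, seed = 1L) {
  use <- which(!is.na(g))
  abort_if(length(use) == 0L, "no non-missing sites")
  with_seed(derive_seed(seed, "bootstrap-q"), {
    qb <- vapply(seq_len(B), function(b) {
      idx <- sample(use, length(use), replace = TRUE)
      sub <- snp_panel(panel$freq_a[idx], panel$freq_b[idx])
      fit_q(g[idx], sub)$q_hat
    }, numeric(1))
    list(bootstrap_se = stats::sd(qb), q_boot = qb)
  })
}

#' Population-level admixture components
#'
#' The parent-A component kA is the mean individual ancestry proportion and
#' kB = 1 - kA, the quantities that enter the admixture-informed expected
#' allele frequency.
#'
#' @param q_hat numeric vector of per-individual ancestry proportions.
#' @return named numeric vector `c(kA, kB)`.
#' @export
population_components <- function(q_hat) {
  abort_if(length(q_hat) == 0L || !is_prob(q_hat),
           "q_hat must be non-empty proportions")
  kA <- mean(q_hat)
  c(kA = kA, kB = 1 - kA)
}

#' Fit ancestry proportions for a whole cohort
#'
#' @param geno site x individual dosage matrix.
#' @param panel a [snp_panel()].
#' @param B bootstrap replicates per individual (0 skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with `individual`, `q_hat`, `bootstrap_se`,
#'   `n_sites_used`, `degenerate`.
#' @export
fit_q_cohort <- function(geno, panel, B = 100L, seed = 1L) {
  abort_if(!is.matrix(geno), "geno must be a site x individual matrix")
  rows <- lapply(seq_len(ncol(geno)), function(j) {
    fit <- fit_q(geno[, j], panel)
    se <- if (B > 0L) {
      bootstrap_q(geno[, j], panel, B = B,
                  seed = derive_seed(seed, paste0("ind", j)))$bootstrap_se
    } else NA_real_
    data.frame(individual = j, q_hat = fit$q_hat, bootstrap_se = se,
               n_sites_used = fit$n_sites_used, degenerate = fit$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
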