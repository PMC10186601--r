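#' Construct a per-site pileup object
#'
#' A pileup holds the quality-passing reads covering one site, with their
#' terminal/interior origin. Inputs are assumed pre-filtered for base and
#' mapping quality (>20); the pileup only bookkeeps what survived.
#'
#' @param reads data.frame with columns `base` (character), `terminal`
#'   (logical), `dist` (integer distance from the nearer read end, NA for
#'   interior reads) and optionally `deaminated` (simulation ground truth).
#' @return a `site_pileup` data.frame; `depth(p)` is `nrow(p)`.
#' @export
site_pileup <- function(reads) {
  abort_if(!is.data.frame(reads) ||
           !all(c("base", "terminal", "dist") %in% names(reads)),
           "reads must have columns base, terminal, dist")
  abort_if(any(reads$terminal & is.na(reads$dist)),
           "terminal reads must carry a distance from the read end")
  class(reads) <- c("site_pileup", "data.frame")
  reads
}

#' Decide how many terminal read positions to mask for deamination
#'
#' Given observed terminal C->T mismatch rates by distance from the read end,
#' returns the smallest m such that every position at distance >= m has a
#' rate at or below the threshold; i.e. the contiguous damaged run at the
#' read end is trimmed, mirroring standard aDNA damage trimming at a 0.05
#' rate cutoff.
#'
#' @param terminal_ct_rates numeric vector of C->T rates, element k giving the
#'   rate at distance k-1 from the read end.
#' @param threshold trim positions with rates above this value (default 0.05).
#' @return integer number of terminal positions to mask.
#' @export
#' @examples
#' decide_trim(c(0.20, 0.08, 0.03, 0.01)) # 2
decide_trim <- function(terminal_ct_rates, threshold = 0.05) {
  if (length(terminal_ct_rates) == 0L) return(0L)
  abort_if(!is_prob(terminal_ct_rates), "rates must lie in [0, 1]")
  over <- which(terminal_ct_rates > threshold)
  if (length(over) == 0L) 0L else max(over)
}

#' Mask the m outermost terminal positions of a pileup
#'
#' @param pileup a [site_pileup()].
#' @param m number of terminal positions to remove (reads whose distance from
#'   the nearer read end is below m are dropped).
#' @return the trimmed `site_pileup`.
#' @export
apply_trim <- function(pileup, m) {
  abort_if(m < 0, "m must be >= 0")
  if (m == 0L || nrow(pileup) == 0L) return(pileup)
  keep <- !(pileup$terminal & pileup$dist < m)
  out <- pileup[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pileup)
  out
}

#' Estimate the terminal C->T damage profile from a set of pileups
#'
#' For each distance from the read end, pools reads across samples whose
#' interior reads are confidently cytosine (so a terminal T is attributable
#' to deamination rather than a true T allele) and reports the T fraction.
#'
#' @param pileups list of [site_pileup()] objects from C-contexts.
#' @param min_interior_c minimum interior C purity for a pileup to contribute.
#' @return numeric vector of C->T rates indexed by distance from read end
#'   (element k = distance k-1); length 0 if no terminal reads observed.
#' @export
estimate_damage_profile <- function(pileups, min_interior_c = 0.9) {
  tc <- list()
  for (p in pileups) {
    interior <- p[!p$terminal, , drop = FALSE]
    if (nrow(interior) == 0L) next
    if (mean(interior$base == "C") < min_interior_c) next
    term <- p[p$terminal, , drop = FALSE]
    if (nrow(term) == 0L) next
    tc[[length(tc) + 1L]] <- term[, c("base", "dist")]
  }
  if (length(tc) == 0L) return(numeric())
  term <- do.call(rbind, tc)
  dmax <- max(term$dist)
  vapply(0:dmax, function(d) {
    at <- term[term$dist == d, , drop = FALSE]
    if (nrow(at) == 0L) return(0)
    mean(at$base == "T")
  }, numeric(1))
}

#' Call a diploid genotype from a site pileup
#'
#' Maximum-likelihood diploid call among \{AA, AB, BB\} for the two
#' segregating bases under a binomial read-sampling model with symmetric
#' error: reads from a homozygote show the other allele with probability
#' `base_error`; reads from a heterozygote show either allele with
#' probability 1/2. QUAL is the phred-scaled complement of the genotype
#' posterior under a uniform prior over the three genotypes. Genotypes at
#' depth below `min_depth` are reported missing, and no pseudo-haploid call
#' is ever emitted: the result is a diploid pair or missing.
#'
#' @param pileup a [site_pileup()] (trim first with [apply_trim()]).
#' @param base_error symmetric per-read error probability, in (0, 0.5).
#' @param min_depth minimum depth for a call (default 3, the aDNA-grade
#'   threshold below which hets cannot be distinguished reliably).
#' @param site_alleles optional two bases defining the site; defaults to the
#'   two most frequent observed bases. Additional observed bases are dropped
#'   with a warning.
#' @return a `genotype_call` list: `allele1`, `allele2` (NA if missing),
#'   `missing`, `depth`, `qual`.
#' @export
call_genotype <- function(pileup, base_error = 0.005, min_depth = 3L,
                          site_alleles = NULL) {
  abort_if(base_error <= 0 || base_error >= 0.5,
           "base_error must lie in (0, 0.5)")
  depth <- nrow(pileup)
  miss <- function() structure(list(allele1 = NA_character_,
                                    allele2 = NA_character_, missing = TRUE,
                                    depth = depth, qual = NA_real_),
                               class = "genotype_call")
  if (depth < min_depth) return(miss())
  tab <- sort(table(pileup$base), decreasing = TRUE)
  if (is.null(site_alleles)) {
    if (length(tab) > 2L) {
      warning("more than two observed bases; using the two most frequent",
              call. = FALSE)
    }
    site_alleles <- names(tab)[seq_len(min(2L, length(tab)))]
    if (length(site_alleles) == 1L) site_alleles <- c(site_alleles, NA)
  }
  nA <- sum(pileup$base == site_alleles[1L])
  nB <- if (is.na(site_alleles[2L])) 0L else sum(pileup$base == site_alleles[2L])
  used <- nA + nB
  if (used < min_depth) return(miss())
  e <- base_error
  ll <- c(AA = nA * log(1 - e) + nB * log(e),
          AB = used * log(0.5),
          BB = nA * log(e) + nB * log(1 - e))
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  g <- which.max(post)
  pair <- switch(names(ll)[g],
                 AA = c(site_alleles[1L], site_alleles[1L]),
                 AB = sort(c(site_alleles[1L], site_alleles[2L])),
                 BB = c(site_alleles[2L], site_alleles[2L]))
  qual <- -10 * log10(max(1 - post[g], 1e-300))
  structure(list(allele1 = pair[1L], allele2 = pair[2L], missing = FALSE,
                 depth = depth, qual = as.numeric(qual)),
            class = "genotype_call")
}

#' Keep a sample for APOE analysis if at least one focal site was called
#'
#' Samples missing a diploid genotype at both polymorphic sites carry no
#' usable allele information and are removed.
#'
#' @param call_rs429358,call_rs7412 `genotype_call` objects (or NULL for a
#'   site with no data).
#' @return TRUE to keep, FALSE to drop.
#' @export
sample_passes_apoe_filter <- function(call_rs429358, call_rs7412) {
  ok <- function(cl) !is.null(cl) && !isTRUE(cl$missing)
  ok(call_rs429358) || ok(call_rs7412)
}

#' Sample QC for the chromosome-scale selection scans
#'
#' High-coverage samples only: chromosome site coverage of at least
#' `cov_min` and mean depth strictly above `depth_min` in the 100-kb window
#' around the focal locus.
#'
#' @param coverage_fraction fraction of chromosome sites covered, in [0, 1].
#' @param local_mean_depth mean depth in the window around the locus.
#' @param cov_min minimum coverage fraction (default 0.70).
#' @param depth_min depth threshold; samples must exceed it (default 5).
#' @return TRUE to keep, FALSE to drop.
#' @export
#' @examples
#' sample_passes_scan_qc(0.69, 10) # FALSE
#' sample_passes_scan_qc(0.90, 5)  # FALSE: strictly greater than 5 required
sample_passes_scan_qc <- function(coverage_fraction, local_mean_depth,
                                  cov_min = 0.70, depth_min = 5) {
  abort_if(!is_prob(coverage_fraction), "coverage fraction must lie in [0, 1]")
  coverage_fraction >= cov_min && local_mean_depth > depth_min
}
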