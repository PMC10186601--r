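#' Weir-Cockerham FST variance components for one site, two populations
#'
#' Implements the Weir & Cockerham (1984) variance-component estimator from
#' diploid genotype counts, including the within-individual (heterozygosity)
#' component: `a` (among populations), `b` (among individuals within
#' populations), `c` (within individuals), and `theta_hat = a / (a + b + c)`.
#' Sites monomorphic in both populations (a + b + c = 0) are undefined and
#' flagged, as are sites where either population has fewer than 2 called
#' chromosomes or the average sample size does not exceed one individual.
#' Negative estimates are retained (not clamped): clamping would distort the
#' chromosome background distribution the outlier scan is built on.
#'
#' @param n0_a,n1_a,n2_a genotype counts (hom-ref, het, hom-alt) in
#'   population A; vectors for a site-wise scan.
#' @param n0_b,n1_b,n2_b genotype counts in population B.
#' @return data.frame with components `a`, `b`, `c`, `theta_hat` and a
#'   `defined` flag (theta_hat is NA where undefined).
#' @export
#' @examples
#' wc_fst_site(0, 0, 10, 10, 0, 0) # fixed difference: theta_hat = 1
wc_fst_site <- function(n0_a, n1_a, n2_a, n0_b, n1_b, n2_b) {
  len <- length(n0_a)
  abort_if(!all(lengths(list(n1_a, n2_a, n0_b, n1_b, n2_b)) == len),
           "genotype count vectors must have equal length")
  abort_if(any(c(n0_a, n1_a, n2_a, n0_b, n1_b, n2_b) < 0, na.rm = TRUE),
           "genotype counts must be non-negative")
  nA <- n0_a + n1_a + n2_a
  nB <- n0_b + n1_b + n2_b
  ok <- nA >= 1 & nB >= 1
  r <- 2
  nbar <- (nA + nB) / r
  ntot <- nA + nB
  nc <- (ntot - (nA^2 + nB^2) / ntot) / (r - 1)
  pA <- (n1_a + 2 * n2_a) / (2 * nA)
  pB <- (n1_b + 2 * n2_b) / (2 * nB)
  hA <- n1_a / nA
  hB <- n1_b / nB
  pbar <- (nA * pA + nB * pB) / ntot
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / ntot
  ok <- ok & nbar > 1 & nc > 0
  inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  defined <- ok & !is.na(denom) & denom != 0
  theta <- ifelse(defined, a / denom, NA_real_)
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  data.frame(a = a, b = b, c = cc, theta_hat = theta, defined = defined)
}

#' Empirical FST percentile background of a chromosome
#'
#' Percentile thresholds (linear interpolation between order statistics,
#' quantile type 7) over the defined per-site FST values; focal sites are
#' flagged when strictly above a threshold.
#'
#' @param theta per-site FST values (NA = undefined, excluded).
#' @param focal focal-site FST value(s) to rank against the background.
#' @param levels percentile levels (default 0.95 and 0.975, the single- and
#'   double-star outlier thresholds).
#' @return list with `thresholds`, `n_defined` and a data.frame `focal`
#'   (`value`, one logical column per threshold, `percentile_rank`).
#' @export
fst_background <- function(theta, focal = numeric(), levels = c(0.95, 0.975)) {
  vals <- theta[!is.na(theta)]
  abort_if(length(vals) < 20L,
           "need at least 20 defined FST values for a background")
  thr <- stats::quantile(vals, levels, names = FALSE, type = 7)
  names(thr) <- paste0("p", levels * 100)
  focal_df <- if (length(focal)) {
    flags <- vapply(seq_along(levels),
                    function(i) focal > thr[i], logical(length(focal)))
    flags <- matrix(flags, nrow = length(focal))
    colnames(flags) <- paste0("above_", names(thr))
    rank <- vapply(focal, function(v) mean(vals <= v), numeric(1))
    data.frame(value = focal, flags, percentile_rank = rank)
  } else {
    data.frame(value = numeric(), percentile_rank = numeric())
  }
  list(thresholds = thr, n_defined = length(vals), focal = focal_df)
}

#' Tajima's normalizing constants for a sample of n chromosomes
#'
#' @param n_chromosomes number of sampled chromosomes (>= 4).
#' @return named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n_chromosomes) {
  n <- n_chromosomes
  abort_if(n < 4, "need at least 4 chromosomes")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for one window
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard normalizing
#' constants derived from the chromosome sample size. Mean pairwise diversity
#' pi is computed from per-site derived-allele counts x as the sum of
#' `2*x*(n-x) / (n*(n-1))`. Windows with no segregating sites are undefined.
#'
#' @param counts derived-allele counts of the window's segregating sites
#'   (each in `1..n-1`).
#' @param n_chromosomes number of sampled chromosomes.
#' @return list with `S`, `pi`, `D` (NA when S = 0) and `defined`.
#' @export
tajimas_d <- function(counts, n_chromosomes) {
  n <- n_chromosomes
  abort_if(n < 4, "need at least 4 chromosomes")
  S <- length(counts)
  if (S == 0L) return(list(S = 0L, pi = 0, D = NA_real_, defined = FALSE))
  abort_if(any(counts < 1 | counts > n - 1),
           "derived-allele counts must lie in 1..n-1")
  k <- tajima_constants(n)
  pi <- sum(2 * counts * (n - counts) / (n * (n - 1)))
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(S = S, pi = pi, D = (pi - S / k$a1) / denom, defined = TRUE)
}

#' Windowed Tajima's D scan with chromosome percentile background
#'
#' Sites are tiled into half-open windows `[start, start + window_len)` from
#' origin 0 (VCF 1-based positions are converted internally, so position
#' `start + window_len` in 1-based coordinates opens the next window). D is
#' computed per window; the chromosome background is summarized by its 5th,
#' 25th, 50th, 75th and 95th percentiles over defined windows, and the focal
#' locus (a set of window indices, e.g. the three 15-kb windows spanning
#' TOMM40-APOE-APOC1) is summarized by the mean of its defined D values,
#' with outlier flags against the 5th/95th percentiles and a below-median
#' indicator.
#'
#' @param sites data.frame with columns `pos` (1-based bp) and `count`
#'   (derived-allele count).
#' @param n_chromosomes number of sampled chromosomes.
#' @param window_len window length in bp (default 15000).
#' @param focal_windows integer 0-based indices of the focal windows.
#' @param n_windows optional total number of tiled windows (so trailing
#'   empty windows are represented); defaults to the last occupied window.
#' @return list with `windows` (per-window data.frame: `window`, `start`,
#'   `S`, `pi`, `D`) and `summary` (percentiles, `locus_mean_D`, flags
#'   `below_p5`, `above_p95`, `below_median`).
#' @export
windowed_scan <- function(sites, n_chromosomes, window_len = 15000L,
                          focal_windows = integer(), n_windows = NULL) {
  abort_if(!all(c("pos", "count") %in% names(sites)),
           "sites must have columns pos and count")
  widx <- if (nrow(sites)) (sites$pos - 1L) %/% window_len else integer()
  last <- if (is.null(n_windows)) {
    max(c(widx, focal_windows, 0L))
  } else n_windows - 1L
  wins <- 0:last
  rows <- lapply(wins, function(w) {
    d <- tajimas_d(sites$count[widx == w], n_chromosomes)
    data.frame(window = w, start = w * window_len, S = d$S, pi = d$pi, D = d$D)
  })
  windows <- do.call(rbind, rows)
  rownames(windows) <- NULL
  dvals <- windows$D[!is.na(windows$D)]
  qs <- if (length(dvals)) {
    stats::quantile(dvals, c(0.05, 0.25, 0.50, 0.75, 0.95), names = FALSE,
                    type = 7)
  } else rep(NA_real_, 5L)
  names(qs) <- c("p5", "p25", "p50", "p75", "p95")
  focal_d <- windows$D[windows$window %in% focal_windows]
  locus_mean <- if (all(is.na(focal_d)) || length(focal_d) == 0L) {
    NA_real_
  } else mean(focal_d, na.rm = TRUE)
  list(windows = windows,
       summary = list(percentiles = qs, locus_mean_D = locus_mean,
                      locus_defined = !is.na(locus_mean),
                      below_p5 = isTRUE(locus_mean < qs[["p5"]]),
                      above_p95 = isTRUE(locus_mean > qs[["p95"]]),
                      below_median = isTRUE(locus_mean < qs[["p50"]])))
}
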