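# Independent oracles used across the suite. Each is a direct transcription
# of a published definition, kept separate from the implementation path it
# checks.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins, probability ordering.
fisher_enum_oracle <- function(x_a, n_a, x_b, n_b) {
  total_alt <- x_a + x_b
  ks <- max(0L, total_alt - n_b):min(n_a, total_alt)
  pr <- dhyper(ks, n_a, n_b, total_alt)
  obs <- dhyper(x_a, n_a, n_b, total_alt)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Two-sided binomial p by pmf enumeration, minimum-likelihood ordering.
binom_enum_oracle <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up adjusted values from the direct formula:
# sorted ascending, adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_formula_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Weir-Cockerham (1984) two-population components via the ANOVA
# mean-squares route (MSP / MSI / MSG on allele indicators), an algebraic
# rearrangement independent of the p-bar/s^2/h-bar coding.
wc_anova_oracle <- function(dose_a, dose_b) {
  nA <- length(dose_a); nB <- length(dose_b)
  N <- nA + nB; r <- 2
  pA <- sum(dose_a) / (2 * nA)
  pB <- sum(dose_b) / (2 * nB)
  pbar <- (2 * nA * pA + 2 * nB * pB) / (2 * N)
  ssg <- sum(dose_a * (2 - dose_a)) / 2 + sum(dose_b * (2 - dose_b)) / 2
  msg <- ssg / N
  ssi <- sum(2 * (dose_a / 2 - pA)^2) + sum(2 * (dose_b / 2 - pB)^2)
  msi <- ssi / (N - r)
  ssp <- 2 * nA * (pA - pbar)^2 + 2 * nB * (pB - pbar)^2
  msp <- ssp / (r - 1)
  nc <- (N - (nA^2 + nB^2) / N) / (r - 1)
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  c <- msg
  list(a = a, b = b, c = c,
       theta = if (a + b + c == 0) NA_real_ else a / (a + b + c))
}

# dosage vector -> genotype class counts (hom-ref, het, hom-alt)
dose_counts <- function(dose) {
  c(sum(dose == 0L), sum(dose == 1L), sum(dose == 2L))
}

# Tajima (1989) D computed end-to-end from its published formulas,
# written out independently of tajimas_d()/tajima_constants().
tajima_direct_oracle <- function(counts, n) {
  S <- length(counts)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi <- sum(counts * (n - counts)) / choose(n, 2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
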