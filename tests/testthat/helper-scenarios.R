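# Shared scenario builders for the tests.

whg_like <- function(n = 25L) population_spec("WHG", 0.00, 0.60, 0.40, n)
ef_like  <- function(n = 90L) population_spec("EF", 0.08, 0.87, 0.05, n)

lf_spec <- function(n = 110L, k_a = 0.18) {
  admixture_spec(whg_like(1L), ef_like(1L), k_a = k_a, n_offspring = n)
}

# A small configuration for pipeline plumbing tests (stage toggles, schema,
# failure handling); statistical behaviour is tested at full size elsewhere.
small_config <- function(seed = 1L, outdir = tempfile("apoeadmix_small_")) {
  cfg <- default_config(seed = seed, outdir = outdir)
  for (nm in names(cfg$populations)) cfg$populations[[nm]]$n <- 10L
  cfg$admixed$LF$n <- 12L
  cfg$admixed$Modern$n <- 12L
  cfg$panel$n_sites <- 150L
  cfg$panel$n_ref <- 15L
  cfg$admix_bootstrap <- 5L
  cfg$scan$n_windows <- 12L
  cfg$scan$focal_windows <- c(4L, 5L, 6L)
  cfg$scan$n_background_sites <- 120L
  cfg$scan$n_per_pop <- 25L
  cfg
}

# Draw an unstructured two-population genotype-count table for nb sites with
# shared allele frequencies, plus an optional differentiated focal site.
draw_fst_sites <- function(nb, n_per_pop, p_focal = NULL) {
  p <- runif(nb, 0.05, 0.95)
  draw <- function(p, n) {
    g <- matrix(rbinom(length(p) * n, 2L, rep(p, n)), nrow = length(p))
    cbind(rowSums(g == 0L), rowSums(g == 1L), rowSums(g == 2L))
  }
  list(bg_a = draw(p, n_per_pop), bg_b = draw(p, n_per_pop),
       focal_a = if (!is.null(p_focal)) draw(p_focal[1L], n_per_pop),
       focal_b = if (!is.null(p_focal)) draw(p_focal[2L], n_per_pop))
}

# One replicate of the five-population scenario at the statistical layer
# (truth genotypes, no pileup noise): cohorts -> epsilon counts -> supervised
# admixture components -> chain expectations -> deviation tests.
# e4_shift adds a post-admixture e4 increase (at e3's expense) to Modern.
# parent_freqs = "observed" plugs each parent's sampled allele frequencies
# into fexp (the full estimation chain, with its unpropagated uncertainty);
# "true" plugs in the generator's parental frequencies, isolating the
# deviation test itself.
stat_layer_run <- function(seed, e4_shift = 0, parent_freqs = "observed") {
  whg_f <- c(0, 0.6, 0.4)
  ef_f <- c(0.08, 0.87, 0.05)
  stp_f <- c(0.06, 0.72, 0.22)
  lf_f <- 0.18 * whg_f + 0.82 * ef_f
  mod_f <- 0.5 * lf_f + 0.5 * stp_f + c(0, -e4_shift, e4_shift)
  cohorts <- list(
    WHG = draw_diploid_apoe(population_spec("WHG", whg_f[1], whg_f[2],
                                            whg_f[3], 25L), seed),
    EF = draw_diploid_apoe(population_spec("EF", ef_f[1], ef_f[2],
                                           ef_f[3], 90L), seed),
    Steppe = draw_diploid_apoe(population_spec("Steppe", stp_f[1], stp_f[2],
                                               stp_f[3], 45L), seed),
    LF = draw_admixed_cohort(
      admixture_spec(population_spec("WHG", whg_f[1], whg_f[2], whg_f[3], 1L),
                     population_spec("EF", ef_f[1], ef_f[2], ef_f[3], 1L),
                     k_a = 0.18, n_offspring = 110L), seed, name = "LF"),
    Modern = draw_diploid_apoe(population_spec("Modern", mod_f[1], mod_f[2],
                                               mod_f[3], 90L), seed))
  counts <- do.call(rbind, lapply(names(cohorts), function(nm) {
    cbind(population = nm,
          count_epsilon(cohorts[[nm]][, c("rs429358_C", "rs7412_T")])[, -1])
  }))
  k_true <- c(LF = 0.18, Modern = 0.5)
  kA <- vapply(names(k_true), function(nm) {
    pan <- simulate_snp_panel(2000L, 0.1,
                              derive_seed(seed, paste0("pan", nm)),
                              n_ref = 50L)
    panel <- snp_panel(estimate_parental_freqs(pan$geno_a)$freq,
                       estimate_parental_freqs(pan$geno_b)$freq)
    n <- if (nm == "LF") 110L else 90L
    coh <- draw_panel_cohort(pan$freq_a, pan$freq_b, k_true[[nm]], n,
                             derive_seed(seed, paste0("coh", nm)))
    population_components(fit_q_cohort(coh, panel, B = 0)$q_hat)[["kA"]]
  }, numeric(1))
  observed <- if (identical(parent_freqs, "true")) {
    data.frame(
      population = rep(c("WHG", "EF", "Steppe", "LF"), each = 3),
      allele = rep(c("e2", "e3", "e4"), 4),
      freq = c(whg_f, ef_f, stp_f, lf_f))
  } else {
    epsilon_frequencies(counts)[, c("population", "allele", "freq")]
  }
  steps <- list(
    demographic_step("LF", "WHG", "EF", kA = kA[["LF"]]),
    demographic_step("Modern", "LF", "Steppe", kA = kA[["Modern"]]))
  exps <- chain_expectations(steps, observed)
  deviation_tests(exps, counts)
}
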