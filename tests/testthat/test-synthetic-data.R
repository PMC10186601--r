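test_that("population specs validate haplotype frequencies", {
  expect_error(population_spec("X", 0.5, 0.5, 0.5, 10), "sum to 1")
  expect_error(population_spec("X", -0.1, 0.9, 0.2, 10), "\\[0, 1\\]")
  expect_error(population_spec("X", 0.1, 0.7, 0.2, 0), "positive integer")
  expect_error(admixture_spec(whg_like(), ef_like(), k_a = 0.3, k_b = 0.3),
               "equal 1")
})

test_that("an e2-free population never carries the rs7412-T allele", {
  g <- draw_diploid_apoe(whg_like(500L), seed = 1)
  expect_true(all(g$rs7412_T == 0L))
  expect_false(any(c(g$hap1, g$hap2) == "e2"))
})

test_that("degenerate frequencies give homozygous cohorts", {
  g <- draw_diploid_apoe(population_spec("all4", 0, 0, 1, 50L), seed = 1)
  expect_true(all(g$rs429358_C == 2L))
  expect_true(all(g$hap1 == "e4" & g$hap2 == "e4"))
})

test_that("sampled haplotype frequencies match the spec within 3 binomial SDs", {
  f <- c(0.1, 0.7, 0.2)
  n <- 5000L
  g <- draw_diploid_apoe(population_spec("P", f[1], f[2], f[3], n), seed = 1)
  haps <- c(g$hap1, g$hap2)
  for (i in 1:3) {
    al <- c("e2", "e3", "e4")[i]
    se <- sqrt(f[i] * (1 - f[i]) / (2 * n))
    expect_lt(abs(mean(haps == al) - f[i]), 3 * se)
  }
})

test_that("haplotype-to-site mapping is the e2/e3/e4 bijection", {
  g <- draw_diploid_apoe(population_spec("P", 0.2, 0.5, 0.3, 300L), seed = 7)
  # reconstruct haplotype counts from site dosages and compare to truth
  expect_identical(g$rs429358_C,
                   (g$hap1 == "e4") + (g$hap2 == "e4"))
  expect_identical(g$rs7412_T,
                   (g$hap1 == "e2") + (g$hap2 == "e2"))
})

test_that("generators are byte-identical under the same seed", {
  s <- population_spec("P", 0.1, 0.7, 0.2, 40L)
  expect_identical(draw_diploid_apoe(s, 3), draw_diploid_apoe(s, 3))
  expect_false(identical(draw_diploid_apoe(s, 3), draw_diploid_apoe(s, 4)))
  w <- window_sim_spec(n_windows = 5L)
  expect_identical(simulate_windows(w, 11), simulate_windows(w, 11))
  m <- sequencing_model()
  expect_identical(simulate_pileup(c("T", "C"), m, 5),
                   simulate_pileup(c("T", "C"), m, 5))
})

test_that("admixed cohorts follow the linear admixture expectation", {
  # k_a = 1 boundary: cohort distribution equals parent A's
  g1 <- draw_admixed_cohort(
    admixture_spec(whg_like(1L), ef_like(1L), k_a = 1, n_offspring = 2000L),
    seed = 2)
  expect_false(any(c(g1$hap1, g1$hap2) == "e2")) # WHG-like carries no e2
  se <- sqrt(0.4 * 0.6 / 4000)
  expect_lt(abs(mean(c(g1$hap1, g1$hap2) == "e4") - 0.4), 3 * se)

  # k_a = 0.18: expected e4 frequency is 0.18*0.4 + 0.82*0.05 = 0.113
  g <- draw_admixed_cohort(lf_spec(5000L), seed = 2)
  fexp <- 0.18 * 0.4 + 0.82 * 0.05
  se <- sqrt(fexp * (1 - fexp) / 10000)
  expect_lt(abs(mean(c(g$hap1, g$hap2) == "e4") - fexp), 3 * se)
  expect_true(all(g$q_true %in% c(0, 0.5, 1)))
})

test_that("noise-free pileups contain only true alleles and determine genotypes", {
  m <- sequencing_model(mean_depth = 20, base_error = 0, deamination_rate = 0)
  g <- draw_diploid_apoe(population_spec("P", 0.2, 0.5, 0.3, 30L), seed = 9)
  for (i in seq_len(nrow(g))) {
    true <- c(c("T", "C")[1 + (g$rs429358_C[i] >= 1)],
              c("T", "C")[1 + (g$rs429358_C[i] == 2)])
    p <- simulate_pileup(true, m, seed = 100 + i)
    expect_true(all(p$base %in% true))
    if (g$rs429358_C[i] == 1L) next # het: both alleles possible
    expect_length(unique(p$base), 1L)
  }
})

test_that("deep heterozygote pileups show both alleles", {
  m <- sequencing_model(mean_depth = 30, base_error = 0, deamination_rate = 0)
  # P(missing an allele) <= 2 * 0.5^30 per draw; 20 draws still ~0 failures
  both <- vapply(1:20, function(s) {
    p <- simulate_pileup(c("T", "C"), m, seed = s)
    all(c("T", "C") %in% p$base)
  }, logical(1))
  expect_true(all(both))
})

test_that("terminal deamination produces T reads at about the damage rate", {
  m <- sequencing_model(mean_depth = 2000, base_error = 0,
                        deamination_rate = 0.3, damaged_terminal_len = 3L)
  p <- simulate_pileup(c("C", "C"), m, seed = 4)
  term <- p[p$terminal, ]
  opportunities <- nrow(term)
  rate <- mean(term$base == "T")
  expect_gt(opportunities, 50)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / opportunities))
  expect_true(all(p$base[p$deaminated] == "T"))
  expect_true(all(!p$deaminated[!p$terminal]))
})

test_that("SNP panel divergence matches the Balding-Nichols target", {
  expect_error(simulate_snp_panel(0, 0.1, 1), ">= 1")
  expect_error(simulate_snp_panel(10, 0, 1), "\\(0, 1\\)")

  tiny <- simulate_snp_panel(500L, 0.0005, seed = 1)
  expect_lt(max(abs(tiny$freq_a - tiny$freq_b)), 0.15)
  expect_lt(mean(abs(tiny$freq_a - tiny$freq_b)), 0.02)

  pan <- simulate_snp_panel(10000L, 0.1, seed = 1)
  hudson <- mean((pan$freq_a - pan$freq_b)^2) /
    mean(pan$freq_a * (1 - pan$freq_b) + pan$freq_b * (1 - pan$freq_a))
  expect_lt(abs(hudson - 0.1), 0.02)
  expect_equal(dim(pan$geno_a), c(10000L, 20L))
  expect_true(all(pan$geno_a %in% 0:2))
})

test_that("windowed site simulation respects theta and the sweep skew", {
  none <- simulate_windows(window_sim_spec(theta_w = 0, n_windows = 10L), 1)
  expect_identical(nrow(none), 0L)

  spec <- window_sim_spec(n_chromosomes = 20L, theta_w = 15, n_windows = 200L,
                          sweep_windows = 0:99, sweep_rare_skew = 3)
  s <- simulate_windows(spec, 5)
  sweep <- s[s$window < 100, ]
  neutral <- s[s$window >= 100, ]
  # sweep windows lose segregating sites in proportion to the skew...
  expect_lt(nrow(sweep), nrow(neutral) / 2)
  # ...and what remains is skewed towards rare variants
  expect_lt(mean(sweep$count), mean(neutral$count))
  expect_true(all(s$count >= 1 & s$count <= 19))
  expect_true(all(s$pos >= 1 & s$pos <= 200 * 15000))
})
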