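make_pileup <- function(bases, dists = rep(NA_integer_, length(bases))) {
  site_pileup(data.frame(base = bases, terminal = !is.na(dists),
                         dist = dists, stringsAsFactors = FALSE))
}

test_that("trim decision masks the contiguous damaged run at the read end", {
  expect_identical(decide_trim(c(0.20, 0.08, 0.03, 0.01)), 2L)
  expect_identical(decide_trim(rep(0, 5)), 0L)
  expect_identical(decide_trim(c(0.3, 0.2, 0.1, 0.06)), 4L)
  expect_identical(decide_trim(numeric()), 0L)
  # an interior blip above threshold still forces trimming up to it
  expect_identical(decide_trim(c(0.2, 0.04, 0.06, 0.01)), 3L)
  expect_identical(decide_trim(c(0.04, 0.04), threshold = 0.03), 2L)
})

test_that("apply_trim removes only reads within m of the read end", {
  p <- make_pileup(c("T", "T", "C", rep("C", 7)),
                   c(0L, 1L, 1L, rep(NA_integer_, 7)))
  expect_identical(apply_trim(p, 0), p)
  t2 <- apply_trim(p, 2)
  expect_identical(nrow(t2), 7L)
  expect_true(all(!t2$terminal))
})

test_that("trimming removes all deamination-origin T reads from simulated damage", {
  m <- sequencing_model(mean_depth = 40, base_error = 0,
                        deamination_rate = 0.5, damaged_terminal_len = 2L)
  for (s in 1:10) {
    p <- simulate_pileup(c("C", "C"), m, seed = s)
    trimmed <- apply_trim(p, m$damaged_terminal_len)
    expect_false(any(trimmed$deaminated))
    expect_true(all(trimmed$base == "C"))
  }
})

test_that("genotype calls follow the binomial likelihood and depth filter", {
  expect_true(call_genotype(make_pileup(c("T", "T")), 0.01)$missing)

  hom <- call_genotype(make_pileup(rep("T", 10)), 0.01)
  expect_false(hom$missing)
  expect_identical(c(hom$allele1, hom$allele2), c("T", "T"))

  het5 <- call_genotype(make_pileup(c(rep("T", 5), rep("C", 5))), 0.01)
  het10 <- call_genotype(make_pileup(c(rep("T", 10), rep("C", 10))), 0.01)
  expect_setequal(c(het5$allele1, het5$allele2), c("T", "C"))
  expect_setequal(c(het10$allele1, het10$allele2), c("T", "C"))
  expect_gt(het10$qual, het5$qual) # doubling the evidence raises confidence
})

test_that("more than two observed bases falls back to the two most frequent", {
  p <- make_pileup(c(rep("T", 6), rep("C", 5), "G"))
  expect_warning(cl <- call_genotype(p, 0.01), "two most frequent")
  expect_setequal(c(cl$allele1, cl$allele2), c("T", "C"))
})

test_that("noise-free calls recover the generator truth; calls are diploid or missing", {
  m <- sequencing_model(mean_depth = 15, base_error = 0, deamination_rate = 0)
  g <- draw_diploid_apoe(population_spec("P", 0.2, 0.5, 0.3, 40L), seed = 3)
  for (i in seq_len(nrow(g))) {
    true <- sort(c(c("T", "C")[1 + (g$rs429358_C[i] >= 1)],
                   c("T", "C")[1 + (g$rs429358_C[i] == 2)]))
    p <- simulate_pileup(true, m, seed = 200 + i)
    cl <- call_genotype(p, base_error = 0.001, site_alleles = c("T", "C"))
    # diploid-or-missing: never a single-allele (pseudo-haploid) call
    expect_identical(is.na(cl$allele1), is.na(cl$allele2))
    if (cl$missing) next
    expect_identical(sort(c(cl$allele1, cl$allele2)), true)
  }
})

test_that("call concordance is non-decreasing in depth", {
  err <- 0.02
  depths <- c(3, 6, 12, 25)
  conc <- vapply(seq_along(depths), function(k) {
    m <- sequencing_model(mean_depth = depths[k], base_error = err,
                          deamination_rate = 0)
    hits <- vapply(1:300, function(s) {
      p <- simulate_pileup(c("T", "C"), m, seed = 1000 * k + s)
      cl <- call_genotype(p, base_error = err, site_alleles = c("T", "C"))
      !cl$missing && !is.na(cl$allele1) && cl$allele1 != cl$allele2
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(conc) > -0.03)) # monotone up to simulation noise
  expect_gt(conc[length(conc)], conc[1])
})

test_that("APOE sample filter keeps any sample with at least one called site", {
  called <- call_genotype(make_pileup(rep("T", 5)), 0.01)
  missing <- call_genotype(make_pileup("T"), 0.01)
  expect_false(sample_passes_apoe_filter(missing, missing))
  expect_true(sample_passes_apoe_filter(called, missing))
  expect_true(sample_passes_apoe_filter(called, called))
})

test_that("scan QC enforces coverage and strict local depth thresholds", {
  expect_false(sample_passes_scan_qc(0.69, 10))
  expect_false(sample_passes_scan_qc(0.90, 5.0)) # depth must exceed 5
  expect_true(sample_passes_scan_qc(0.70, 5.01))
  expect_true(sample_passes_scan_qc(1.0, 100))
})

test_that("damage profiles are recovered from C-context pileups", {
  m <- sequencing_model(mean_depth = 30, base_error = 0,
                        deamination_rate = 0.35, damaged_terminal_len = 2L)
  piles <- lapply(1:80, function(s) simulate_pileup(c("C", "C"), m, seed = s))
  prof <- estimate_damage_profile(piles)
  expect_gte(length(prof), 2L)
  expect_gt(prof[1], 0.05)
  expect_gt(prof[2], 0.05)
  expect_true(all(prof[-(1:2)] == 0))
  expect_identical(decide_trim(prof), 2L)
})
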