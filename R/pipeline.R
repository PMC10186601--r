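#' Default pipeline configuration
#'
#' A declarative list collecting every filter threshold and scenario
#' parameter of the pipeline: aDNA genotype filters (minimum depth 3,
#' site QUAL > 50, chromosome coverage >= 0.70, local mean depth > 5,
#' deamination trim threshold 0.05), the 90% confidence level, the 0.05 FDR,
#' the 15-kb scan windows, the demographic chain and the synthetic
#' five-population scenario (WHG, EF, LF, Steppe, Modern) that emulates the
#' European APOE study design: an epsilon-2-free, epsilon-4-rich
#' hunter-gatherer population, early farmers with the lowest epsilon-4 and
#' highest epsilon-3 frequency, late farmers formed as 0.18 WHG + 0.82 EF,
#' and a modern gene pool formed from late farmers and steppe herders.
#'
#' @param seed integer run seed.
#' @param outdir output directory.
#' @return a config list; see [validate_config()] for the invariants.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("apoeadmix_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("simulate", "genotype", "freq", "admix", "expect", "scan"),
    filters = list(min_depth = 3L, qual_min = 50, cov_min = 0.70,
                   depth_min = 5, deamination_threshold = 0.05,
                   caller_base_error = 0.005),
    allow_below_default_depth = FALSE,
    ci_level = 0.90,
    fdr_q = 0.05,
    sequencing = list(mean_depth = 5, base_error = 0.005,
                      deamination_rate = 0.15, damaged_terminal_len = 2L,
                      read_len = 60L),
    populations = list(
      WHG    = list(f_e2 = 0.00, f_e3 = 0.60, f_e4 = 0.40, n = 25L),
      EF     = list(f_e2 = 0.08, f_e3 = 0.87, f_e4 = 0.05, n = 90L),
      Steppe = list(f_e2 = 0.06, f_e3 = 0.72, f_e4 = 0.22, n = 45L)),
    admixed = list(
      LF     = list(parent_a = "WHG", parent_b = "EF", k_a = 0.18, n = 110L),
      Modern = list(parent_a = "LF", parent_b = "Steppe", k_a = 0.50,
                    n = 90L)),
    chain = list(
      list(offspring = "LF", parent_a = "WHG", parent_b = "EF"),
      list(offspring = "Modern", parent_a = "LF", parent_b = "Steppe")),
    panel = list(n_sites = 2000L, divergence = 0.1, n_ref = 50L,
                 pseudocount = 0.5),
    admix_bootstrap = 100L,
    scan = list(window_len = 15000L, n_windows = 60L,
                focal_windows = c(20L, 21L, 22L), n_chromosomes = 20L,
                theta_w = 15,
                d_populations = list(WHG = "neutral", EF = "sweep"),
                sweep_rare_skew = 3,
                fst_pair = c("WHG", "EF"), n_background_sites = 1000L,
                n_per_pop = 50L,
                percentiles = c(0.95, 0.975)),
    chrom_label = "chr19",
    focal_sites = list(rs429358 = list(pos = 44908684L, ref = "T", alt = "C"),
                       rs7412   = list(pos = 44908822L, ref = "C", alt = "T"))
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults field by field; anything not
#' mentioned keeps its default.
#'
#' @param path YAML file.
#' @param seed optional seed overriding both default and file.
#' @return a config list.
#' @export
load_config <- function(path, seed = NULL) {
  abort_if(!file.exists(path), "config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("config file not parseable: ",
                                            conditionMessage(e), call. = FALSE))
  cfg <- utils::modifyList(default_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a config list as returned by [default_config()].
#' @return character vector of violations, each naming the offending field
#'   and the rule; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  bad <- function(msg) v <<- c(v, msg)
  f <- config$filters
  if (f$min_depth < 3 && !isTRUE(config$allow_below_default_depth)) {
    bad("filters.min_depth: below the default minimum of 3 requires allow_below_default_depth")
  }
  if (f$min_depth < 1) bad("filters.min_depth: must be >= 1")
  if (f$cov_min < 0 || f$cov_min > 1) bad("filters.cov_min: must lie in [0, 1]")
  if (f$depth_min < 0) bad("filters.depth_min: must be >= 0")
  if (f$deamination_threshold < 0 || f$deamination_threshold > 1) {
    bad("filters.deamination_threshold: must lie in [0, 1]")
  }
  if (config$ci_level <= 0 || config$ci_level >= 1) {
    bad("ci_level: must lie in (0, 1)")
  }
  if (config$fdr_q <= 0 || config$fdr_q >= 1) bad("fdr_q: must lie in (0, 1)")
  if (config$scan$window_len < 1) bad("scan.window_len: must be positive")
  known <- c("simulate", "genotype", "freq", "admix", "expect", "scan")
  if (!all(config$stages %in% known)) {
    bad(paste0("stages: unknown stage(s) ",
               paste(setdiff(config$stages, known), collapse = ", ")))
  }
  for (nm in names(config$populations)) {
    p <- config$populations[[nm]]
    s <- p$f_e2 + p$f_e3 + p$f_e4
    if (abs(s - 1) > 1e-12) {
      bad(paste0("populations.", nm, ": haplotype frequencies must sum to 1"))
    }
  }
  # the demographic chain must be acyclic: every parent must be a base
  # population or an earlier offspring
  defined <- names(config$populations)
  for (st in config$chain) {
    if (!all(c(st$parent_a, st$parent_b) %in% defined)) {
      bad(paste0("chain.", st$offspring,
                 ": parent(s) not defined before this step (cycle or gap)"))
    }
    defined <- c(defined, st$offspring)
  }
  for (nm in names(config$admixed)) {
    a <- config$admixed[[nm]]
    if (a$k_a < 0 || a$k_a > 1) {
      bad(paste0("admixed.", nm, ".k_a: must lie in [0, 1]"))
    }
  }
  v
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[setdiff(names(config), "outdir")]), tmp)
  unname(tools::md5sum(tmp))
}

# Resolve the haplotype frequency vector of every population in the
# scenario, composing admixture events in chain order.
resolve_scenario_freqs <- function(config) {
  freqs <- lapply(config$populations, function(p) {
    c(e2 = p$f_e2, e3 = p$f_e3, e4 = p$f_e4)
  })
  for (nm in names(config$admixed)) {
    a <- config$admixed[[nm]]
    abort_if(!all(c(a$parent_a, a$parent_b) %in% names(freqs)),
             "admixed population '", nm, "' has undefined parents")
    freqs[[nm]] <- a$k_a * freqs[[a$parent_a]] + (1 - a$k_a) * freqs[[a$parent_b]]
  }
  freqs
}

stage_marker <- function(outdir, stage, failed = FALSE) {
  if (failed) writeLines(stage, file.path(outdir, paste0("FAILED_", stage)))
}

## ---- pipeline stages -------------------------------------------------------

stage_simulate <- function(config, state) {
  seed <- config$seed
  freqs <- resolve_scenario_freqs(config)
  cohorts <- list()
  for (nm in names(config$populations)) {
    p <- config$populations[[nm]]
    spec <- population_spec(nm, p$f_e2, p$f_e3, p$f_e4, p$n)
    cohorts[[nm]] <- draw_diploid_apoe(spec, seed)
  }
  for (nm in names(config$admixed)) {
    a <- config$admixed[[nm]]
    fa <- freqs[[a$parent_a]]; fb <- freqs[[a$parent_b]]
    spec <- admixture_spec(
      population_spec(a$parent_a, fa[["e2"]], fa[["e3"]], fa[["e4"]], 1L),
      population_spec(a$parent_b, fb[["e2"]], fb[["e3"]], fb[["e4"]], 1L),
      k_a = a$k_a, n_offspring = a$n)
    cohorts[[nm]] <- draw_admixed_cohort(spec, seed, name = nm)
  }
  truth <- do.call(rbind, lapply(cohorts, function(d) {
    d$q_true <- if ("q_true" %in% names(d)) d$q_true else NA_real_
    d
  }))
  rownames(truth) <- NULL
  state$truth <- truth

  # per-sample pileups at both focal sites
  model <- do.call(sequencing_model, config$sequencing)
  site_geno <- function(dosage, ref, alt) {
    switch(as.character(dosage), `0` = c(ref, ref), `1` = c(ref, alt),
           `2` = c(alt, alt))
  }
  fs <- config$focal_sites
  pile <- list()
  for (i in seq_len(nrow(truth))) {
    sm <- truth$sample[i]
    pile[[sm]] <- list(
      rs429358 = simulate_pileup(
        site_geno(truth$rs429358_C[i], fs$rs429358$ref, fs$rs429358$alt),
        model, derive_seed(seed, paste0(sm, ":rs429358"))),
      rs7412 = simulate_pileup(
        site_geno(truth$rs7412_T[i], fs$rs7412$ref, fs$rs7412$alt),
        model, derive_seed(seed, paste0(sm, ":rs7412"))))
  }
  state$pileups <- pile

  # SNP panels for the supervised admixture steps (unlinked; the second
  # demographic step gets its own independent panel)
  pn <- config$panel
  state$panels <- list()
  state$panel_cohorts <- list()
  ak <- names(config$admixed)
  for (i in seq_along(ak)) {
    nm <- ak[i]
    a <- config$admixed[[nm]]
    pan <- simulate_snp_panel(pn$n_sites, pn$divergence,
                              derive_seed(seed, paste0("panel:", nm)),
                              n_ref = pn$n_ref)
    coh <- draw_panel_cohort(pan$freq_a, pan$freq_b, a$k_a, a$n,
                             derive_seed(seed, paste0("panelcoh:", nm)))
    state$panels[[nm]] <- pan
    state$panel_cohorts[[nm]] <- coh
  }

  # windowed variation for the Tajima's D scans
  sc <- config$scan
  state$window_sites <- list()
  for (nm in names(sc$d_populations)) {
    sweep <- identical(sc$d_populations[[nm]], "sweep")
    spec <- window_sim_spec(
      n_chromosomes = sc$n_chromosomes, theta_w = sc$theta_w,
      window_len_bp = sc$window_len, n_windows = sc$n_windows,
      sweep_windows = if (sweep) sc$focal_windows else integer(),
      sweep_rare_skew = sc$sweep_rare_skew)
    state$window_sites[[nm]] <-
      simulate_windows(spec, derive_seed(seed, paste0("windows:", nm)))
  }

  # chromosome background genotype counts for the FST scan: unstructured
  # sites shared between the focal population pair, with a site QUAL
  with_seed(derive_seed(seed, "fst-background"), {
    nb <- sc$n_background_sites
    p <- stats::runif(nb, 0.05, 0.95)
    draw_counts <- function(p, n) {
      t(vapply(p, function(pp) {
        as.integer(stats::rmultinom(1, n, c((1 - pp)^2, 2 * pp * (1 - pp),
                                            pp^2)))
      }, integer(3)))
    }
    state$fst_background_sites <- data.frame(
      site = sprintf("bg%05d", seq_len(nb)),
      qual = stats::runif(nb, 30, 500),
      a0 = NA, a1 = NA, a2 = NA, b0 = NA, b1 = NA, b2 = NA)
    ca <- draw_counts(p, sc$n_per_pop)
    cb <- draw_counts(p, sc$n_per_pop)
    state$fst_background_sites[, c("a0", "a1", "a2")] <- ca
    state$fst_background_sites[, c("b0", "b1", "b2")] <- cb
  })

  # outputs
  od <- config$outdir
  write_tsv(truth, file.path(od, "apoe_truth.tsv"))
  write_tsv(truth[, c("sample", "population")], file.path(od, "samples.tsv"))
  params <- do.call(rbind, lapply(names(freqs), function(nm) {
    data.frame(population = nm, f_e2 = freqs[[nm]][["e2"]],
               f_e3 = freqs[[nm]][["e3"]], f_e4 = freqs[[nm]][["e4"]],
               k_a = if (nm %in% names(config$admixed))
                 config$admixed[[nm]]$k_a else NA_real_)
  }))
  write_tsv(params, file.path(od, "true_params.tsv"))
  pr <- do.call(rbind, lapply(names(pile), function(sm) {
    do.call(rbind, lapply(names(pile[[sm]]), function(site) {
      p <- pile[[sm]][[site]]
      if (nrow(p) == 0L) return(NULL)
      cbind(data.frame(sample = sm, site = site), as.data.frame(p))
    }))
  }))
  write_tsv(pr, file.path(od, "pileups.tsv"))
  fs <- config$focal_sites
  truth_dosage <- rbind(truth$rs429358_C, truth$rs7412_T)
  colnames(truth_dosage) <- truth$sample
  write_genotype_vcf(truth_dosage, config$chrom_label,
                     c(fs$rs429358$pos, fs$rs7412$pos),
                     c("rs429358", "rs7412"),
                     c(fs$rs429358$ref, fs$rs7412$ref),
                     c(fs$rs429358$alt, fs$rs7412$alt),
                     file.path(od, "apoe_truth.vcf"))
  invisible(state)
}

stage_genotype <- function(config, state) {
  abort_if(is.null(state$pileups), "genotype stage requires simulate outputs")
  f <- config$filters
  # damage profile from rs7412 C-contexts (interior reads confidently C)
  profile <- estimate_damage_profile(
    lapply(state$pileups, function(x) x$rs7412))
  m <- decide_trim(profile, f$deamination_threshold)
  samples <- names(state$pileups)
  call_site <- function(p, ref, alt) {
    call_genotype(apply_trim(p, m), base_error = f$caller_base_error,
                  min_depth = f$min_depth, site_alleles = c(ref, alt))
  }
  fs <- config$focal_sites
  rows <- lapply(samples, function(sm) {
    c1 <- call_site(state$pileups[[sm]]$rs429358, fs$rs429358$ref,
                    fs$rs429358$alt)
    c2 <- call_site(state$pileups[[sm]]$rs7412, fs$rs7412$ref, fs$rs7412$alt)
    dose <- function(cl, alt) {
      if (cl$missing) NA_integer_ else sum(c(cl$allele1, cl$allele2) == alt)
    }
    data.frame(sample = sm,
               rs429358_C = dose(c1, fs$rs429358$alt),
               rs7412_T = dose(c2, fs$rs7412$alt),
               dp_rs429358 = c1$depth, dp_rs7412 = c2$depth,
               gq_rs429358 = c1$qual, gq_rs7412 = c2$qual,
               keep = sample_passes_apoe_filter(c1, c2),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls$population <- state$truth$population[match(calls$sample,
                                                  state$truth$sample)]
  state$trim_m <- m
  state$damage_profile <- profile
  state$calls <- calls

  od <- config$outdir
  kept <- calls[calls$keep, , drop = FALSE]
  dosage <- rbind(kept$rs429358_C, kept$rs7412_T)
  colnames(dosage) <- kept$sample
  dp <- rbind(kept$dp_rs429358, kept$dp_rs7412)
  gq <- rbind(kept$gq_rs429358, kept$gq_rs7412)
  write_genotype_vcf(dosage, config$chrom_label,
                     c(fs$rs429358$pos, fs$rs7412$pos),
                     c("rs429358", "rs7412"),
                     c(fs$rs429358$ref, fs$rs7412$ref),
                     c(fs$rs429358$alt, fs$rs7412$alt),
                     file.path(od, "apoe_calls.vcf"),
                     dp = dp, gq = gq)
  write_tsv(calls, file.path(od, "apoe_calls.tsv"))
  write_tsv(calls[!calls$keep, c("sample", "population")],
            file.path(od, "dropped_samples.tsv"))
  invisible(state)
}

stage_freq <- function(config, state) {
  abort_if(is.null(state$calls), "freq stage requires genotype outputs")
  kept <- state$calls[state$calls$keep, , drop = FALSE]
  counts <- do.call(rbind, lapply(split(kept, kept$population), count_epsilon))
  rownames(counts) <- NULL
  state$counts <- counts
  state$freqs <- epsilon_frequencies(counts, level = config$ci_level)
  state$pairwise <- pairwise_freq_tests(counts, q = config$fdr_q)
  od <- config$outdir
  write_tsv(counts, file.path(od, "epsilon_counts.tsv"))
  write_tsv(state$freqs, file.path(od, "epsilon_frequencies.tsv"))
  write_tsv(state$pairwise, file.path(od, "pairwise_tests.tsv"))
  invisible(state)
}

stage_admix <- function(config, state) {
  abort_if(is.null(state$panels), "admix stage requires simulate outputs")
  pn <- config$panel
  rows <- list()
  comp <- list()
  for (nm in names(config$admixed)) {
    pan <- state$panels[[nm]]
    fa <- estimate_parental_freqs(pan$geno_a, pn$pseudocount)
    fb <- estimate_parental_freqs(pan$geno_b, pn$pseudocount)
    kept <- fa$kept & fb$kept
    panel <- snp_panel(fa$freq[kept[fa$kept]], fb$freq[kept[fb$kept]])
    est <- fit_q_cohort(state$panel_cohorts[[nm]][kept, , drop = FALSE],
                        panel, B = config$admix_bootstrap,
                        seed = derive_seed(config$seed, paste0("boot:", nm)))
    est$population <- nm
    rows[[nm]] <- est
    comp[[nm]] <- population_components(est$q_hat)
  }
  state$ancestry <- do.call(rbind, rows)
  rownames(state$ancestry) <- NULL
  state$components <- comp
  od <- config$outdir
  write_tsv(state$ancestry, file.path(od, "ancestry_estimates.tsv"))
  ct <- do.call(rbind, lapply(names(comp), function(nm) {
    a <- config$admixed[[nm]]
    data.frame(population = nm, parent_a = a$parent_a, parent_b = a$parent_b,
               kA = comp[[nm]][["kA"]], kB = comp[[nm]][["kB"]],
               k_a_true = a$k_a)
  }))
  write_tsv(ct, file.path(od, "admixture_components.tsv"))
  invisible(state)
}

stage_expect <- function(config, state) {
  abort_if(is.null(state$freqs), "expect stage requires freq outputs")
  abort_if(is.null(state$components), "expect stage requires admix outputs")
  steps <- lapply(config$chain, function(st) {
    kA <- state$components[[st$offspring]][["kA"]]
    abort_if(is.null(kA), "no admixture components for step '",
             st$offspring, "'")
    demographic_step(st$offspring, st$parent_a, st$parent_b, kA = kA)
  })
  observed <- state$freqs[, c("population", "allele", "freq")]
  exps <- chain_expectations(steps, observed)
  state$expectations <- exps
  state$deviation <- deviation_tests(exps, state$counts)
  od <- config$outdir
  write_tsv(exps, file.path(od, "expected_frequencies.tsv"))
  write_tsv(state$deviation, file.path(od, "deviation_tests.tsv"))
  invisible(state)
}

stage_scan <- function(config, state) {
  abort_if(is.null(state$fst_background_sites),
           "scan stage requires simulate outputs")
  abort_if(is.null(state$calls), "scan stage requires genotype outputs")
  sc <- config$scan
  f <- config$filters
  bg <- state$fst_background_sites
  bg <- bg[bg$qual > f$qual_min, , drop = FALSE]
  wc_bg <- wc_fst_site(bg$a0, bg$a1, bg$a2, bg$b0, bg$b1, bg$b2)

  # focal-site genotype counts from the called APOE genotypes
  kept <- state$calls[state$calls$keep, , drop = FALSE]
  pair <- sc$fst_pair
  gcounts <- function(pop, col) {
    d <- kept[[col]][kept$population == pop]
    d <- d[!is.na(d)]
    c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  }
  focal_rows <- lapply(names(config$focal_sites), function(site) {
    col <- paste0(site, "_", config$focal_sites[[site]]$alt)
    ca <- gcounts(pair[1L], col); cb <- gcounts(pair[2L], col)
    wc <- wc_fst_site(ca[1L], ca[2L], ca[3L], cb[1L], cb[2L], cb[3L])
    data.frame(site = site, theta_hat = wc$theta_hat, defined = wc$defined)
  })
  focal <- do.call(rbind, focal_rows)
  bgout <- fst_background(wc_bg$theta_hat,
                          focal = ifelse(focal$defined, focal$theta_hat, NA),
                          levels = sc$percentiles)
  state$fst <- list(background = cbind(bg[, c("site", "qual")], wc_bg),
                    focal = cbind(focal, bgout$focal),
                    thresholds = bgout$thresholds)

  dscans <- lapply(names(state$window_sites), function(nm) {
    ws <- state$window_sites[[nm]]
    res <- windowed_scan(ws, attr(ws, "n_chromosomes"),
                         window_len = sc$window_len,
                         focal_windows = sc$focal_windows,
                         n_windows = sc$n_windows)
    res$population <- nm
    res
  })
  names(dscans) <- names(state$window_sites)
  state$d_scan <- dscans

  od <- config$outdir
  write_tsv(state$fst$background, file.path(od, "fst_sites.tsv"))
  write_tsv(state$fst$focal, file.path(od, "fst_focal.tsv"))
  wtab <- do.call(rbind, lapply(names(dscans), function(nm) {
    cbind(population = nm, dscans[[nm]]$windows)
  }))
  write_tsv(wtab, file.path(od, "tajimas_d_windows.tsv"))
  sumtab <- do.call(rbind, lapply(names(dscans), function(nm) {
    s <- dscans[[nm]]$summary
    data.frame(population = nm, t(s$percentiles),
               locus_mean_D = s$locus_mean_D, below_p5 = s$below_p5,
               above_p95 = s$above_p95, below_median = s$below_median)
  }))
  thr <- state$fst$thresholds
  scan_summary <- list(fst_thresholds = as.list(thr), tajima = sumtab)
  write_tsv(sumtab, file.path(od, "scan_summary.tsv"))
  write_tsv(data.frame(level = names(thr), threshold = as.numeric(thr)),
            file.path(od, "fst_thresholds.tsv"))
  state$scan_summary <- scan_summary
  invisible(state)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order
#' (simulate, genotype, freq, admix, expect, scan), writes every stage's
#' TSV/VCF outputs under `config$outdir`, and finishes with a manifest of
#' output checksums. Re-running with an identical configuration and seed
#' reproduces byte-identical outputs and hence an identical manifest. A
#' failing stage aborts with the stage named, leaving earlier outputs in
#' place next to a `FAILED_<stage>` marker.
#'
#' @param config a configuration list ([default_config()] or
#'   [load_config()]); it is validated first and any violation aborts the
#'   run.
#' @return invisibly, a list with the in-memory stage results (`truth`,
#'   `calls`, `counts`, `freqs`, `pairwise`, `ancestry`, `components`,
#'   `expectations`, `deviation`, `fst`, `d_scan`) and the `manifest`
#'   data.frame.
#' @export
run_all <- function(config = default_config()) {
  viol <- validate_config(config)
  abort_if(length(viol) > 0,
           "invalid configuration:\n", paste("-", viol, collapse = "\n"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  runners <- list(simulate = stage_simulate, genotype = stage_genotype,
                  freq = stage_freq, admix = stage_admix,
                  expect = stage_expect, scan = stage_scan)
  for (stage in c("simulate", "genotype", "freq", "admix", "expect", "scan")) {
    if (!stage %in% config$stages) next
    tryCatch(runners[[stage]](config, state),
             error = function(e) {
               stage_marker(config$outdir, stage, failed = TRUE)
               stop("stage '", stage, "' failed: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  files <- sort(list.files(config$outdir, full.names = TRUE))
  files <- files[!grepl("manifest\\.tsv$", files)]
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  attr(manifest, "config_md5") <- config_hash(config)
  attr(manifest, "seed") <- config$seed
  attr(manifest, "package_version") <-
    as.character(utils::packageVersion("apoeadmix"))
  header <- data.frame(file = c("#config_md5", "#seed", "#package_version"),
                       md5 = c(config_hash(config), as.character(config$seed),
                               attr(manifest, "package_version")))
  write_tsv(rbind(header, manifest), file.path(config$outdir, "manifest.tsv"))
  out <- as.list(state)
  out$manifest <- manifest
  invisible(out)
}
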