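#' Specify a parental population by its APOE epsilon-haplotype frequencies
#'
#' The three common APOE haplotypes are defined by two coding SNPs:
#' e4 = rs429358-C with rs7412-C, e3 = rs429358-T with rs7412-C and
#' e2 = rs429358-T with rs7412-T. The rare e1 recombinant (C with T) is
#' excluded from the alphabet: the populations modelled here do not carry it,
#' and a three-letter alphabet makes unphased diplotypes decomposable.
#'
#' @param name population label.
#' @param f_e2,f_e3,f_e4 haplotype frequencies; must sum to 1 within 1e-12.
#' @param n_individuals number of diploid individuals to simulate.
#' @return a `population_spec` list.
#' @export
#' @examples
#' population_spec("WHG", f_e2 = 0, f_e3 = 0.6, f_e4 = 0.4, n_individuals = 25)
population_spec <- function(name, f_e2, f_e3, f_e4, n_individuals) {
  abort_if(!is.character(name) || length(name) != 1L, "name must be a label")
  f <- c(e2 = f_e2, e3 = f_e3, e4 = f_e4)
  abort_if(!is_prob(f), "haplotype frequencies must lie in [0, 1]")
  abort_if(abs(sum(f) - 1) > 1e-12,
           "haplotype frequencies must sum to 1 (got ", sum(f), ")")
  abort_if(n_individuals < 1 || n_individuals != round(n_individuals),
           "n_individuals must be a positive integer")
  structure(list(name = name, f = f, n_individuals = as.integer(n_individuals)),
            class = "population_spec")
}

#' Specify a two-way admixture event
#'
#' @param parent_a,parent_b [population_spec()] objects.
#' @param k_a,k_b mixing proportions (must sum to 1 within 1e-12). The default
#'   0.18/0.82 pair is the WHG/EF ancestry split of the European late farmers.
#' @param n_offspring number of admixed individuals.
#' @return an `admixture_spec` list.
#' @export
admixture_spec <- function(parent_a, parent_b, k_a = 0.18, k_b = 1 - k_a,
                           n_offspring = 100L) {
  abort_if(!inherits(parent_a, "population_spec") ||
           !inherits(parent_b, "population_spec"),
           "parents must be population_spec objects")
  abort_if(!is_prob(c(k_a, k_b)), "mixing proportions must lie in [0, 1]")
  abort_if(abs(k_a + k_b - 1) > 1e-12, "k_a + k_b must equal 1")
  abort_if(n_offspring < 1, "n_offspring must be positive")
  structure(list(parent_a = parent_a, parent_b = parent_b,
                 k_a = k_a, k_b = k_b, n_offspring = as.integer(n_offspring)),
            class = "admixture_spec")
}

#' Specify an ancient-DNA-like sequencing noise model
#'
#' Depth is Poisson; each read base is a uniformly chosen true allele, flipped
#' with probability `base_error`; molecules additionally suffer terminal
#' cytosine deamination (C read as T) within `damaged_terminal_len` bases of a
#' read end with probability `deamination_rate`.
#'
#' @param mean_depth mean per-site depth of coverage.
#' @param base_error per-base sequencing/mapping error probability.
#' @param deamination_rate probability of a terminal C->T flip per damaged
#'   position.
#' @param damaged_terminal_len number of read-end positions subject to damage.
#' @param read_len read length in bp, used to place the site at a random
#'   offset so each read has a defined distance from its nearer end.
#' @return a `sequencing_model` list.
#' @export
sequencing_model <- function(mean_depth = 5, base_error = 0.005,
                             deamination_rate = 0.15,
                             damaged_terminal_len = 2L, read_len = 60L) {
  abort_if(mean_depth <= 0, "mean_depth must be positive")
  abort_if(!is_prob(c(base_error, deamination_rate)),
           "probabilities must lie in [0, 1]")
  abort_if(damaged_terminal_len < 0, "damaged_terminal_len must be >= 0")
  abort_if(read_len < 2 * damaged_terminal_len + 1,
           "read_len too short for the damaged terminal length")
  structure(list(mean_depth = mean_depth, base_error = base_error,
                 deamination_rate = deamination_rate,
                 damaged_terminal_len = as.integer(damaged_terminal_len),
                 read_len = as.integer(read_len)),
            class = "sequencing_model")
}

#' Specify a windowed variation simulation for the selection scans
#'
#' Neutral windows draw their number of segregating sites from a Poisson with
#' mean `theta_w * a1(n_chromosomes)` (the Watterson expectation) and
#' derived-allele counts i with probability proportional to 1/i, the standard
#' neutral frequency spectrum. Sweep windows skew the spectrum towards rare
#' variants (probability proportional to i^-sweep_rare_skew) and reduce the
#' mean number of segregating sites by the factor `sweep_rare_skew`.
#'
#' @param n_chromosomes even number of sampled chromosomes (>= 4).
#' @param theta_w Watterson's theta per window.
#' @param window_len_bp window length in bp (15 kb by default).
#' @param n_windows number of tiled windows.
#' @param sweep_windows integer indices (0-based) of sweep-like windows.
#' @param sweep_rare_skew exponent (>= 1) of the rare-variant skew.
#' @return a `window_sim_spec` list.
#' @export
window_sim_spec <- function(n_chromosomes = 20L, theta_w = 15,
                            window_len_bp = 15000L, n_windows = 60L,
                            sweep_windows = integer(), sweep_rare_skew = 3) {
  abort_if(n_chromosomes < 4 || n_chromosomes %% 2 != 0,
           "n_chromosomes must be an even integer >= 4")
  abort_if(theta_w < 0, "theta_w must be non-negative")
  abort_if(window_len_bp < 1 || n_windows < 1, "window geometry invalid")
  abort_if(length(sweep_windows) &&
           (min(sweep_windows) < 0 || max(sweep_windows) >= n_windows),
           "sweep_windows must be window indices in [0, n_windows)")
  abort_if(sweep_rare_skew < 1, "sweep_rare_skew must be >= 1")
  structure(list(n_chromosomes = as.integer(n_chromosomes), theta_w = theta_w,
                 window_len_bp = as.integer(window_len_bp),
                 n_windows = as.integer(n_windows),
                 sweep_windows = as.integer(sweep_windows),
                 sweep_rare_skew = sweep_rare_skew),
            class = "window_sim_spec")
}

# Haplotype -> per-site allele dosage. Dosages are counts of the
# allele-defining base: rs429358-C (e4-defining) and rs7412-T (e2-defining).
hap_dosage <- function(hap) {
  list(rs429358_C = as.integer(hap == "e4"),
       rs7412_T   = as.integer(hap == "e2"))
}

#' Draw phased two-site APOE genotypes for one population
#'
#' Each individual carries two haplotypes drawn i.i.d. from \{e2, e3, e4\}
#' with the spec's frequencies. Phase is retained as ground truth; the
#' unphased per-site dosages (count of rs429358-C and of rs7412-T alleles)
#' are what downstream genotype calling sees.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `population`, `hap1`, `hap2`,
#'   `rs429358_C`, `rs7412_T`.
#' @export
#' @examples
#' g <- draw_diploid_apoe(population_spec("WHG", 0, 0.6, 0.4, 10), seed = 1)
#' table(c(g$hap1, g$hap2))
draw_diploid_apoe <- function(spec, seed) {
  abort_if(!inherits(spec, "population_spec"), "spec must be a population_spec")
  n <- spec$n_individuals
  with_seed(derive_seed(seed, paste0("apoe:", spec$name)), {
    haps <- sample(c("e2", "e3", "e4"), 2L * n, replace = TRUE, prob = spec$f)
    hap1 <- haps[seq_len(n)]
    hap2 <- haps[n + seq_len(n)]
    d1 <- hap_dosage(hap1); d2 <- hap_dosage(hap2)
    data.frame(sample = sprintf("%s_%03d", spec$name, seq_len(n)),
               population = spec$name, hap1 = hap1, hap2 = hap2,
               rs429358_C = d1$rs429358_C + d2$rs429358_C,
               rs7412_T = d1$rs7412_T + d2$rs7412_T,
               stringsAsFactors = FALSE)
  })
}

#' Draw an admixed cohort of phased APOE genotypes
#'
#' Each haplotype descends from parent A with probability `k_a` and otherwise
#' from parent B, then is drawn from that parent's haplotype frequencies. The
#' expected haplotype frequency in the cohort is therefore the linear
#' admixture expectation `k_a * fA + k_b * fB`.
#'
#' @param spec an [admixture_spec()].
#' @param seed integer seed.
#' @param name label for the admixed cohort.
#' @return data.frame as in [draw_diploid_apoe()], plus `q_true` (realized
#'   fraction of the individual's two haplotypes descending from parent A).
#' @export
draw_admixed_cohort <- function(spec, seed, name = "admixed") {
  abort_if(!inherits(spec, "admixture_spec"), "spec must be an admixture_spec")
  n <- spec$n_offspring
  with_seed(derive_seed(seed, paste0("admix:", name)), {
    src <- matrix(stats::runif(2L * n) < spec$k_a, nrow = n) # TRUE = parent A
    # inverse-CDF draw so both parental origins are sampled in one pass
    eps <- c("e2", "e3", "e4")
    draw_haps <- function(from_a) {
      cuts_a <- cumsum(spec$parent_a$f)
      cuts_b <- cumsum(spec$parent_b$f)
      u <- stats::runif(length(from_a))
      idx_a <- findInterval(u, cuts_a, left.open = TRUE) + 1L
      idx_b <- findInterval(u, cuts_b, left.open = TRUE) + 1L
      eps[ifelse(from_a, pmin(idx_a, 3L), pmin(idx_b, 3L))]
    }
    hap1 <- draw_haps(src[, 1L])
    hap2 <- draw_haps(src[, 2L])
    d1 <- hap_dosage(hap1); d2 <- hap_dosage(hap2)
    out <- data.frame(sample = sprintf("%s_%03d", name, seq_len(n)),
                      population = name, hap1 = hap1, hap2 = hap2,
                      rs429358_C = d1$rs429358_C + d2$rs429358_C,
                      rs7412_T = d1$rs7412_T + d2$rs7412_T,
                      q_true = rowMeans(src),
                      stringsAsFactors = FALSE)
    attr(out, "k_a") <- spec$k_a
    out
  })
}

#' Simulate a per-site read pileup for one diploid genotype
#'
#' Depth is Poisson(`mean_depth`). Each read samples one of the two true
#' alleles uniformly, lands at a uniform offset within the read (giving a
#' distance from the nearer read end), suffers terminal C->T deamination
#' within `damaged_terminal_len` bases of the end, and finally a symmetric
#' base-calling error between the two segregating bases. Bases are assumed
#' pre-filtered for base/mapping quality, so every simulated read counts.
#'
#' @param genotype character vector of two true alleles, e.g. `c("T", "C")`.
#' @param model a [sequencing_model()].
#' @param seed integer seed.
#' @param site_alleles the two segregating bases at the site (error flips
#'   between them); defaults to `c("T", "C")`, which covers both APOE sites.
#' @return a `site_pileup`: data.frame with one row per read,
#'   columns `base`, `terminal`, `dist` (distance from nearer read end, NA for
#'   interior), `deaminated` (ground-truth damage flag).
#' @export
simulate_pileup <- function(genotype, model, seed, site_alleles = c("T", "C")) {
  abort_if(length(genotype) != 2L || anyNA(genotype),
           "genotype must name two alleles")
  abort_if(!inherits(model, "sequencing_model"), "model must be a sequencing_model")
  with_seed(derive_seed(seed, "pileup"), {
    depth <- stats::rpois(1L, model$mean_depth)
    if (depth == 0L) {
      return(site_pileup(data.frame(base = character(), terminal = logical(),
                                    dist = integer(), deaminated = logical())))
    }
    true <- sample(genotype, depth, replace = TRUE)
    offset <- sample.int(model$read_len, depth, replace = TRUE) - 1L
    dist <- pmin(offset, model$read_len - 1L - offset)
    terminal <- dist < model$damaged_terminal_len
    base <- true
    deam <- terminal & base == "C" &
      stats::runif(depth) < model$deamination_rate
    base[deam] <- "T"
    flip <- stats::runif(depth) < model$base_error
    other <- ifelse(base == site_alleles[1L], site_alleles[2L], site_alleles[1L])
    base[flip] <- other[flip]
    site_pileup(data.frame(base = base, terminal = terminal,
                           dist = ifelse(terminal, dist, NA_integer_),
                           deaminated = deam, stringsAsFactors = FALSE))
  })
}

#' Simulate an unlinked SNP panel with diverged parental populations
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); each parental
#' frequency is drawn from a Balding-Nichols beta distribution around the
#' ancestral value with the requested divergence, and parental reference
#' genotypes are drawn per parent under Hardy-Weinberg.
#'
#' @param n_sites number of panel sites (>= 1).
#' @param fst_divergence Balding-Nichols F between the parents, in (0, 1).
#' @param seed integer seed.
#' @param n_ref number of reference individuals per parent.
#' @return list with `freq_a`, `freq_b` (true parental alt-allele
#'   frequencies), `geno_a`, `geno_b` (site x individual dosage matrices) and
#'   `ancestral` frequencies.
#' @export
simulate_snp_panel <- function(n_sites, fst_divergence, seed, n_ref = 20L) {
  abort_if(n_sites < 1, "n_sites must be >= 1")
  abort_if(fst_divergence <= 0 || fst_divergence >= 1,
           "fst_divergence must lie in (0, 1)")
  with_seed(derive_seed(seed, "panel"), {
    p <- stats::runif(n_sites, 0.05, 0.95)
    f <- (1 - fst_divergence) / fst_divergence
    freq_a <- stats::rbeta(n_sites, p * f, (1 - p) * f)
    freq_b <- stats::rbeta(n_sites, p * f, (1 - p) * f)
    geno <- function(fr) matrix(stats::rbinom(n_sites * n_ref, 2L, fr),
                                nrow = n_sites)
    list(freq_a = freq_a, freq_b = freq_b,
         geno_a = geno(freq_a), geno_b = geno(freq_b), ancestral = p)
  })
}

#' Draw admixed genotypes across a SNP panel
#'
#' Under free recombination (the panel is unlinked) an individual with
#' parent-A ancestry proportion q has genotype `Binomial(2, q*fA + (1-q)*fB)`
#' at each site.
#'
#' @param freq_a,freq_b per-site parental allele frequencies.
#' @param q ancestry proportion(s); scalar or one per individual.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return site x individual dosage matrix with attribute `q_true`.
#' @export
draw_panel_cohort <- function(freq_a, freq_b, q, n, seed) {
  abort_if(length(freq_a) != length(freq_b), "parental frequency length mismatch")
  abort_if(!is_prob(q), "q must lie in [0, 1]")
  q <- rep_len(q, n)
  with_seed(derive_seed(seed, "panel-cohort"), {
    g <- vapply(seq_len(n), function(j) {
      stats::rbinom(length(freq_a), 2L, q[j] * freq_a + (1 - q[j]) * freq_b)
    }, integer(length(freq_a)))
    g <- matrix(g, nrow = length(freq_a))
    attr(g, "q_true") <- q
    g
  })
}

#' Simulate segregating sites in tiled windows
#'
#' @param spec a [window_sim_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `window` (0-based index), `pos` (1-based
#'   bp position), `count` (derived-allele count in `1..n_chromosomes-1`) and
#'   attribute `n_chromosomes`.
#' @export
simulate_windows <- function(spec, seed) {
  abort_if(!inherits(spec, "window_sim_spec"), "spec must be a window_sim_spec")
  n <- spec$n_chromosomes
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  with_seed(derive_seed(seed, "windows"), {
    res <- lapply(seq_len(spec$n_windows) - 1L, function(w) {
      sweep <- w %in% spec$sweep_windows
      mean_s <- spec$theta_w * a1 / (if (sweep) spec$sweep_rare_skew else 1)
      s <- stats::rpois(1L, mean_s)
      if (s == 0L) return(NULL)
      wts <- if (sweep) i^(-spec$sweep_rare_skew) else 1 / i
      count <- sample(i, s, replace = TRUE, prob = wts)
      pos <- sort(sample.int(spec$window_len_bp, s, replace = TRUE)) +
        w * spec$window_len_bp
      data.frame(window = w, pos = pos, count = count)
    })
    out <- do.call(rbind, c(res, list(data.frame(window = integer(),
                                                 pos = integer(),
                                                 count = integer()))))
    rownames(out) <- NULL
    attr(out, "n_chromosomes") <- n
    out
  })
}
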