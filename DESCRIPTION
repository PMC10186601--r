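Package: apoeadmix
Title: Admixture-Informed Analysis of APOE Allele Trajectories in Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether allele-frequency change at the two-SNP APOE
    locus (rs429358, rs7412; haplotypes e2/e3/e4) across ancient and modern
    European populations is explained by ancient admixture or requires
    selection. Implements ancient-DNA-grade diploid genotype filtering from
    per-site pileup counts (depth, deamination trimming), haplotype-aware
    epsilon-allele counting with exact Clopper-Pearson intervals and pairwise
    Fisher tests under FDR control, supervised two-way admixture estimation by
    maximum likelihood with site-bootstrap uncertainty, admixture-informed
    expected allele frequencies over a two-step demographic chain with
    two-sided binomial deviation tests, and chromosome-background percentile
    scans of per-site Weir-Cockerham FST and windowed Tajima's D. A synthetic
    data module generates parental and admixed cohorts, aDNA-like pileups and
    neutral or sweep-like variation windows so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
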