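Package: paleocohort
Title: Steppe-Ancestry Arrival Timing, Mismatch Diversity and Kinship for
    Ancient DNA Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing time-transect cohorts of low-coverage
    ancient genomes. Implements a jump-plus-exponential-decay model for the
    arrival and subsequent decline of steppe-related ancestry, fitted by
    bounded least squares with Monte Carlo propagation of radiocarbon-date
    uncertainty and weighted kernel density summaries of the arrival time.
    Provides pairwise mismatch rates on pseudo-haploid genotypes with a
    permutation test for diversity shifts across a date cutoff, READ-style
    mismatch-based kinship classification with uniparental-marker
    consistency checks, outgroup-f3 and D-statistics with weighted block
    jackknife errors including an autosome-versus-X sex-bias contrast,
    derived-allele frequency reports for phenotypic SNPs, EIGENSTRAT
    input/output, and a fully seeded synthetic-cohort generator for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'arrival-model.R'
    'arrival-montecarlo.R'
    'demo.R'
    'fstats.R'
    'io-cohort.R'
    'io-eigenstrat.R'
    'kinship.R'
    'mismatch.R'
    'paleocohort-package.R'
    'simulate-cohort.R'
    'simulate-genotypes.R'
    'simulate-pedigree.R'
    'utils.R'
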