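# paleocohort

Statistics for dated cohorts of low-coverage ancient genomes, built for
the Late Neolithic / Early Bronze Age transition in Central Europe: when
did steppe-related ancestry arrive, how did genetic diversity change
around that turnover, and who was related to whom in the multiple
burials?

The package is aimed at archaeogenetics practitioners who already have
pseudo-haploid genotypes (EIGENSTRAT), per-individual calibrated
radiocarbon intervals, and qpAdm-style ancestry proportions, and who
need the bespoke downstream analyses:

* **Arrival model.** Steppe-ancestry proportion over time t (years
  calBCE) is modeled as 0 for t > t_e, jumping to p_e at t_e and
  decaying exponentially so that it projects to p_0 at time zero:
  f(t) = p_e · exp(−λ(t_e − t)) with λ = log(p_e/p_0)/t_e. Parameters
  are fitted by bounded least squares (start p_0 = 0.1, p_e = 0.8, t_e
  at the mean nonzero-ancestry date), with exactly-zero-ancestry
  individuals dated after t_e contributing zero residual so they do not
  bias p_e downward. Radiocarbon uncertainty is propagated by
  resampling each date from a truncated normal whose 95% range is the
  calibrated interval, refitting (by default 100000 times), retaining
  stable solutions (positive-definite Hessian), and reporting the mode
  of a kernel density weighted by exp(rss_min − rss_i).
* **Diversity.** Pairwise mismatch rates over jointly covered SNPs
  (pairs need more than 10000 overlapping sites on the full panel),
  and a permutation test for the mean-rate shift across 2700 calBCE
  that permutes *individual* period labels, respecting the shared-
  individual dependence among pairs.
* **Kinship.** READ-style classification of pair mismatch rates
  normalized by the within-group median (cuts 0.625 / 0.8125 / 0.90625
  for identical / first / second degree), checked against mtDNA and
  Y-haplogroup transmission and X/Y-based sex inference.
* **f-statistics.** Outgroup f3 and D with weighted block-jackknife
  errors, plus the autosome-versus-X f3 contrast that detects
  male-biased steppe admixture (positive delta = X carries less steppe
  ancestry), and Table-style derived-allele frequency reports for
  pigmentation/lactase SNPs with automatic damage flags for A/T
  variants.
* **Synthetic cohorts.** A seeded generator (jump-and-decline ancestry,
  Balding–Nichols source pools, sex-biased X transmission, 3-generation
  pedigrees with Mendelian and uniparental transmission) that emulates
  the cohort structure, with full truth bookkeeping, so every stage is
  testable offline.

## Worked example

```r
library(paleocohort)
demo <- runDemo(seed = 7, nReps = 200)
cat(demo$markdown)
```

```
# paleocohort demo report

- seed: 7; cohort of 100 individuals
- generating jump time: 2750 calBCE
- arrival-time KDE mode: 2757.1 calBCE (95% interval 2710.6-2846.2, retention 0.82)
- diversity shift (after - before 2700 calBCE): 0.007383 (p = 0.002)
- kinship first-degree/unrelated accuracy vs truth: 1.00
- D(Outgroup, Cohort; SteppeRef, NeoRef) = 0.03703 (Z = 5.81)
- autosome-vs-X f3 contrast delta = 0.002488 (Z = 0.73)
```

Reading the report: the cohort was generated with a steppe-ancestry
jump at 2750 calBCE; the Monte Carlo arrival estimate (200 date
resamplings here) puts the KDE mode at 2757 calBCE with a 95% weighted
interval of roughly ±70 years, retaining 82% of repetitions as stable.
The injected post-turnover diversity increase appears as a +0.0074 mean
mismatch shift (permutation p = 0.002). All first-degree and unrelated
pedigree pairs are classified correctly and confirmed by uniparental
markers. The strongly positive D confirms the cohort shares more drift
with the steppe-like than the Neolithic-like reference, and the
positive (weak at these SNP counts) autosome-vs-X delta reflects the
generator's male-biased admixture.

Individual stages are exported directly — `readEigenstrat()`,
`readCohort()`, `fitArrival()`, `monteCarloArrival()`,
`pairwiseMismatch()`, `diversityShift()`, `kinshipCalls()`,
`inferSex()`, `groupFreqs()`, `outgroupF3()`, `dStat()`,
`xAutosomeContrast()`, `phenotypeReport()`, and the `simulate*()`
generators. A thin command-line wrapper with `simulate` / `arrival` /
`mismatch` / `kinship` / `fstats` / `freq` / `demo` subcommands lives
at `inst/cli/paleocohort-cli.R`. See the vignette
(`vignettes/arrival-diversity-kinship.Rmd`) for the model, its
assumptions and the numerical choices.

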