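---
title: "Modeling steppe-ancestry arrival, diversity shifts and kinship in ancient DNA time transects"
author: "paleocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling steppe-ancestry arrival, diversity shifts and kinship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocohort)
```

## The scientific setting

Dense time transects of low-coverage ancient genomes from Late Neolithic
and Early Bronze Age Central Europe show a rapid appearance of ancestry
related to Pontic–Caspian steppe pastoralists early in the third
millennium BCE, followed by a gradual decline of that component over the
next thousand years. `paleocohort` provides the bespoke statistics such a
study needs downstream of standard genotyping and qpAdm-style admixture
estimation:

* a parametric model for the **arrival time** of the steppe-related
  component, fitted under radiocarbon-date uncertainty;
* **pairwise mismatch rates** on pseudo-haploid genotypes, with a
  permutation test for the diversity increase across a date cutoff;
* READ-style **kinship classification** with mtDNA / Y-haplogroup
  consistency checks and X/Y-based sex inference;
* **outgroup-f3 and D statistics** with weighted block-jackknife errors,
  including an autosome-versus-X contrast for sex-biased admixture;
* a fully seeded **synthetic-cohort generator** so that every stage can
  be validated against known truth without any external data.

All genotype data are pseudo-haploid: one randomly sampled allele per
site per individual, the standard representation when coverage is far
below 1x per strand. Heterozygous calls cannot occur by construction,
and the container class enforces that.

## The arrival model

Let $t$ be time in calibrated years BCE (increasing into the past). The
steppe-ancestry proportion is modeled as zero before the jump time
$t_e$, jumping to $p_e$ at $t_e$, then decaying exponentially so that it
is projected to reach $p_0$ at time zero:

$$
f(t) \;=\;
\begin{cases}
0, & t > t_e,\\[2pt]
p_e\, e^{-\lambda\,(t_e - t)}, \quad
\lambda = \dfrac{\log(p_e/p_0)}{t_e}, & t \le t_e .
\end{cases}
$$

This is the unique pure exponential through the two pinned points
$(t_e, p_e)$ and $(0, p_0)$; the same exponential extends to negative
$t$ (CE dates), which the IO layer flags since placing post-BCE
individuals on this axis is an extrapolation.

Parameters are estimated by least squares against per-individual
ancestry proportions. Two details matter:

**The zero-residual rule.** Individuals with an ancestry proportion of
exactly zero that are dated *after* $t_e$ contribute zero residual. The
motivation is empirical: unadmixed individuals persist for centuries
after the arrival (plausibly mobile members of parallel societies), and
letting them pull the fitted curve down would bias $p_e$ downward. On
synthetic cohorts with 10% such individuals, the masked fit is centred
on the generating $p_e$ while the unmasked fit is biased low (this is
asserted by the test suite). The direction is an *average* property,
not a per-realization guarantee: zero-ancestry individuals falling late
in the post-arrival span steepen the unmasked decay and can push its
$p_e$ *above* the masked fit on a minority of realizations.

**Piecewise-constant profile in $t_e$.** For a fixed decay shape
$(p_0, \lambda)$ the fitted values depend on $t_e$ only through which
observations fall on the zero branch, so the profiled objective is a
step function of $t_e$, constant between adjacent observation dates;
with the masking rule active it is, moreover, flat for every $t_e$ above
the oldest nonzero-ancestry date. Three numerical choices follow:

1. *Optimization* uses Nelder–Mead on a logistic-transformed
   parameterization ($p_e = \mathrm{expit}(b)$,
   $p_0 = p_e\,\mathrm{expit}(a)$, $t_e$ affine-logistic inside its
   box), which enforces $0 < p_0 \le p_e \le 1$ and the $t_e$ bounds
   exactly while keeping the search space smooth. Five deterministic
   jittered restarts plus an endpoint-polish loop handle the
   piecewise-smooth objective. The default start is $p_0 = 0.1$,
   $p_e = 0.8$ and $t_e$ at the mean date of the nonzero-ancestry
   observations; default $t_e$ bounds are the observed date range
   widened by the typical interval width.
2. *Stability assessment*: a fit is retained only if the central
   finite-difference Hessian of the RSS at the optimum is positive
   definite (all eigenvalues above $10^{-8}$). The Hessian is computed
   on scale-standardized parameters ($t_e$ in kiloyears; proportions as
   is), because in raw units the smallest eigenvalue sits below
   finite-difference noise. The $t_e$ step is floored at the mean
   observation spacing: curvature is measured at the resolving power of
   the date design, and a jump time stranded in a data gap shows no
   curvature and is rightly rejected as unstable.
3. *Identifiability*: noise-free data identify $t_e$ only up to the gap
   between the bracketing observation dates. With observation noise,
   pre-arrival individuals acquire small positive proportions (noise is
   resampled into $[0,1]$, never clipped, to avoid point masses at the
   bounds), cannot be masked, and bound $t_e$ from above, so every
   stochastic analysis is well posed.

**Date uncertainty.** Each individual's calibrated interval is treated
as the 95% range of a normal distribution centred at the midpoint and
truncated at the bounds
($\sigma = (\text{upper}-\text{lower})/(2 \times 1.959964)$).
`monteCarloArrival()` resamples all dates, refits, retains stable
converged solutions, and weights repetition $i$ by
$\exp(\mathrm{rss}_{\min} - \mathrm{rss}_i)$ — the ratio of
exponentiated residual sums of squares, so the best repetition has
weight 1. A variance-scaled variant
$\exp\{(\mathrm{rss}_{\min} - \mathrm{rss}_i)/(2\hat\sigma^2)\}$ with
$\hat\sigma^2 = \mathrm{rss}_{\min}/n$, the likelihood-ratio form under
Gaussian residuals, is available as `weightMode = "scaled"`; the literal
form is the default. The reported estimate is the mode of the weighted
Gaussian KDE of the retained $t_e$ values (Silverman bandwidth on the
weight-effective sample size; density renormalized to integrate to 1 on
its grid), with the central 95% of the weighted sample as interval. The
production default is 100000 repetitions; validation experiments use
500, which already locates the mode to within a few decades.

```{r arrival-example}
cfg <- simulationConfig(nIndividuals = 60, intervalWidthRange = c(200, 200),
                        seed = 42)
sim <- simulateCohort(cfg)
est <- monteCarloArrival(sim$cohort, nReps = 200, seed = 42)
est
```

## Pairwise mismatch and the diversity shift

The mismatch rate of a pair is the fraction of jointly non-missing SNPs
with differing haploid calls; pairs must share strictly more than
`minOverlap` SNPs (default 10000, the convention for 1240k-panel data —
scale it down for smaller synthetic panels). The implementation is three
matrix cross-products and agrees exactly with a per-pair loop, which the
tests assert on random fixtures.

The diversity question — did mean pairwise mismatch increase after the
turnover horizon (default cutoff 2700 calBCE)? — involves pair-level
observations that share individuals, so they are not independent. The
original robust mixed-model treatment (sample IDs as random effects) is
replaced here by a permutation test that respects the same dependence:
*individual* period labels are permuted and the pair grouping is
recomputed, giving an exact test under exchangeability, with an add-one
two-sided p-value. Individuals whose interval contains the cutoff are
excluded by default (`byMidpoint = TRUE` classifies them by midpoint
instead). A cluster-aggregated linear model (per-individual mean rates)
provides a complementary effect CI, and site-level means are reported
alongside. The synthetic module can inject an exact expected-mismatch
gap between two frequency pools via `calibratedMismatchPools()` (a
closed-form shrink of frequencies towards 0.5), which the test suite
uses to confirm recovery of a gap of 0.009 — the magnitude of interest
in this literature.

## Kinship

Within a group (site or cohort), the expected-unrelated mismatch level
is taken as the *median* pair rate, robust to a minority of true
relatives; each pair's normalized score is rate/baseline. Expected
scores are 0.5 for identical genomes/twins, 0.75 for first-degree and
0.875 for second-degree pairs (enumerate the allele draws: a shared
parental allele is sampled on both sides with probability 1/4 per
shared-IBD chromosome). Classification cuts sit halfway between
consecutive expectations — 0.625, 0.8125, 0.90625 — following the READ
scheme; boundary values go to the more-related class. Uniparental
checks then flag impossible first-degree calls: two females must share
an mtDNA label, male–male pairs must share a Y label; configurations
that could be a father–child pair are undecidable and reported as
`not_applicable`, never errors. Genetic sex comes from the Y fraction
of sex-chromosome signal ($R = y/(x+y)$; female below 0.05, male above
0.20 — between the two thresholds the call is `undetermined`).

Pedigree simulations (founders in Hardy–Weinberg proportions, Mendelian
transmission, pseudo-haploid observation layer, matrilineal mtDNA and
patrilineal Y labels) provide ground truth; at 20000 SNPs and 30%
missingness, first-degree versus unrelated classification is essentially
perfect, and the 0.75/0.5 mismatch ratios are reproduced to within a few
percent.

## f3, D and the sex-bias contrast

Group allele frequencies are haploid counts from pseudo-haploid calls —
no diploid correction and no within-group heterozygosity correction;
male and female X calls each count once. Outgroup
$f_3(O; A, B) = \overline{(f_O - f_A)(f_O - f_B)}$ measures shared
drift; the D statistic uses the allele-frequency product form
$$
D = \frac{\sum_s (f_W - f_X)(f_Y - f_Z)}
         {\sum_s (f_W + f_X - 2 f_W f_X)(f_Y + f_Z - 2 f_Y f_Z)} .
$$
Under this ordering convention, gene flow from $Y$ into $X$ drives $D$
negative. Standard errors come from a weighted delete-one-block
jackknife over contiguous SNP blocks (default 500 SNPs; synthetic data
carry no genetic map, so fixed SNP-count blocks stand in for map-based
blocks). The sex-bias analysis computes the same outgroup f3 on
autosomal and X SNP sets separately;
$\Delta = f_3^{\text{auto}} - f_3^{X}$ with independent jackknife SEs
is positive when steppe ancestry entered predominantly through males,
because the X chromosome then carries less of it.

Phenotype reports (defaults: SLC45A2 rs16891982, SLC24A5 rs1426654,
HERC2 rs12913832, LCT rs4988235) give per-group derived-allele
frequencies with covered counts; positions whose ref/alt pair involves
A or T are flagged automatically, replacing the manual inspection such
calls need because post-mortem deamination (C→T/G→A) mimics them at low
coverage.

## The synthetic-data generator

`simulationConfig()` defaults define the emulated study conditions:
~100 individuals spanning 4800–1700 calBCE; interval widths 60–300
years; a jump at 2750 calBCE to $p_e = 0.6$ with $p_0 = 0.09$, which
projects the decline to ≈0.30 at 1750 calBCE (the "drop to 25–35% a
millennium later" regime); observation noise 0.05 (qpAdm gives no SE
model, so this knob is a plausible magnitude, not calibrated); 10% of
post-arrival individuals carry exactly zero ancestry and are female
with probability 0.9 (mirroring, without hard-coding, the observation
that such individuals were female). Genotypes come from two
Balding–Nichols pools (ancestral frequencies Uniform(0.05, 0.95);
divergence `fstSources`, default 0.1, split evenly between the two
branches) with per-call source choice at the individual's proportion;
X SNPs use the female-shifted proportion
$\alpha(1 - \text{maleAdmixtureBias})$. Reference panels (steppe-like,
Neolithic-like, and a further-diverged outgroup) are appended for
f-statistics, and the generator exports its complete bookkeeping (pool
frequencies, per-allele source, realized per-individual source
fractions) so estimators are scored against truth.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and recombination maps
(SNPs are independent, so jackknife blocks are exchangeable by
construction), reference bias and post-mortem damage in the calls,
contamination, non-uniform temporal sampling, and radiocarbon
calibration-curve error structure (intervals are symmetric truncated
normals around the true date). Conclusions about those failure modes
need real data or sequence-level simulators.

## Reproducibility and problem sizes

Every stochastic function takes a seed, and multi-stage runs derive
per-stage substreams from one root seed (`subSeed()`), so outputs are
byte-identical under a fixed seed — the test suite asserts this
end-to-end. Validation problem sizes were chosen so the whole suite
runs comfortably on a single CPU: 500 Monte Carlo repetitions per
arrival experiment (against the production default of 100000), panels
of 3000–10000 SNPs with overlap thresholds scaled proportionally, and
100–200 replicate simulations for calibration checks; at these sizes
every recovery property above is already sharp.

## Known limitations

* The jump time is set-identified between bracketing observation dates;
  reported intervals reflect date uncertainty and weighting, not that
  residual discreteness (negligible for realistic cohort sizes).
* The literal weight form is extremely aggressive when the RSS varies
  strongly across repetitions (weights decay as $e^{-\Delta rss}$ in
  squared-proportion units); the scaled mode is statistically the
  better-motivated choice and may supersede the literal default in a
  future release.
* The permutation diversity test assumes exchangeability of individuals
  under the null within the labelled set; strong site structure under
  the null would call for within-site permutation, which
  the site-level decomposition helps diagnose.
* Kinship degrees beyond second (and half- versus full-sibling
  distinctions) are outside the resolution of mismatch-based
  classification at these coverages.
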