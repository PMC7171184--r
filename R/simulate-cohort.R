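#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a Late Neolithic / Early Bronze Age time transect
#' from the northern Alpine region: ~100 individuals spanning 4800-1700
#' calBCE with radiocarbon interval widths of decades to centuries; a
#' steppe-ancestry jump near 2750 calBCE to about 60\% followed by an
#' exponential decline that reaches roughly 30\% a thousand years later
#' (p0 = 0.09 projects exactly that); qpAdm-like observation noise of
#' 0.05 proportion units; and a 10\% fraction of post-arrival individuals
#' carrying exactly zero steppe ancestry, assigned female with
#' probability 0.9 (mirroring the observation that unadmixed individuals
#' persisting after the arrival were female, without hard-coding it).
#'
#' @param nIndividuals cohort size.
#' @param dateSpan c(oldest, youngest) calBCE.
#' @param intervalWidthRange range of reported 95\% interval widths,
#'   years.
#' @param trueParams generating [arrivalParams()].
#' @param noiseSd sd of the Gaussian observation noise (proportion
#'   units); noise is re-drawn, not clipped, until the observation lies
#'   in [0,1], to avoid point masses at the bounds.
#' @param zeroAncestryFraction fraction of post-jump individuals whose
#'   observation is exactly 0.
#' @param nSnps,nXSnps autosomal and X-chromosome SNP counts.
#' @param fstSources Balding-Nichols divergence between the two source
#'   allele-frequency pools (Neolithic-like vs steppe-like).
#' @param missingRate per-call missingness probability.
#' @param maleAdmixtureBias excess of steppe ancestry transmitted through
#'   males, realized as a reduced X-chromosome steppe proportion:
#'   \code{xProp = prop * (1 - bias)}.
#' @param nRefPerGroup reference individuals per external panel group
#'   (steppe-like, Neolithic-like, outgroup) added by
#'   [simulateGenotypes()].
#' @param outgroupFst Balding-Nichols divergence of the outgroup pool.
#' @param nSites number of burial sites the cohort is spread over.
#' @param seed root seed; every generator output is a deterministic
#'   function of it.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nIndividuals = 100,
                             dateSpan = c(4800, 1700),
                             intervalWidthRange = c(60, 300),
                             trueParams = arrivalParams(0.09, 0.6, 2750),
                             noiseSd = 0.05,
                             zeroAncestryFraction = 0.1,
                             nSnps = 5000, nXSnps = 500,
                             fstSources = 0.1,
                             missingRate = 0.1,
                             maleAdmixtureBias = 0,
                             nRefPerGroup = 10,
                             outgroupFst = 0.3,
                             nSites = 6,
                             seed = 1) {
  cfg <- list(nIndividuals = nIndividuals, dateSpan = dateSpan,
              intervalWidthRange = intervalWidthRange,
              trueParams = trueParams, noiseSd = noiseSd,
              zeroAncestryFraction = zeroAncestryFraction,
              nSnps = nSnps, nXSnps = nXSnps, fstSources = fstSources,
              missingRate = missingRate,
              maleAdmixtureBias = maleAdmixtureBias,
              nRefPerGroup = nRefPerGroup, outgroupFst = outgroupFst,
              nSites = nSites, seed = seed)
  rates <- c(noiseSd = noiseSd >= 0,
             zeroAncestryFraction = zeroAncestryFraction >= 0 &&
               zeroAncestryFraction <= 1,
             fstSources = fstSources >= 0 && fstSources < 1,
             missingRate = missingRate >= 0 && missingRate <= 1,
             maleAdmixtureBias = maleAdmixtureBias >= 0 &&
               maleAdmixtureBias <= 1)
  if (!all(rates))
    stop("config rate(s) out of range: ",
         paste(names(rates)[!rates], collapse = ", "))
  if (dateSpan[1] <= dateSpan[2])
    stop("dateSpan must be (oldest, youngest) with oldest > youngest")
  if (nIndividuals < 1 || nSnps < 1) stop("counts must be positive")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a dated ancient cohort with ancestry observations
#'
#' True dates are uniform on the configured span; reported intervals are
#' centred on the true date with widths uniform in the configured range
#' (so every interval contains its true date).  Observed proportions are
#' the model curve at the true date plus truncated-resampled Gaussian
#' noise, except for the designated zero-ancestry individuals, whose
#' observation is exactly 0.  Sexes are ~1:1 apart from the
#' zero-ancestry individuals (female with probability 0.9).  mtDNA and
#' Y-haplogroup labels are drawn from small label pools; females carry no
#' Y label.
#'
#' @param cfg a [simulationConfig()].
#' @return list with \code{cohort} (an \linkS4class{AncientCohort}) and
#'   \code{trueDates} (named numeric, the generating dates).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(subSeed(cfg$seed, "cohort"))
  n <- cfg$nIndividuals
  ids <- sprintf("SIM%03d", seq_len(n))
  tru <- stats::runif(n, cfg$dateSpan[2], cfg$dateSpan[1])
  width <- stats::runif(n, cfg$intervalWidthRange[1],
                        cfg$intervalWidthRange[2])
  upper <- round(tru + width / 2)
  lower <- round(tru - width / 2)

  curve <- modelCurve(tru, cfg$trueParams)
  prop <- curve
  if (cfg$noiseSd > 0) {
    todo <- seq_len(n)
    while (length(todo)) {       # resample, never clip, into [0, 1]
      prop[todo] <- curve[todo] + stats::rnorm(length(todo), 0, cfg$noiseSd)
      todo <- todo[prop[todo] < 0 | prop[todo] > 1]
    }
  }

  te <- cfg$trueParams[["te"]]
  post <- which(tru < te)
  nZero <- round(cfg$zeroAncestryFraction * length(post))
  zeroIdx <- if (nZero > 0) sample(post, nZero) else integer()
  prop[zeroIdx] <- 0

  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  if (length(zeroIdx))
    sex[zeroIdx] <- ifelse(stats::runif(length(zeroIdx)) < 0.9,
                           "female", "male")

  site <- sample(sprintf("Site%02d", seq_len(cfg$nSites)), n, replace = TRUE)
  region <- c("West", "East")[1 + (as.integer(sub("Site", "", site)) %%
                                     2)]
  mtPool <- c("H1", "H3", "J1c", "K1a", "T2b", "U5b", "X2", "W1")
  yPool <- c("R1b", "R1a", "G2a", "I2a", "E1b")
  mt <- sample(mtPool, n, replace = TRUE)
  y <- ifelse(sex == "male", sample(yPool, n, replace = TRUE),
              NA_character_)

  cohort <- AncientCohort(data.frame(
    id = ids, sex = sex, site = site, region = region,
    upper_bce = upper, lower_bce = lower, mt_label = mt, y_label = y,
    steppe_prop = prop, se = cfg$noiseSd))
  list(cohort = cohort, trueDates = stats::setNames(tru, ids))
}
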