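#' Simulate allele-frequency pools by Balding-Nichols drift
#'
#' Ancestral frequencies are uniform on \code{ancestralRange}; each
#' population's frequencies are Beta-distributed around the ancestral
#' value with the population's divergence F:
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} (F = 0 copies the ancestral
#' frequencies).  Optional one-way gene flow mixes a recipient's
#' frequencies towards a donor after drift.
#'
#' @param nSnps number of SNPs.
#' @param fst named numeric of per-population divergences.
#' @param admixture optional named list: for each recipient population, a
#'   list \code{(from = donor, frac = mixing fraction)}.
#' @param ancestralRange range of the ancestral frequency draw.
#' @param seed integer seed.
#' @return list with \code{freqs} (SNP x population matrix) and
#'   \code{ancestral}.
#' @export
simulateDriftPools <- function(nSnps, fst, admixture = NULL,
                               ancestralRange = c(0.05, 0.95), seed = 1) {
  set.seed(subSeed(seed, "pools"))
  p <- stats::runif(nSnps, ancestralRange[1], ancestralRange[2])
  freqs <- vapply(fst, function(F) {
    if (F <= 0) return(p)
    stats::rbeta(nSnps, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }, numeric(nSnps))
  colnames(freqs) <- names(fst)
  for (rec in names(admixture)) {
    a <- admixture[[rec]]
    freqs[, rec] <- (1 - a$frac) * freqs[, rec] + a$frac * freqs[, a$from]
  }
  list(freqs = freqs, ancestral = p)
}

#' Draw pseudo-haploid individuals from frequency pools
#'
#' Each call is a single Bernoulli draw from the individual's
#' population-frequency column; missingness is independent per call.
#'
#' @param poolFreqs SNP x population frequency matrix.
#' @param nPerPop named integer: individuals per population.
#' @param missingRate per-call missingness.
#' @param chrom chromosome labels per SNP (default spread over 1..22).
#' @param seed integer seed.
#' @return A \linkS4class{PseudoHaploidGenotypes} with \code{colData$group}.
#' @export
simulatePoolGenotypes <- function(poolFreqs, nPerPop, missingRate = 0,
                                  chrom = NULL, seed = 1) {
  set.seed(subSeed(seed, "pool-genotypes"))
  nSnps <- nrow(poolFreqs)
  groups <- rep(names(nPerPop), nPerPop)
  nInd <- length(groups)
  calls <- matrix(NA_integer_, nSnps, nInd)
  for (j in seq_len(nInd))
    calls[, j] <- as.integer(stats::runif(nSnps) < poolFreqs[, groups[j]])
  if (missingRate > 0)
    calls[matrix(stats::runif(nSnps * nInd) < missingRate, nSnps, nInd)] <-
      NA_integer_
  ids <- sprintf("%s_%02d", groups, stats::ave(seq_len(nInd), groups,
                                               FUN = seq_along))
  colnames(calls) <- ids
  if (is.null(chrom)) chrom <- sort(rep_len(1:22, nSnps))
  PseudoHaploidGenotypes(
    calls, chrom = chrom, position = seq_len(nSnps) * 1000L,
    colData = S4Vectors::DataFrame(group = groups, row.names = ids))
}

#' Simulate two-source admixed pseudo-haploid genotypes for a cohort
#'
#' Two source allele-frequency pools (Neolithic-like and steppe-like)
#' diverge from a common ancestral frequency by Balding-Nichols drift
#' with the configured F.  Each call of each cohort individual is drawn
#' by first choosing a source with probability equal to the individual's
#' steppe-ancestry proportion, then sampling one allele from that pool;
#' X-chromosome SNPs use the female-shifted proportion
#' \code{prop * (1 - maleAdmixtureBias)}, realizing sex-biased admixture
#' as an autosome-vs-X difference.  Missingness is independent per call.
#' Reference individuals (steppe-like at proportion 1, Neolithic-like at
#' 0, plus a further-diverged outgroup pool) are appended for
#' f-statistics.
#'
#' Generator bookkeeping is kept in \code{metadata()}: \code{pools} (the
#' frequency pools), \code{sourceMatrix} (TRUE where the allele was drawn
#' from the steppe pool) and \code{sourceFractions} (realized per-
#' individual steppe-source fractions on autosomes and X), so estimators
#' can be scored against truth.
#'
#' @param cfg a [simulationConfig()].
#' @param cohort an \linkS4class{AncientCohort}; individuals without an
#'   ancestry observation are simulated at proportion 0.
#' @return A \linkS4class{PseudoHaploidGenotypes}.
#' @export
simulateGenotypes <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "SimulationConfig"), is(cohort, "AncientCohort"))
  df <- individuals(cohort)
  props <- ifelse(is.na(df$steppe_prop), 0, df$steppe_prop)
  nA <- cfg$nSnps; nX <- cfg$nXSnps
  nSnps <- nA + nX

  pools <- simulateDriftPools(
    nSnps, fst = c(neolithic = cfg$fstSources / 2,
                   steppe = cfg$fstSources / 2,
                   outgroup = cfg$outgroupFst),
    seed = subSeed(cfg$seed, "genotype-pools"))
  fN <- pools$freqs[, "neolithic"]
  fS <- pools$freqs[, "steppe"]

  set.seed(subSeed(cfg$seed, "genotypes"))
  isX <- c(rep(FALSE, nA), rep(TRUE, nX))
  nInd <- nrow(df)
  propMat <- matrix(rep(props, each = nSnps), nSnps, nInd)
  propMat[isX, ] <- propMat[isX, ] * (1 - cfg$maleAdmixtureBias)
  src <- matrix(stats::runif(nSnps * nInd), nSnps, nInd) < propMat
  pmat <- ifelse(src, fS, fN)
  calls <- matrix(as.integer(stats::runif(nSnps * nInd) < pmat),
                  nSnps, nInd)

  nRef <- cfg$nRefPerGroup
  refGroups <- c(rep("SteppeRef", nRef), rep("NeoRef", nRef),
                 rep("Outgroup", nRef))
  refFreq <- cbind(matrix(fS, nSnps, nRef), matrix(fN, nSnps, nRef),
                   matrix(pools$freqs[, "outgroup"], nSnps, nRef))
  refCalls <- matrix(as.integer(
    stats::runif(nSnps * length(refGroups)) < refFreq),
    nSnps, length(refGroups))

  all <- cbind(calls, refCalls)
  if (cfg$missingRate > 0)
    all[matrix(stats::runif(length(all)) < cfg$missingRate,
               nSnps, ncol(all))] <- NA_integer_
  ids <- c(df$id, sprintf("%s_%02d", refGroups,
                          c(seq_len(nRef), seq_len(nRef), seq_len(nRef))))
  colnames(all) <- ids

  chrom <- c(rep_len(1:22, nA)[order(rep_len(1:22, nA))], rep("X", nX))
  g <- PseudoHaploidGenotypes(
    all, chrom = chrom, position = c(seq_len(nA) * 1000L,
                                     seq_len(nX) * 1000L),
    colData = S4Vectors::DataFrame(
      group = c(rep("Cohort", nInd), refGroups),
      sex = c(df$sex, rep("unknown", length(refGroups))),
      row.names = ids))
  S4Vectors::metadata(g) <- list(
    pools = data.frame(ancestral = pools$ancestral, neolithic = fN,
                       steppe = fS, outgroup = pools$freqs[, "outgroup"]),
    sourceMatrix = src,
    sourceFractions = data.frame(
      id = df$id,
      autosome = colMeans(src[!isX, , drop = FALSE]),
      x = if (nX > 0) colMeans(src[isX, , drop = FALSE]) else NA_real_))
  g
}

#' Frequency pools calibrated to an expected pairwise-mismatch gap
#'
#' For pseudo-haploid individuals drawn from a pool with frequency p the
#' expected mismatch at a SNP is \code{2p(1-p) = 0.5 - 2(p-0.5)^2}, so a
#' pool whose frequencies are shrunk towards 0.5 by a factor
#' \code{s = sqrt(1 - gap / (2 * mean((p-0.5)^2)))} has a mean expected
#' mismatch exactly \code{gap} higher.  Used to inject a known
#' diversity shift between a before-cutoff and an after-cutoff group.
#'
#' @param nSnps number of SNPs.
#' @param gap target expected-mismatch increase of the second pool.
#' @param freqRange base-frequency range.
#' @param seed integer seed.
#' @return list with \code{before}, \code{after} frequency vectors and
#'   the exact expected mismatch of each.
#' @export
calibratedMismatchPools <- function(nSnps, gap = 0.009,
                                    freqRange = c(0.15, 0.85), seed = 1) {
  set.seed(subSeed(seed, "mismatch-pools"))
  q <- stats::runif(nSnps, freqRange[1], freqRange[2])
  v <- mean((q - 0.5)^2)
  if (gap > 2 * v) stop("gap too large for the base frequency spread")
  s <- sqrt(1 - gap / (2 * v))
  q2 <- 0.5 + (q - 0.5) * s
  list(before = q, after = q2,
       expectedBefore = mean(2 * q * (1 - q)),
       expectedAfter = mean(2 * q2 * (1 - q2)))
}
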