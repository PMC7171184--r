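#' Analysis run configuration
#'
#' Bundles the knobs shared by the pipeline stages, each with its
#' documented default: the date cutoff for the diversity comparison
#' (2700 calBCE), the pair-overlap threshold (10000 SNPs, exclusive),
#' the Monte Carlo repetition count (100000; scale down for quick runs),
#' the arrival-weight mode, the jackknife block size (500 SNPs), the
#' kinship classification cuts and the sex-ratio thresholds.  All
#' randomness flows from the single root seed via named per-stage
#' substreams ([subSeed()]).
#'
#' @param seed root seed.
#' @param cutoffBce diversity-shift cutoff, calBCE.
#' @param minOverlap pairwise-overlap threshold.
#' @param nReps Monte Carlo repetitions for the arrival model.
#' @param weightMode \code{"literal"} or \code{"scaled"}.
#' @param blockSize jackknife block size, SNPs.
#' @param kinshipThresholds the three [classifyDegree()] cuts.
#' @param sexThresholds c(femaleMax, maleMin) for [inferSex()].
#' @param paths optional named list of input/output paths.
#' @return A validated list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1, cutoffBce = 2700, minOverlap = 10000,
                      nReps = 100000, weightMode = "literal",
                      blockSize = 500,
                      kinshipThresholds = c(0.625, 0.8125, 0.90625),
                      sexThresholds = c(0.05, 0.20), paths = list()) {
  stopifnot(seed == as.integer(seed), cutoffBce > 0, minOverlap >= 1,
            nReps >= 1, weightMode %in% c("literal", "scaled"),
            blockSize >= 1, length(kinshipThresholds) == 3,
            length(sexThresholds) == 2)
  structure(list(seed = as.integer(seed), cutoffBce = cutoffBce,
                 minOverlap = minOverlap, nReps = nReps,
                 weightMode = weightMode, blockSize = blockSize,
                 kinshipThresholds = kinshipThresholds,
                 sexThresholds = sexThresholds, paths = paths),
            class = "RunConfig")
}

#' Read / write a RunConfig as YAML
#' @param path YAML file path.
#' @return [readRunConfig()]: a \code{RunConfig}; [writeRunConfig()]:
#'   \code{path}, invisibly.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' @rdname readRunConfig
#' @param config a [runConfig()].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' End-to-end demonstration run on a synthetic cohort
#'
#' Simulates a ~100-individual time-transect cohort (jump near 2750
#' calBCE, decline towards 0.25-0.35 by the youngest dates) plus
#' genotypes, pedigrees and reference panels, runs every stage —
#' arrival-time Monte Carlo, diversity shift, kinship classification
#' scored against generator truth, D statistic, autosome-vs-X contrast,
#' phenotype frequencies — and returns one structured report.  The
#' whole run is a deterministic function of \code{seed}.
#'
#' @param seed root seed.
#' @param nReps Monte Carlo repetitions for the arrival stage (default
#'   500 for a fast demonstration; raise towards 100000 for production
#'   smoothness).
#' @param nIndividuals cohort size.
#' @param outDir if non-NULL, writes \code{report.json} and
#'   \code{report.md} there.
#' @return list (invisibly when writing): \code{report} (named values),
#'   \code{arrival}, \code{diversity}, \code{kinship}, \code{fstats}
#'   objects, and \code{markdown} (the rendered report text).
#' @export
runDemo <- function(seed = 1, nReps = 500, nIndividuals = 100,
                    outDir = NULL) {
  cfg <- simulationConfig(nIndividuals = nIndividuals,
                          nSnps = 4000, nXSnps = 800,
                          missingRate = 0.1, maleAdmixtureBias = 0.5,
                          seed = subSeed(seed, "demo"))
  sim <- simulateCohort(cfg)
  cohort <- sim$cohort
  g <- simulateGenotypes(cfg, cohort)

  arrival <- monteCarloArrival(cohort, nReps = nReps,
                               seed = subSeed(seed, "demo-arrival"))

  # demo panels are far smaller than a 1240k capture; scale the overlap
  # threshold to the panel so pairs survive
  minOv <- round(cfg$nSnps / 8)
  pairs <- pairwiseMismatch(g[, individuals(cohort)$id],
                            minOverlap = minOv)
  diversity <- diversityShift(pairs, cohort, cutoff = 2700, nPerm = 999,
                              seed = subSeed(seed, "demo-diversity"))

  ped <- data.frame(
    id = c("GF", "GM", "F1", "M1", "C1", "C2", "U1", "U2"),
    father = c(NA, NA, "GF", NA, "F1", "F1", NA, NA),
    mother = c(NA, NA, "GM", NA, "M1", "M1", NA, NA),
    sex = c("male", "female", "male", "female", "male", "female",
            "male", "female"))
  pedsim <- simulatePedigree(ped, nSnps = 8000, missingRate = 0.2,
                             seed = subSeed(seed, "demo-pedigree"))
  calls <- kinshipCalls(pedsim$genotypes, pedsim$records,
                        minOverlap = 1000)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truthMap <- stats::setNames(pedsim$truth$degree,
                              key(pedsim$truth$id_a, pedsim$truth$id_b))
  truthDeg <- truthMap[key(calls$id_a, calls$id_b)]
  scored <- truthDeg %in% c("first", "unrelated")
  kinAcc <- mean((calls$degree == truthDeg)[scored])

  freqs <- groupFreqs(g)
  dres <- dStat(freqs, "Outgroup", "Cohort", "SteppeRef", "NeoRef",
                blockSize = 250)
  contrast <- xAutosomeContrast(g, testGroup = "Cohort",
                                steppeRefGroup = "SteppeRef",
                                outgroup = "Outgroup", blockSize = 250)

  report <- list(
    seed = seed,
    n_individuals = nIndividuals,
    true_te = cfg$trueParams[["te"]],
    arrival_te_mode = round(arrival@pointEstimate, 1),
    arrival_te_interval = round(arrival@interval, 1),
    arrival_retention = arrival@nRetained / arrival@nReps,
    diversity_effect = signif(diversity@effect, 4),
    diversity_p = signif(diversity@pValue, 4),
    kinship_accuracy = kinAcc,
    d_stat = signif(dres@value, 4),
    d_z = round(dres@z, 2),
    x_contrast_delta = signif(contrast$delta, 4),
    x_contrast_z = round(contrast$deltaZ, 2))

  md <- c(
    "# paleocohort demo report", "",
    sprintf("- seed: %d; cohort of %d individuals", seed, nIndividuals),
    sprintf("- generating jump time: %.0f calBCE", report$true_te),
    sprintf("- arrival-time KDE mode: %.1f calBCE (95%% interval %.1f-%.1f, retention %.2f)",
            report$arrival_te_mode, report$arrival_te_interval[1],
            report$arrival_te_interval[2], report$arrival_retention),
    sprintf("- diversity shift (after - before 2700 calBCE): %.4g (p = %.3g)",
            report$diversity_effect, report$diversity_p),
    sprintf("- kinship first-degree/unrelated accuracy vs truth: %.2f",
            report$kinship_accuracy),
    sprintf("- D(Outgroup, Cohort; SteppeRef, NeoRef) = %.4g (Z = %.2f)",
            report$d_stat, report$d_z),
    sprintf("- autosome-vs-X f3 contrast delta = %.4g (Z = %.2f)",
            report$x_contrast_delta, report$x_contrast_z))

  out <- list(report = report, arrival = arrival, diversity = diversity,
              kinship = calls, fstats = list(d = dres, contrast = contrast),
              markdown = paste(md, collapse = "\n"))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(out$markdown, file.path(outDir, "report.md"))
    return(invisible(out))
  }
  out
}
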