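test_that("cohort generator honours the model curve and its config", {
  cfg <- simulationConfig(nIndividuals = 200, noiseSd = 0,
                          zeroAncestryFraction = 0, seed = 5)
  sim <- simulateCohort(cfg)
  obs <- individuals(sim$cohort)$steppe_prop
  expect_equal(obs, unname(modelCurve(sim$trueDates, cfg$trueParams)))
  # pre-jump branch: zero ancestry by construction
  pre <- sim$trueDates > cfg$trueParams[["te"]]
  expect_true(all(obs[pre] == 0))
  # reported intervals contain the generating date
  df <- individuals(sim$cohort)
  expect_true(all(df$upper_bce + 0.5 >= sim$trueDates &
                  df$lower_bce - 0.5 <= sim$trueDates))
})

test_that("observation noise has the configured spread", {
  cfg <- simulationConfig(nIndividuals = 10000, noiseSd = 0.05,
                          zeroAncestryFraction = 0, seed = 6)
  sim <- simulateCohort(cfg)
  res <- individuals(sim$cohort)$steppe_prop -
    modelCurve(sim$trueDates, cfg$trueParams)
  # use the post-jump middle of the curve, away from the truncation at 0
  mid <- sim$trueDates < 2700 & sim$trueDates > 2000
  expect_gt(sd(res[mid]), 0.045)
  expect_lt(sd(res[mid]), 0.055)
  expect_true(all(individuals(sim$cohort)$steppe_prop >= 0 &
                  individuals(sim$cohort)$steppe_prop <= 1))
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- simulationConfig(nIndividuals = 30, nSnps = 200, nXSnps = 40,
                          seed = 7)
  a <- simulateCohort(cfg); b <- simulateCohort(cfg)
  expect_identical(individuals(a$cohort), individuals(b$cohort))
  expect_identical(a$trueDates, b$trueDates)
  ga <- simulateGenotypes(cfg, a$cohort)
  gb <- simulateGenotypes(cfg, b$cohort)
  expect_identical(genotypeCalls(ga), genotypeCalls(gb))
  expect_identical(S4Vectors::metadata(ga)$sourceMatrix,
                   S4Vectors::metadata(gb)$sourceMatrix)
})

test_that("zero-ancestry individuals are mostly female and exactly zero", {
  cfg <- simulationConfig(nIndividuals = 400, zeroAncestryFraction = 0.2,
                          seed = 8)
  sim <- simulateCohort(cfg)
  df <- individuals(sim$cohort)
  zero <- df$steppe_prop == 0 & sim$trueDates < cfg$trueParams[["te"]]
  expect_gt(sum(zero), 0)
  expect_gt(mean(df$sex[zero] == "female"), 0.75)
})

test_that("exchangeable genotypes match the analytic mismatch expectation", {
  cfg <- simulationConfig(nIndividuals = 20, nSnps = 2000, nXSnps = 0,
                          fstSources = 0, missingRate = 0, seed = 9,
                          zeroAncestryFraction = 1, nRefPerGroup = 2)
  sim <- simulateCohort(cfg)
  df <- individuals(sim$cohort); df$steppe_prop <- 0
  g <- simulateGenotypes(cfg, AncientCohort(df))
  cohortIds <- df$id
  pm <- pairwiseMismatch(g[, cohortIds], minOverlap = 100)
  p <- S4Vectors::metadata(g)$pools$neolithic
  expected <- mean(2 * p * (1 - p))
  expect_lt(abs(mean(pm$rate) - expected), 0.01)
})

test_that("missingness and sex-biased admixture behave as configured", {
  cfg <- simulationConfig(nIndividuals = 10, nSnps = 100, nXSnps = 20,
                          missingRate = 1, seed = 10)
  sim <- simulateCohort(cfg)
  g <- simulateGenotypes(cfg, sim$cohort)
  expect_true(all(is.na(genotypeCalls(g))))

  cfg2 <- simulationConfig(nIndividuals = 60, nSnps = 3000, nXSnps = 1500,
                           dateSpan = c(2700, 1800),
                           zeroAncestryFraction = 0,
                           maleAdmixtureBias = 0.6, missingRate = 0,
                           seed = 11)
  sim2 <- simulateCohort(cfg2)
  g2 <- simulateGenotypes(cfg2, sim2$cohort)
  sf <- S4Vectors::metadata(g2)$sourceFractions
  expect_gt(mean(sf$autosome), mean(sf$x))
})

test_that("pedigree transmission follows Mendelian and uniparental rules", {
  ped <- data.frame(
    id = c("F1", "M1", "S1", "D1", "T1"),
    father = c(NA, NA, "F1", "F1", NA),
    mother = c(NA, NA, "M1", "M1", NA),
    sex = c("male", "female", "male", "female", "male"),
    twin_of = c(NA, NA, NA, NA, "S1"))
  ps <- simulatePedigree(ped, nSnps = 30000, missingRate = 0, seed = 12)
  rec <- ps$records
  # matrilineal mtDNA, patrilineal Y
  expect_identical(rec$mt_label[rec$id == "D1"],
                   rec$mt_label[rec$id == "M1"])
  expect_identical(rec$y_label[rec$id == "S1"],
                   rec$y_label[rec$id == "F1"])
  expect_true(is.na(rec$y_label[rec$id == "D1"]))

  # pseudo-haploid mismatch ratios: parent-offspring 0.75x unrelated,
  # identical twins 0.5x (allele-draw enumeration under shared IBD)
  pm <- pairwiseMismatch(ps$genotypes, minOverlap = 1000)
  key <- paste(pm$id_a, pm$id_b)
  unrel <- pm$rate[key == "F1 M1"]
  po <- pm$rate[key == "F1 S1"]
  tw <- pm$rate[key == "S1 T1"]
  expect_lt(abs(po / unrel - 0.75), 0.03)
  expect_lt(abs(tw / unrel - 0.5), 0.03)

  # truth degrees from the kinship coefficients
  tr <- ps$truth
  deg <- function(a, b) tr$degree[tr$id_a == a & tr$id_b == b |
                                  tr$id_a == b & tr$id_b == a]
  expect_identical(deg("F1", "S1"), "first")
  expect_identical(deg("S1", "D1"), "first")
  expect_identical(deg("S1", "T1"), "identical")
  expect_identical(deg("F1", "M1"), "unrelated")
})

test_that("pedigree structural errors are rejected", {
  bad <- data.frame(id = c("A", "B"), father = c("B", "A"),
                    mother = c(NA, NA), sex = c("male", "male"))
  expect_error(simulatePedigree(bad, 10),
               "both parents or none|cyclic")
  cyc <- data.frame(id = c("A", "B"), father = c("B", "A"),
                    mother = c("B", "A"), sex = c("male", "male"))
  expect_error(simulatePedigree(cyc, 10), "cyclic|male|female")
  notmale <- data.frame(id = c("P", "C"), father = c(NA, "P"),
                        mother = c(NA, NA), sex = c("female", "male"))
  expect_error(simulatePedigree(notmale, 10), "father without male sex")
})

test_that("calibrated pools inject the requested mismatch gap exactly", {
  pools <- calibratedMismatchPools(5000, gap = 0.009, seed = 14)
  expect_equal(pools$expectedAfter - pools$expectedBefore, 0.009,
               tolerance = 1e-12)
})
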