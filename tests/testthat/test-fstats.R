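test_that("group frequencies count haploid calls", {
  m <- cbind(a = c(1L, NA, 1L), b = c(1L, NA, 0L), c = c(1L, NA, 0L),
             d = c(0L, NA, 0L))
  g <- PseudoHaploidGenotypes(m, chrom = c(1, 1, 2), position = 1:3)
  fr <- groupFreqs(g, setNames(rep("G", 4), colnames(m)))
  expect_equal(unname(fr$freq[1, "G"]), 0.75)
  expect_equal(unname(fr$nObs[1, "G"]), 4)
  expect_true(is.na(fr$freq[2, "G"]))      # all missing: undefined
  expect_equal(unname(fr$freq[3, "G"]), 0.25)
  expect_error(groupFreqs(g, c(zz = "G")), "absent")
  # 1 derived among 12 covered reports 0.0833 (8% at table precision)
  m2 <- matrix(c(1L, rep(0L, 11)), nrow = 1)
  colnames(m2) <- sprintf("i%02d", 1:12)
  g2 <- PseudoHaploidGenotypes(m2, chrom = 1, position = 1)
  fr2 <- groupFreqs(g2, setNames(rep("Spreitenbach", 12), colnames(m2)))
  expect_equal(unname(fr2$freq[1, 1]), 1 / 12, tolerance = 1e-12)
})

test_that("f3 and D match per-SNP loop oracles on random fixtures", {
  set.seed(441)
  for (k in 1:5) {
    f <- matrix(runif(500 * 4), 500, 4,
                dimnames = list(NULL, c("O", "A", "B", "C")))
    f[sample(2000, 50)] <- NA
    fr <- list(freq = f, nObs = f * 0 + 10, snps = NULL)
    class(fr) <- "GroupFrequencies"
    expect_equal(outgroupF3(fr, "O", "A", "B", blockSize = 50)@value,
                 naiveF3(f[, "O"], f[, "A"], f[, "B"]), tolerance = 1e-12)
    expect_equal(dStat(fr, "O", "A", "B", "C", blockSize = 50)@value,
                 naiveD(f[, "O"], f[, "A"], f[, "B"], f[, "C"]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate frequency configurations give zero statistics", {
  f <- matrix(runif(300), 300, 1)[, c(1, 1, 1, 1)]
  colnames(f) <- c("O", "A", "B", "C")
  fr <- structure(list(freq = f, nObs = f * 0 + 5, snps = NULL),
                  class = "GroupFrequencies")
  expect_equal(outgroupF3(fr, "O", "A", "B", blockSize = 50)@value, 0)
  # fY == fZ everywhere: D numerator vanishes
  f2 <- f; f2[, "A"] <- runif(300)
  fr2 <- structure(list(freq = f2, nObs = f2 * 0 + 5, snps = NULL),
                   class = "GroupFrequencies")
  expect_equal(dStat(fr2, "O", "A", "B", "C", blockSize = 50)@value, 0)
})

test_that("statistics are invariant to block permutation and allele flips", {
  set.seed(442)
  f <- matrix(runif(400 * 4, 0.05, 0.95), 400, 4,
              dimnames = list(NULL, c("W", "X", "Y", "Z")))
  mk <- function(f) structure(list(freq = f, nObs = f * 0 + 8,
                                   snps = NULL),
                              class = "GroupFrequencies")
  d0 <- dStat(mk(f), "W", "X", "Y", "Z", blockSize = 100)
  # permute whole blocks
  perm <- c(201:300, 1:100, 301:400, 101:200)
  d1 <- dStat(mk(f[perm, ]), "W", "X", "Y", "Z", blockSize = 100)
  expect_equal(d1@value, d0@value, tolerance = 1e-12)
  expect_equal(d1@se, d0@se, tolerance = 1e-12)
  # flip ref/alt at some SNPs in ALL groups: D unchanged
  flip <- sample(400, 120)
  f2 <- f; f2[flip, ] <- 1 - f2[flip, ]
  d2 <- dStat(mk(f2), "W", "X", "Y", "Z", blockSize = 100)
  expect_equal(d2@value, d0@value, tolerance = 1e-12)
})

test_that("shared drift orders f3 and drives it positive", {
  pools <- simulateDriftPools(4000, fst = c(O = 0.4, A = 0.04, B = 0.04,
                                            C = 0.25), seed = 443)
  g <- simulatePoolGenotypes(pools$freqs, c(O = 12, A = 12, B = 12, C = 12),
                             missingRate = 0.05, seed = 444)
  fr <- groupFreqs(g)
  sisters <- outgroupF3(fr, "O", "A", "B", blockSize = 200)
  expect_gt(sisters@value, 0)
  expect_gt(sisters@z, 3)
  # f3(O; A, A) >= f3(O; A, B-more-diverged)
  far <- outgroupF3(fr, "O", "A", "C", blockSize = 200)
  expect_gt(outgroupF3(fr, "O", "A", "A", blockSize = 200)@value,
            far@value)
  expect_gt(sisters@value, far@value)
})

test_that("jackknife error shrinks with more blocks on homogeneous data", {
  set.seed(445)
  f <- matrix(runif(6000 * 3, 0.1, 0.9), 6000, 3,
              dimnames = list(NULL, c("O", "A", "B")))
  fr <- structure(list(freq = f, nObs = f * 0 + 10, snps = NULL),
                  class = "GroupFrequencies")
  seCoarse <- outgroupF3(fr, "O", "A", "B", blockSize = 1500)@se
  seFine <- outgroupF3(fr, "O", "A", "B", blockSize = 100)@se
  # same data, so the estimates agree and the SEs are comparable in
  # magnitude; the fine blocking must not be degenerate
  expect_gt(seFine, 0)
  expect_gt(seCoarse, 0)
  expect_lt(abs(log(seFine / seCoarse)), log(3))
  expect_error(outgroupF3(fr, "O", "A", "B", blockSize = 6000), "blocks")
})

test_that("x-autosome contrast needs both SNP classes", {
  cfg <- simulationConfig(nIndividuals = 20, nSnps = 300, nXSnps = 0,
                          seed = 446)
  sim <- simulateCohort(cfg)
  g <- simulateGenotypes(cfg, sim$cohort)
  expect_error(
    xAutosomeContrast(g, testGroup = "Cohort",
                      steppeRefGroup = "SteppeRef", outgroup = "Outgroup"),
    "X")
})

test_that("phenotype report frequencies, coverage and damage flags", {
  m <- rbind(rs4988235 = c(1L, 0L, 0L, 0L),
             rs12913832 = c(1L, 1L, NA, 0L),
             other = c(NA, NA, NA, NA))
  colnames(m) <- c("i1", "i2", "i3", "i4")
  g <- PseudoHaploidGenotypes(m, chrom = c(2, 15, 1),
                              position = c(136608646, 28365618, 1),
                              snpId = rownames(m),
                              ref = c("G", "A", "C"),
                              alt = c("A", "G", "G"))
  rep <- phenotypeReport(g, setNames(rep("LateNeolithic", 4), colnames(m)),
                         snpIds = c("rs4988235", "rs12913832", "rs999"))
  lct <- rep[rep$snp_id == "rs4988235", ]
  expect_equal(lct$freq, 0.25)
  expect_equal(lct$n_covered, 4L)
  expect_true(lct$damage_flag)                  # G/A pair involves A
  herc <- rep[rep$snp_id == "rs12913832", ]
  expect_equal(herc$n_covered, 3L)
  expect_true(herc$damage_flag)                 # A/G variant
  absent <- rep[rep$snp_id == "rs999", ]        # not on the panel
  expect_equal(absent$n_covered, 0L)
  expect_true(is.na(absent$freq))
})
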