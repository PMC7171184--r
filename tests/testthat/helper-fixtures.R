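# shared fixtures and independent oracles used across the suite

# random pseudo-haploid matrix (SNPs x individuals) with missingness
randomCalls <- function(nSnps, nInd, missingRate = 0.1, p = 0.5) {
  m <- matrix(as.integer(runif(nSnps * nInd) < p), nSnps, nInd)
  if (missingRate > 0)
    m[matrix(runif(nSnps * nInd) < missingRate, nSnps, nInd)] <- NA_integer_
  colnames(m) <- sprintf("I%03d", seq_len(nInd))
  m
}

randomGenotypes <- function(nSnps, nInd, missingRate = 0.1, nX = 0) {
  chrom <- c(sort(rep_len(1:22, nSnps - nX)), rep("X", nX))
  PseudoHaploidGenotypes(randomCalls(nSnps, nInd, missingRate),
                         chrom = chrom, position = seq_len(nSnps))
}

# brute-force double-loop mismatch oracle
naiveMismatch <- function(m, minOverlap) {
  ids <- colnames(m)
  out <- NULL
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    n <- sum(ok)
    if (n > minOverlap)
      out <- rbind(out, data.frame(
        id_a = ids[i], id_b = ids[j], n_overlap = n,
        rate = sum(m[ok, i] != m[ok, j]) / n))
  }
  out
}

# per-SNP loop oracles for the f statistics (no blocking; value only)
naiveF3 <- function(fo, fa, fb) {
  vals <- numeric(0)
  for (s in seq_along(fo))
    if (!is.na(fo[s]) && !is.na(fa[s]) && !is.na(fb[s]))
      vals <- c(vals, (fo[s] - fa[s]) * (fo[s] - fb[s]))
  mean(vals)
}
naiveD <- function(fw, fx, fy, fz) {
  num <- den <- 0
  for (s in seq_along(fw)) {
    if (anyNA(c(fw[s], fx[s], fy[s], fz[s]))) next
    num <- num + (fw[s] - fx[s]) * (fy[s] - fz[s])
    den <- den + (fw[s] + fx[s] - 2 * fw[s] * fx[s]) *
                 (fy[s] + fz[s] - 2 * fy[s] * fz[s])
  }
  num / den
}

# small cohort table for IO and grouping tests
toyCohortDf <- function() {
  data.frame(
    id = c("MX193", "OB001", "OB002", "SG001", "SG002"),
    sex = c("female", "male", "male", "female", "unknown"),
    site = c("Aesch", "Oberbipp", "Oberbipp", "Singen", "Singen"),
    region = c("West", "West", "West", "East", "East"),
    upper_bce = c(2213, 3300, 3250, 2450, 2400),
    lower_bce = c(2031, 3100, 3050, 2300, 2250),
    mt_label = c("U5b", "H1", "H1", "J1c", NA),
    y_label = c(NA, "R1b", "R1b", NA, NA),
    steppe_prop = c(0, NA, 0.05, 0.55, 0.48),
    se = c(0.02, NA, 0.02, 0.04, 0.05),
    stringsAsFactors = FALSE)
}

# noise-free arrival fixture whose dates bracket the jump tightly, so the
# jump time is identified to well under the test tolerance
bracketedArrivalFixture <- function(params = arrivalParams(0.1, 0.8, 2750)) {
  te <- params[["te"]]
  dates <- c(seq(4400, te + 50, length.out = 15), te + 0.5,
             te - 0.5, seq(te - 20, 1800, length.out = 33))
  list(dates = dates, props = modelCurve(dates, params), params = params)
}
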