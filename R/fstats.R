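#' Per-group derived-allele frequencies
#'
#' Frequencies are haploid counts from pseudo-haploid calls (derived
#' calls / non-missing calls per SNP per group); no diploid or
#' within-group heterozygosity correction is applied — the pseudo-
#' haploid convention.  Male and female X calls each count once.
#' SNPs with zero non-missing calls in a group are undefined (NA).
#'
#' @param g a \linkS4class{PseudoHaploidGenotypes}.
#' @param assignment named character (id -> group), a data.frame with
#'   \code{id} and \code{group}, or NULL to use \code{colData(g)$group}.
#' @return list of class \code{GroupFrequencies} with \code{freq} and
#'   \code{nObs} (SNP x group matrices) and \code{snps} (the
#'   \code{GRanges} annotation).
#' @export
groupFreqs <- function(g, assignment = NULL) {
  stopifnot(is(g, "PseudoHaploidGenotypes"))
  if (is.null(assignment)) {
    cd <- SummarizedExperiment::colData(g)
    if (!"group" %in% colnames(cd))
      stop("no assignment given and colData(g) has no 'group' column")
    assignment <- stats::setNames(cd$group, colnames(g))
  }
  if (is.data.frame(assignment))
    assignment <- stats::setNames(assignment$group, assignment$id)
  unknown <- setdiff(names(assignment), colnames(g))
  if (length(unknown))
    stop("assigned id(s) absent from genotypes: ",
         paste(unknown, collapse = ", "))
  m <- genotypeCalls(g)
  groups <- unique(assignment)
  freq <- nObs <- matrix(NA_real_, nrow(m), length(groups),
                         dimnames = list(rownames(m), groups))
  for (grp in groups) {
    ids <- names(assignment)[assignment == grp]
    if (!length(ids)) stop("empty group: ", grp)
    sub <- m[, ids, drop = FALSE]
    n <- rowSums(!is.na(sub))
    d <- rowSums(sub == 1L, na.rm = TRUE)
    nObs[, grp] <- n
    freq[, grp] <- ifelse(n > 0, d / n, NA_real_)
  }
  structure(list(freq = freq, nObs = nObs, snps = snpInfo(g)),
            class = "GroupFrequencies")
}

# weighted delete-one-block jackknife for a ratio-of-sums statistic
# (Busing et al. 1999); den = 1 per SNP turns it into a mean
.blockJackknife <- function(num, den, blockSize) {
  n <- length(num)
  if (n < 2) stop("need >= 2 usable SNPs")
  starts <- seq(1, n, by = blockSize)
  blocks <- findInterval(seq_len(n), starts)
  B <- max(blocks)
  if (B < 2)
    stop(sprintf("fewer than 2 blocks (%d SNPs, block size %d)",
                 n, blockSize))
  m <- tabulate(blocks, B)
  Snum <- sum(num); Sden <- sum(den)
  if (Sden == 0) stop("zero denominator")
  bn <- vapply(seq_len(B), function(j) sum(num[blocks == j]), numeric(1))
  bd <- vapply(seq_len(B), function(j) sum(den[blocks == j]), numeric(1))
  theta <- Snum / Sden
  thetaJ <- (Snum - bn) / (Sden - bd)
  w <- m / n
  h <- n / m
  thetaDot <- B * theta - sum((1 - w) * thetaJ)
  tau <- h * theta - (h - 1) * thetaJ
  var <- mean((tau - thetaDot)^2 / (h - 1))
  list(value = theta, se = sqrt(var), nBlocks = B, nSnps = n)
}

.fstatResult <- function(stat, jk) {
  new("FStatResult", statistic = stat, value = jk$value, se = jk$se,
      z = if (jk$se > 0) jk$value / jk$se else NaN,
      nSnps = as.integer(jk$nSnps), nBlocks = as.integer(jk$nBlocks))
}

#' Outgroup f3 statistic with block-jackknife error
#'
#' \code{f3(O; A, B) = mean over SNPs of (fO - fA)(fO - fB)}: the shared
#' drift of A and B relative to the outgroup O — larger values mean more
#' shared ancestry.  Only SNPs with defined frequencies in all three
#' groups are used; the standard error is a weighted delete-one-block
#' jackknife over contiguous SNP blocks.
#'
#' @param freqs a [groupFreqs()] result.
#' @param outgroup,a,b group names.
#' @param blockSize SNPs per jackknife block (default 500).
#' @return An \linkS4class{FStatResult}.
#' @export
outgroupF3 <- function(freqs, outgroup, a, b, blockSize = 500) {
  f <- freqs$freq
  use <- stats::complete.cases(f[, c(outgroup, a, b)])
  fo <- f[use, outgroup]; fa <- f[use, a]; fb <- f[use, b]
  jk <- .blockJackknife((fo - fa) * (fo - fb), rep(1, sum(use)), blockSize)
  .fstatResult("f3", jk)
}

#' D statistic with block-jackknife error
#'
#' \deqn{D(W, X; Y, Z) = \frac{\sum_s (f_W - f_X)(f_Y - f_Z)}
#'   {\sum_s (f_W + f_X - 2 f_W f_X)(f_Y + f_Z - 2 f_Y f_Z)}}
#' over SNPs with defined frequencies in all four groups.  D = 0 under
#' treeness of ((W, X), (Y, Z)); under the ordering convention used here
#' gene flow from Y into X drives D negative (X and Y share excess
#' alleles).  Jackknife SE weighted by per-block SNP counts.
#'
#' @param freqs a [groupFreqs()] result.
#' @param w,x,y,z group names.
#' @param blockSize SNPs per jackknife block.
#' @return An \linkS4class{FStatResult}.
#' @export
dStat <- function(freqs, w, x, y, z, blockSize = 500) {
  f <- freqs$freq
  use <- stats::complete.cases(f[, c(w, x, y, z)])
  fw <- f[use, w]; fx <- f[use, x]; fy <- f[use, y]; fz <- f[use, z]
  num <- (fw - fx) * (fy - fz)
  den <- (fw + fx - 2 * fw * fx) * (fy + fz - 2 * fy * fz)
  jk <- .blockJackknife(num, den, blockSize)
  .fstatResult("D", jk)
}

#' Autosome-versus-X outgroup-f3 contrast for sex-biased admixture
#'
#' Computes \code{f3(outgroup; test, steppeRef)} separately on autosomal
#' and X-chromosome SNPs and reports
#' \code{delta = f3_autosomes - f3_X} with a combined jackknife SE
#' (independent block sets).  When steppe ancestry entered predominantly
#' through males, the X chromosome carries less of it, the test group's
#' X is less closely related to the steppe reference, and delta is
#' positive.
#'
#' @param g a \linkS4class{PseudoHaploidGenotypes} containing both
#'   autosomal and X SNPs.
#' @param assignment as in [groupFreqs()].
#' @param testGroup,steppeRefGroup,outgroup group names.
#' @param blockSize autosomal block size; the X block size is scaled
#'   down proportionally to the X SNP share (at least 2 X blocks are
#'   required or an error names the count).
#' @return list with \code{f3Auto}, \code{f3X}
#'   (\linkS4class{FStatResult}s), \code{delta}, \code{deltaSe},
#'   \code{deltaZ}.
#' @export
xAutosomeContrast <- function(g, assignment = NULL, testGroup,
                              steppeRefGroup, outgroup, blockSize = 500) {
  x <- isXSnp(g)
  if (!any(x)) stop("no X-chromosome SNPs present")
  if (!any(!x)) stop("no autosomal SNPs present")
  fa <- groupFreqs(g[!x, ], assignment)
  fx <- groupFreqs(g[x, ], assignment)
  xBlock <- max(2, round(blockSize * sum(x) / sum(!x)))
  f3a <- outgroupF3(fa, outgroup, testGroup, steppeRefGroup, blockSize)
  nXuse <- sum(stats::complete.cases(
    fx$freq[, c(outgroup, testGroup, steppeRefGroup)]))
  if (nXuse / xBlock < 2)
    stop(sprintf("too few X blocks: %d usable X SNPs give %d block(s)",
                 nXuse, max(1L, nXuse %/% xBlock)))
  f3x <- outgroupF3(fx, outgroup, testGroup, steppeRefGroup, xBlock)
  delta <- f3a@value - f3x@value
  se <- sqrt(f3a@se^2 + f3x@se^2)
  list(f3Auto = f3a, f3X = f3x, delta = delta, deltaSe = se,
       deltaZ = delta / se)
}

#' Derived-allele frequency report for phenotypic SNPs
#'
#' Per group and SNP: derived-allele frequency among covered individuals
#' and the covered count.  Positions whose ref/alt pair involves A or T
#' are flagged (\code{damage_flag}): at low coverage, post-mortem
#' deamination (C-to-T / G-to-A) can mimic such alleles, so these calls
#' deserve scrutiny — the flag automates the manual inspection such
#' positions traditionally receive.  SNPs absent from the panel are
#' reported as uncovered, not an error.  Defaults cover the classic
#' pigmentation and lactase-persistence set: SLC45A2 (rs16891982),
#' SLC24A5 (rs1426654), HERC2 (rs12913832), LCT (rs4988235).
#'
#' @param g a \linkS4class{PseudoHaploidGenotypes}.
#' @param assignment as in [groupFreqs()].
#' @param snpIds SNP ids to report.
#' @return data.frame with \code{group}, \code{snp_id}, \code{freq},
#'   \code{n_covered}, \code{n_group}, \code{damage_flag}.
#' @export
phenotypeReport <- function(g, assignment = NULL,
                            snpIds = c("rs16891982", "rs1426654",
                                       "rs12913832", "rs4988235")) {
  stopifnot(is(g, "PseudoHaploidGenotypes"))
  if (is.null(assignment)) {
    cd <- SummarizedExperiment::colData(g)
    assignment <- stats::setNames(cd$group, colnames(g))
  }
  if (is.data.frame(assignment))
    assignment <- stats::setNames(assignment$group, assignment$id)
  rr <- snpInfo(g)
  m <- genotypeCalls(g)
  groups <- unique(assignment)
  out <- expand.grid(group = groups, snp_id = snpIds,
                     stringsAsFactors = FALSE)
  out$freq <- NA_real_
  out$n_covered <- 0L
  out$n_group <- as.integer(table(assignment)[out$group])
  out$damage_flag <- FALSE
  for (k in seq_len(nrow(out))) {
    i <- match(out$snp_id[k], rr$snp_id)
    if (is.na(i)) next                      # absent from panel: uncovered
    ids <- names(assignment)[assignment == out$group[k]]
    calls <- m[i, ids]
    n <- sum(!is.na(calls))
    out$n_covered[k] <- n
    if (n > 0) out$freq[k] <- sum(calls == 1L, na.rm = TRUE) / n
    out$damage_flag[k] <- any(c(rr$ref[i], rr$alt[i]) %in% c("A", "T"))
  }
  out
}
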