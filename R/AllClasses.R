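#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Pseudo-haploid genotype container
#'
#' Extends \linkS4class{RangedSummarizedExperiment} with a single assay
#' \code{"calls"} holding one haploid call per individual per SNP:
#' \code{0} = reference allele, \code{1} = alternative/derived allele,
#' \code{NA} = missing.  Heterozygous calls cannot be represented, by
#' construction: each ancient individual contributes a single randomly
#' sampled allele per site, the standard representation for low-coverage
#' ancient DNA.  Rows are SNPs (with chromosome, position and ref/alt
#' alleles in \code{rowRanges}), columns are individuals.
#'
#' @slot .. inherits all slots from \code{RangedSummarizedExperiment}.
#' @seealso [PseudoHaploidGenotypes()] for the constructor,
#'   [readEigenstrat()] / [writeEigenstrat()] for file IO.
#' @export
setClass("PseudoHaploidGenotypes", contains = "RangedSummarizedExperiment")

setValidity("PseudoHaploidGenotypes", function(object) {
  msgs <- character()
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    msgs <- c(msgs, "assay 'calls' is required")
  else {
    m <- SummarizedExperiment::assay(object, "calls")
    bad <- m[!is.na(m)]
    if (length(bad) && !all(bad %in% c(0L, 1L)))
      msgs <- c(msgs,
        "calls must be 0 (ref), 1 (derived) or NA; pseudo-haploid data has no heterozygotes")
  }
  sn <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))
  ok <- sn %in% c(as.character(1:22), "X")
  if (!all(ok))
    msgs <- c(msgs, sprintf("unsupported chromosome label(s): %s",
                            paste(unique(sn[!ok]), collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "individual ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PseudoHaploidGenotypes object
#'
#' @param calls integer/numeric matrix, SNPs in rows and individuals in
#'   columns; values 0, 1 or NA.  Column names are individual ids.
#' @param chrom chromosome per SNP, in \code{1:22} or \code{"X"}
#'   (\code{"23"} is accepted and mapped to \code{"X"}).
#' @param position 1-based physical position per SNP.
#' @param snpId SNP identifiers; defaults to \code{snp1, snp2, ...}.
#' @param ref,alt reference and alternative allele letters per SNP.
#' @param colData optional \code{DataFrame} of per-individual annotation.
#' @return A \linkS4class{PseudoHaploidGenotypes} object.
#' @examples
#' g <- PseudoHaploidGenotypes(
#'   matrix(c(0, 1, NA, 1), 2, 2, dimnames = list(NULL, c("I1", "I2"))),
#'   chrom = c(1, "X"), position = c(100, 200))
#' @export
PseudoHaploidGenotypes <- function(calls, chrom, position, snpId = NULL,
                                   ref = NULL, alt = NULL, colData = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n <- nrow(calls)
  chrom <- as.character(chrom)
  chrom[chrom == "23"] <- "X"
  if (is.null(snpId)) snpId <- paste0("snp", seq_len(n))
  if (is.null(ref)) ref <- rep("G", n)
  if (is.null(alt)) alt <- rep("A", n)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("ind", seq_len(ncol(calls)))
  rr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(position), width = 1L),
    snp_id = as.character(snpId), ref = as.character(ref),
    alt = as.character(alt))
  names(rr) <- as.character(snpId)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(calls))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = rr, colData = colData)
  new("PseudoHaploidGenotypes", se)
}

#' Ancient cohort metadata with ancestry observations
#'
#' One row per dated ancient individual: id, genetic sex, site and region,
#' the calibrated radiocarbon interval (calBCE; positive values increase
#' into the past, negative values denote CE dates), mtDNA haplotype and Y
#' haplogroup labels, and the upstream qpAdm-style steppe-ancestry
#' proportion with its standard error (NA when no ancestry estimate is
#' available for the individual).
#'
#' @slot individuals a \code{DataFrame} with columns \code{id}, \code{sex}
#'   (\code{"female"}, \code{"male"}, \code{"unknown"}), \code{site},
#'   \code{region}, \code{upper_bce}, \code{lower_bce}, \code{mt_label},
#'   \code{y_label}, \code{steppe_prop}, \code{se}.
#' @seealso [AncientCohort()], [readCohort()], [simulateCohort()]
#' @export
setClass("AncientCohort", slots = c(individuals = "DataFrame"))

.cohort_cols <- c("id", "sex", "site", "region", "upper_bce", "lower_bce",
                  "mt_label", "y_label", "steppe_prop", "se")

setValidity("AncientCohort", function(object) {
  df <- object@individuals
  msgs <- character()
  miss <- setdiff(.cohort_cols, colnames(df))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$id))
    msgs <- c(msgs, "duplicate individual id(s)")
  if (!all(df$sex %in% c("female", "male", "unknown")))
    msgs <- c(msgs, "sex must be female/male/unknown")
  if (any(df$upper_bce < df$lower_bce, na.rm = TRUE))
    msgs <- c(msgs, "upper_bce (older bound) must be >= lower_bce")
  p <- df$steppe_prop
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msgs <- c(msgs, "steppe_prop outside [0, 1]")
  badY <- df$sex == "female" & !is.na(df$y_label)
  if (any(badY))
    msgs <- c(msgs, sprintf("y_label present for female individual(s): %s",
                            paste(df$id[badY], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an AncientCohort
#'
#' @param individuals data.frame (or DataFrame) with the columns described
#'   in \linkS4class{AncientCohort}; \code{mt_label}, \code{y_label},
#'   \code{steppe_prop} and \code{se} may be omitted and default to NA.
#' @return An \linkS4class{AncientCohort}.
#' @export
AncientCohort <- function(individuals) {
  df <- as.data.frame(individuals, stringsAsFactors = FALSE)
  for (col in c("mt_label", "y_label"))
    if (!col %in% colnames(df)) df[[col]] <- NA_character_
  for (col in c("steppe_prop", "se"))
    if (!col %in% colnames(df)) df[[col]] <- NA_real_
  df$id <- as.character(df$id)
  df$upper_bce <- as.numeric(df$upper_bce)
  df$lower_bce <- as.numeric(df$lower_bce)
  new("AncientCohort", individuals = S4Vectors::DataFrame(df[, .cohort_cols]))
}

#' Jump-plus-exponential-decay model parameters
#'
#' The steppe-ancestry trajectory is 0 before the jump time \code{te}
#' (calBCE, i.e. for dates older than \code{te}), jumps to \code{pe} at
#' \code{te}, and decays exponentially towards the present so that it is
#' projected to reach \code{p0} at time zero (0 BCE/CE).
#'
#' @param p0 projected proportion at time zero; \code{0 < p0 <= pe}.
#' @param pe proportion at the jump; \code{pe <= 1}.
#' @param te jump time, years calBCE; \code{te > 0}.
#' @return Named numeric vector of class \code{ArrivalParams}.
#' @examples arrivalParams(0.1, 0.8, 2750)
#' @export
arrivalParams <- function(p0, pe, te) {
  stopifnot(is.numeric(p0), is.numeric(pe), is.numeric(te))
  if (!(p0 > 0 && p0 <= pe && pe <= 1))
    stop("require 0 < p0 <= pe <= 1")
  if (te <= 0) stop("te must be > 0 (years calBCE)")
  structure(c(p0 = p0, pe = pe, te = te), class = "ArrivalParams")
}

#' One bounded least-squares fit of the arrival model
#'
#' @slot params named numeric (p0, pe, te) at the optimum.
#' @slot rss residual sum of squares at the optimum (squared-proportion
#'   units), after the zero-residual masking rule.
#' @slot converged logical; optimizer reported convergence.
#' @slot hessianPD logical; all eigenvalues of the finite-difference
#'   Hessian at the optimum exceed the positive-definiteness tolerance.
#'   Only meaningful when \code{converged}.
#' @slot nUsed number of observations contributing residuals.
#' @slot nZeroMasked number of zero-ancestry observations dated after the
#'   fitted jump whose residual was set to zero.
#' @slot start the starting parameter values used.
#' @slot teBounds the box constraint applied to te.
#' @export
setClass("ArrivalFit", slots = c(
  params = "numeric", rss = "numeric", converged = "logical",
  hessianPD = "logical", nUsed = "integer", nZeroMasked = "integer",
  start = "numeric", teBounds = "numeric"))

#' Monte Carlo arrival-time estimate under date uncertainty
#'
#' @slot teSamples data.frame with one row per retained repetition:
#'   \code{te}, \code{rss}, \code{weight} (in (0,1], max 1).
#' @slot kde data.frame \code{te}, \code{density}: the weighted Gaussian
#'   kernel density, normalized to integrate to 1 over the grid.
#' @slot pointEstimate te at the density mode (years calBCE).
#' @slot interval central 95\% of the weighted te sample.
#' @slot nReps,nRetained repetitions attempted / retained (converged with
#'   positive-definite Hessian).
#' @slot bandwidth KDE bandwidth (years).
#' @slot weightMode \code{"literal"} or \code{"scaled"}.
#' @export
setClass("ArrivalEstimate", slots = c(
  teSamples = "data.frame", kde = "data.frame", pointEstimate = "numeric",
  interval = "numeric", nReps = "integer", nRetained = "integer",
  bandwidth = "numeric", weightMode = "character"))

#' f-statistic result with block-jackknife error
#'
#' @slot statistic \code{"f3"} or \code{"D"}.
#' @slot value the statistic.
#' @slot se weighted delete-one-block jackknife standard error.
#' @slot z \code{value / se}.
#' @slot nSnps number of jointly defined SNPs used.
#' @slot nBlocks number of contiguous SNP blocks.
#' @export
setClass("FStatResult", slots = c(
  statistic = "character", value = "numeric", se = "numeric", z = "numeric",
  nSnps = "integer", nBlocks = "integer"))

#' Diversity shift across a date cutoff
#'
#' @slot effect mean pairwise mismatch rate difference (after - before).
#' @slot pValue two-sided permutation p-value (add-one corrected).
#' @slot confint effect plus the central 95\% of the centred permutation
#'   distribution (a permutation interval for the effect).
#' @slot nPairsBefore,nPairsAfter pair counts per period.
#' @slot perSite site-level decomposition (within-site pairs only).
#' @slot permEffects the null permutation effects.
#' @slot lmConfint 95\% CI for the period effect from a linear model on
#'   per-individual mean mismatch rates (cluster-aggregated response).
#' @export
setClass("DiversityShiftResult", slots = c(
  effect = "numeric", pValue = "numeric", confint = "numeric",
  nPairsBefore = "integer", nPairsAfter = "integer",
  perSite = "data.frame", permEffects = "numeric", lmConfint = "numeric"))
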