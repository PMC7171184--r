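#' @include AllClasses.R
NULL

#' Accessors for paleocohort classes
#'
#' \code{genotypeCalls} returns the SNP-by-individual call matrix,
#' \code{snpInfo} the SNP annotation as a \code{GRanges},
#' \code{isXSnp} a logical marking X-chromosome SNPs,
#' \code{individuals} the per-individual metadata of a cohort,
#' \code{ancestryObservations} the subset of individuals carrying an
#' ancestry estimate, and \code{dateMidpoints} the radiocarbon interval
#' midpoints (calBCE).
#'
#' @param x a \linkS4class{PseudoHaploidGenotypes} or
#'   \linkS4class{AncientCohort} object.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "PseudoHaploidGenotypes", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setMethod("snpInfo", "PseudoHaploidGenotypes", function(x)
  SummarizedExperiment::rowRanges(x))

#' @rdname accessors
#' @export
setGeneric("isXSnp", function(x) standardGeneric("isXSnp"))

#' @rdname accessors
#' @export
setMethod("isXSnp", "PseudoHaploidGenotypes", function(x)
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x))) == "X")

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname accessors
#' @export
setMethod("individuals", "AncientCohort", function(x)
  as.data.frame(x@individuals))

#' @rdname accessors
#' @export
setGeneric("ancestryObservations", function(x)
  standardGeneric("ancestryObservations"))

#' @rdname accessors
#' @export
setMethod("ancestryObservations", "AncientCohort", function(x) {
  df <- as.data.frame(x@individuals)
  df[!is.na(df$steppe_prop), c("id", "steppe_prop", "se")]
})

#' @rdname accessors
#' @export
setGeneric("dateMidpoints", function(x) standardGeneric("dateMidpoints"))

#' @rdname accessors
#' @export
setMethod("dateMidpoints", "AncientCohort", function(x) {
  df <- as.data.frame(x@individuals)
  stats::setNames((df$upper_bce + df$lower_bce) / 2, df$id)
})

setMethod("show", "AncientCohort", function(object) {
  df <- as.data.frame(object@individuals)
  cat(sprintf("AncientCohort: %d individuals, %d sites\n",
              nrow(df), length(unique(df$site))))
  if (nrow(df)) {
    cat(sprintf("  dates: %.0f-%.0f calBCE (interval midpoints)\n",
                max((df$upper_bce + df$lower_bce) / 2),
                min((df$upper_bce + df$lower_bce) / 2)))
    cat(sprintf("  ancestry observations: %d (zero-ancestry: %d)\n",
                sum(!is.na(df$steppe_prop)),
                sum(df$steppe_prop == 0, na.rm = TRUE)))
  }
  invisible(object)
})

setMethod("show", "ArrivalFit", function(object) {
  p <- object@params
  cat("ArrivalFit (jump + exponential decay, least squares)\n")
  cat(sprintf("  p0 = %.4f, pe = %.4f, te = %.1f calBCE\n",
              p["p0"], p["pe"], p["te"]))
  cat(sprintf("  rss = %.6g over %d obs (%d zero-ancestry masked)\n",
              object@rss, object@nUsed, object@nZeroMasked))
  cat(sprintf("  converged: %s, Hessian positive-definite: %s\n",
              object@converged, object@hessianPD))
  invisible(object)
})

setMethod("show", "ArrivalEstimate", function(object) {
  cat("ArrivalEstimate (Monte Carlo over radiocarbon-date uncertainty)\n")
  cat(sprintf("  te mode = %.0f calBCE, 95%% interval [%.0f, %.0f]\n",
              object@pointEstimate, object@interval[1], object@interval[2]))
  cat(sprintf("  retained %d / %d repetitions, weight mode '%s', bw %.1f y\n",
              object@nRetained, object@nReps, object@weightMode,
              object@bandwidth))
  invisible(object)
})

setMethod("show", "FStatResult", function(object) {
  cat(sprintf("%s = %.6g (SE %.3g, Z = %.2f); %d SNPs in %d blocks\n",
              object@statistic, object@value, object@se, object@z,
              object@nSnps, object@nBlocks))
  invisible(object)
})

setMethod("show", "DiversityShiftResult", function(object) {
  cat("DiversityShiftResult (pairwise mismatch, permutation inference)\n")
  cat(sprintf("  effect (after - before) = %.5f, p = %.4g\n",
              object@effect, object@pValue))
  cat(sprintf("  permutation interval [%.5f, %.5f]; %d / %d pairs\n",
              object@confint[1], object@confint[2],
              object@nPairsBefore, object@nPairsAfter))
  invisible(object)
})

#' Extract a tidy summary of an f-statistic result
#' @param object an \linkS4class{FStatResult}.
#' @return one-row data.frame with value, se, z, nSnps, nBlocks.
#' @export
fstatSummary <- function(object) {
  stopifnot(is(object, "FStatResult"))
  data.frame(statistic = object@statistic, value = object@value,
             se = object@se, z = object@z, n_snps = object@nSnps,
             n_blocks = object@nBlocks)
}
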