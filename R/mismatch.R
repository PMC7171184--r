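#' Pairwise mismatch rates between pseudo-haploid individuals
#'
#' For every unordered pair, the fraction of jointly non-missing SNPs at
#' which the two haploid calls differ — the standard proxy for genetic
#' diversity and relatedness in low-coverage ancient DNA.  Pairs with at
#' most \code{minOverlap} overlapping SNPs are omitted (strictly more
#' than \code{minOverlap} are required) and counted in the
#' \code{"nDropped"} attribute.  Computed by matrix products; agrees
#' exactly with a per-pair loop.
#'
#' @param g a \linkS4class{PseudoHaploidGenotypes}.
#' @param minOverlap minimum overlapping-SNP count (exclusive bound);
#'   default 10000, the conventional panel threshold.
#' @param chroms \code{"autosomes"} (default), \code{"X"} or
#'   \code{"all"}.
#' @return data.frame with \code{id_a}, \code{id_b}, \code{n_overlap},
#'   \code{rate}; attribute \code{nDropped} counts under-threshold pairs.
#' @export
pairwiseMismatch <- function(g, minOverlap = 10000,
                             chroms = c("autosomes", "X", "all")) {
  chroms <- match.arg(chroms)
  stopifnot(is(g, "PseudoHaploidGenotypes"))
  if (minOverlap < 1) stop("minOverlap must be >= 1")
  m <- genotypeCalls(g)
  x <- isXSnp(g)
  if (chroms == "autosomes") m <- m[!x, , drop = FALSE]
  if (chroms == "X") m <- m[x, , drop = FALSE]

  P <- (!is.na(m)) * 1
  A <- m; A[is.na(A)] <- 0L
  storage.mode(A) <- "double"
  N <- crossprod(P)
  AP <- crossprod(A, P)
  M <- AP + t(AP) - 2 * crossprod(A)

  ids <- colnames(m)
  idx <- which(upper.tri(N), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n_overlap <- N[idx]
  rate <- ifelse(n_overlap > 0, M[idx] / n_overlap, NA_real_)
  keep <- n_overlap > minOverlap
  out <- data.frame(id_a = ids[idx[keep, 1]], id_b = ids[idx[keep, 2]],
                    n_overlap = as.integer(n_overlap[keep]),
                    rate = rate[keep], stringsAsFactors = FALSE)
  attr(out, "nDropped") <- sum(!keep)
  out
}

# period label per individual relative to the cutoff, from the interval
# midpoint; intervals containing the cutoff are NA unless byMidpoint
.periodLabels <- function(df, cutoff, byMidpoint = FALSE) {
  mid <- (df$upper_bce + df$lower_bce) / 2
  period <- ifelse(mid > cutoff, "before", "after")
  if (!byMidpoint)
    period[df$upper_bce >= cutoff & df$lower_bce <= cutoff] <- NA
  stats::setNames(period, df$id)
}

#' Diversity shift in pairwise mismatch rates across a date cutoff
#'
#' Tests whether mean pairwise mismatch rates differ between pairs of
#' individuals both dated before versus both after a cutoff (default
#' 2700 calBCE, the horizon of the steppe-ancestry turnover).  Pairs
#' straddling the cutoff are excluded.  Because every individual enters
#' many pairs, pair-level observations are dependent; inference therefore
#' permutes the period labels of the \emph{individuals} and recomputes
#' the pair grouping, which preserves the shared-individual dependence
#' structure (the role played by per-sample random effects in a
#' mixed-model formulation).  Two-sided p-value with add-one correction.
#'
#' An auxiliary linear model on per-individual mean mismatch rates
#' (cluster-aggregated response) provides an effect confidence interval.
#'
#' @param pairs output of [pairwiseMismatch()].
#' @param cohort an \linkS4class{AncientCohort} (or its
#'   \code{individuals()} data.frame) dating the pair members.
#' @param cutoff calBCE cutoff, default 2700.
#' @param nPerm number of permutations, default 9999.
#' @param seed integer seed for the permutations.
#' @param byMidpoint include individuals whose interval contains the
#'   cutoff, classified by midpoint (default FALSE: excluded).
#' @return A \linkS4class{DiversityShiftResult}.
#' @export
diversityShift <- function(pairs, cohort, cutoff = 2700, nPerm = 9999,
                           seed = 1, byMidpoint = FALSE) {
  df <- if (is(cohort, "AncientCohort")) individuals(cohort) else cohort
  period <- .periodLabels(df, cutoff, byMidpoint)
  site <- stats::setNames(df$site, df$id)

  pa <- period[pairs$id_a]; pb <- period[pairs$id_b]
  same <- !is.na(pa) & !is.na(pb) & pa == pb
  pp <- pairs[same, ]
  grp <- pa[same]
  nBefore <- sum(grp == "before"); nAfter <- sum(grp == "after")
  if (nBefore < 2 || nAfter < 2)
    stop(sprintf("need >= 2 pairs per side of the cutoff (before: %d, after: %d)",
                 nBefore, nAfter))
  effect <- mean(pp$rate[grp == "after"]) - mean(pp$rate[grp == "before"])

  # permute individual labels among the labelled individuals
  labelled <- names(period)[!is.na(period)]
  labs <- period[labelled]
  ia <- match(pairs$id_a, labelled)
  ib <- match(pairs$id_b, labelled)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]; rates <- pairs$rate[ok]
  set.seed(subSeed(seed, "diversity-perm"))
  permEffects <- vapply(seq_len(nPerm), function(k) {
    pl <- sample(labs)
    la <- pl[ia]; lb <- pl[ib]
    aft <- la == "after" & lb == "after"
    bef <- la == "before" & lb == "before"
    if (sum(aft) < 1 || sum(bef) < 1) return(NA_real_)
    mean(rates[aft]) - mean(rates[bef])
  }, numeric(1))
  permEffects <- permEffects[!is.na(permEffects)]
  p <- (1 + sum(abs(permEffects) >= abs(effect))) /
       (length(permEffects) + 1)
  ci <- effect + stats::quantile(permEffects - mean(permEffects),
                                 c(0.025, 0.975), names = FALSE)

  # site-level decomposition over within-site pairs
  sa <- site[pp$id_a]; sb <- site[pp$id_b]
  within <- sa == sb
  perSite <- if (any(within)) {
    agg <- stats::aggregate(rate ~ site + period,
      data = data.frame(rate = pp$rate[within], site = sa[within],
                        period = grp[within]), FUN = mean)
    cnt <- stats::aggregate(rate ~ site + period,
      data = data.frame(rate = pp$rate[within], site = sa[within],
                        period = grp[within]), FUN = length)
    agg$n_pairs <- cnt$rate
    names(agg)[3] <- "mean_rate"
    agg
  } else data.frame(site = character(), period = character(),
                    mean_rate = numeric(), n_pairs = integer())

  # cluster-aggregated lm: per-individual mean rate ~ period
  indRates <- tapply(c(pp$rate, pp$rate), c(pp$id_a, pp$id_b), mean)
  indPeriod <- period[names(indRates)]
  lmci <- tryCatch({
    fit <- stats::lm(r ~ p,
                     data = data.frame(r = as.numeric(indRates),
                                       p = factor(indPeriod,
                                                  c("before", "after"))))
    as.numeric(stats::confint(fit)["pafter", ])
  }, error = function(e) c(NA_real_, NA_real_))

  new("DiversityShiftResult", effect = effect, pValue = p,
      confint = as.numeric(ci), nPairsBefore = as.integer(nBefore),
      nPairsAfter = as.integer(nAfter), perSite = perSite,
      permEffects = permEffects, lmConfint = lmci)
}
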