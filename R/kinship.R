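#' Normalize pairwise mismatch rates to an expected-unrelated baseline
#'
#' READ-style normalization: within each group (burial site, or globally)
#' the baseline is the median pair mismatch rate — robust to a minority
#' of true relatives — and each pair's score is its rate divided by the
#' baseline.  Unrelated pairs score around 1; closer relatives score
#' progressively lower.
#'
#' @param pairs output of [pairwiseMismatch()].
#' @param records per-individual metadata (an
#'   \linkS4class{AncientCohort}, or a data.frame with \code{id} and
#'   \code{site}); required for \code{grouping = "site"}.
#' @param grouping \code{"global"} (default) or \code{"site"}.  Under
#'   site grouping, pairs whose members come from different sites fall
#'   back to the global baseline.
#' @return \code{pairs} with added columns \code{group},
#'   \code{baseline}, \code{normalized_score}.
#' @export
normalizeScores <- function(pairs, records = NULL,
                            grouping = c("global", "site")) {
  grouping <- match.arg(grouping)
  if (nrow(pairs) < 2) stop("need >= 2 pairs to form a baseline")
  if (grouping == "site") {
    if (is.null(records)) stop("site grouping needs per-individual records")
    df <- if (is(records, "AncientCohort")) individuals(records) else records
    site <- stats::setNames(df$site, df$id)
    sa <- site[pairs$id_a]; sb <- site[pairs$id_b]
    pairs$group <- ifelse(!is.na(sa) & !is.na(sb) & sa == sb, sa, "global")
  } else pairs$group <- "global"

  med <- tapply(pairs$rate, pairs$group, stats::median)
  small <- names(which(table(pairs$group) < 2))
  med[small] <- stats::median(pairs$rate)
  if (any(med[pairs$group] == 0))
    stop("degenerate data: zero median mismatch rate in group(s) ",
         paste(names(med)[med == 0], collapse = ", "))
  pairs$baseline <- as.numeric(med[pairs$group])
  pairs$normalized_score <- pairs$rate / pairs$baseline
  pairs
}

#' Classify relatedness degree from a normalized mismatch score
#'
#' Thresholds follow the READ scheme: the expected normalized score is
#' 0.5 for identical individuals/twins, 0.75 for first-degree and 0.875
#' for second-degree relatives, and the cuts sit halfway between
#' consecutive expectations (0.625, 0.8125, 0.90625).  Boundary values
#' are assigned to the more-related class.
#'
#' @param score normalized score(s) from [normalizeScores()].
#' @param thresholds the three ascending cuts.
#' @return character vector in \code{identical}, \code{first},
#'   \code{second}, \code{unrelated}.
#' @examples classifyDegree(c(0.5, 0.75, 0.875, 1))
#' @export
classifyDegree <- function(score,
                           thresholds = c(0.625, 0.8125, 0.90625)) {
  stopifnot(all(score > 0), length(thresholds) == 3,
            !is.unsorted(thresholds))
  cut <- findInterval(score, thresholds, left.open = TRUE)
  c("identical", "first", "second", "unrelated")[cut + 1]
}

#' Check kinship calls against uniparental markers
#'
#' For pairs classified identical or first-degree, mtDNA and Y labels
#' must be consistent with some first-degree relationship given the
#' sexes:
#' \itemize{
#'   \item mtDNA: two females (mother-daughter or sisters) must share the
#'     label — a difference is inconsistent ("no").  If either member is
#'     male, a differing label could still be a father-child pair, so the
#'     check is undecidable ("not_applicable").  A shared label is always
#'     "yes".
#'   \item Y: only male-male pairs are checkable (father-son or
#'     brothers share the Y); differing labels are "no".
#' }
#' Missing labels, missing sex, or degrees below first give
#' "not_applicable"; the check never errors on incomplete records.
#'
#' @param calls data.frame with \code{id_a}, \code{id_b}, \code{degree}.
#' @param records an \linkS4class{AncientCohort} or data.frame with
#'   \code{id}, \code{sex}, \code{mt_label}, \code{y_label}.
#' @return \code{calls} with added \code{mt_consistent},
#'   \code{y_consistent} columns.
#' @export
checkUniparental <- function(calls, records) {
  df <- if (is(records, "AncientCohort")) individuals(records) else records
  idx_a <- match(calls$id_a, df$id)
  idx_b <- match(calls$id_b, df$id)
  sexA <- df$sex[idx_a]; sexB <- df$sex[idx_b]
  mtA <- df$mt_label[idx_a]; mtB <- df$mt_label[idx_b]
  yA <- df$y_label[idx_a]; yB <- df$y_label[idx_b]
  close <- calls$degree %in% c("identical", "first")

  mt <- rep("not_applicable", nrow(calls))
  known <- close & !is.na(mtA) & !is.na(mtB)
  mt[known & mtA == mtB] <- "yes"
  femF <- known & mtA != mtB & !is.na(sexA) & !is.na(sexB) &
    sexA == "female" & sexB == "female"
  mt[femF] <- "no"
  mt[known & mtA != mtB & calls$degree == "identical"] <- "no"

  y <- rep("not_applicable", nrow(calls))
  mm <- close & !is.na(sexA) & !is.na(sexB) &
    sexA == "male" & sexB == "male" & !is.na(yA) & !is.na(yB)
  y[mm & yA == yB] <- "yes"
  y[mm & yA != yB] <- "no"

  calls$mt_consistent <- mt
  calls$y_consistent <- y
  calls
}

#' Full mismatch-based kinship pipeline
#'
#' [pairwiseMismatch()] then [normalizeScores()], [classifyDegree()] and
#' [checkUniparental()] in one call.
#'
#' @param g a \linkS4class{PseudoHaploidGenotypes}.
#' @param records per-individual metadata (see [checkUniparental()]).
#' @param minOverlap,chroms passed to [pairwiseMismatch()].
#' @param grouping passed to [normalizeScores()].
#' @return data.frame of kinship calls, one row per retained pair.
#' @export
kinshipCalls <- function(g, records, minOverlap = 10000,
                         chroms = "autosomes",
                         grouping = c("global", "site")) {
  pairs <- pairwiseMismatch(g, minOverlap = minOverlap, chroms = chroms)
  scored <- normalizeScores(pairs, records, grouping = match.arg(grouping))
  scored$degree <- classifyDegree(scored$normalized_score)
  checkUniparental(scored, records)
}

#' Infer genetic sex from X versus Y read or call counts
#'
#' With shotgun or capture data the fraction of sex-chromosome signal on
#' the Y, \code{R = y / (x + y)}, is near 0 for females (only
#' mismapping) and near 1/3 for males (one Y per two X-equivalents in
#' the 1240k-style target set).
#'
#' @param xCount,yCount read or call counts on X and Y.
#' @param femaleMax R below this is called female (default 0.05).
#' @param maleMin R above this is called male (default 0.20).
#' @return character vector: \code{"female"}, \code{"male"} or
#'   \code{"undetermined"}.
#' @examples inferSex(c(1000, 1000), c(10, 450))
#' @export
inferSex <- function(xCount, yCount, femaleMax = 0.05, maleMin = 0.20) {
  if (length(xCount) != length(yCount))
    stop("xCount and yCount must have equal length")
  tot <- xCount + yCount
  if (any(tot <= 0)) stop("zero total sex-chromosome count")
  r <- yCount / tot
  ifelse(r < femaleMax, "female",
         ifelse(r > maleMin, "male", "undetermined"))
}
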