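#' Read cohort metadata and ancestry tables
#'
#' Reads two tab-separated tables and joins them on \code{id}:
#' \describe{
#'   \item{meta}{columns \code{id, sex, site, region, upper_bce,
#'     lower_bce, mt_label, y_label}.  Dates are calibrated radiocarbon
#'     years BCE, positive increasing into the past; CE dates are coded
#'     as negative calBCE (these individuals are flagged with a message,
#'     since placing post-BCE individuals on the model time axis is an
#'     extrapolation).  Empty \code{mt_label}/\code{y_label} cells mean
#'     absent.}
#'   \item{ancestry}{columns \code{id, steppe_prop, se}: the upstream
#'     qpAdm-style steppe-ancestry proportion per individual.}
#' }
#' Individuals without an ancestry row are retained with an absent
#' observation.  Duplicate ids, proportions outside [0,1] and inverted
#' date intervals are errors.
#'
#' @param metaPath path to the metadata TSV.
#' @param ancestryPath path to the ancestry TSV; may be an empty table.
#' @return An \linkS4class{AncientCohort}.
#' @seealso [writeCohort()]
#' @export
readCohort <- function(metaPath, ancestryPath) {
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("id", "sex", "site", "region", "upper_bce", "lower_bce",
            "mt_label", "y_label")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata TSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$id))
    stop("duplicate id(s) in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  meta$upper_bce <- as.numeric(meta$upper_bce)
  meta$lower_bce <- as.numeric(meta$lower_bce)
  if (any(is.na(meta$upper_bce)) || any(is.na(meta$lower_bce)))
    stop("non-numeric date bound(s) in metadata")
  bad <- meta$upper_bce < meta$lower_bce
  if (any(bad))
    stop("upper_bce < lower_bce for id(s): ",
         paste(meta$id[bad], collapse = ", "))
  meta$mt_label[!nzchar(meta$mt_label)] <- NA_character_
  meta$y_label[!nzchar(meta$y_label)] <- NA_character_

  anc <- utils::read.delim(ancestryPath, stringsAsFactors = FALSE)
  if (nrow(anc)) {
    need2 <- c("id", "steppe_prop")
    miss2 <- setdiff(need2, colnames(anc))
    if (length(miss2))
      stop("ancestry TSV missing column(s): ", paste(miss2, collapse = ", "))
    if (anyDuplicated(anc$id))
      stop("duplicate id(s) in ancestry table")
    if (!"se" %in% colnames(anc)) anc$se <- NA_real_
    unknown <- setdiff(anc$id, meta$id)
    if (length(unknown))
      stop("ancestry rows for id(s) absent from metadata: ",
           paste(unknown, collapse = ", "))
    p <- as.numeric(anc$steppe_prop)
    if (any(is.na(p) | p < 0 | p > 1))
      stop("steppe_prop outside [0, 1] for id(s): ",
           paste(anc$id[is.na(p) | p < 0 | p > 1], collapse = ", "))
    idx <- match(meta$id, anc$id)
    meta$steppe_prop <- p[idx]
    meta$se <- as.numeric(anc$se)[idx]
  } else {
    meta$steppe_prop <- NA_real_
    meta$se <- NA_real_
  }

  ce <- meta$lower_bce < 0
  if (any(ce))
    message(sum(ce), " individual(s) with CE (negative calBCE) dates: ",
            paste(meta$id[ce], collapse = ", "))
  AncientCohort(meta)
}

#' Write cohort metadata and ancestry tables
#'
#' Inverse of [readCohort()]; absent labels are written as empty cells and
#' only individuals with an ancestry observation get an ancestry row.
#'
#' @param cohort an \linkS4class{AncientCohort}.
#' @param metaPath,ancestryPath output TSV paths.
#' @return \code{metaPath}, invisibly.
#' @export
writeCohort <- function(cohort, metaPath, ancestryPath) {
  stopifnot(is(cohort, "AncientCohort"))
  df <- individuals(cohort)
  meta <- df[, c("id", "sex", "site", "region", "upper_bce", "lower_bce",
                 "mt_label", "y_label")]
  meta$mt_label[is.na(meta$mt_label)] <- ""
  meta$y_label[is.na(meta$y_label)] <- ""
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  anc <- df[!is.na(df$steppe_prop), c("id", "steppe_prop", "se")]
  utils::write.table(anc, ancestryPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(metaPath)
}
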