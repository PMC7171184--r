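#' Read pseudo-haploid genotypes from EIGENSTRAT files
#'
#' Reads \code{prefix.geno}, \code{prefix.snp} and \code{prefix.ind}.
#' Two dialects are supported: haploid-coded genotypes in \{0, 1, 9\}
#' (one allele per call) and pseudo-haploid data stored in the diploid
#' coding \{0, 2, 9\} (alt homozygote 2 mapped to a derived call 1).
#' Under \code{dialect = "auto"} a file containing any \code{1} among the
#' scanned non-missing values is taken as haploid-coded, otherwise as
#' diploid-coded: pseudo-haploid data in diploid coding never uses 1.
#' A \code{1} in a file known to be diploid-coded (or a \code{2} in a
#' haploid-coded file) is a heterozygote-in-pseudo-haploid error.
#'
#' Chromosome \code{23} in the .snp file is exposed as \code{"X"}.
#' Individual and SNP order is preserved exactly as on disk.
#'
#' @param prefix path prefix of the three files.
#' @param dialect \code{"auto"} (default), \code{"haploid"} or
#'   \code{"diploid"}.
#' @return A \linkS4class{PseudoHaploidGenotypes}; the .ind sex and group
#'   columns are kept in \code{colData}.
#' @seealso [writeEigenstrat()]
#' @export
readEigenstrat <- function(prefix, dialect = c("auto", "haploid", "diploid")) {
  dialect <- match.arg(dialect)
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing EIGENSTRAT file(s): ", paste(missing, collapse = ", "))

  ind <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "group"))
  snp <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE)
  if (ncol(snp) < 6)
    stop("EIGENSTRAT format error: .snp must have 6 columns ",
         "(snp_id chrom genpos physpos ref alt)")
  colnames(snp)[1:6] <- c("snp_id", "chrom", "genpos", "physpos", "ref", "alt")

  lines <- readLines(paths[1])
  if (length(lines) != nrow(snp))
    stop(sprintf(
      "EIGENSTRAT format error: .geno has %d rows but .snp has %d lines",
      length(lines), nrow(snp)))
  widths <- nchar(lines)
  if (any(widths != nrow(ind)))
    stop(sprintf(
      "EIGENSTRAT format error: .geno row width %d but .ind has %d lines",
      widths[which(widths != nrow(ind))[1]], nrow(ind)))

  m <- matrix(utf8ToInt(paste(lines, collapse = "")) - 48L,
              nrow = nrow(snp), ncol = nrow(ind), byrow = TRUE)
  vals <- m[m != 9L]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("EIGENSTRAT format error: .geno values must be in {0,1,2,9}")

  if (dialect == "auto") {
    has1 <- any(vals == 1L)
    has2 <- any(vals == 2L)
    if (has1 && has2)
      stop("heterozygote in pseudo-haploid data: .geno mixes values 1 and 2")
    dialect <- if (has1) "haploid" else "diploid"
  }
  if (dialect == "diploid" && any(vals == 1L))
    stop("heterozygote in pseudo-haploid data: value 1 in diploid-coded .geno")
  if (dialect == "haploid" && any(vals == 2L))
    stop("value 2 is invalid in a haploid-coded .geno")

  m[m == 9L] <- NA_integer_
  if (dialect == "diploid") m[m == 2L] <- 1L
  colnames(m) <- ind$id

  sex <- c(F = "female", M = "male", U = "unknown")[ind$sex]
  sex[is.na(sex)] <- "unknown"
  PseudoHaploidGenotypes(
    m, chrom = snp$chrom, position = snp$physpos, snpId = snp$snp_id,
    ref = snp$ref, alt = snp$alt,
    colData = S4Vectors::DataFrame(sex = unname(sex), group = ind$group,
                                   row.names = ind$id))
}

#' Write pseudo-haploid genotypes as EIGENSTRAT files
#'
#' Inverse of [readEigenstrat()]: derived calls are written as \code{1}
#' (haploid dialect) or \code{2} (diploid dialect), missing calls as
#' \code{9} in both; chromosome \code{"X"} is written as \code{23}.
#' Output is canonical, so write-read-write round-trips byte-identically.
#'
#' @param g a \linkS4class{PseudoHaploidGenotypes}.
#' @param prefix output path prefix.
#' @param dialect \code{"haploid"} or \code{"diploid"}.
#' @return \code{prefix}, invisibly.
#' @export
writeEigenstrat <- function(g, prefix, dialect = c("haploid", "diploid")) {
  dialect <- match.arg(dialect)
  stopifnot(is(g, "PseudoHaploidGenotypes"))
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    stop("unwritable path: directory does not exist: ", dir)

  m <- genotypeCalls(g)
  out <- m
  if (dialect == "diploid") out[m == 1L] <- 2L
  out[is.na(m)] <- 9L
  lines <- apply(out, 1L, paste, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))

  rr <- snpInfo(g)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  chrom[chrom == "X"] <- "23"
  snp <- data.frame(rr$snp_id, chrom, 0, GenomicRanges::start(rr),
                    rr$ref, rr$alt)
  utils::write.table(snp, paste0(prefix, ".snp"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  cd <- SummarizedExperiment::colData(g)
  sex <- if ("sex" %in% colnames(cd))
    c(female = "F", male = "M", unknown = "U")[cd$sex] else
    rep("U", ncol(g))
  grp <- if ("group" %in% colnames(cd)) cd$group else rep("Cohort", ncol(g))
  utils::write.table(data.frame(colnames(m), unname(sex), grp),
                     paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
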