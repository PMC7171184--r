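#' Simulate a pedigree with Mendelian transmission
#'
#' Founders receive diploid genotypes in Hardy-Weinberg proportions from
#' the founder allele-frequency pool; each child inherits, per SNP, one
#' allele drawn at random from each parent's diploid genotype.  The
#' observation layer is pseudo-haploid: one of the two alleles of each
#' individual is sampled per SNP, with independent missingness.  mtDNA
#' labels follow the maternal line and Y-haplogroup labels the paternal
#' line (females carry none).  An optional \code{twin_of} column makes an
#' individual an identical twin (diploid genotype copied).
#'
#' True pairwise relationship degrees are derived from the recursive
#' kinship coefficient phi: \code{identical} (phi > 0.354, twins),
#' \code{first} (parent-offspring, full siblings), \code{second}
#' (grandparent, avuncular, half-siblings), else \code{unrelated}.
#'
#' @param structure data.frame with columns \code{id}, \code{father},
#'   \code{mother} (NA for founders), \code{sex} (\code{"male"} /
#'   \code{"female"}), optional \code{twin_of}.
#' @param nSnps number of autosomal SNPs.
#' @param founderFreqs founder pool allele frequencies (length 1 or
#'   \code{nSnps}); default Uniform(0.05, 0.95) draws.
#' @param missingRate per-call missingness of the pseudo-haploid layer.
#' @param seed integer seed.
#' @return list with \code{genotypes}
#'   (\linkS4class{PseudoHaploidGenotypes}), \code{truth} (data.frame
#'   \code{id_a, id_b, degree} for all pairs) and \code{records}
#'   (data.frame \code{id, sex, mt_label, y_label}).
#' @examples
#' trio <- data.frame(id = c("F1", "M1", "C1"),
#'                    father = c(NA, NA, "F1"), mother = c(NA, NA, "M1"),
#'                    sex = c("male", "female", "male"))
#' ped <- simulatePedigree(trio, nSnps = 100, seed = 7)
#' @export
simulatePedigree <- function(structure, nSnps, founderFreqs = NULL,
                             missingRate = 0, seed = 1) {
  st <- as.data.frame(structure, stringsAsFactors = FALSE)
  if (!"twin_of" %in% colnames(st)) st$twin_of <- NA_character_
  ids <- as.character(st$id)
  if (anyDuplicated(ids)) stop("duplicate pedigree id(s)")
  for (col in c("father", "mother", "twin_of")) {
    ref <- st[[col]][!is.na(st[[col]])]
    if (!all(ref %in% ids))
      stop("unknown ", col, " id(s): ",
           paste(setdiff(ref, ids), collapse = ", "))
  }
  badF <- !is.na(st$father) & st$sex[match(st$father, ids)] != "male"
  if (any(badF)) stop("father without male sex: ",
                      paste(unique(st$father[badF]), collapse = ", "))
  badM <- !is.na(st$mother) & st$sex[match(st$mother, ids)] != "female"
  if (any(badM)) stop("mother without female sex: ",
                      paste(unique(st$mother[badM]), collapse = ", "))

  # topological order; a cycle leaves unplaceable individuals
  placed <- character()
  remaining <- ids
  while (length(remaining)) {
    dep <- st[match(remaining, ids), ]
    ready <- remaining[
      (is.na(dep$father) | dep$father %in% placed) &
      (is.na(dep$mother) | dep$mother %in% placed) &
      (is.na(dep$twin_of) | dep$twin_of %in% placed)]
    if (!length(ready)) stop("cyclic pedigree involving: ",
                             paste(remaining, collapse = ", "))
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }

  set.seed(subSeed(seed, "pedigree"))
  if (is.null(founderFreqs)) founderFreqs <- stats::runif(nSnps, 0.05, 0.95)
  p <- rep_len(founderFreqs, nSnps)

  # diploid genotypes as two allele vectors per individual
  al1 <- al2 <- matrix(NA_integer_, nSnps, length(ids),
                       dimnames = list(NULL, ids))
  mt <- y <- stats::setNames(rep(NA_character_, length(ids)), ids)
  founderCount <- 0L
  for (id in placed) {
    row <- st[match(id, ids), ]
    if (!is.na(row$twin_of)) {
      al1[, id] <- al1[, row$twin_of]; al2[, id] <- al2[, row$twin_of]
      mt[id] <- mt[row$twin_of]
      if (row$sex == "male") y[id] <- y[row$twin_of]
      next
    }
    if (is.na(row$father) && is.na(row$mother)) {
      founderCount <- founderCount + 1L
      al1[, id] <- as.integer(stats::runif(nSnps) < p)
      al2[, id] <- as.integer(stats::runif(nSnps) < p)
      mt[id] <- sprintf("mt%02d", founderCount)
      if (row$sex == "male") y[id] <- sprintf("y%02d", founderCount)
    } else {
      if (is.na(row$father) || is.na(row$mother))
        stop("individual ", id, " must have both parents or none")
      pickF <- stats::runif(nSnps) < 0.5
      al1[, id] <- ifelse(pickF, al1[, row$father], al2[, row$father])
      pickM <- stats::runif(nSnps) < 0.5
      al2[, id] <- ifelse(pickM, al1[, row$mother], al2[, row$mother])
      mt[id] <- mt[row$mother]
      if (row$sex == "male") y[id] <- y[row$father]
    }
  }

  pickObs <- matrix(stats::runif(nSnps * length(ids)) < 0.5, nSnps,
                    length(ids))
  calls <- ifelse(pickObs, al1, al2)
  if (missingRate > 0)
    calls[matrix(stats::runif(length(calls)) < missingRate,
                 nSnps, length(ids))] <- NA_integer_
  colnames(calls) <- ids
  g <- PseudoHaploidGenotypes(
    calls, chrom = sort(rep_len(1:22, nSnps)),
    position = seq_len(nSnps) * 1000L,
    colData = S4Vectors::DataFrame(sex = st$sex, group = "Pedigree",
                                   row.names = ids))
  S4Vectors::metadata(g) <- list(founderFreqs = p)

  phi <- .kinshipMatrix(st, placed)
  pairs <- utils::combn(ids, 2)
  deg <- apply(pairs, 2, function(ab) {
    k <- phi[ab[1], ab[2]]
    if (k > 0.354) "identical"
    else if (k > 0.177) "first"
    else if (k > 0.088) "second"
    else "unrelated"
  })
  list(genotypes = g,
       truth = data.frame(id_a = pairs[1, ], id_b = pairs[2, ],
                          degree = deg, stringsAsFactors = FALSE),
       records = data.frame(id = ids, sex = st$sex, mt_label = unname(mt),
                            y_label = unname(y),
                            stringsAsFactors = FALSE))
}

# recursive kinship coefficients over a topologically ordered pedigree;
# twins are treated as genetic copies of their template
.kinshipMatrix <- function(st, order) {
  ids <- as.character(st$id)
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  parent <- function(id, which) {
    row <- st[match(id, ids), ]
    if (!is.na(row$twin_of)) row <- st[match(row$twin_of, ids), ]
    row[[which]]
  }
  for (a in seq_along(order)) {
    i <- order[a]
    fi <- parent(i, "father"); mi <- parent(i, "mother")
    phi[i, i] <- 0.5 * (1 + if (!is.na(fi) && !is.na(mi))
      phi[fi, mi] else 0)
    for (b in seq_len(a - 1)) {
      j <- order[b]
      if (!is.na(st$twin_of[match(i, ids)]) &&
          st$twin_of[match(i, ids)] == j) {
        phi[i, j] <- phi[j, i] <- phi[j, j]
        next
      }
      v <- if (!is.na(fi) && !is.na(mi))
        0.5 * (phi[fi, j] + phi[mi, j]) else 0
      phi[i, j] <- phi[j, i] <- v
    }
  }
  phi
}
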