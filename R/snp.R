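#' Region classification and position labels
#'
#' Maps 0-based alignment columns to the intron/exon structure of the
#' fragment and to human-readable position labels: intronic columns are
#' numbered backwards from the intron/exon boundary (the last intronic
#' base is -1), exonic columns forwards from it (the first exonic base
#' is +1). With an 829 bp intron, column 671 is "SNP-158".
#'
#' @param columnIndex integer vector of 0-based column indices.
#' @param annotation a [FragmentAnnotation-class].
#' @return data.frame with `columnIndex`, `region` ("INTRONIC" or
#'   "EXONIC") and integer `positionLabel`.
#' @examples
#' ann <- fragmentAnnotation(6, 9, 0, "ACGTACATGGGATTTTAG")
#' classifyRegion(c(0, 5, 6), ann)
#' @export
classifyRegion <- function(columnIndex, annotation) {
  columnIndex <- as.integer(columnIndex)
  L <- intronLength(annotation) + exonLength(annotation)
  if (any(columnIndex < 0L | columnIndex >= L))
    .pcError(sprintf("column index out of range [0, %d)", L),
             "inputError")
  intron <- columnIndex < intronLength(annotation)
  data.frame(
    columnIndex = columnIndex,
    region = ifelse(intron, "INTRONIC", "EXONIC"),
    positionLabel = ifelse(intron,
      -(intronLength(annotation) - columnIndex),
      columnIndex - intronLength(annotation) + 1L)
  )
}

#' Coding effect of an exonic substitution
#'
#' Translates the reference codon containing the column and the codon
#' with the alternative base substituted, under the standard genetic
#' code and the fragment's reading-frame phase. Codons extending outside
#' the sequenced exon, or containing N, give NA with a warning.
#'
#' @param columnIndex 0-based exonic column index.
#' @param altAllele the alternative base (A/C/G/T).
#' @param annotation a [FragmentAnnotation-class] with the reference
#'   sequence.
#' @return "SYNONYMOUS", "NONSYNONYMOUS", or NA.
#' @examples
#' ann <- fragmentAnnotation(0, 9, 0, "GGAATGAAA")
#' codingEffect(2, "G", ann) # GGA -> GGG, Gly -> Gly
#' codingEffect(5, "A", ann) # ATG -> ATA, Met -> Ile
#' @export
codingEffect <- function(columnIndex, altAllele, annotation) {
  columnIndex <- as.integer(columnIndex)
  iLen <- intronLength(annotation)
  L <- iLen + exonLength(annotation)
  if (columnIndex < iLen || columnIndex >= L)
    .pcError("codingEffect requires an exonic column", "inputError")
  exIdx <- columnIndex - iLen
  phase <- (exIdx + annotation@cdsFrameOffset) %% 3L
  start <- columnIndex - phase
  if (start < iLen || start + 2L >= L) {
    warning(sprintf(
      "codon for column %d extends outside the sequenced exon",
      columnIndex))
    return(NA_character_)
  }
  ref <- strsplit(substr(referenceSequence(annotation),
                         start + 1L, start + 3L), "")[[1]]
  if (any(!ref %in% c("A", "C", "G", "T"))) {
    warning(sprintf("codon for column %d contains ambiguous bases",
                    columnIndex))
    return(NA_character_)
  }
  alt <- ref
  alt[columnIndex - start + 1L] <- toupper(altAllele)
  aaRef <- GENETIC_CODE[[paste(ref, collapse = "")]]
  aaAlt <- GENETIC_CODE[[paste(alt, collapse = "")]]
  if (identical(aaRef, aaAlt)) "SYNONYMOUS" else "NONSYNONYMOUS"
}

#' Call SNPs from a consensus alignment with the minimum-carrier rule
#'
#' Scans every alignment column, decodes diploid genotypes
#' ([genotypeColumn()]), and calls a column a SNP when strictly more
#' than `minCarriers` specimens carry at least one copy of the
#' alternative (non-reference) allele -- heterozygotes count as one
#' carrying specimen. Columns with more than two segregating bases are
#' excluded with a warning. The reference allele is taken from the
#' annotation's reference sequence when available (the overall majority
#' allele otherwise).
#'
#' @param alignment output of [readAlignment()] (or anything it
#'   accepts).
#' @param annotation optional [FragmentAnnotation-class]; enables region
#'   labels and coding effects.
#' @param minCarriers exclusive carrier threshold (default 3: a variant
#'   must be present in more than 3 specimens).
#' @return list of class `SnpCalls` with elements `snps` (data.frame:
#'   `positionLabel, columnIndex, ref, alt, region, effect, carriers`),
#'   `dosage` (SNP x specimen matrix of alt-allele dosages 0/1/2, NA =
#'   missing), `specimen` and `locality` vectors, and the annotation.
#' @export
callSnps <- function(alignment, annotation = NULL, minCarriers = 3L) {
  aln <- readAlignment(alignment)
  mat <- toupper(as.matrix(aln))
  spec <- metadata(aln)$specimen
  locs <- metadata(aln)$locality
  if (!is.null(annotation) &&
      ncol(mat) != intronLength(annotation) + exonLength(annotation))
    .pcError("alignment width does not match fragment annotation",
             "inputError")
  rows <- list()
  dosages <- list()
  for (col in seq_len(ncol(mat))) {
    g <- genotypeColumn(mat[, col])
    if (length(g$segregating) < 2L) next
    if (g$multiAllelic) {
      warning(sprintf("multi-allelic column %d (0-based) excluded",
                      col - 1L))
      next
    }
    counts <- table(factor(as.vector(g$alleles), levels = g$segregating))
    if (!is.null(annotation)) {
      refBase <- substr(referenceSequence(annotation), col, col)
      if (!refBase %in% g$segregating)
        refBase <- names(which.max(counts))
    } else {
      refBase <- names(which.max(counts))
    }
    altBase <- setdiff(g$segregating, refBase)
    dos <- rowSums(g$alleles == altBase)
    dos[is.na(g$alleles[, 1])] <- NA
    carriers <- sum(dos >= 1, na.rm = TRUE)
    if (carriers <= minCarriers) next
    rows[[length(rows) + 1L]] <- data.frame(
      columnIndex = col - 1L, ref = refBase, alt = altBase,
      carriers = carriers)
    dosages[[length(dosages) + 1L]] <- dos
  }
  snps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(columnIndex = integer(), ref = character(),
               alt = character(), carriers = integer())
  if (!is.null(annotation) && nrow(snps)) {
    reg <- classifyRegion(snps$columnIndex, annotation)
    snps$region <- reg$region
    snps$positionLabel <- reg$positionLabel
    snps$effect <- NA_character_
    ex <- which(snps$region == "EXONIC")
    for (i in ex)
      snps$effect[i] <- codingEffect(snps$columnIndex[i], snps$alt[i],
                                     annotation)
  } else {
    snps$region <- rep(NA_character_, nrow(snps))
    snps$positionLabel <- snps$columnIndex + 1L
    snps$effect <- rep(NA_character_, nrow(snps))
  }
  snps <- snps[, c("positionLabel", "columnIndex", "ref", "alt",
                   "region", "effect", "carriers")]
  dosage <- if (length(dosages))
    do.call(rbind, dosages) else matrix(NA_real_, 0, ncol = nrow(mat))
  colnames(dosage) <- spec
  rownames(dosage) <- as.character(snps$positionLabel)
  structure(
    list(snps = snps, dosage = dosage, specimen = spec,
         locality = locs, annotation = annotation,
         minCarriers = minCarriers),
    class = "SnpCalls")
}

#' @export
print.SnpCalls <- function(x, ...) {
  cat("SnpCalls:", nrow(x$snps), "SNPs from", length(x$specimen),
      "specimens (carrier rule: >", x$minCarriers, "specimens)\n")
  invisible(x)
}

#' Assemble per-population allele frequencies into a SnpFrequencySet
#'
#' Aggregates the per-specimen dosages of [callSnps()] into
#' per-population alternative-allele counts and frequencies:
#' `freq = alt_count / (2 x non-missing diploids)`. Populations with no
#' genotyped specimen at a column get a missing frequency.
#'
#' @param calls a `SnpCalls` object.
#' @param localities locality table ([readLocalities()]); every locality
#'   id appearing in the alignment must be present.
#' @param pcpp optional pCPP table ([pcppTable()]); when given, `pcppH`
#'   is attached to the population data for association analysis.
#' @return A [SnpFrequencySet-class].
#' @export
snpFrequencySet <- function(calls, localities, pcpp = NULL) {
  stopifnot(inherits(calls, "SnpCalls"))
  popIds <- as.character(localities$id)
  unknown <- setdiff(unique(calls$locality), popIds)
  if (length(unknown))
    .pcError(paste("locality id(s) not in locality table:",
                   paste(unknown, collapse = ", ")), "inputError")
  popFactor <- factor(calls$locality, levels = popIds)
  nSnp <- nrow(calls$snps)
  altCount <- matrix(0, nSnp, length(popIds),
                     dimnames = list(rownames(calls$dosage), popIds))
  totalCount <- altCount
  for (p in seq_along(popIds)) {
    idx <- which(popFactor == popIds[p])
    if (!length(idx) || !nSnp) next
    d <- calls$dosage[, idx, drop = FALSE]
    altCount[, p] <- rowSums(d, na.rm = TRUE)
    totalCount[, p] <- 2 * rowSums(!is.na(d))
  }
  freq <- altCount / totalCount
  freq[!is.finite(freq)] <- NA
  cd <- DataFrame(localities, row.names = popIds)
  if (!is.null(pcpp)) {
    m <- match(popIds, as.character(pcpp$localityId))
    if (anyNA(m))
      .pcError("pcpp table does not cover all localities", "inputError")
    cd$pcppH <- pcpp$pcppH[m]
    cd$crossingDay <- pcpp$crossingDay[m]
  }
  se <- SummarizedExperiment(
    assays = list(altCount = altCount, totalCount = totalCount,
                  freq = freq),
    rowData = DataFrame(calls$snps, row.names = rownames(calls$dosage)),
    colData = cd
  )
  out <- new("SnpFrequencySet", se)
  metadata(out)$dosage <- calls$dosage
  metadata(out)$specimenLocality <- calls$locality
  metadata(out)$annotation <- calls$annotation
  out
}
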