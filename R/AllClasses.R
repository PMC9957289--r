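#' Fragment annotation for a partially intronic, partially exonic amplicon
#'
#' Describes the sequenced fragment: an intronic prefix followed by an
#' exonic suffix, the reading-frame phase of the first exonic base, and
#' the reference sequence. Column indices are 0-based throughout.
#'
#' @slot intronLen integer, length in bp of the intronic prefix.
#' @slot exonLen integer, length in bp of the exonic suffix.
#' @slot cdsFrameOffset integer in 0..2; phase of the first exonic base
#'   within its codon (0 = the first exonic base starts a codon).
#' @slot referenceSeq character, the reference fragment sequence
#'   (A/C/G/T), of length `intronLen + exonLen`.
#' @exportClass FragmentAnnotation
setClass("FragmentAnnotation",
  representation(
    intronLen = "integer",
    exonLen = "integer",
    cdsFrameOffset = "integer",
    referenceSeq = "character"
  )
)

setValidity("FragmentAnnotation", function(object) {
  msg <- character()
  if (object@intronLen < 0L || object@exonLen < 0L)
    msg <- c(msg, "intronLen and exonLen must be non-negative")
  if (!object@cdsFrameOffset %in% 0:2)
    msg <- c(msg, "cdsFrameOffset must be 0, 1 or 2")
  if (length(object@referenceSeq) != 1L)
    msg <- c(msg, "referenceSeq must be a single string")
  else if (nchar(object@referenceSeq) != object@intronLen + object@exonLen)
    msg <- c(msg, sprintf(
      "referenceSeq length (%d) != intronLen + exonLen (%d)",
      nchar(object@referenceSeq), object@intronLen + object@exonLen))
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentAnnotation
#'
#' @param intronLen bp count of the intronic prefix.
#' @param exonLen bp count of the exonic suffix.
#' @param cdsFrameOffset reading-frame phase (0..2) of the first exonic
#'   base.
#' @param referenceSeq reference fragment sequence (string, or a
#'   `DNAString`/length-1 `DNAStringSet`).
#' @return A [FragmentAnnotation-class] object.
#' @examples
#' ann <- fragmentAnnotation(6, 9, 0, "ACGTACATGGGATTTTAG")
#' intronLength(ann)
#' @export
fragmentAnnotation <- function(intronLen, exonLen, cdsFrameOffset = 0L,
                               referenceSeq) {
  new("FragmentAnnotation",
    intronLen = as.integer(intronLen),
    exonLen = as.integer(exonLen),
    cdsFrameOffset = as.integer(cdsFrameOffset),
    referenceSeq = toupper(as.character(referenceSeq))
  )
}

#' @describeIn fragmentAnnotation length of the intronic prefix (bp)
#' @param object,x a `FragmentAnnotation`
#' @export
intronLength <- function(object) object@intronLen

#' @describeIn fragmentAnnotation length of the exonic suffix (bp)
#' @export
exonLength <- function(object) object@exonLen

#' @describeIn fragmentAnnotation reference sequence as a character string
#' @export
referenceSequence <- function(object) object@referenceSeq

setMethod("show", "FragmentAnnotation", function(object) {
  cat("FragmentAnnotation:", object@intronLen, "bp intron +",
      object@exonLen, "bp exon; frame offset",
      object@cdsFrameOffset, "\n")
})

#' Annual photoperiod-temperature trajectory for one locality
#'
#' The closed yearly trajectory in the (photoperiod, temperature) plane:
#' for each day of a 365-day year, the civil-twilight day length and the
#' daily temperature interpolated from monthly means. Traversed
#' Jan 1 -> Dec 31 it runs counter-clockwise in the Northern Hemisphere
#' whenever temperature lags photoperiod.
#'
#' @slot localityId character scalar.
#' @slot latitude degrees north the photoperiods were computed at.
#' @slot day integer vector 1..365.
#' @slot photoperiod numeric, hours of light per 24 h, in \[0, 24\].
#' @slot temperature numeric, interpolated daily temperature, degrees C.
#' @seealso [buildEllipse()], [predictedCriticalPhotoperiod()]
#' @exportClass ClimateEllipse
setClass("ClimateEllipse",
  representation(
    localityId = "character",
    latitude = "numeric",
    day = "integer",
    photoperiod = "numeric",
    temperature = "numeric"
  )
)

setValidity("ClimateEllipse", function(object) {
  msg <- character()
  if (length(object@day) != 365L ||
      !identical(object@day, 1:365))
    msg <- c(msg, "day must be the integers 1..365")
  if (length(object@photoperiod) != 365L ||
      any(object@photoperiod < 0 | object@photoperiod > 24))
    msg <- c(msg, "photoperiod must be 365 values in [0, 24]")
  if (length(object@temperature) != 365L ||
      any(!is.finite(object@temperature)))
    msg <- c(msg, "temperature must be 365 finite values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClimateEllipse", function(object) {
  cat("ClimateEllipse for", object@localityId, "\n")
  cat("  photoperiod: ", sprintf("%.2f", min(object@photoperiod)), "-",
      sprintf("%.2f", max(object@photoperiod)), "h\n")
  cat("  temperature: ", sprintf("%.1f", min(object@temperature)), "-",
      sprintf("%.1f", max(object@temperature)), "degC\n")
})

#' SNP-by-population allele-frequency container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass holding,
#' for each called SNP (rows) and each population (columns), the
#' alternative-allele count, the total number of genotyped alleles
#' (2 x non-missing diploids), and the alternative-allele frequency.
#' `rowData` carries the per-SNP annotation (position label, ref/alt,
#' region, coding effect, carrier count); `colData` carries the locality
#' table (coordinates, altitude, lineage, and pCPP when attached);
#' `metadata` keeps the per-specimen dosage matrix used for LD.
#'
#' @seealso [snpFrequencySet()], [alleleFrequencies()], [fstMatrix()],
#'   [associateAll()]
#' @exportClass SnpFrequencySet
setClass("SnpFrequencySet", contains = "SummarizedExperiment")

setValidity("SnpFrequencySet", function(object) {
  msg <- character()
  need <- c("altCount", "totalCount", "freq")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, paste("assays must include",
                        paste(need, collapse = ", ")))
  else {
    f <- assay(object, "freq")
    if (any(f < 0 | f > 1, na.rm = TRUE))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (any(assay(object, "altCount") > assay(object, "totalCount"),
            na.rm = TRUE))
      msg <- c(msg, "altCount must not exceed totalCount")
  }
  rd <- rowData(object)
  if (!all(c("positionLabel", "region", "carriers") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry positionLabel, region, carriers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SnpFrequencySet", function(object) {
  rd <- rowData(object)
  cat("SnpFrequencySet:", nrow(object), "SNPs x", ncol(object),
      "populations\n")
  cat("  regions:", sum(rd$region == "INTRONIC"), "intronic /",
      sum(rd$region == "EXONIC"), "exonic\n")
  if ("lineage" %in% colnames(colData(object))) {
    tab <- table(colData(object)$lineage)
    cat("  lineages:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  if ("pcppH" %in% colnames(colData(object)))
    cat("  pCPP attached:",
        sprintf("%.2f-%.2f h", min(colData(object)$pcppH),
                max(colData(object)$pcppH)), "\n")
})

#' @describeIn snpFrequencySet population-by-SNP matrix of
#'   alternative-allele frequencies (rows = populations, columns = SNP
#'   position labels).
#' @export
alleleFrequencies <- function(x) {
  stopifnot(is(x, "SnpFrequencySet"))
  t(assay(x, "freq"))
}

#' @describeIn snpFrequencySet population-by-SNP matrix of genotyped
#'   diploid counts.
#' @export
sampleSizes <- function(x) {
  stopifnot(is(x, "SnpFrequencySet"))
  t(assay(x, "totalCount")) / 2
}

#' @describeIn snpFrequencySet per-SNP annotation table (data.frame).
#' @export
snpInfo <- function(x) {
  stopifnot(is(x, "SnpFrequencySet"))
  as.data.frame(rowData(x))
}

#' @describeIn snpFrequencySet locality/population table (data.frame).
#' @export
populationData <- function(x) {
  stopifnot(is(x, "SnpFrequencySet"))
  as.data.frame(colData(x))
}
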