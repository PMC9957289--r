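MONTH_COLS <- tolower(month.abb)

#' Read a locality table
#'
#' CSV with header `id,name,latitude,longitude,altitude,lineage,
#' n_specimens` (decimal degrees WGS-84, lineage WEST/EAST).
#'
#' @param path CSV path (lines starting with `#` ignored).
#' @return Validated data.frame.
#' @export
readLocalities <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "latitude", "longitude", "altitude", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .pcError(paste("locality table missing column(s):",
                   paste(miss, collapse = ", ")), "formatError")
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    .pcError("coordinates out of range", "inputError")
  if (!all(df$lineage %in% c("WEST", "EAST")))
    .pcError("lineage must be WEST or EAST", "inputError")
  if (anyDuplicated(df$id))
    .pcError("duplicate locality ids", "inputError")
  df
}

#' Read a monthly temperature table
#'
#' CSV with header `id,jan,feb,...,dec`, one row per locality,
#' multi-year monthly mean temperatures in degrees C.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
readTemperatures <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("id", MONTH_COLS), names(df))
  if (length(miss))
    .pcError(paste("temperature table missing column(s):",
                   paste(miss, collapse = ", ")), "formatError")
  vals <- as.matrix(df[, MONTH_COLS])
  if (any(!is.finite(vals)))
    .pcError("temperature table contains non-finite values",
             "inputError")
  df
}

#' Read a fragment annotation
#'
#' YAML with keys `intron_len`, `exon_len`, `cds_frame_offset`, plus a
#' reference FASTA.
#'
#' @param yamlPath annotation YAML path.
#' @param referenceFasta reference FASTA path (first record used).
#' @return A [FragmentAnnotation-class].
#' @export
readFragmentAnnotation <- function(yamlPath, referenceFasta) {
  y <- read_yaml(yamlPath)
  ref <- readDNAStringSet(referenceFasta)
  fragmentAnnotation(y$intron_len, y$exon_len,
                     y$cds_frame_offset %||% 0L,
                     as.character(ref[[1]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-file input diagnostics
#'
#' Checks consistency across the locality table, temperature table and
#' alignment: locality ids referenced by specimens must exist, every
#' locality needs a temperature series, coordinates must be in range.
#'
#' @param localities locality data.frame.
#' @param temps temperature data.frame.
#' @param alignment optional alignment (anything [readAlignment()]
#'   accepts).
#' @return Character vector of diagnostics; empty when clean.
#' @export
validateInputs <- function(localities, temps, alignment = NULL) {
  diag <- character()
  orphanT <- setdiff(as.character(localities$id),
                     as.character(temps$id))
  if (length(orphanT))
    diag <- c(diag, paste("localities without temperature series:",
                          paste(orphanT, collapse = ", ")))
  missCols <- setdiff(MONTH_COLS, names(temps))
  if (length(missCols))
    diag <- c(diag, paste("temperature table lacks month column(s):",
                          paste(missCols, collapse = ", ")))
  if (any(abs(localities$latitude) > 90))
    diag <- c(diag, "latitude out of [-90, 90]")
  if (any(abs(localities$longitude) > 180))
    diag <- c(diag, "longitude out of [-180, 180]")
  if (!is.null(alignment)) {
    aln <- readAlignment(alignment)
    orphanA <- setdiff(unique(metadata(aln)$locality),
                       as.character(localities$id))
    if (length(orphanA))
      diag <- c(diag, paste(
        "alignment locality id(s) not in locality table:",
        paste(orphanA, collapse = ", ")))
  }
  diag
}

.provenance <- function(...) {
  sprintf("# photocline %s | %s",
          as.character(packageVersion("photocline")),
          paste(..., sep = " "))
}

.writeTable <- function(df, path, header, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Compute pCPP for all localities (pipeline stage)
#'
#' @param localities locality data.frame or CSV path.
#' @param temps temperature data.frame or CSV path.
#' @param thresholdC temperature threshold, degrees C.
#' @param outFile optional CSV output (`id,threshold_c,crossing_day,
#'   pcpp_h` with a provenance header line).
#' @return pCPP data.frame (see [pcppTable()]).
#' @export
runPcpp <- function(localities, temps, thresholdC = 6.6,
                    outFile = NULL) {
  if (is.character(localities)) localities <- readLocalities(localities)
  if (is.character(temps)) temps <- readTemperatures(temps)
  pc <- pcppTable(localities, temps, thresholdC)
  if (!is.null(outFile)) {
    out <- data.frame(id = pc$localityId, threshold_c = pc$thresholdC,
                      crossing_day = pc$crossingDay, pcpp_h = pc$pcppH)
    .writeTable(out, outFile,
                .provenance(sprintf("threshold_c=%g", thresholdC)))
  }
  pc
}

#' Run the full pipeline
#'
#' pCPP derivation, SNP calling, allele frequencies, F_ST / LD /
#' neighbor-joining tree, and per-lineage gene-environment association;
#' writes per-stage tables plus a machine-readable JSON summary. All
#' outputs are deterministic for fixed inputs and carry a provenance
#' header.
#'
#' @param localities locality data.frame or CSV path.
#' @param temps temperature data.frame or CSV path.
#' @param alignment alignment (path or object, see [readAlignment()]).
#' @param annotation a [FragmentAnnotation-class].
#' @param outDir output directory (created if needed); NULL skips
#'   writing.
#' @param thresholdC pCPP temperature threshold.
#' @param alpha significance level on adjusted p.
#' @param minCarriers exclusive carrier threshold for SNP calling.
#' @param excludePopulations ids dropped from association (sensitivity
#'   analysis).
#' @param distance tree distance, "fst" or "da".
#' @return list with `pcpp`, `set` (the [SnpFrequencySet-class]), `fst`,
#'   `fstSummary`, `ld`, `tree`, `associations` (per lineage), and
#'   `summary` (the JSON-ready list).
#' @export
runFull <- function(localities, temps, alignment, annotation,
                    outDir = NULL, thresholdC = 6.6, alpha = 0.05,
                    minCarriers = 3L, excludePopulations = NULL,
                    distance = c("fst", "da")) {
  distance <- match.arg(distance)
  if (is.character(localities)) localities <- readLocalities(localities)
  if (is.character(temps)) temps <- readTemperatures(temps)
  diag <- validateInputs(localities, temps, alignment)
  if (length(diag))
    .pcError(paste("input validation failed:",
                   paste(diag, collapse = "; ")), "inputError")
  pc <- pcppTable(localities, temps, thresholdC)
  calls <- callSnps(alignment, annotation, minCarriers)
  set <- snpFrequencySet(calls, localities, pcpp = pc)
  # order populations within lineage blocks from long to short pCPP for
  # the F_ST heatmap convention
  pd <- populationData(set)
  ord <- order(factor(pd$lineage, levels = c("WEST", "EAST")),
               -pd$pcppH)
  fst <- fstMatrix(set)[ord, ord]
  fsum <- fstSummary(fst, pd$lineage[ord])
  ld <- ldMatrix(set)
  tree <- populationTree(set, distance)
  lineages <- intersect(c("WEST", "EAST"), unique(pd$lineage))
  assoc <- lapply(setNames(lineages, lineages), function(li) {
    pops <- sum(pd$lineage == li &
                  !(rownames(pd) %in% excludePopulations))
    if (pops < 3) return(NULL)
    associateAll(set, lineage = li, alpha = alpha,
                 excludePopulations = excludePopulations)
  })
  info <- snpInfo(set)
  summary <- list(
    nPopulations = nrow(pd),
    nSpecimens = length(metadata(set)$specimenLocality),
    thresholdC = thresholdC,
    alpha = alpha,
    pcppRangeH = range(pc$pcppH),
    snpCounts = list(
      total = nrow(info),
      intronic = sum(info$region == "INTRONIC"),
      exonic = sum(info$region == "EXONIC"),
      synonymous = sum(info$effect == "SYNONYMOUS", na.rm = TRUE),
      nonsynonymous = sum(info$effect == "NONSYNONYMOUS", na.rm = TRUE)
    ),
    fst = lapply(split(fsum, fsum$block), function(b)
      list(nPairs = b$nPairs, min = b$min, mean = b$mean, max = b$max)),
    significantSnps = lapply(assoc, function(a) {
      if (is.null(a)) return(NULL)
      lapply(split(a, a$proxy), function(pp)
        sum(pp$significant))
    })
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    prov <- .provenance(sprintf("threshold_c=%g alpha=%g", thresholdC,
                                alpha))
    .writeTable(data.frame(id = pc$localityId,
                           threshold_c = pc$thresholdC,
                           crossing_day = pc$crossingDay,
                           pcpp_h = pc$pcppH),
                file.path(outDir, "pcpp.csv"), prov)
    .writeTable(info, file.path(outDir, "snps.tsv"), prov, sep = "\t")
    .writeTable(data.frame(id = rownames(alleleFrequencies(set)),
                           round(alleleFrequencies(set), 6),
                           check.names = FALSE),
                file.path(outDir, "frequencies.csv"), prov)
    .writeTable(data.frame(id = rownames(fst), round(fst, 6),
                           check.names = FALSE),
                file.path(outDir, "fst.csv"), prov)
    .writeTable(fsum, file.path(outDir, "fst_summary.tsv"), prov,
                sep = "\t")
    .writeTable(data.frame(snp = rownames(ld), round(ld, 6),
                           check.names = FALSE),
                file.path(outDir, "ld.csv"), prov)
    writeLines(c(prov, tree$newick), file.path(outDir, "tree.nwk"))
    for (li in names(assoc)) {
      if (is.null(assoc[[li]])) next
      .writeTable(assoc[[li]],
                  file.path(outDir,
                            sprintf("associations_%s.tsv",
                                    tolower(li))),
                  prov, sep = "\t")
      .writeTable(manhattanTable(assoc[[li]]),
                  file.path(outDir,
                            sprintf("manhattan_%s.tsv", tolower(li))),
                  prov, sep = "\t")
    }
    write_json(summary, file.path(outDir, "summary.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(pcpp = pc, set = set, fst = fst, fstSummary = fsum, ld = ld,
       tree = tree, associations = assoc, summary = summary)
}
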