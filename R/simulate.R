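#' Simulation configuration
#'
#' Parameters of the synthetic study generator, defaulting to the
#' paper-like setting: 43 localities (15 western + 28 eastern) spanning
#' latitudes 42-59 N, ~6 diploid specimens per locality, a 1678 bp
#' fragment (829 bp intron + 849 bp exon), 49 biallelic SNPs of which 12
#' follow a planted pCPP cline, and sinusoid-like annual temperature
#' cycles whose amplitude grows with continentality (eastern longitude).
#'
#' @param seed integer RNG seed ([simulateDataset()] applies it once).
#' @param nPopsWest,nPopsEast localities per lineage.
#' @param specimensPerPop diploid specimens per locality.
#' @param intronLen,exonLen fragment structure, bp.
#' @param cdsFrameOffset reading-frame phase of the first exonic base.
#' @param nSnpsTotal total polymorphic sites planted.
#' @param nClineSnps how many of them follow the pCPP cline.
#' @param clineSlope frequency change per hour of pCPP (cline SNPs).
#' @param lineageDivergence Beta(a, a) concentration for neutral
#'   baseline frequencies, drawn independently per lineage; small values
#'   (< 1) push lineage baselines toward 0/1 and induce high
#'   between-lineage differentiation.
#' @param driftKappa Beta concentration of per-population frequency
#'   noise around the baseline/cline value (beta-binomial
#'   overdispersion of sampled genotypes); larger = less drift.
#' @param thresholdC pCPP temperature threshold, degrees C.
#' @param tempMeanIntercept,tempMeanLatSlope annual mean temperature
#'   model `mu = intercept - slope * latitude` (degrees C).
#' @param tempAmpBase,tempAmpLonSlope annual amplitude model
#'   `A = base + slope * (longitude + 10)` (continentality).
#' @param tempLagMonths phase lag of the temperature cycle behind the
#'   calendar (months); makes temperature lag photoperiod so the annual
#'   trajectory opens into a counter-clockwise loop.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nPopsWest = 15L, nPopsEast = 28L,
                             specimensPerPop = 6L,
                             intronLen = 829L, exonLen = 849L,
                             cdsFrameOffset = 0L,
                             nSnpsTotal = 49L, nClineSnps = 12L,
                             clineSlope = 0.12,
                             lineageDivergence = 0.5,
                             driftKappa = 60,
                             thresholdC = 6.6,
                             tempMeanIntercept = 23,
                             tempMeanLatSlope = 0.245,
                             tempAmpBase = 6,
                             tempAmpLonSlope = 0.22,
                             tempLagMonths = 0.5) {
  cfg <- as.list(environment())
  counts <- c(cfg$nPopsWest + cfg$nPopsEast, cfg$specimensPerPop,
              cfg$intronLen, cfg$exonLen, cfg$nSnpsTotal)
  if (any(counts <= 0))
    .pcError("all counts must be positive", "inputError")
  if (cfg$nClineSnps > cfg$nSnpsTotal)
    .pcError("nClineSnps cannot exceed nSnpsTotal", "inputError")
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$nPopsWest, "WEST +", x$nPopsEast,
      "EAST populations,", x$specimensPerPop, "specimens each;",
      x$nSnpsTotal, "SNPs (", x$nClineSnps, "pCPP-cline )\n")
  invisible(x)
}

#' Generate a synthetic locality table
#'
#' Latitudes uniform in 42-59 N; western longitudes in -6..5 E, eastern
#' in 14..39 E; altitudes log-uniform in 4..2146 m. Uses the current RNG
#' state (seed once, e.g. in [simulateDataset()]).
#'
#' @param cfg a [simulationConfig()].
#' @return data.frame `id, name, latitude, longitude, altitude, lineage,
#'   n_specimens`.
#' @export
synthLocalities <- function(cfg) {
  nW <- cfg$nPopsWest; nE <- cfg$nPopsEast
  ids <- c(sprintf("W%02d", seq_len(nW)), sprintf("E%02d", seq_len(nE)))
  lineage <- rep(c("WEST", "EAST"), c(nW, nE))
  data.frame(
    id = ids,
    name = paste0("synthetic-", ids),
    latitude = runif(nW + nE, 42, 59),
    longitude = c(runif(nW, -6, 5), runif(nE, 14, 39)),
    altitude = exp(runif(nW + nE, log(4), log(2146))),
    lineage = lineage,
    n_specimens = cfg$specimensPerPop
  )
}

#' Generate monthly temperature series for synthetic localities
#'
#' `T(m) = mu - A cos(2 pi (m - 1 - lag) / 12)` with annual mean
#' decreasing in latitude and amplitude increasing with eastern
#' longitude (continentality). Generation fails if any site's annual
#' cycle does not cross the pCPP threshold.
#'
#' @param cfg a [simulationConfig()].
#' @param localities table from [synthLocalities()].
#' @return data.frame `id, jan, ..., dec`.
#' @export
synthClimate <- function(cfg, localities) {
  months <- tolower(month.abb)
  out <- data.frame(id = localities$id)
  for (m in seq_len(12)) out[[months[m]]] <- NA_real_
  for (i in seq_len(nrow(localities))) {
    mu <- cfg$tempMeanIntercept -
      cfg$tempMeanLatSlope * localities$latitude[i]
    A <- cfg$tempAmpBase +
      cfg$tempAmpLonSlope * (localities$longitude[i] + 10)
    temps <- mu - A * cos(2 * pi * (1:12 - 1 - cfg$tempLagMonths) / 12)
    if (cfg$thresholdC <= min(temps) || cfg$thresholdC >= max(temps))
      .pcError(sprintf(
        "climate for '%s' never crosses %.1f degC; adjust config",
        localities$id[i], cfg$thresholdC), "generationError")
    out[i, months] <- temps
  }
  out
}

# default SNP position labels reserved for planted cline SNPs; mirrors
# the convention that the strongest clinal sites sit near the
# intron/exon boundary (-158, -128) and in the early exon (+126)
CLINE_LABEL_POOL <- c(-158L, -128L, -144L, -90L, -50L,
                      126L, 250L, 400L, 520L, 640L, 700L, 780L)

#' Plant true per-population allele frequencies
#'
#' Cline SNPs: `p = clamp(0.5 + beta * (pCPP - mean pCPP), 0.02, 0.98)`.
#' Neutral SNPs: a lineage-specific baseline drawn from
#' Beta(a, a) (a = `lineageDivergence`; independent per lineage, so the
#' two lineages diverge), plus per-population Beta noise with
#' concentration `driftKappa`.
#'
#' @param cfg a [simulationConfig()].
#' @param localities table from [synthLocalities()].
#' @param pcpp pCPP table from [pcppTable()] for these localities.
#' @return list: `freq` (population x SNP matrix of true frequencies,
#'   columns named by position label), `truth` (data.frame `label,
#'   region, class, baselineWest, baselineEast`).
#' @export
synthTruthFrequencies <- function(cfg, localities, pcpp) {
  nIntron <- round(cfg$nSnpsTotal * 22 / 49)
  nCline <- cfg$nClineSnps
  # reserved labels that actually fit this fragment; keep exonic labels
  # clear of the fragment end so codons stay inside the sequenced exon
  validPool <- CLINE_LABEL_POOL[
    (CLINE_LABEL_POOL < 0 & -CLINE_LABEL_POOL <= cfg$intronLen) |
    (CLINE_LABEL_POOL > 0 & CLINE_LABEL_POOL <= cfg$exonLen - 5L)]
  clineLabels <- validPool[seq_len(min(nCline, length(validPool)))]
  intronPool <- setdiff(-(seq_len(cfg$intronLen)), clineLabels)
  exonPool <- setdiff(seq_len(cfg$exonLen - 5L), clineLabels)
  shortfall <- nCline - length(clineLabels)
  if (shortfall > 0) {
    nExtraI <- min(shortfall, length(intronPool))
    extra <- sample(intronPool, nExtraI)
    if (shortfall > nExtraI)
      extra <- c(extra, sample(exonPool, shortfall - nExtraI))
    clineLabels <- c(clineLabels, extra)
    intronPool <- setdiff(intronPool, extra)
    exonPool <- setdiff(exonPool, extra)
  }
  nClineIntron <- sum(clineLabels < 0)
  neutIntron <- min(max(0L, nIntron - nClineIntron),
                    cfg$nSnpsTotal - nCline)
  neutExon <- cfg$nSnpsTotal - nCline - neutIntron
  labels <- c(sort(c(clineLabels[clineLabels < 0],
                     sample(intronPool, neutIntron))),
              sort(c(clineLabels[clineLabels > 0],
                     sample(exonPool, neutExon))))
  isCline <- labels %in% clineLabels
  P <- nrow(localities)
  m <- match(localities$id, pcpp$localityId)
  pc <- pcpp$pcppH[m]
  pcCentered <- pc - mean(pc)
  west <- localities$lineage == "WEST"
  freq <- matrix(NA_real_, P, length(labels),
                 dimnames = list(localities$id, as.character(labels)))
  truth <- data.frame(label = labels,
                      region = ifelse(labels < 0, "INTRONIC", "EXONIC"),
                      class = ifelse(isCline, "cline", "neutral"),
                      baselineWest = NA_real_, baselineEast = NA_real_)
  for (s in seq_along(labels)) {
    if (isCline[s]) {
      base <- pmin(pmax(0.5 + cfg$clineSlope * pcCentered, 0.02), 0.98)
      truth$baselineWest[s] <- truth$baselineEast[s] <- 0.5
    } else {
      bw <- min(max(rbeta(1, cfg$lineageDivergence,
                          cfg$lineageDivergence), 0.05), 0.95)
      be <- min(max(rbeta(1, cfg$lineageDivergence,
                          cfg$lineageDivergence), 0.05), 0.95)
      base <- ifelse(west, bw, be)
      truth$baselineWest[s] <- bw
      truth$baselineEast[s] <- be
    }
    k <- cfg$driftKappa
    freq[, s] <- rbeta(P, base * k, (1 - base) * k)
  }
  freq <- pmin(pmax(freq, 0.02), 0.98)
  list(freq = freq, truth = truth)
}

# label -> 0-based column: negative labels count back from the boundary,
# positive labels 1-based into the exon
.labelToColumn <- function(label, intronLen) {
  ifelse(label < 0, intronLen + label, intronLen + label - 1L)
}

#' Synthesize a diploid consensus alignment from true frequencies
#'
#' Builds a random A/C/G/T reference fragment, places each SNP at the
#' column its position label implies, and draws per-specimen diploid
#' genotypes Binomial(2, p_pop) (the Beta noise already applied to
#' `p_pop` makes the allele counts beta-binomially overdispersed).
#' Heterozygotes are written as IUPAC ambiguity codes. Columns whose
#' sampled carriers fail the `> 3` rule are redrawn (with a message), so
#' every planted SNP is callable.
#'
#' @param cfg a [simulationConfig()].
#' @param localities table from [synthLocalities()].
#' @param truthFreq output of [synthTruthFrequencies()].
#' @param genotypeMode "binomial" (default) draws genotypes randomly;
#'   "exact" assigns each population the allele counts closest to its
#'   true frequency (deterministic given the truth; useful for
#'   noise-free round-trip checks).
#' @return list: `alignment` (named `DNAStringSet`,
#'   `specimen|locality` headers), `annotation`
#'   ([FragmentAnnotation-class]), `columns` (0-based SNP columns).
#' @export
synthAlignment <- function(cfg, localities, truthFreq,
                           genotypeMode = c("binomial", "exact")) {
  genotypeMode <- match.arg(genotypeMode)
  L <- cfg$intronLen + cfg$exonLen
  refChars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  labels <- as.integer(colnames(truthFreq$freq))
  cols <- .labelToColumn(labels, cfg$intronLen)
  nSpec <- cfg$specimensPerPop
  P <- nrow(localities)
  N <- P * nSpec
  specLoc <- rep(localities$id, each = nSpec)
  specIds <- sprintf("S%03d", seq_len(N))
  mat <- matrix(refChars, nrow = N, ncol = L, byrow = TRUE)
  resampled <- 0L
  for (s in seq_along(labels)) {
    col <- cols[s] + 1L
    ref <- refChars[col]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    p <- truthFreq$freq[specLoc, s]
    for (try in seq_len(60L)) {
      g <- if (genotypeMode == "exact") {
        # per population: alt-allele count rounded from 2n p, packed as
        # homozygotes plus at most one heterozygote
        unlist(lapply(seq_len(P), function(pop) {
          tot <- round(2 * nSpec * truthFreq$freq[pop, s])
          c(rep(2, tot %/% 2), rep(1, tot %% 2),
            rep(0, nSpec - tot %/% 2 - tot %% 2))
        }))
      } else {
        rbinom(N, 2, p)
      }
      if (sum(g >= 1) > 3L || genotypeMode == "exact") break
      resampled <- resampled + 1L
    }
    chars <- character(N)
    chars[g == 0] <- ref
    chars[g == 2] <- alt
    chars[g == 1] <- .hetCode(ref, alt)
    mat[, col] <- chars
  }
  if (resampled > 0)
    message(resampled,
            " column redraw(s) to satisfy the >3-carrier rule")
  aln <- DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(aln) <- paste(specIds, specLoc, sep = "|")
  list(
    alignment = aln,
    annotation = fragmentAnnotation(cfg$intronLen, cfg$exonLen,
                                    cfg$cdsFrameOffset,
                                    paste(refChars, collapse = "")),
    columns = cols
  )
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG once from `cfg$seed`, then chains
#' [synthLocalities()] -> [synthClimate()] -> [pcppTable()] ->
#' [synthTruthFrequencies()] -> [synthAlignment()]. Fully deterministic
#' given the config.
#'
#' @param cfg a [simulationConfig()].
#' @param dir optional output directory; when given, writes
#'   `localities.csv`, `temps.csv`, `alignment.fasta`,
#'   `reference.fasta`, `annotation.yaml` and `truth.tsv`.
#' @return list with `localities`, `temps`, `pcpp`, `truth` (truth
#'   table), `trueFreq`, `alignment`, `annotation`, `config`.
#' @export
simulateDataset <- function(cfg = simulationConfig(), dir = NULL) {
  set.seed(cfg$seed)
  localities <- synthLocalities(cfg)
  temps <- synthClimate(cfg, localities)
  pcpp <- pcppTable(localities, temps, cfg$thresholdC)
  tf <- synthTruthFrequencies(cfg, localities, pcpp)
  al <- synthAlignment(cfg, localities, tf)
  out <- list(localities = localities, temps = temps, pcpp = pcpp,
              truth = tf$truth, trueFreq = tf$freq,
              alignment = al$alignment, annotation = al$annotation,
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(localities, file.path(dir, "localities.csv"),
              row.names = FALSE)
    write.csv(temps, file.path(dir, "temps.csv"), row.names = FALSE)
    writeXStringSet(al$alignment, file.path(dir, "alignment.fasta"))
    ref <- DNAStringSet(referenceSequence(al$annotation))
    names(ref) <- "reference"
    writeXStringSet(ref, file.path(dir, "reference.fasta"))
    write_yaml(list(intron_len = cfg$intronLen,
                    exon_len = cfg$exonLen,
                    cds_frame_offset = cfg$cdsFrameOffset),
               file.path(dir, "annotation.yaml"))
    write.table(tf$truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  out
}
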