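#' Great-circle distance
#'
#' Haversine distance on a sphere of Earth's mean radius (6371.0088 km).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectors
#'   recycled).
#' @return Distance in km.
#' @examples
#' haversineKm(0, 0, 0, 1) # ~ 111.19 km
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Absolute pairwise differences over all unordered population pairs
#'
#' Condensed vector of `|v_i - v_j|` over pairs `i < j`, in the fixed
#' lexicographic order of [utils::combn()] -- identical for every proxy
#' and SNP, so condensed vectors are directly comparable.
#'
#' @param values numeric vector, one value per population (>= 3).
#' @return Numeric vector of length `P (P - 1) / 2`.
#' @examples
#' pairwiseDelta(c(1, 4, 6))
#' @export
pairwiseDelta <- function(values) {
  if (length(values) < 3L)
    .pcError("need at least 3 populations", "inputError")
  idx <- combn(length(values), 2)
  abs(values[idx[1, ]] - values[idx[2, ]])
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom, n being the number of
#' (pairwise) points. With pairwise-difference designs the points are
#' not independent, so the nominal p is anticonservative; see
#' [associateAll()] for the optional permutation p-value.
#'
#' @param x,y equal-length numeric vectors (>= 3 points, both
#'   non-constant).
#' @return list with `r`, `r2` and `p`.
#' @examples
#' pearsonTest(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    .pcError("x and y must have equal length >= 3", "inputError")
  if (var(x) == 0 || var(y) == 0)
    .pcError("correlation undefined for constant input",
             "constantInputError")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' `p_(i)` by `m / i`, enforce monotonicity from the largest rank down,
#' cap at 1, and return in input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    .pcError("p-values must lie in [0, 1]", "inputError")
  p.adjust(pvals, method = "BH")
}

# pair index matrix for P populations (combn order, cached per call)
.pairIdx <- function(P) combn(P, 2)

# proxy pairwise-difference vectors for a population table
.proxyDeltas <- function(pd, proxies) {
  P <- nrow(pd)
  idx <- .pairIdx(P)
  out <- list()
  for (pr in proxies) {
    out[[pr]] <- switch(pr,
      GEO = haversineKm(pd$latitude[idx[1, ]], pd$longitude[idx[1, ]],
                        pd$latitude[idx[2, ]], pd$longitude[idx[2, ]]),
      LAT = abs(pd$latitude[idx[1, ]] - pd$latitude[idx[2, ]]),
      LON = abs(pd$longitude[idx[1, ]] - pd$longitude[idx[2, ]]),
      ALT = abs(pd$altitude[idx[1, ]] - pd$altitude[idx[2, ]]),
      PCPP = abs(pd$pcppH[idx[1, ]] - pd$pcppH[idx[2, ]]),
      .pcError(paste("unknown proxy:", pr), "inputError"))
  }
  out
}

#' Population-based gene-environment association
#'
#' For each SNP polymorphic within the selected populations and each
#' environmental proxy, correlates the pairwise absolute differences in
#' population allele frequency with the pairwise differences in the
#' proxy (great-circle distance for GEO; `|delta|` of latitude,
#' longitude, altitude, and pCPP). P-values are Benjamini-Hochberg
#' adjusted within each proxy across that lineage's SNPs.
#'
#' @param x a [SnpFrequencySet-class]; for the PCPP proxy its population
#'   data must carry `pcppH` (attach via [snpFrequencySet()]'s `pcpp`
#'   argument).
#' @param lineage optional lineage label ("WEST"/"EAST") restricting the
#'   populations; NULL uses all.
#' @param proxies subset of `c("GEO","LAT","LON","ALT","PCPP")`.
#' @param alpha significance level applied to the adjusted p.
#' @param excludePopulations population ids dropped before analysis
#'   (e.g. island populations for a sensitivity run).
#' @param permutations if > 0, adds a Mantel-style permutation p-value
#'   (`pPerm`) obtained by permuting population labels of the proxy;
#'   exchangeability-correct but slower. Default 0 (off).
#' @return data.frame with one row per SNP x proxy: `snpLabel, proxy,
#'   nPairs, r, r2, p, pAdj, significant` (+ `pPerm`), ordered by
#'   position label within proxy.
#' @export
associateAll <- function(x, lineage = NULL,
                         proxies = c("GEO", "LAT", "LON", "ALT", "PCPP"),
                         alpha = 0.05, excludePopulations = NULL,
                         permutations = 0L) {
  stopifnot(is(x, "SnpFrequencySet"))
  pd <- populationData(x)
  keep <- rep(TRUE, nrow(pd))
  if (!is.null(lineage)) keep <- keep & pd$lineage %in% lineage
  if (!is.null(excludePopulations))
    keep <- keep & !(rownames(pd) %in% excludePopulations)
  pd <- pd[keep, , drop = FALSE]
  if (nrow(pd) < 3L)
    .pcError("need at least 3 populations after filtering",
             "inputError")
  if ("PCPP" %in% proxies && is.null(pd$pcppH))
    .pcError("PCPP proxy requested but no pcppH in population data",
             "inputError")
  freq <- alleleFrequencies(x)[keep, , drop = FALSE]
  deltas <- .proxyDeltas(pd, proxies)
  idx <- .pairIdx(nrow(pd))
  labels <- snpInfo(x)$positionLabel
  res <- list()
  for (s in seq_len(ncol(freq))) {
    fv <- freq[, s]
    okPop <- is.finite(fv)
    if (sum(okPop) < 3L) next
    vals <- fv[okPop]
    if (max(vals) == min(vals)) next  # monomorphic in this lineage
    pairOk <- okPop[idx[1, ]] & okPop[idx[2, ]]
    dFreq <- abs(fv[idx[1, ]] - fv[idx[2, ]])[pairOk]
    for (pr in proxies) {
      dProx <- deltas[[pr]][pairOk]
      if (var(dProx) == 0) next
      pt <- pearsonTest(dProx, dFreq)
      row <- data.frame(
        snpLabel = labels[s], proxy = pr, nPairs = sum(pairOk),
        r = pt$r, r2 = pt$r2, p = pt$p)
      if (permutations > 0) {
        obs <- abs(pt$r)
        hits <- 0L
        prox <- pd[[switch(pr, GEO = "latitude", LAT = "latitude",
                           LON = "longitude", ALT = "altitude",
                           PCPP = "pcppH")]]
        for (b in seq_len(permutations)) {
          perm <- sample(nrow(pd))
          pdp <- pd
          if (pr == "GEO") {
            pdp$latitude <- pd$latitude[perm]
            pdp$longitude <- pd$longitude[perm]
          } else {
            nm <- switch(pr, LAT = "latitude", LON = "longitude",
                         ALT = "altitude", PCPP = "pcppH")
            pdp[[nm]] <- pd[[nm]][perm]
          }
          dp <- .proxyDeltas(pdp, pr)[[pr]][pairOk]
          if (var(dp) == 0) next
          if (abs(cor(dp, dFreq)) >= obs) hits <- hits + 1L
        }
        row$pPerm <- (hits + 1) / (permutations + 1)
      }
      res[[length(res) + 1L]] <- row
    }
  }
  if (!length(res))
    return(data.frame(snpLabel = integer(), proxy = character(),
                      nPairs = integer(), r = numeric(), r2 = numeric(),
                      p = numeric(), pAdj = numeric(),
                      significant = logical()))
  out <- do.call(rbind, res)
  out$pAdj <- NA_real_
  for (pr in unique(out$proxy)) {
    sel <- out$proxy == pr
    out$pAdj[sel] <- bhAdjust(out$p[sel])
  }
  out$significant <- out$pAdj < alpha
  out[order(out$proxy, out$snpLabel), , drop = FALSE]
}

#' Scatter data for one SNP x proxy panel
#'
#' The (pairwise proxy difference, pairwise frequency difference) points
#' behind one association test, ready for plotting.
#'
#' @inheritParams associateAll
#' @param snpLabel position label of the SNP.
#' @param proxy one of "GEO","LAT","LON","ALT","PCPP".
#' @return data.frame with `popA, popB, deltaProxy, deltaFreq`.
#' @export
scatterData <- function(x, snpLabel, proxy, lineage = NULL) {
  pd <- populationData(x)
  keep <- if (is.null(lineage)) rep(TRUE, nrow(pd)) else
    pd$lineage %in% lineage
  pd <- pd[keep, , drop = FALSE]
  freq <- alleleFrequencies(x)[keep, , drop = FALSE]
  s <- match(snpLabel, snpInfo(x)$positionLabel)
  if (is.na(s)) .pcError("unknown SNP label", "inputError")
  idx <- .pairIdx(nrow(pd))
  dProx <- .proxyDeltas(pd, proxy)[[proxy]]
  fv <- freq[, s]
  data.frame(
    popA = rownames(pd)[idx[1, ]], popB = rownames(pd)[idx[2, ]],
    deltaProxy = dProx,
    deltaFreq = abs(fv[idx[1, ]] - fv[idx[2, ]]))
}

#' Manhattan-plot table from association results
#'
#' Per SNP and proxy: `-log10(pAdj)` and r-squared, ordered by position
#' label, matching the per-panel presentation of clinal-association
#' Manhattan plots.
#'
#' @param assoc output of [associateAll()].
#' @return data.frame `snpLabel, proxy, negLog10PAdj, r2, significant`.
#' @export
manhattanTable <- function(assoc) {
  data.frame(
    snpLabel = assoc$snpLabel, proxy = assoc$proxy,
    negLog10PAdj = -log10(pmax(assoc$pAdj, .Machine$double.xmin)),
    r2 = assoc$r2, significant = assoc$significant)
}
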