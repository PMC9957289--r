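# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the package implementation.

# Solar declination from the perihelion-anchored ecliptic-longitude
# approximation (independent of the Spencer Fourier series used by the
# package).
oracleDeclination <- function(d) {
  -asin(0.39779 * cos(pi / 180 * (0.98565 * (d + 10) +
        1.914 * sin(pi / 180 * 0.98565 * (d - 2))))) * 180 / pi
}

oracleDaylength <- function(lat, d, depressionDeg = 6) {
  dec <- oracleDeclination(d) * pi / 180
  phi <- lat * pi / 180
  cosH <- (cos((90 + depressionDeg) * pi / 180) - sin(phi) * sin(dec)) /
    (cos(phi) * cos(dec))
  cosH <- pmin(pmax(cosH, -1), 1)
  2 * acos(cosH) * 180 / pi / 15
}

# Continuous periodic piecewise-linear interpolation of monthly means
# (re-derived, not the package's integer-day version).
oracleTempAt <- function(temps, day) {
  anchors <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  x <- c(anchors[12] - 365, anchors, anchors[1] + 365)
  y <- c(temps[12], temps, temps[1])
  approx(x, y, xout = day)$y
}

# Brute-force pCPP: scan the interpolated daily temperature at 0.01-day
# resolution, take the last upward crossing before the annual maximum.
orclePcppScan <- function(latitude, temps, threshold, step = 0.01) {
  d <- seq(1, 365.99, by = step)
  tv <- oracleTempAt(temps, ifelse(d > 365, d - 365, d))
  nxt <- c(tv[-1], tv[1])
  up <- which(tv < threshold & nxt >= threshold)
  if (!length(up)) return(NULL)
  days <- d[up] + step / 2
  dmax <- d[which.max(tv)]
  before <- days[days <= dmax]
  day <- if (length(before)) max(before) else max(days)
  list(day = day,
       pcpp = oracleDaylength(latitude, day, depressionDeg = 6))
}

# Naive flat SNP caller: per-column scan with its own IUPAC decoding,
# independent of genotypeColumn()/callSnps().
naiveCallSnps <- function(seqMat, referenceSeq, minCarriers = 3) {
  decode <- c(A = "AA", C = "CC", G = "GG", T = "TT",
              R = "AG", Y = "CT", S = "CG", W = "AT",
              K = "GT", M = "AC")
  refChars <- strsplit(referenceSeq, "")[[1]]
  called <- integer(0)
  for (j in seq_len(ncol(seqMat))) {
    gt <- decode[toupper(seqMat[, j])]
    alleles <- unlist(strsplit(gt[!is.na(gt)], ""))
    seg <- unique(alleles)
    if (length(seg) != 2) next
    ref <- refChars[j]
    if (!ref %in% seg) ref <- names(sort(-table(alleles)))[1]
    alt <- setdiff(seg, ref)
    carriers <- sum(vapply(gt, function(g)
      !is.na(g) && grepl(alt, g), logical(1)))
    if (carriers > minCarriers) called <- c(called, j - 1L)
  }
  called
}

# Symbol-by-symbol multilocus G_ST (direct transcription of the
# estimator definition; no vectorised shortcuts shared with the
# package).
oracleGst <- function(pA, pB, nA, nB) {
  sumHT <- 0
  sumHS <- 0
  for (l in seq_along(pA)) {
    pbar <- (pA[l] + pB[l]) / 2
    if (pbar <= 0 || pbar >= 1) next
    hsA <- (2 * nA[l] / (2 * nA[l] - 1)) *
      (1 - pA[l]^2 - (1 - pA[l])^2)
    hsB <- (2 * nB[l] / (2 * nB[l] - 1)) *
      (1 - pB[l]^2 - (1 - pB[l])^2)
    hs <- (hsA + hsB) / 2
    nh <- 2 / (1 / nA[l] + 1 / nB[l])
    ht <- (2 * nh / (2 * nh - 1)) * (1 - pbar^2 - (1 - pbar)^2)
    sumHT <- sumHT + ht
    sumHS <- sumHS + hs
  }
  if (sumHT == 0) return(0)
  max(0, min(1, (sumHT - sumHS) / sumHT))
}

# Build a small alignment matrix (specimens x columns) into named
# sequences acceptable to readAlignment().
alnFromMatrix <- function(mat, localities) {
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("S", seq_len(nrow(mat)), "|", localities)
  seqs
}

# Sinusoid monthly temperature series: mean mu, amplitude A, coldest
# around month (1 + lag).
sinusoidTemps <- function(mu, A, lagMonths = 0.5) {
  mu - A * cos(2 * pi * (1:12 - 1 - lagMonths) / 12)
}
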