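# Day-of-year anchors for monthly means: the 15th of each month in a
# 365-day year (Feb = 28 d). Interpolation is periodic across Dec -> Jan.
MID_MONTH_DAYS <- c(15L, 46L, 74L, 105L, 135L, 166L,
                    196L, 227L, 258L, 288L, 319L, 349L)

.checkDay <- function(day) {
  # fractional days up to (not including) 366 are allowed so that
  # interpolated crossing days between Dec 31 and Jan 1 remain valid
  if (any(!is.finite(day)) || any(day < 1 | day >= 366))
    .pcError("day_of_year must lie in [1, 365]", "inputError")
}

#' Solar declination
#'
#' Declination of the sun for a day of a 365-day year, from the Spencer
#' Fourier-series expansion (accuracy well under 0.3 degrees, ample for
#' day-length work). Fractional days are accepted so that interpolated
#' threshold-crossing days can be used directly.
#'
#' @param dayOfYear numeric vector in \[1, 365\] (fractional allowed).
#' @return Declination in degrees, in about \[-23.45, 23.45\].
#' @examples
#' solarDeclination(172) # near the June solstice, ~ +23.4
#' @export
solarDeclination <- function(dayOfYear) {
  .checkDay(dayOfYear)
  g <- 2 * pi * (dayOfYear - 1) / 365
  dec <- 0.006918 -
    0.399912 * cos(g)     + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.001480 * sin(3 * g)
  dec * 180 / pi
}

#' Civil-twilight day length
#'
#' Hours of light per 24 h between civil dawn and civil dusk, i.e. with
#' the sun's center no lower than `depressionDeg` (default 6) degrees
#' below the horizon. The hour-angle cosine is clamped to \[-1, 1\], so
#' polar day yields 24 h and polar night 0 h. `depressionDeg = 0` gives
#' the geometric (sunrise-to-sunset, no refraction) day length.
#'
#' @param latitude degrees north, in \[-90, 90\].
#' @param dayOfYear numeric in \[1, 365\] (fractional allowed); recycled
#'   against `latitude`.
#' @param depressionDeg solar depression defining dawn/dusk, degrees.
#' @return Day length in hours, in \[0, 24\].
#' @examples
#' civilDaylength(52, 86)   # spring day length at 52 N
#' civilDaylength(70, 172)  # polar day -> 24
#' @export
civilDaylength <- function(latitude, dayOfYear, depressionDeg = 6) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    .pcError("latitude must lie in [-90, 90]", "inputError")
  .checkDay(dayOfYear)
  phi <- latitude * pi / 180
  dec <- solarDeclination(dayOfYear) * pi / 180
  zen <- (90 + depressionDeg) * pi / 180
  cosH <- (cos(zen) - sin(phi) * sin(dec)) / (cos(phi) * cos(dec))
  cosH[!is.finite(cosH)] <- sign(cosH[!is.finite(cosH)]) # +-Inf at poles
  cosH[is.na(cosH)] <- 1
  cosH <- pmin(pmax(cosH, -1), 1)
  # acos(-1)/pi is exactly 1, so polar day is exactly 24 h and polar
  # night exactly 0 h
  acos(cosH) / pi * 24
}

#' Interpolate monthly mean temperatures to daily values
#'
#' Periodic piecewise-linear interpolation of 12 monthly means, anchored
#' at mid-month days (Jan 15 = day 15, ..., Dec 15 = day 349) and
#' wrapping December to January. Linear interpolation cannot overshoot,
#' so daily values stay within the monthly min/max.
#'
#' @param temps numeric vector of 12 monthly means, Jan..Dec, degrees C.
#' @return Numeric vector of 365 daily temperatures.
#' @examples
#' range(interpolateDailyTemperature(c(-3, -1, 3, 8, 13, 17,
#'                                     19, 18, 14, 9, 4, 0)))
#' @export
interpolateDailyTemperature <- function(temps) {
  temps <- as.numeric(temps)
  if (length(temps) != 12L || any(!is.finite(temps)))
    .pcError("need exactly 12 finite monthly temperatures", "inputError")
  x <- c(MID_MONTH_DAYS[12] - 365, MID_MONTH_DAYS, MID_MONTH_DAYS[1] + 365)
  y <- c(temps[12], temps, temps[1])
  approx(x, y, xout = 1:365)$y
}

#' Build the annual photoperiod-temperature trajectory of a locality
#'
#' Combines the civil-twilight day length at the locality's latitude with
#' the daily interpolation of its monthly mean temperatures into a
#' [ClimateEllipse-class].
#'
#' @param locality one-row data.frame (or list) with at least `id` and
#'   `latitude`.
#' @param temps either a numeric vector of 12 monthly means, or a one-row
#'   data.frame with an `id` column followed by the 12 monthly columns
#'   (as read by [readTemperatures()]); when an id is present it must
#'   match `locality$id`.
#' @return A [ClimateEllipse-class] object.
#' @examples
#' loc <- data.frame(id = "L1", latitude = 52)
#' ell <- buildEllipse(loc, 10 - 10 * cos(2 * pi * (1:12 - 1.5) / 12))
#' ell
#' @export
buildEllipse <- function(locality, temps) {
  id <- as.character(locality$id)
  if (is.data.frame(temps) || is.list(temps)) {
    if (!is.null(temps$id) && as.character(temps$id) != id)
      .pcError(sprintf(
        "temperature series id '%s' does not match locality '%s'",
        temps$id, id), "inputError")
    temps <- as.numeric(temps[setdiff(names(temps), "id")])
  }
  new("ClimateEllipse",
    localityId = id,
    latitude = as.numeric(locality$latitude),
    day = 1:365,
    photoperiod = civilDaylength(locality$latitude, 1:365),
    temperature = interpolateDailyTemperature(temps)
  )
}

#' Signed area of the photoperiod-temperature trajectory
#'
#' Shoelace signed area of the closed annual trajectory with photoperiod
#' on x and temperature on y; positive values mean counter-clockwise
#' traversal (Jan -> Dec), which is the Northern-Hemisphere pattern when
#' temperature lags photoperiod. A zero phase lag collapses the loop to
#' a (near-)degenerate curve with area ~ 0.
#'
#' @param ellipse a [ClimateEllipse-class].
#' @return Signed area in hours x degrees C.
#' @export
ellipseSignedArea <- function(ellipse) {
  x <- ellipse@photoperiod
  y <- ellipse@temperature
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# rising threshold crossings of a daily series, circular over the year;
# returns fractional days in [1, 366)
.risingCrossings <- function(temp, threshold) {
  nxt <- c(temp[-1], temp[1])
  i <- which(temp < threshold & nxt >= threshold)
  if (!length(i)) return(numeric(0))
  frac <- (threshold - temp[i]) / (nxt[i] - temp[i])
  d <- i + frac
  ifelse(d >= 366, d - 365, d)
}

#' Predicted critical photoperiod (pCPP)
#'
#' Day length at the spring crossing of the annual trajectory: the day
#' when the interpolated daily temperature rises through `thresholdC`
#' while day length is increasing toward summer. For unimodal annual
#' temperature cycles there is exactly one rising crossing; with several,
#' the last rising crossing before the day of the annual temperature
#' maximum is taken (the "spring" crossing of the ellipse). The crossing
#' day is refined by linear interpolation between adjacent days.
#'
#' @param ellipse a [ClimateEllipse-class].
#' @param thresholdC temperature threshold in degrees C (default 6.6, a
#'   proxy for the onset of grass growth); must lie strictly between the
#'   annual minimum and maximum, otherwise a `noCrossingError` naming the
#'   locality is raised.
#' @return data.frame with columns `localityId`, `thresholdC`,
#'   `crossingDay` (fractional day of year), `pcppH` (hours of light per
#'   24 h).
#' @examples
#' loc <- data.frame(id = "L1", latitude = 52)
#' ell <- buildEllipse(loc, 10 - 10 * cos(2 * pi * (1:12 - 0.5) / 12))
#' predictedCriticalPhotoperiod(ell, 6.6)
#' @export
predictedCriticalPhotoperiod <- function(ellipse, thresholdC = 6.6) {
  temp <- ellipse@temperature
  if (thresholdC <= min(temp) || thresholdC >= max(temp))
    .pcError(sprintf(
      "no %.2f degC crossing for locality '%s' (annual range %.2f..%.2f)",
      thresholdC, ellipse@localityId, min(temp), max(temp)),
      "noCrossingError")
  cross <- .risingCrossings(temp, thresholdC)
  if (!length(cross))
    .pcError(sprintf("no rising crossing for locality '%s'",
                     ellipse@localityId), "noCrossingError")
  dmax <- which.max(temp)
  before <- cross[cross <= dmax]
  day <- if (length(before)) max(before) else max(cross)
  data.frame(
    localityId = ellipse@localityId,
    thresholdC = thresholdC,
    crossingDay = day,
    pcppH = civilDaylength(ellipse@latitude, day)
  )
}

#' pCPP for a table of localities
#'
#' Runs [buildEllipse()] and [predictedCriticalPhotoperiod()] across a
#' locality table and matching temperature table.
#'
#' @param localities data.frame as from [readLocalities()] (needs `id`,
#'   `latitude`).
#' @param temps data.frame as from [readTemperatures()]: `id` plus 12
#'   monthly columns.
#' @param thresholdC temperature threshold, degrees C.
#' @return data.frame `localityId, thresholdC, crossingDay, pcppH`, one
#'   row per locality, in the order of `localities`.
#' @export
pcppTable <- function(localities, temps, thresholdC = 6.6) {
  rownames(temps) <- as.character(temps$id)
  missing <- setdiff(as.character(localities$id), rownames(temps))
  if (length(missing))
    .pcError(paste("no temperature series for:",
                   paste(missing, collapse = ", ")), "inputError")
  out <- lapply(seq_len(nrow(localities)), function(i) {
    loc <- localities[i, ]
    ell <- buildEllipse(loc, temps[as.character(loc$id), ])
    predictedCriticalPhotoperiod(ell, thresholdC)
  })
  do.call(rbind, out)
}
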