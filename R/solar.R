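# Solar and lunar geometry: low-precision ephemeris (NOAA/Meeus class)
# sufficient for twilight classification and moon phase, not for navigation.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

# days since J2000.0 for POSIXct (UTC)
.j2000_days <- function(instant) {
  as.numeric(instant) / 86400 + 2440587.5 - 2451545
}

.obliquity <- 23.4397 * .deg2rad

.solar_mean_anomaly <- function(d) (357.5291 + 0.98560028 * d) * .deg2rad

.ecliptic_longitude <- function(M) {
  C <- (1.9148 * sin(M) + 0.02 * sin(2 * M) + 0.0003 * sin(3 * M)) * .deg2rad
  P <- 102.9372 * .deg2rad # perihelion of the Earth
  M + C + P + pi
}

.sun_coords <- function(d) {
  M <- .solar_mean_anomaly(d)
  L <- .ecliptic_longitude(M)
  list(
    dec = asin(sin(L) * sin(.obliquity)),
    ra  = atan2(sin(L) * cos(.obliquity), cos(L))
  )
}

.sidereal_time <- function(d, lw) (280.16 + 360.9856235 * d) * .deg2rad - lw

#' Solar elevation angle
#'
#' Geometric (unrefracted) elevation of the sun above the horizon, computed
#' with a standard low-precision solar-position algorithm (accuracy a few
#' tenths of a degree over 1950--2050, ample for twilight classification).
#'
#' @param lat,lon Position in decimal degrees (lat in \[-90, 90\], lon in
#'   \[-180, 180\]).
#' @param instant A `POSIXct` time (UTC); vectorised over `instant` and over
#'   `lat`/`lon` jointly.
#' @return Solar elevation in degrees.
#' @examples
#' solar_elevation(55, -50, as.POSIXct("2019-01-15 16:00:00", tz = "UTC"))
#' @export
solar_elevation <- function(lat, lon, instant) {
  stopifnot(all(lat >= -90 & lat <= 90), all(lon >= -180 & lon <= 180))
  if (!inherits(instant, "POSIXct")) {
    stop("`instant` must be POSIXct (UTC)")
  }
  d <- .j2000_days(instant)
  lw <- -lon * .deg2rad
  phi <- lat * .deg2rad
  s <- .sun_coords(d)
  H <- .sidereal_time(d, lw) - s$ra
  asin(sin(phi) * sin(s$dec) + cos(phi) * cos(s$dec) * cos(H)) * .rad2deg
}

#' Light-category levels
#'
#' @return Character vector of the four light categories, brightest first.
#' @export
light_levels <- function() c("day", "civil_twilight", "nautical_twilight", "night")

#' Classify solar elevation into light categories
#'
#' Day (> 0 deg), civil twilight (0 to -6), nautical twilight (-6 to -12),
#' night (below -12). A boundary elevation is assigned to the brighter class,
#' so 0 is day, -6 is civil and -12 is nautical twilight.
#'
#' @param elevation Solar elevation in degrees (vectorised).
#' @return Factor with levels `light_levels()`.
#' @export
classify_light <- function(elevation) {
  stopifnot(is.numeric(elevation), all(is.finite(elevation)))
  lv <- light_levels()
  idx <- ifelse(elevation >= 0, 1L,
         ifelse(elevation >= -6, 2L,
         ifelse(elevation >= -12, 3L, 4L)))
  factor(lv[idx], levels = lv)
}

.moon_coords <- function(d) {
  L <- (218.316 + 13.176396 * d) * .deg2rad # mean longitude
  M <- (134.963 + 13.064993 * d) * .deg2rad # mean anomaly
  F <- (93.272 + 13.229350 * d) * .deg2rad  # mean distance
  l <- L + 6.289 * .deg2rad * sin(M)
  b <- 5.128 * .deg2rad * sin(F)
  dt <- 385001 - 20905 * cos(M) # distance, km
  list(
    ra = atan2(sin(l) * cos(.obliquity) - tan(b) * sin(.obliquity), cos(l)),
    dec = asin(sin(b) * cos(.obliquity) + cos(b) * sin(.obliquity) * sin(l)),
    dist = dt
  )
}

#' Illuminated fraction of the moon
#'
#' Fraction of the lunar disc illuminated at 12:00 UTC on a date, from the
#' standard phase-angle approximation: 0 at new moon, 1 at full moon.
#'
#' @param date A `Date` (or something coercible); vectorised.
#' @return Numeric fraction in \[0, 1\].
#' @examples
#' moon_fraction(as.Date("2019-01-21")) # a full moon
#' @export
moon_fraction <- function(date) {
  date <- as.Date(date)
  instant <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC")
  d <- .j2000_days(instant)
  s <- .sun_coords(d)
  m <- .moon_coords(d)
  sdist <- 149598000 # earth-sun distance, km
  phi <- acos(sin(s$dec) * sin(m$dec) +
              cos(s$dec) * cos(m$dec) * cos(s$ra - m$ra))
  inc <- atan2(sdist * sin(phi), m$dist - sdist * cos(phi))
  (1 + cos(inc)) / 2
}

#' Mean daily position from dawn and dusk estimates
#'
#' Averages a dawn and a dusk geolocation estimate into the single daily
#' position used for light-category classification. Latitudes are averaged
#' arithmetically; longitudes are averaged on the circle so that positions
#' straddling the antimeridian behave correctly. If one estimate is missing
#' the other is returned and flagged; if both are missing the position is
#' missing.
#'
#' @param dawn,dusk Numeric length-2 vectors `c(lat, lon)`; `NULL` or a
#'   vector of `NA`s means that estimate is missing.
#' @return A list with `lat`, `lon` and `source` (one of
#'   `"mean_of_dawn_dusk"`, `"dawn_only"`, `"dusk_only"`, `"missing"`).
#' @export
mean_daily_position <- function(dawn, dusk) {
  ok <- function(p) !is.null(p) && length(p) == 2 && all(is.finite(p))
  has_dawn <- ok(dawn)
  has_dusk <- ok(dusk)
  if (!has_dawn && !has_dusk) {
    return(list(lat = NA_real_, lon = NA_real_, source = "missing"))
  }
  if (has_dawn && !has_dusk) {
    return(list(lat = dawn[1], lon = dawn[2], source = "dawn_only"))
  }
  if (!has_dawn && has_dusk) {
    return(list(lat = dusk[1], lon = dusk[2], source = "dusk_only"))
  }
  stopifnot(abs(dawn[1]) <= 90, abs(dusk[1]) <= 90)
  lons <- c(dawn[2], dusk[2]) * .deg2rad
  lon <- atan2(mean(sin(lons)), mean(cos(lons))) * .rad2deg
  list(lat = mean(c(dawn[1], dusk[1])), lon = lon, source = "mean_of_dawn_dusk")
}
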