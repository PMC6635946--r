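#' @name solar_time
#' @title Solar position and day/night classification
#'
#' @description Low-precision (NOAA/Meeus-class) solar ephemeris:
#' geometric solar elevation, dawn/dusk crossing times for a chosen
#' solar depression angle, and a total day/night classifier. Accuracy is
#' a few hundredths of a degree in elevation, well under a minute in
#' event times -- ample for diel classification of animal fixes.
NULL

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Julian ephemeris century from POSIXct (UTC)
julian_century <- function(t) {
  jd <- as.numeric(t) / 86400 + 2440587.5
  (jd - 2451545) / 36525
}

# declination (deg) and equation of time (minutes) at time t
solar_basis <- function(t) {
  T <- julian_century(t)
  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) +
    sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * T)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega)
  epsr <- deg2rad(eps)
  decl <- asin(sin(epsr) * sin(deg2rad(app_long)))
  y <- tan(epsr / 2)^2
  L0r <- deg2rad(L0)
  eot <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  )
  list(declination = decl, eot_minutes = eot)
}

#' Geometric solar elevation
#'
#' @param lat,lon Site latitude/longitude, decimal degrees (|lat| <= 90;
#'   east longitude positive).
#' @param t POSIXct instant(s), UTC.
#' @return Solar elevation above the horizon, degrees (no refraction).
#' @export
solar_elevation <- function(lat, lon, t) {
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90")
  b <- solar_basis(t)
  minutes_utc <- (as.numeric(t) %% 86400) / 60
  tst <- (minutes_utc + b$eot_minutes + 4 * lon) %% 1440
  ha <- deg2rad(tst / 4 - 180)
  latr <- deg2rad(lat)
  sinel <- sin(latr) * sin(b$declination) +
    cos(latr) * cos(b$declination) * cos(ha)
  rad2deg(asin(pmin(pmax(sinel, -1), 1)))
}

# start of the local solar day containing t: UTC midnight shifted by
# -lon/15 hours, chosen so local solar midnight falls near the window
# edges and dawn/dusk both lie inside one window
local_day_start <- function(t, lon) {
  shift <- lon / 15 * 3600
  tl <- as.numeric(t) + shift
  as.POSIXct(floor(tl / 86400) * 86400 - shift,
    origin = "1970-01-01", tz = "UTC"
  )
}

#' Dawn and dusk times for a local date
#'
#' Finds the instants at which the solar elevation crosses
#' `-depression_angle` within the local solar day containing `t`
#' (bracketing on a 10-minute grid, then root refinement to well under
#' 30 s). In polar no-event situations the polarity of the whole day is
#' returned instead.
#'
#' @inheritParams solar_elevation
#' @param t Any instant in the local date of interest (POSIXct, UTC).
#' @param depression_angle Solar depression defining dawn/dusk, degrees
#'   (>= 0; 6 = civil twilight).
#' @return List with `dawn`, `dusk` (POSIXct or NA) and `polarity`
#'   (`"events"`, `"always_day"` or `"always_night"`).
#' @export
crepuscule_times <- function(lat, lon, t, depression_angle = 6) {
  if (depression_angle < 0) stop("depression_angle must be >= 0")
  day0 <- local_day_start(t, lon)
  grid <- day0 + seq(0, 86400, by = 600)
  f <- solar_elevation(lat, lon, grid) + depression_angle
  if (all(f >= 0)) return(list(dawn = NA, dusk = NA, polarity = "always_day"))
  if (all(f < 0)) return(list(dawn = NA, dusk = NA, polarity = "always_night"))
  refine <- function(i) {
    r <- stats::uniroot(
      function(s) solar_elevation(lat, lon, day0 + s) + depression_angle,
      lower = as.numeric(difftime(grid[i], day0, units = "secs")),
      upper = as.numeric(difftime(grid[i + 1], day0, units = "secs")),
      tol = 1
    )
    day0 + r$root
  }
  ups <- which(f[-length(f)] < 0 & f[-1] >= 0)
  downs <- which(f[-length(f)] >= 0 & f[-1] < 0)
  dawn <- if (length(ups)) refine(ups[1]) else NA
  dusk <- if (length(downs)) refine(downs[length(downs)]) else NA
  list(dawn = dawn, dusk = dusk, polarity = "events")
}

#' Classify instants as day or night
#'
#' Day runs from dawn (inclusive) to dusk (exclusive) of the local solar
#' date containing each instant; everything else is night. Polar
#' no-event days classify as all-day or all-night. Total: every
#' timestamp receives a class.
#'
#' @inheritParams solar_elevation
#' @param t POSIXct vector, UTC.
#' @param depression_angle Degrees below the horizon defining dawn/dusk
#'   (default 6, civil twilight).
#' @return Character vector, `"day"` or `"night"`.
#' @export
classify_day_night <- function(t, lat, lon, depression_angle = 6) {
  t <- as.POSIXct(t, tz = "UTC")
  day0 <- local_day_start(t, lon)
  out <- character(length(t))
  for (d0 in unique(as.numeric(day0))) {
    sel <- which(as.numeric(day0) == d0)
    ct <- crepuscule_times(lat, lon, t[sel[1]], depression_angle)
    out[sel] <- if (ct$polarity == "always_day") {
      "day"
    } else if (ct$polarity == "always_night") {
      "night"
    } else if (is.na(ct$dawn[1]) || is.na(ct$dusk[1])) {
      # transition day at high latitude with a single crossing: fall
      # back to the instantaneous elevation
      ifelse(solar_elevation(lat, lon, t[sel]) >= -depression_angle,
        "day", "night"
      )
    } else {
      ifelse(t[sel] >= ct$dawn & t[sel] < ct$dusk, "day", "night")
    }
  }
  out
}
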