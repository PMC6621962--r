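#' Sunrise and sunset times
#'
#' Standard solar-geometry computation (equation of time, solar declination
#' and hour angle at the 90.833-degree refraction-corrected zenith),
#' accurate to a minute or two at mid-latitudes — ample for splitting
#' movement steps into day and night.
#'
#' @param dates `Date` vector.
#' @param lat latitude, decimal degrees.
#' @param lon longitude, decimal degrees, positive east.
#' @return list of POSIXct UTC vectors `sunrise`, `sunset`.
#' @export
sun_times <- function(dates, lat, lon) {
  doy <- as.integer(format(as.Date(dates), "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cosha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  cosha <- pmin(1, pmax(-1, cosha))
  ha_deg <- acos(cosha) * 180 / pi
  midnight <- as.POSIXct(paste(as.Date(dates), "00:00:00"), tz = "UTC")
  list(sunrise = midnight + 60 * (720 - 4 * (lon + ha_deg) - eqtime),
       sunset = midnight + 60 * (720 - 4 * (lon - ha_deg) - eqtime))
}
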