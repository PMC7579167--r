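#' Locate a timestamp on a GPS track
#'
#' Time is the common key joining sensors, positions and diary entries.
#' A query time coinciding with a fix returns that fix with confidence
#' `"exact"`; a time strictly between two fixes returns the linear
#' interpolation of longitude/latitude, with confidence `"interpolated"`
#' when the bracketing fixes are at most `max_gap_s` apart and `"low"` when
#' they are further apart (the interpolated value is still returned, but
#' flagged). Times outside the track span are not located: the record is
#' retained with confidence `"unlocatable"` and `NA` coordinates.
#'
#' Interpolation is performed in geographic coordinates, which is adequate
#' at walking-scale fix spacings; residual GPS uncertainty is surfaced via
#' the confidence flag rather than corrected.
#'
#' @param time Query time(s), `POSIXct` or numeric UNIX seconds.
#' @param track A [geo_track] (>= 2 fixes, strictly increasing times).
#' @param max_gap_s Largest fix spacing still considered reliable, seconds.
#' @return A data frame with columns `lon`, `lat`, `confidence`.
#' @export
locate <- function(time, track, max_gap_s = 10) {
  stopifnot(inherits(track, "geo_track"))
  tt <- as.numeric(track$time)
  if (any(diff(tt) <= 0)) {
    stop("track times must be strictly increasing", call. = FALSE)
  }
  q <- as.numeric(time)
  n <- length(q)
  lon <- rep(NA_real_, n); lat <- rep(NA_real_, n)
  conf <- rep("unlocatable", n)
  inside <- q >= tt[1] & q <= tt[length(tt)]
  if (any(inside)) {
    qi <- q[inside]
    il <- findInterval(qi, tt)
    exact <- qi == tt[il]
    lon_i <- lat_i <- numeric(length(qi))
    conf_i <- character(length(qi))
    lon_i[exact] <- track$lon[il[exact]]
    lat_i[exact] <- track$lat[il[exact]]
    conf_i[exact] <- "exact"
    if (any(!exact)) {
      j <- il[!exact]
      frac <- (qi[!exact] - tt[j]) / (tt[j + 1] - tt[j])
      lon_i[!exact] <- track$lon[j] + frac * (track$lon[j + 1] - track$lon[j])
      lat_i[!exact] <- track$lat[j] + frac * (track$lat[j + 1] - track$lat[j])
      conf_i[!exact] <- ifelse(tt[j + 1] - tt[j] <= max_gap_s,
                               "interpolated", "low")
    }
    lon[inside] <- lon_i; lat[inside] <- lat_i; conf[inside] <- conf_i
  }
  data.frame(lon = lon, lat = lat, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Georeference detected events against a GPS track
#'
#' Fills the `lon`, `lat` and `georef_confidence` columns of a `mos_events`
#' data frame by [locate()]-ing each onset time. Events outside the track
#' span are retained, flagged `"unlocatable"`.
#'
#' @param events A `mos_events` data frame.
#' @param track A [geo_track].
#' @param max_gap_s Passed to [locate()].
#' @return The events with location columns filled.
#' @export
georeference_events <- function(events, track, max_gap_s = 10) {
  if (nrow(events) == 0L) return(events)
  loc <- locate(events$onset_time, track, max_gap_s)
  events$lon <- loc$lon
  events$lat <- loc$lat
  events$georef_confidence <- loc$confidence
  events
}

#' Georeference diary entries lacking coordinates
#'
#' Entries flagged `needs_georef` are located by timestamp against the
#' participant's track; entries that already carry coordinates are left
#' untouched.
#'
#' @param diary A `diary_entries` data frame.
#' @param track A [geo_track].
#' @param max_gap_s Passed to [locate()].
#' @return The diary with coordinates filled where resolvable and a
#'   `georef_confidence` column.
#' @export
georeference_diary <- function(diary, track, max_gap_s = 10) {
  if (!"georef_confidence" %in% names(diary)) {
    diary$georef_confidence <- ifelse(diary$needs_georef, NA_character_,
                                      "reported")
  }
  todo <- which(diary$needs_georef)
  if (length(todo) > 0) {
    loc <- locate(diary$time[todo], track, max_gap_s)
    diary$lon[todo] <- loc$lon
    diary$lat[todo] <- loc$lat
    diary$georef_confidence[todo] <- loc$confidence
    diary$needs_georef[todo] <- is.na(loc$lon)
  }
  diary
}
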