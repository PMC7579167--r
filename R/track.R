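#' Construct a GPS track
#'
#' A `geo_track` is a sequence of timestamped WGS84 fixes for one participant
#' session. Timestamps must be strictly increasing after construction
#' (duplicate-time fixes are collapsed to the last occurrence, with a
#' warning) and at least 2 fixes are required for time interpolation.
#'
#' @param participant_id Identifier.
#' @param time `POSIXct` (UTC) or numeric UNIX seconds.
#' @param lon,lat Coordinates in degrees; `lon` in \[-180, 180\], `lat` in
#'   \[-90, 90\].
#' @param accuracy_m Optional horizontal accuracy per fix, metres.
#' @return An object of class `geo_track`.
#' @export
geo_track <- function(participant_id, time, lon, lat, accuracy_m = NULL) {
  if (is.numeric(time)) {
    time <- as.POSIXct(time, origin = "1970-01-01", tz = "UTC")
  }
  attr(time, "tzone") <- "UTC"
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  n <- length(time)
  if (length(lon) != n || length(lat) != n) {
    stop("time, lon and lat must have equal length", call. = FALSE)
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of range: need lat in [-90,90], lon in [-180,180]",
         call. = FALSE)
  }
  if (is.null(accuracy_m)) accuracy_m <- rep(NA_real_, n)
  o <- order(as.numeric(time))
  time <- time[o]; lon <- lon[o]; lat <- lat[o]; accuracy_m <- accuracy_m[o]
  dup <- duplicated(as.numeric(time), fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicate-time fix(es) collapsed to last occurrence",
                    sum(dup)), call. = FALSE)
    time <- time[!dup]; lon <- lon[!dup]; lat <- lat[!dup]
    accuracy_m <- accuracy_m[!dup]
  }
  if (length(time) < 2L) {
    stop("a usable track needs at least 2 distinct-time fixes",
         call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         time = time, lon = lon, lat = lat, accuracy_m = accuracy_m),
    class = "geo_track"
  )
}

#' @export
print.geo_track <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<geo_track> participant %s: %d fixes, %s .. %s UTC\n",
              x$participant_id, n,
              format(x$time[1], "%H:%M:%S"),
              format(x$time[n], "%H:%M:%S")))
  invisible(x)
}

read_track_gpx <- function(path, participant_id) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) pts <- xml2::xml_find_all(doc, ".//wpt")
  if (length(pts) == 0) stop(sprintf("no trackpoints in '%s'", path),
                             call. = FALSE)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tnodes <- lapply(pts, function(p) xml2::xml_find_first(p, "./time"))
  tstr <- vapply(tnodes, function(n) {
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
  }, character(1))
  if (all(is.na(tstr))) {
    stop(sprintf("track '%s' carries no time information; cannot be used for georeferencing",
                 path), call. = FALSE)
  }
  keep <- !is.na(tstr)
  time <- as.POSIXct(tstr[keep], tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                    "%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS"))
  geo_track(participant_id, time, lon[keep], lat[keep])
}

read_track_geojson <- function(path, participant_id) {
  gj <- jsonlite::read_json(path)
  coords <- NULL; times <- NULL
  grab_feature <- function(feat) {
    geom <- feat$geometry
    if (is.null(geom)) return(NULL)
    if (geom$type %in% c("LineString", "MultiPoint")) {
      tprop <- feat$properties$times
      if (is.null(tprop)) tprop <- feat$properties$coordTimes
      if (is.null(tprop)) return(NULL)
      list(coords = geom$coordinates, times = tprop)
    } else if (geom$type == "Point") {
      tprop <- feat$properties$time
      if (is.null(tprop)) return(NULL)
      list(coords = list(geom$coordinates), times = list(tprop))
    } else NULL
  }
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop(sprintf("'%s' is not a GeoJSON Feature/FeatureCollection",
                             path), call. = FALSE)
  for (f in feats) {
    g <- grab_feature(f)
    if (!is.null(g)) {
      coords <- c(coords, g$coords)
      times <- c(times, g$times)
    }
  }
  if (is.null(coords) || length(coords) == 0) {
    stop(sprintf("track '%s' carries no time information; cannot be used for georeferencing",
                 path), call. = FALSE)
  }
  lon <- vapply(coords, function(c) as.numeric(c[[1]]), numeric(1))
  lat <- vapply(coords, function(c) as.numeric(c[[2]]), numeric(1))
  tvals <- unlist(times, use.names = FALSE)
  time <- if (is.numeric(tvals)) {
    as.POSIXct(tvals, origin = "1970-01-01", tz = "UTC")
  } else {
    as.POSIXct(tvals, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                              "%Y-%m-%d %H:%M:%OS"))
  }
  geo_track(participant_id, time, lon, lat)
}

#' Read a GPS track (GPX 1.1 or GeoJSON)
#'
#' GPX trackpoints must carry `<time>` elements; GeoJSON tracks are read
#' from a `LineString`/`MultiPoint` feature with a per-point `times`
#' property (RFC 7946 coordinates, lon first) or a FeatureCollection of
#' `Point` features each with a `time` property. Tracks without time
#' information are rejected, since time is the key joining physiological,
#' positional and diary data.
#'
#' @param path Path to a `.gpx` or `.geojson`/`.json` file.
#' @param participant_id Identifier (default: file stem).
#' @return A [geo_track].
#' @export
read_track <- function(path, participant_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]+$", "", basename(path))
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "gpx") read_track_gpx(path, participant_id)
  else read_track_geojson(path, participant_id)
}

#' Write a GPS track as GPX 1.1
#'
#' @param track A [geo_track].
#' @param path Output `.gpx` path.
#' @return Invisibly, `path`.
#' @export
write_track_gpx <- function(track, path) {
  stopifnot(inherits(track, "geo_track"))
  tstr <- format(track$time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  pts <- sprintf('      <trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
                 track$lat, track$lon, tstr)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="stressmapr" xmlns="http://www.topografix.com/GPX/1/1">',
    "  <trk>",
    sprintf("    <name>%s</name>", track$participant_id),
    "    <trkseg>",
    pts,
    "    </trkseg>",
    "  </trk>",
    "</gpx>"), path)
  invisible(path)
}
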