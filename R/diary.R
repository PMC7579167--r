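#' Closed eDiary vocabularies
#'
#' Emotion qualities and trigger categories the diary app offers; entries
#' outside these vocabularies are validation errors, not coerced.
#'
#' @format Character vectors.
#' @name diary_vocab
NULL

#' @rdname diary_vocab
#' @export
diary_emotions <- c("happiness", "anger/disgust", "sadness", "fear")

#' @rdname diary_vocab
#' @export
diary_triggers <- c("cars", "bicycles", "green space", "people", "sights",
                    "cityscape", "weather", "intersections")

#' Valence of a diary emotion
#'
#' Maps each emotion quality to `"positive"` (happiness) or `"negative"`
#' (anger/disgust, sadness, fear), the partition used when fusing diary
#' entries with sensor-derived stress rates.
#'
#' @param emotion Character vector drawn from [diary_emotions].
#' @return Character vector `"positive"`/`"negative"`.
#' @export
diary_valence <- function(emotion) {
  ifelse(emotion == "happiness", "positive", "negative")
}

validate_diary <- function(df, intensity_scale, path) {
  bad_e <- setdiff(unique(df$emotion), diary_emotions)
  if (length(bad_e) > 0) {
    stop(sprintf("unknown emotion label(s) in '%s': %s (allowed: %s)",
                 path, paste(sQuote(bad_e), collapse = ", "),
                 paste(diary_emotions, collapse = ", ")), call. = FALSE)
  }
  bad_t <- setdiff(unique(df$trigger), diary_triggers)
  if (length(bad_t) > 0) {
    stop(sprintf("unknown trigger label(s) in '%s': %s (allowed: %s)",
                 path, paste(sQuote(bad_t), collapse = ", "),
                 paste(diary_triggers, collapse = ", ")), call. = FALSE)
  }
  it <- df$intensity
  if (any(!is.na(it) & (it < intensity_scale[1] | it > intensity_scale[2]))) {
    stop(sprintf("diary intensity outside declared scale [%g, %g] in '%s'",
                 intensity_scale[1], intensity_scale[2], path),
         call. = FALSE)
  }
  df
}

#' Read eDiary entries (CSV or GeoJSON)
#'
#' Each entry records the quality of the perceived emotion, its trigger
#' category, and an ordinal intensity, with a timestamp and (optionally) a
#' location. CSV columns: `participant_id`, `timestamp` (UNIX seconds or
#' ISO-8601 UTC), `lon`, `lat` (may be empty), `emotion`, `trigger`,
#' `intensity`. GeoJSON: a FeatureCollection of Points whose properties
#' carry the same fields. Entries without coordinates are flagged
#' `needs_georef` and can be located later via [georeference_diary()].
#'
#' @param path Input file.
#' @param intensity_scale Length-2 numeric, inclusive ordinal scale bounds
#'   (default `c(1, 5)`).
#' @return A data frame of class `diary_entries` with columns
#'   `participant_id`, `time` (`POSIXct` UTC), `lon`, `lat`, `emotion`,
#'   `trigger`, `intensity`, `needs_georef`.
#' @export
read_diary <- function(path, intensity_scale = c(1, 5)) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("geojson", "json")) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (is.null(feats)) stop(sprintf("'%s' is not a GeoJSON FeatureCollection",
                                     path), call. = FALSE)
    rows <- lapply(feats, function(f) {
      p <- f$properties
      co <- f$geometry$coordinates
      data.frame(
        participant_id = as.character(p$participant_id %||% NA_character_),
        timestamp = as.character(p$time %||% p$timestamp %||% NA_character_),
        lon = if (is.null(co)) NA_real_ else as.numeric(co[[1]]),
        lat = if (is.null(co)) NA_real_ else as.numeric(co[[2]]),
        emotion = as.character(p$emotion %||% NA_character_),
        trigger = as.character(p$trigger %||% NA_character_),
        intensity = as.numeric(p$intensity %||% NA_real_),
        stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("participant_id", "timestamp", "emotion", "trigger",
              "intensity")
    if (!all(need %in% names(df))) {
      stop(sprintf("diary CSV needs columns %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    if (!"lon" %in% names(df)) df$lon <- NA_real_
    if (!"lat" %in% names(df)) df$lat <- NA_real_
  }
  ts <- df$timestamp
  tsn <- suppressWarnings(as.numeric(ts))
  time <- if (all(!is.na(tsn))) {
    as.POSIXct(tsn, origin = "1970-01-01", tz = "UTC")
  } else {
    as.POSIXct(as.character(ts), tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                              "%Y-%m-%d %H:%M:%OS"))
  }
  out <- data.frame(
    participant_id = as.character(df$participant_id),
    time = time,
    lon = suppressWarnings(as.numeric(df$lon)),
    lat = suppressWarnings(as.numeric(df$lat)),
    emotion = as.character(df$emotion),
    trigger = as.character(df$trigger),
    intensity = suppressWarnings(as.numeric(df$intensity)),
    stringsAsFactors = FALSE)
  out$needs_georef <- is.na(out$lon) | is.na(out$lat)
  out <- validate_diary(out, intensity_scale, path)
  class(out) <- c("diary_entries", "data.frame")
  out
}

#' Write eDiary entries as CSV
#'
#' @param diary A `diary_entries` data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_diary <- function(diary, path) {
  df <- as.data.frame(diary)
  df$timestamp <- sprintf("%.3f", as.numeric(df$time))
  df <- df[, c("participant_id", "timestamp", "lon", "lat", "emotion",
               "trigger", "intensity")]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
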