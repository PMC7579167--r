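#' Moment-of-stress rule configuration
#'
#' The detector fires at an onset time t when three clauses hold on the
#' filtered signals:
#' \enumerate{
#'   \item the phasic GSR is near-monotonically non-decreasing over
#'     \[t, t + `gsr_rise_window_s`\] (each step may dip at most
#'     `monotonicity_tolerance_us`) with a strictly positive net change;
#'   \item the rise is steep enough: the slope angle
#'     `atan((dGSR/dt) / slope_scale_us_per_s) * 180/pi` over the window is
#'     at least `min_slope_deg` (an angle of a uS-versus-seconds line is
#'     scale dependent, so the axis scale is an explicit knob; by default
#'     1 uS per second maps to 45 degrees);
#'   \item skin temperature responds with the characteristic delayed drop:
#'     within \[t + `st_lag_s`, t + `st_lag_s` + `st_search_window_s`\] the
#'     smoothed ST contains a local maximum followed by a local minimum
#'     whose drop is at least `st_min_drop_degc` (0 = any strict decrease).
#' }
#' A single physiological event satisfies the sliding rule at many adjacent
#' onsets, so firings closer than `merge_refractory_s` are merged into one
#' event keeping the earliest onset and the steepest slope.
#'
#' @param gsr_rise_window_s GSR rise window, seconds (default 5).
#' @param st_lag_s Lag between GSR onset and the start of the ST search
#'   window, seconds (default 3).
#' @param min_slope_deg Minimum GSR slope angle, degrees (default 10).
#' @param st_search_window_s Length of the ST search window after the lag,
#'   seconds (default 10).
#' @param monotonicity_tolerance_us Per-step dip tolerated in the rise, uS.
#' @param st_min_drop_degc Minimum ST max-to-min drop, degrees C.
#' @param merge_refractory_s Firings closer than this are one event, s.
#' @param slope_scale_us_per_s Axis scale defining the slope angle.
#' @return An object of class `mos_rule_config`.
#' @export
mos_rule_config <- function(gsr_rise_window_s = 5,
                            st_lag_s = 3,
                            min_slope_deg = 10,
                            st_search_window_s = 10,
                            monotonicity_tolerance_us = 0.005,
                            st_min_drop_degc = 0,
                            merge_refractory_s = 5,
                            slope_scale_us_per_s = 1) {
  stopifnot(gsr_rise_window_s > 0, st_lag_s > 0, st_search_window_s > 0,
            merge_refractory_s > 0, slope_scale_us_per_s > 0,
            min_slope_deg >= 0, min_slope_deg < 90,
            monotonicity_tolerance_us >= 0, st_min_drop_degc >= 0)
  structure(as.list(environment()), class = "mos_rule_config")
}

# Local extrema of a series with deterministic plateau handling: interior
# extrema are sign changes of the first difference (zero-runs skipped, so a
# plateau resolves to its earliest sample). Boundary convention: a leading
# plateau followed by a decrease counts as a maximum at the first sample,
# and a trailing decrease counts its end as a minimum.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(max = integer(0), min = integer(0)))
  d <- sign(diff(x))
  nz <- which(d != 0)
  mx <- integer(0); mn <- integer(0)
  if (length(nz) == 0L) return(list(max = mx, min = mn))
  s <- d[nz]
  if (s[1] < 0) mx <- c(mx, 1L)
  if (length(nz) >= 2L) {
    ch <- which(s[-length(s)] != s[-1])
    for (k in ch) {
      pos <- nz[k] + 1L
      if (s[k] > 0) mx <- c(mx, pos) else mn <- c(mn, pos)
    }
  }
  if (s[length(s)] < 0) mn <- c(mn, nz[length(nz)] + 1L)
  list(max = sort(mx), min = sort(mn))
}

# Validated (max, next-min) pairs within a window: for each local maximum,
# the next local minimum after it, kept if the drop clears min_drop (or any
# strict decrease when min_drop == 0; strictness is guaranteed by
# construction of the extrema).
st_drop_pairs <- function(st, min_drop) {
  ex <- local_extrema(st)
  if (length(ex$max) == 0L || length(ex$min) == 0L) {
    return(data.frame(max_i = integer(0), min_i = integer(0),
                      drop = numeric(0)))
  }
  nxt <- findInterval(ex$max, ex$min) + 1L
  ok <- nxt <= length(ex$min)
  max_i <- ex$max[ok]
  min_i <- ex$min[nxt[ok]]
  drop <- st[max_i] - st[min_i]
  keep <- drop >= min_drop & drop > 0
  data.frame(max_i = max_i[keep], min_i = min_i[keep], drop = drop[keep])
}

detect_mos_segment <- function(g, s, fs, cfg, seg_offset, start_time,
                               participant_id) {
  n <- length(g)
  W <- round(cfg$gsr_rise_window_s * fs)
  L <- round(cfg$st_lag_s * fs)
  S <- round(cfg$st_search_window_s * fs)
  last_onset <- n - max(W, L + S)
  if (last_onset < 1L) return(NULL)

  d <- diff(g)
  bad <- as.numeric(d < -cfg$monotonicity_tolerance_us)
  csb <- c(0, cumsum(bad))
  i <- seq_len(last_onset)
  mono <- (csb[i + W] - csb[i]) == 0
  net <- g[i + W] - g[i]
  slope_deg <- atan((net / (W / fs)) / cfg$slope_scale_us_per_s) * 180 / pi
  gsr_ok <- mono & net > 0 & slope_deg >= cfg$min_slope_deg

  # ST clause, evaluated on the per-onset search window [i+L, i+L+S]
  # (only where the GSR clauses already hold): the window must contain a
  # local maximum followed by a local minimum with a sufficient drop.
  cand_i <- which(gsr_ok)
  if (length(cand_i) == 0L) return(NULL)
  st_pair <- matrix(NA_integer_, nrow = length(cand_i), ncol = 2L)
  st_ok <- logical(length(cand_i))
  for (j in seq_along(cand_i)) {
    a <- cand_i[j] + L
    win <- s[a:(a + S)]
    pairs <- st_drop_pairs(win, cfg$st_min_drop_degc)
    if (nrow(pairs) > 0) {
      st_ok[j] <- TRUE
      st_pair[j, ] <- c(a + pairs$max_i[1] - 1L, a + pairs$min_i[1] - 1L)
    }
  }
  fire <- cand_i[st_ok]
  if (length(fire) == 0L) return(NULL)
  st_pair <- st_pair[st_ok, , drop = FALSE]

  # merge firings closer than the refractory window
  gap <- diff(fire) / fs
  cluster <- cumsum(c(1, as.numeric(gap >= cfg$merge_refractory_s)))
  # time of segment-local 1-based sample index
  t_of <- function(k) start_time + (seg_offset + k - 2L) / fs
  out <- lapply(split(seq_along(fire), cluster), function(jj) {
    idx <- fire[jj]
    onset <- idx[1]
    best <- idx[which.max(slope_deg[idx])]
    data.frame(
      participant_id = participant_id,
      onset_time = t_of(onset),
      window_end_time = t_of(onset + W),
      gsr_slope_deg = slope_deg[best],
      gsr_delta_us = net[best],
      st_max_time = t_of(st_pair[jj[1], 1]),
      st_min_time = t_of(st_pair[jj[1], 2]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect moments of stress
#'
#' Runs the rule-based stress template over a filtered trace: a sustained
#' (>= 5 s by default) phasic GSR increase with slope angle >= 10 degrees,
#' followed after a 3 s lag by a skin-temperature local maximum and
#' subsequent local minimum. See [mos_rule_config()] for the clause
#' definitions and knobs. Segments split by long measurement gaps are
#' scanned independently, so the template never straddles unmeasured spans.
#'
#' @param trace A `filtered_trace` from [preprocess_trace()]; passing an
#'   unfiltered trace is a contract error.
#' @param cfg A [mos_rule_config].
#' @return A data frame of class `mos_events`, sorted by onset time, with
#'   columns `participant_id`, `onset_time`, `window_end_time`,
#'   `gsr_slope_deg`, `gsr_delta_us`, `st_max_time`, `st_min_time`, plus
#'   location columns (`lon`, `lat`, `georef_confidence`) filled by
#'   [georeference_events()].
#' @export
detect_mos <- function(trace, cfg = mos_rule_config()) {
  if (!inherits(trace, "filtered_trace")) {
    stop("detect_mos() requires a filtered trace; run preprocess_trace() first",
         call. = FALSE)
  }
  min_dur <- cfg$gsr_rise_window_s + cfg$st_lag_s + cfg$st_search_window_s
  n <- length(trace$gsr_phasic)
  if (n / trace$fs < min_dur) {
    stop(sprintf("trace too short for the rule template: %.1f s < %.1f s",
                 n / trace$fs, min_dur), call. = FALSE)
  }
  res <- lapply(trace$segments, function(seg) {
    idx <- seg[1]:seg[2]
    g <- trace$gsr_phasic[idx]
    if (anyNA(g)) return(NULL)
    detect_mos_segment(g, trace$st_smooth[idx], trace$fs, cfg,
                       seg_offset = seg[1], start_time = trace$start_time,
                       participant_id = trace$participant_id)
  })
  ev <- do.call(rbind, res)
  if (is.null(ev)) {
    ev <- data.frame(participant_id = character(0),
                     onset_time = as.POSIXct(character(0), tz = "UTC"),
                     window_end_time = as.POSIXct(character(0), tz = "UTC"),
                     gsr_slope_deg = numeric(0), gsr_delta_us = numeric(0),
                     st_max_time = as.POSIXct(character(0), tz = "UTC"),
                     st_min_time = as.POSIXct(character(0), tz = "UTC"),
                     stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$onset_time), , drop = FALSE]
  rownames(ev) <- NULL
  ev$lon <- rep(NA_real_, nrow(ev))
  ev$lat <- rep(NA_real_, nrow(ev))
  ev$georef_confidence <- rep(NA_character_, nrow(ev))
  class(ev) <- c("mos_events", "data.frame")
  ev
}

#' Score detections against annotated ground truth
#'
#' Greedy one-to-one matching: candidate (event, truth) pairs are ranked by
#' absolute onset difference, and pairs within `match_tol_s` are accepted in
#' order, each event and truth onset matched at most once.
#'
#' @param events A `mos_events` data frame (or vector of onset times).
#' @param truth Vector of true onset times (`POSIXct` or numeric seconds),
#'   sorted.
#' @param match_tol_s Matching tolerance, seconds (default 5).
#' @return List with `precision`, `recall`, `n_matched`, `n_events`,
#'   `n_truth`. With zero detected events precision is reported as 1 (no
#'   false positives); with empty truth recall is 1.
#' @export
evaluate_detection <- function(events, truth, match_tol_s = 5) {
  et <- if (is.data.frame(events)) as.numeric(events$onset_time)
        else as.numeric(events)
  tt <- as.numeric(truth)
  nE <- length(et); nT <- length(tt)
  if (nE == 0L || nT == 0L) {
    return(list(precision = 1, recall = if (nT == 0L) 1 else 0,
                n_matched = 0L, n_events = nE, n_truth = nT))
  }
  dt <- abs(outer(et, tt, "-"))
  cand <- which(dt <= match_tol_s, arr.ind = TRUE)
  matched <- 0L
  if (nrow(cand) > 0) {
    cand <- cand[order(dt[cand]), , drop = FALSE]
    used_e <- logical(nE); used_t <- logical(nT)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_e[i] && !used_t[j]) {
        used_e[i] <- TRUE; used_t[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(precision = matched / nE, recall = matched / nT,
       n_matched = matched, n_events = nE, n_truth = nT)
}

#' Write detected events as CSV
#'
#' @param events A `mos_events` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_csv <- function(events, path) {
  df <- as.data.frame(events)
  for (col in c("onset_time", "window_end_time", "st_max_time",
                "st_min_time")) {
    df[[col]] <- sprintf("%.3f", as.numeric(df[[col]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write detected events as GeoJSON points
#'
#' Unlocated events (no coordinates) are omitted from the geometry layer
#' with a warning.
#'
#' @param events A `mos_events` data frame, georeferenced.
#' @param path Output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_events_geojson <- function(events, path) {
  df <- as.data.frame(events)
  loc <- !is.na(df$lon) & !is.na(df$lat)
  if (any(!loc)) {
    warning(sprintf("%d unlocated event(s) omitted from GeoJSON output",
                    sum(!loc)), call. = FALSE)
  }
  df <- df[loc, , drop = FALSE]
  feats <- lapply(seq_len(nrow(df)), function(r) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[r], df$lat[r])),
         properties = list(
           participant_id = df$participant_id[r],
           onset_time = format(df$onset_time[r], "%Y-%m-%dT%H:%M:%OS3Z",
                               tz = "UTC"),
           gsr_slope_deg = df$gsr_slope_deg[r],
           gsr_delta_us = df$gsr_delta_us[r],
           georef_confidence = df$georef_confidence[r]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
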