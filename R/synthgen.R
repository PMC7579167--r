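#' Synthetic campaign scenario configuration
#'
#' Describes a walking field campaign to simulate: participants walk a
#' route past stressor sites (e.g. busy intersections); each passage may
#' plant a stress response in the physiological signals and may prompt a
#' negative-valence diary entry. The planted GSR response is a linear rise
#' over `rise_duration_s` followed by an exponential decay
#' (`decay_tau_s`); skin temperature plateaus, then drops linearly by
#' `st_drop_degc` starting `st_lag_s` after onset and recovers. With the
#' default amplitude (1.5 uS over 5 s, a 16.7 degree slope at the default
#' axis scale) every planted event clears the 10 degree rule threshold
#' with a wide margin. Gaussian white noise is added to both channels
#' before filtering, so the preprocessing low-pass is exercised
#' meaningfully.
#'
#' @param seed RNG seed; identical seeds give byte-identical campaigns.
#' @param n_participants Number of participants.
#' @param walk_duration_s Walk length in seconds.
#' @param walk_speed_mps Walking speed, m/s.
#' @param route Optional polyline (2-column lon/lat matrix). Default: a
#'   rectangular loop around `base_lonlat` long enough for the walk (a
#'   shorter explicit route is a configuration error).
#' @param base_lonlat Campaign area centre (default: Salzburg old town).
#' @param n_stressors Number of auto-placed stressor sites (used when
#'   `stressor_sites` is `NULL`); sites are spread evenly along the route.
#' @param stressor_sites Optional data frame `lon`, `lat`, `radius_m`,
#'   `event_probability`.
#' @param event_probability Per-passage probability of planting an event
#'   (for auto-placed sites).
#' @param fs Sampling frequency of the physiological channels, Hz.
#' @param gps_interval_s GPS fix interval, seconds.
#' @param baseline_gsr_us,gsr_noise_sd_us Tonic conductance level and
#'   white-noise SD, uS.
#' @param baseline_st_degc,st_noise_sd_degc Skin temperature baseline and
#'   noise SD, degrees C.
#' @param rise_duration_s,rise_amplitude_us,decay_tau_s GSR event template.
#' @param st_lag_s,st_drop_degc,st_drop_duration_s,st_recovery_s ST event
#'   template.
#' @param diary_report_probability Probability a passage yields a diary
#'   entry.
#' @param reduction_factor Planted-event thinning for pre-post scenarios:
#'   the number of planted events is `round(reduction_factor * n_fired)`,
#'   thinned deterministically in count so that annotation rate ratios are
#'   exact by construction.
#' @param start_time Campaign start (`POSIXct` UTC).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            n_participants = 1,
                            walk_duration_s = 1800,
                            walk_speed_mps = 1.4,
                            route = NULL,
                            base_lonlat = c(13.043, 47.800),
                            n_stressors = 8,
                            stressor_sites = NULL,
                            event_probability = 0.9,
                            fs = 4,
                            gps_interval_s = 1,
                            baseline_gsr_us = 2,
                            gsr_noise_sd_us = 0.05,
                            baseline_st_degc = 33,
                            st_noise_sd_degc = 0.02,
                            rise_duration_s = 5,
                            rise_amplitude_us = 1.5,
                            decay_tau_s = 4,
                            st_lag_s = 3,
                            st_drop_degc = 0.3,
                            st_drop_duration_s = 5,
                            st_recovery_s = 10,
                            diary_report_probability = 0.5,
                            reduction_factor = 1,
                            start_time = as.POSIXct("2018-09-05 09:00:00",
                                                    tz = "UTC")) {
  stopifnot(event_probability >= 0, event_probability <= 1,
            diary_report_probability >= 0, diary_report_probability <= 1,
            reduction_factor >= 0, reduction_factor <= 1,
            walk_duration_s > 0, walk_speed_mps > 0, fs > 0)
  slope_deg <- atan(rise_amplitude_us / rise_duration_s) * 180 / pi
  if (slope_deg < 10) {
    stop(sprintf("planted GSR slope %.1f deg does not clear the 10 deg rule threshold; raise rise_amplitude_us",
                 slope_deg), call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_config")
}

# metres per degree at a reference latitude (local equirectangular scale,
# used only to lay out synthetic routes)
.deg_scale <- function(lat) {
  list(mlat = 111132.954 - 559.822 * cos(2 * lat * pi / 180) +
         1.175 * cos(4 * lat * pi / 180),
       mlon = 111412.84 * cos(lat * pi / 180) -
         93.5 * cos(3 * lat * pi / 180))
}

default_route <- function(cfg) {
  need_m <- cfg$walk_duration_s * cfg$walk_speed_mps
  half <- need_m / 8 + 20   # rectangle perimeter 8*half >= need + margin
  sc <- .deg_scale(cfg$base_lonlat[2])
  dx <- half / sc$mlon
  dy <- half / sc$mlat
  lon0 <- cfg$base_lonlat[1]; lat0 <- cfg$base_lonlat[2]
  cbind(lon = c(lon0 - dx, lon0 + dx, lon0 + dx, lon0 - dx, lon0 - dx),
        lat = c(lat0 - dy, lat0 - dy, lat0 + dy, lat0 + dy, lat0 - dy))
}

# position along a polyline at given travelled distances (metres)
route_position <- function(route, dist_m) {
  sc <- .deg_scale(mean(route[, 2]))
  seg_dx <- diff(route[, 1]) * sc$mlon
  seg_dy <- diff(route[, 2]) * sc$mlat
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  if (any(dist_m > total + 1e-9)) {
    stop(sprintf("route too short: %.0f m of walking requested on a %.0f m route",
                 max(dist_m), total), call. = FALSE)
  }
  d <- pmin(dist_m, total)
  i <- pmax(findInterval(d, cum, rightmost.closed = TRUE), 1L)
  frac <- (d - cum[i]) / seg_len[i]
  cbind(lon = route[i, 1] + frac * diff(route[, 1])[i],
        lat = route[i, 2] + frac * diff(route[, 2])[i])
}

route_length <- function(route) {
  sc <- .deg_scale(mean(route[, 2]))
  sum(sqrt((diff(route[, 1]) * sc$mlon)^2 + (diff(route[, 2]) * sc$mlat)^2))
}

#' Generate a synthetic walking campaign
#'
#' Simulates every data stream the pipeline ingests — physiological traces
#' with planted, annotated stress responses, GPS tracks, and probabilistic
#' diary entries — for `n_participants` walking the configured route. Each
#' planted event is annotated with its true onset time and stressor site,
#' making the full detection/georeferencing/mapping chain testable against
#' ground truth without field data.
#'
#' @param cfg A [scenario_config].
#' @return An object of class `campaign`: a list with `cfg` and
#'   `participants`, each participant a list of `physio` ([physio_trace]),
#'   `track` ([geo_track]), `diary` (diary entries) and `truth` (data frame
#'   of planted onsets and site ids).
#' @export
generate_campaign <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  route <- if (is.null(cfg$route)) default_route(cfg) else as.matrix(cfg$route)
  total_len <- route_length(route)
  walk_len <- cfg$walk_duration_s * cfg$walk_speed_mps
  if (walk_len > total_len + 1e-9) {
    stop(sprintf("route too short: walk needs %.0f m but route is %.0f m",
                 walk_len, total_len), call. = FALSE)
  }
  sites <- cfg$stressor_sites
  if (is.null(sites)) {
    # spread sites evenly along the walked stretch, away from the ends
    pass_t <- seq(60, cfg$walk_duration_s - 60,
                  length.out = cfg$n_stressors)
    pos <- route_position(route, pass_t * cfg$walk_speed_mps)
    sites <- data.frame(site_id = seq_len(cfg$n_stressors),
                        lon = pos[, 1], lat = pos[, 2], radius_m = 10,
                        event_probability = cfg$event_probability)
  } else {
    sites <- as.data.frame(sites)
    if (!"site_id" %in% names(sites)) sites$site_id <- seq_len(nrow(sites))
    if (!"radius_m" %in% names(sites)) sites$radius_m <- 10
    if (!"event_probability" %in% names(sites)) {
      sites$event_probability <- cfg$event_probability
    }
  }
  n_samp <- round(cfg$walk_duration_s * cfg$fs) + 1L
  t_rel <- (seq_len(n_samp) - 1L) / cfg$fs
  gps_t <- seq(0, cfg$walk_duration_s, by = cfg$gps_interval_s)
  sc <- .deg_scale(mean(route[, 2]))

  participants <- lapply(seq_len(cfg$n_participants), function(p) {
    pid <- sprintf("P%02d", p)
    p_start <- cfg$start_time + (p - 1) * (cfg$walk_duration_s + 120)
    pos <- route_position(route, pmin(gps_t * cfg$walk_speed_mps,
                                      total_len))
    # first-entry passage time at each site
    pass <- vapply(seq_len(nrow(sites)), function(k) {
      dx <- (pos[, 1] - sites$lon[k]) * sc$mlon
      dy <- (pos[, 2] - sites$lat[k]) * sc$mlat
      hit <- which(sqrt(dx^2 + dy^2) <= sites$radius_m[k])
      if (length(hit) == 0L) NA_real_ else gps_t[hit[1]]
    }, numeric(1))
    reachable <- which(!is.na(pass) &
                         pass <= cfg$walk_duration_s - 30 & pass >= 30)
    fired <- reachable[stats::runif(length(reachable)) <=
                         sites$event_probability[reachable]]
    if (cfg$reduction_factor < 1 && length(fired) > 0) {
      n_keep <- round(cfg$reduction_factor * length(fired))
      fired <- sort(sample(fired, n_keep))
    }
    onset_idx <- round(pass[fired] * cfg$fs) + 1L
    onset_t <- (onset_idx - 1L) / cfg$fs

    gsr <- rep(cfg$baseline_gsr_us, n_samp)
    st <- rep(cfg$baseline_st_degc, n_samp)
    for (o in onset_t) {
      dt <- t_rel - o
      rise <- dt >= 0 & dt <= cfg$rise_duration_s
      decay <- dt > cfg$rise_duration_s
      gsr[rise] <- gsr[rise] +
        cfg$rise_amplitude_us * dt[rise] / cfg$rise_duration_s
      gsr[decay] <- gsr[decay] + cfg$rise_amplitude_us *
        exp(-(dt[decay] - cfg$rise_duration_s) / cfg$decay_tau_s)
      d0 <- cfg$st_lag_s
      d1 <- d0 + cfg$st_drop_duration_s
      d2 <- d1 + cfg$st_recovery_s
      dropping <- dt >= d0 & dt < d1
      recovering <- dt >= d1 & dt < d2
      st[dropping] <- st[dropping] -
        cfg$st_drop_degc * (dt[dropping] - d0) / cfg$st_drop_duration_s
      st[recovering] <- st[recovering] -
        cfg$st_drop_degc * (1 - (dt[recovering] - d1) / cfg$st_recovery_s)
    }
    if (cfg$gsr_noise_sd_us > 0) {
      gsr <- gsr + stats::rnorm(n_samp, 0, cfg$gsr_noise_sd_us)
    }
    if (cfg$st_noise_sd_degc > 0) {
      st <- st + stats::rnorm(n_samp, 0, cfg$st_noise_sd_degc)
    }

    # diary entries at site passages, negative valence at stressor sites
    rep_draw <- stats::runif(length(reachable))
    reporting <- reachable[rep_draw <= cfg$diary_report_probability]
    diary <- if (length(reporting) > 0) {
      dtimes <- pass[reporting] + 5
      dpos <- route_position(route, pmin(dtimes * cfg$walk_speed_mps,
                                         total_len))
      data.frame(
        participant_id = pid,
        time = p_start + dtimes,
        lon = dpos[, 1], lat = dpos[, 2],
        emotion = sample(c("anger/disgust", "sadness", "fear"),
                         length(reporting), replace = TRUE),
        trigger = sample(c("cars", "intersections", "people", "bicycles"),
                         length(reporting), replace = TRUE),
        intensity = sample(3:5, length(reporting), replace = TRUE),
        needs_georef = FALSE,
        stringsAsFactors = FALSE)
    } else {
      data.frame(participant_id = character(0),
                 time = as.POSIXct(character(0), tz = "UTC"),
                 lon = numeric(0), lat = numeric(0),
                 emotion = character(0), trigger = character(0),
                 intensity = numeric(0), needs_georef = logical(0),
                 stringsAsFactors = FALSE)
    }
    class(diary) <- c("diary_entries", "data.frame")

    truth <- data.frame(participant_id = rep(pid, length(fired)),
                        site_id = sites$site_id[fired],
                        onset_time = p_start + onset_t,
                        stringsAsFactors = FALSE)

    list(
      physio = physio_trace(pid, p_start, cfg$fs, gsr, st),
      track = geo_track(pid, as.numeric(p_start) + gps_t,
                        pos[, 1], pos[, 2]),
      diary = diary,
      truth = truth)
  })
  structure(list(cfg = cfg, sites = sites, participants = participants),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  np <- length(x$participants)
  ne <- sum(vapply(x$participants, function(p) nrow(p$truth), numeric(1)))
  nd <- sum(vapply(x$participants, function(p) nrow(p$diary), numeric(1)))
  cat(sprintf("<campaign> %d participant(s), %d planted event(s), %d diary entr%s, seed %d\n",
              np, ne, nd, if (nd == 1) "y" else "ies", x$cfg$seed))
  invisible(x)
}

#' Write a synthetic campaign in the formats the readers ingest
#'
#' One directory per participant containing Empatica-style `EDA.csv` and
#' `TEMP.csv`, a GPX track, `diary.csv` and the ground-truth annotations
#' (`truth.csv`). Guarantees round-trip coverage of every reader; output is
#' byte-identical for identical seeds.
#'
#' @param campaign A [generate_campaign()] result.
#' @param dir Output directory.
#' @return Invisibly, the participant directories.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dirs <- vapply(campaign$participants, function(p) {
    pd <- file.path(dir, p$physio$participant_id)
    if (!dir.exists(pd)) dir.create(pd)
    write_physio(p$physio, pd)
    write_track_gpx(p$track, file.path(pd, "track.gpx"))
    write_diary(p$diary, file.path(pd, "diary.csv"))
    truth <- p$truth
    truth$onset_time <- sprintf("%.3f", as.numeric(truth$onset_time))
    utils::write.csv(truth, file.path(pd, "truth.csv"), row.names = FALSE)
    pd
  }, character(1))
  invisible(dirs)
}
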