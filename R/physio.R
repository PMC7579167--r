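#' Construct a physiological trace
#'
#' A `physio_trace` holds uniformly sampled skin conductance (GSR, in
#' microsiemens) and skin temperature (ST, in degrees Celsius) for one
#' participant session. Sample `i` (1-based) is taken at
#' `start_time + (i - 1) / fs` seconds.
#'
#' Plausibility gates are applied on construction: GSR must lie within the
#' physically plausible 0--100 microsiemens sensor range and ST within
#' 15--45 degrees C. Out-of-range samples are flagged (per-sample logical
#' vectors in `$flags`), never silently dropped, so that unit mistakes
#' (e.g. conductance delivered in nanosiemens, 1000x too large) surface
#' loudly.
#'
#' @param participant_id Opaque participant/session identifier.
#' @param start_time Absolute start time (`POSIXct`, stored as UTC) or a
#'   numeric UNIX epoch.
#' @param fs Sampling frequency in Hz (> 0).
#' @param gsr Numeric vector of conductance values in microsiemens.
#' @param st Numeric vector of temperature values in degrees Celsius; must
#'   have the same length as `gsr`.
#' @param interpolated Optional logical vector marking samples filled by gap
#'   interpolation.
#' @param segments Optional list of `c(first, last)` index pairs delimiting
#'   contiguous measured segments (gaps longer than the interpolation limit
#'   split the trace; stages downstream process segments independently).
#' @return An object of class `physio_trace`.
#' @export
physio_trace <- function(participant_id, start_time, fs, gsr, st,
                         interpolated = NULL, segments = NULL) {
  if (is.numeric(start_time)) {
    start_time <- as.POSIXct(start_time, origin = "1970-01-01", tz = "UTC")
  }
  attr(start_time, "tzone") <- "UTC"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  gsr <- as.numeric(gsr)
  st <- as.numeric(st)
  if (length(gsr) != length(st)) {
    stop(sprintf("GSR and ST must have equal length (got %d and %d)",
                 length(gsr), length(st)), call. = FALSE)
  }
  n <- length(gsr)
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  if (is.null(segments)) segments <- list(c(1L, n))
  flags <- list(
    gsr_implausible = !is.na(gsr) & (gsr < 0 | gsr > 100),
    st_implausible  = !is.na(st) & (st < 15 | st > 45),
    interpolated    = interpolated
  )
  structure(
    list(participant_id = as.character(participant_id),
         start_time = start_time, fs = fs,
         gsr = gsr, st = st, flags = flags, segments = segments),
    class = "physio_trace"
  )
}

#' @export
print.physio_trace <- function(x, ...) {
  n <- length(x$gsr)
  cat(sprintf("<physio_trace> participant %s\n", x$participant_id))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), start %s UTC\n",
              n, x$fs, n / x$fs, format(x$start_time, "%Y-%m-%d %H:%M:%OS3")))
  cat(sprintf("  GSR [%.3f, %.3f] uS, ST [%.2f, %.2f] degC\n",
              min(x$gsr, na.rm = TRUE), max(x$gsr, na.rm = TRUE),
              min(x$st, na.rm = TRUE), max(x$st, na.rm = TRUE)))
  nf <- sum(x$flags$gsr_implausible) + sum(x$flags$st_implausible)
  if (nf > 0) cat(sprintf("  %d sample(s) flagged implausible\n", nf))
  if (length(x$segments) > 1L)
    cat(sprintf("  %d segments (long gaps split the trace)\n",
                length(x$segments)))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A `physio_trace`.
#' @return `POSIXct` vector of per-sample timestamps.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$gsr) - 1L) / trace$fs
}

# Resample an irregularly timed channel onto a uniform grid.
# Gaps <= max_gap_s are linearly interpolated (flagged); longer gaps are
# left NA and later split the trace into segments.
resample_uniform <- function(time_s, values, grid_s, max_gap_s = 2) {
  ok <- !is.na(values)
  time_s <- time_s[ok]; values <- values[ok]
  out <- stats::approx(time_s, values, xout = grid_s, method = "linear",
                       rule = 1, ties = "ordered")$y
  # Mark grid points falling inside an over-long source gap as missing
  gap_start <- time_s[-length(time_s)]
  gap_len <- diff(time_s)
  long <- which(gap_len > max_gap_s)
  # a grid point "coincides" with a source sample if within 1 us of one
  il <- findInterval(grid_s, time_s)
  d_left <- ifelse(il >= 1, grid_s - time_s[pmax(il, 1L)], Inf)
  d_right <- ifelse(il < length(time_s),
                    time_s[pmin(il + 1L, length(time_s))] - grid_s, Inf)
  interp <- !is.na(out) & pmin(d_left, d_right) > 1e-6
  for (j in long) {
    inside <- grid_s > gap_start[j] & grid_s < gap_start[j] + gap_len[j]
    out[inside] <- NA_real_
    interp[inside] <- FALSE
  }
  list(values = out, interpolated = interp)
}

# Derive contiguous segments (index ranges) from the NA pattern, then drop
# the NAs by keeping the trace but recording segment boundaries.
na_segments <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], ends[k]))
}

read_e4_channel <- function(path) {
  head2 <- readLines(path, n = 2L)
  start <- suppressWarnings(as.numeric(strsplit(head2[1], ",")[[1]][1]))
  rate <- suppressWarnings(as.numeric(strsplit(head2[2], ",")[[1]][1]))
  if (length(head2) < 2L || is.na(start) || is.na(rate) || rate <= 0) {
    stop(sprintf("malformed Empatica-style header in '%s': line 1 must be ",
                 path), "the UNIX start time and line 2 the sampling rate",
         call. = FALSE)
  }
  vals <- utils::read.csv(path, header = FALSE, skip = 2L)[[1]]
  list(start = start, fs = rate, values = as.numeric(vals))
}

#' Read a physiological trace from disk
#'
#' Two dialects are supported. The `e4` dialect is the Empatica-wristband
#' CSV convention: one file per channel, line 1 holding the UNIX start time,
#' line 2 the sampling rate in Hz, and one value per subsequent line. The
#' `generic` dialect is a single timestamped CSV with columns
#' `timestamp` (UNIX seconds or ISO-8601, interpreted as UTC), `gsr`
#' (microsiemens) and `st` (degrees Celsius).
#'
#' Both channels are resampled by linear interpolation onto a common uniform
#' grid at `fs` Hz. Source gaps up to `max_gap_s` seconds are interpolated
#' and flagged; longer gaps split the trace into independently processed
#' segments so that the stress-rule template never straddles unmeasured
#' spans.
#'
#' @param path For `dialect = "e4"`: a directory containing `EDA.csv` and
#'   `TEMP.csv`, or a character vector of the two file paths (GSR first).
#'   For `dialect = "generic"`: a single CSV path.
#' @param dialect `"e4"` or `"generic"`.
#' @param participant_id Identifier attached to the trace (default: derived
#'   from the file name).
#' @param fs Target sampling frequency in Hz of the common grid (default 4,
#'   the native Empatica rate for both channels).
#' @param max_gap_s Longest gap (seconds) bridged by interpolation.
#' @param tz_offset_s Offset added to input timestamps to normalize local
#'   times to UTC (default 0: inputs already UTC).
#' @return A [physio_trace].
#' @export
read_physio <- function(path, dialect = c("e4", "generic"),
                        participant_id = NULL, fs = 4, max_gap_s = 2,
                        tz_offset_s = 0) {
  dialect <- match.arg(dialect)
  if (dialect == "e4") {
    if (length(path) == 1L && dir.exists(path)) {
      eda_path <- file.path(path, "EDA.csv")
      temp_path <- file.path(path, "TEMP.csv")
    } else if (length(path) == 2L) {
      eda_path <- path[1]; temp_path <- path[2]
    } else {
      stop("for dialect 'e4' give a directory with EDA.csv and TEMP.csv, ",
           "or c(eda_path, temp_path)", call. = FALSE)
    }
    for (p in c(eda_path, temp_path)) {
      if (!file.exists(p)) stop(sprintf("file not found: '%s'", p),
                                call. = FALSE)
    }
    eda <- read_e4_channel(eda_path)
    tmp <- read_e4_channel(temp_path)
    if (is.null(participant_id)) {
      participant_id <- basename(dirname(normalizePath(eda_path)))
    }
    t0 <- max(eda$start, tmp$start) + tz_offset_s
    t_end <- min(eda$start + (length(eda$values) - 1) / eda$fs,
                 tmp$start + (length(tmp$values) - 1) / tmp$fs) + tz_offset_s
    if (t_end <= t0) stop("EDA and TEMP files do not overlap in time",
                          call. = FALSE)
    grid <- seq(0, t_end - t0, by = 1 / fs)
    g <- resample_uniform(eda$start + tz_offset_s - t0 +
                            (seq_along(eda$values) - 1) / eda$fs,
                          eda$values, grid, max_gap_s)
    s <- resample_uniform(tmp$start + tz_offset_s - t0 +
                            (seq_along(tmp$values) - 1) / tmp$fs,
                          tmp$values, grid, max_gap_s)
  } else {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                                 call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("timestamp", "gsr", "st")
    if (!all(need %in% names(df))) {
      stop("generic physio CSV needs columns timestamp, gsr, st",
           call. = FALSE)
    }
    bad <- which(is.na(df$gsr) | is.na(df$st) |
                   (is.character(df$gsr) & df$gsr == "") |
                   (is.character(df$st) & df$st == ""))
    if (length(bad) > 0) {
      stop(sprintf("missing GSR/ST value at data row %d of '%s'",
                   bad[1], path), call. = FALSE)
    }
    ts <- df$timestamp
    if (is.character(ts)) {
      tsn <- suppressWarnings(as.numeric(ts))
      if (all(!is.na(tsn))) {
        ts <- tsn
      } else {
        ts <- as.numeric(as.POSIXct(ts, tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                   "%Y-%m-%d %H:%M:%OS")))
      }
    }
    if (any(is.na(ts))) stop("unparseable timestamp in generic physio CSV",
                             call. = FALSE)
    if (any(diff(ts) <= 0)) {
      stop(sprintf("non-monotonic timestamps in '%s' (first at row %d)",
                   path, which(diff(ts) <= 0)[1] + 1L), call. = FALSE)
    }
    ts <- ts + tz_offset_s
    if (is.null(participant_id)) {
      participant_id <- sub("\\.[^.]+$", "", basename(path))
    }
    t0 <- ts[1]
    grid <- seq(0, ts[length(ts)] - t0, by = 1 / fs)
    g <- resample_uniform(ts - t0, as.numeric(df$gsr), grid, max_gap_s)
    s <- resample_uniform(ts - t0, as.numeric(df$st), grid, max_gap_s)
  }
  miss <- is.na(g$values) | is.na(s$values)
  segs <- na_segments(ifelse(miss, NA_real_, 1))
  tr <- physio_trace(participant_id, t0, fs, g$values, s$values,
                     interpolated = g$interpolated | s$interpolated,
                     segments = segs)
  if (any(tr$flags$gsr_implausible) || any(tr$flags$st_implausible)) {
    warning(sprintf(
      "plausibility gates tripped for participant %s: %d GSR sample(s) < 0 uS, %d ST sample(s) outside 15-45 degC (check units)",
      tr$participant_id, sum(tr$flags$gsr_implausible),
      sum(tr$flags$st_implausible)), call. = FALSE)
  }
  tr
}

#' Write a physiological trace in the Empatica-style CSV dialect
#'
#' Emits `EDA.csv` and `TEMP.csv` under `dir` (line 1 UNIX start time,
#' line 2 sampling rate, one value per following line, 6 decimal places).
#' `read_physio(dir, "e4")` round-trips sample values to 6 decimals and
#' metadata exactly.
#'
#' @param trace A [physio_trace].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths written.
#' @export
write_physio <- function(trace, dir) {
  stopifnot(inherits(trace, "physio_trace"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  start <- as.numeric(trace$start_time)
  paths <- c(EDA = file.path(dir, "EDA.csv"),
             TEMP = file.path(dir, "TEMP.csv"))
  for (ch in c("EDA", "TEMP")) {
    vals <- if (ch == "EDA") trace$gsr else trace$st
    writeLines(c(sprintf("%.6f", start), sprintf("%.6f", trace$fs),
                 sprintf("%.6f", vals)), paths[[ch]])
  }
  invisible(paths)
}
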