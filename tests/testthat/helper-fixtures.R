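# Shared fixture builders and independent reference implementations.
# Everything here is deliberately naive (straight loops, closed forms) so
# that it can serve as an oracle for the vectorized package code.

# Build a filtered_trace directly from phasic/ST series, bypassing the
# filters, to probe the detector in isolation.
fake_filtered <- function(gsr_phasic, st_smooth, fs = 4,
                          start = as.POSIXct("2018-09-05 09:00:00",
                                             tz = "UTC"),
                          participant_id = "T01") {
  tr <- physio_trace(participant_id, start, fs, gsr_phasic, st_smooth)
  tr$gsr_phasic <- as.numeric(gsr_phasic)
  tr$st_smooth <- as.numeric(st_smooth)
  class(tr) <- c("filtered_trace", class(tr))
  tr
}

# The planted template of the detection examples: phasic GSR rising
# linearly rise_from -> rise_to over [t_on, t_on + 5], then flat; ST flat
# until st_peak_t then falling linearly to st_end_val at st_end_t.
template_series <- function(duration_s = 60, fs = 4, t_on = 10,
                            rise_to = 1, st_peak_t = 13.5,
                            st_end_t = 20, st_end_val = 32.8,
                            st_base = 33) {
  t <- seq(0, duration_s, by = 1 / fs)
  g <- numeric(length(t))
  g[t >= t_on & t <= t_on + 5] <- (t[t >= t_on & t <= t_on + 5] - t_on) / 5 * rise_to
  g[t > t_on + 5] <- rise_to
  s <- rep(st_base, length(t))
  fall <- t > st_peak_t & t <= st_end_t
  s[fall] <- st_base + (st_end_val - st_base) *
    (t[fall] - st_peak_t) / (st_end_t - st_peak_t)
  s[t > st_end_t] <- st_end_val
  list(t = t, g = g, s = s)
}

# Independent straight-line reference implementation of the stress rule:
# literal per-onset loops over the three clauses, plus the same
# earliest-onset merging convention. Returns merged onset times (seconds
# from trace start).
ref_detect_onsets <- function(g, s, fs, rise_s = 5, lag_s = 3,
                              search_s = 10, min_slope_deg = 10,
                              tol = 0.005, min_drop = 0, refractory_s = 5,
                              slope_scale = 1) {
  n <- length(g)
  W <- round(rise_s * fs); L <- round(lag_s * fs); S <- round(search_s * fs)
  fires <- integer(0)
  for (i in seq_len(max(n - max(W, L + S), 0))) {
    mono <- TRUE
    for (k in i:(i + W - 1)) {
      if (g[k + 1] - g[k] < -tol) { mono <- FALSE; break }
    }
    if (!mono) next
    net <- g[i + W] - g[i]
    if (!(net > 0)) next
    slope <- atan((net / (W / fs)) / slope_scale) * 180 / pi
    if (slope < min_slope_deg) next
    # window [i+L, i+L+S]: a local max (plateau start counts) followed by
    # a strictly lower local min
    win <- s[(i + L):(i + L + S)]
    ok <- FALSE
    m <- length(win)
    for (a in 1:(m - 1)) {
      # max candidates: the window start (boundary convention) or the
      # earliest sample strictly above its predecessor (plateau -> earliest)
      is_max <- (a == 1) || (win[a] > win[a - 1])
      if (!is_max) next
      # need a strict decrease after a, reaching a local min
      for (b in (a + 1):m) {
        if (win[b] < win[a]) {
          # b is a min if it stops decreasing (or window ends)
          turn <- (b == m) || (win[b + 1] >= win[b])
          dec_before <- win[b] < win[b - 1] || win[b] < win[a]
          if (turn && dec_before && (win[a] - win[b]) >= min_drop &&
              (win[a] - win[b]) > 0) { ok <- TRUE; break }
        }
      }
      if (ok) break
    }
    if (ok) fires <- c(fires, i)
  }
  if (length(fires) == 0) return(numeric(0))
  merged <- fires[1]
  last <- fires[1]
  for (f in fires[-1]) {
    if ((f - last) / fs >= refractory_s) merged <- c(merged, f)
    last <- f
  }
  (merged - 1) / fs
}

# Brute-force double-loop Gi* oracle (scalar arithmetic only).
oracle_gi_star <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    swx <- 0; sw <- 0; sw2 <- 0
    for (j in seq_len(n)) {
      swx <- swx + W[i, j] * x[j]
      sw <- sw + W[i, j]
      sw2 <- sw2 + W[i, j]^2
    }
    den <- S * sqrt((n * sw2 - sw^2) / (n - 1))
    z[i] <- if (is.na(den) || den == 0 || S == 0) 0 else (swx - xbar * sw) / den
  }
  z
}

# Small helper: write an Empatica-style channel file.
write_e4_file <- function(path, start, fs, values) {
  writeLines(c(sprintf("%.6f", start), sprintf("%.6f", fs),
               sprintf("%.6f", values)), path)
}
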