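#' Filtering configuration
#'
#' Defaults follow standard electrodermal-activity practice: a 0.5 Hz
#' low-pass removes high-frequency technical noise, and a 0.05 Hz high-pass
#' removes the slow tonic conductance level (each participant's baseline),
#' leaving the fast phasic component that stress responses ride on. Both
#' filters are Butterworth designs applied forward--backward (zero phase),
#' so detected event timing is not shifted.
#'
#' @param lowpass_cutoff_hz Low-pass cutoff, Hz.
#' @param highpass_cutoff_hz High-pass cutoff, Hz; must be below the
#'   low-pass cutoff.
#' @param filter_order Butterworth order per pass (default 2).
#' @param filter_family Only `"butterworth"` is implemented.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_cutoff_hz = 0.5,
                              highpass_cutoff_hz = 0.05,
                              filter_order = 2,
                              filter_family = "butterworth") {
  filter_family <- match.arg(filter_family, "butterworth")
  if (!(highpass_cutoff_hz > 0 && highpass_cutoff_hz < lowpass_cutoff_hz)) {
    stop("need 0 < highpass_cutoff_hz < lowpass_cutoff_hz", call. = FALSE)
  }
  if (filter_order < 1 || filter_order != round(filter_order)) {
    stop("filter_order must be a positive integer", call. = FALSE)
  }
  structure(list(lowpass_cutoff_hz = lowpass_cutoff_hz,
                 highpass_cutoff_hz = highpass_cutoff_hz,
                 filter_order = as.integer(filter_order),
                 filter_family = filter_family),
            class = "preprocess_config")
}

# minimum series length accepted by the zero-phase filters
filter_min_length <- function(order) 3L * (3L * as.integer(order) + 1L)

zero_phase <- function(x, fs, cutoff, order, type) {
  if (fs / 2 <= cutoff) {
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff, fs / 2), call. = FALSE)
  }
  n <- length(x)
  if (n < filter_min_length(order)) {
    stop(sprintf("series too short for order-%d zero-phase filtering (need >= %d samples, got %d)",
                 order, filter_min_length(order), length(x)), call. = FALSE)
  }
  flt <- signal::butter(order, cutoff / (fs / 2), type = type)
  # Edge handling: extend with the odd-symmetric reflection long enough for
  # the zero-state startup transient to decay inside the padding, so that
  # e.g. a constant input maps to an (numerically) exact constant response.
  pr <- min(max(Mod(polyroot(rev(flt$a)))), 0.999)
  pad <- min(n - 1L, max(9L * order, ceiling(log(1e-13) / log(pr))))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(flt, ext)
  y[(pad + 1):(pad + n)]
}

#' Zero-phase low-pass filter
#'
#' Forward--backward Butterworth low-pass; output has exactly zero phase
#' shift and the same length as the input. The effective magnitude response
#' of the double pass is the square of the single-pass response (see
#' [filter_response()]).
#'
#' @param x Uniformly sampled numeric series.
#' @param fs Sampling frequency, Hz.
#' @param cfg A [preprocess_config].
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cfg = preprocess_config()) {
  zero_phase(x, fs, cfg$lowpass_cutoff_hz, cfg$filter_order, "low")
}

#' Zero-phase high-pass filter (tonic baseline removal)
#'
#' Removes the slowly varying tonic conductance level (DC and drifts below
#' the cutoff), leaving the phasic component. DC is fully rejected: a
#' constant input maps to (numerically) zero.
#'
#' @inheritParams lowpass
#' @return Filtered series, same length as `x`.
#' @export
highpass_tonic_removal <- function(x, fs, cfg = preprocess_config()) {
  zero_phase(x, fs, cfg$highpass_cutoff_hz, cfg$filter_order, "high")
}

#' Analytic magnitude response of the configured filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| of the designed digital Butterworth
#' filter directly from its transfer-function coefficients, raised to
#' `passes` (2 for the forward--backward, zero-phase application). This is
#' the closed-form prediction that measured steady-state sinusoid
#' attenuation must match.
#'
#' @param f_hz Probe frequencies, Hz.
#' @param fs Sampling frequency, Hz.
#' @param cutoff_hz Filter cutoff, Hz.
#' @param order Butterworth order.
#' @param type `"low"` or `"high"`.
#' @param passes Number of filter passes (default 2: zero-phase).
#' @return Numeric vector of gains.
#' @export
filter_response <- function(f_hz, fs, cutoff_hz, order = 2,
                            type = c("low", "high"), passes = 2) {
  type <- match.arg(type)
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = type)
  w <- 2 * pi * f_hz / fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(flt$b * zz^-(seq_along(flt$b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(flt$a * zz^-(seq_along(flt$a) - 1)),
                complex(1))
  Mod(num / den)^passes
}

#' Separate phasic GSR and smoothed skin temperature
#'
#' Applies the full filtering chain to a trace: GSR is low-passed then
#' high-passed, yielding the phasic component `gsr_phasic` (tonic baseline
#' removed); skin temperature receives the low-pass only (`st_smooth`),
#' since the stress rule inspects ST local extrema in absolute terms.
#' Segments separated by long measurement gaps are filtered independently.
#'
#' @param trace A [physio_trace].
#' @param cfg A [preprocess_config].
#' @return A `filtered_trace` (extends `physio_trace`) with fields
#'   `gsr_phasic` and `st_smooth` on the same time base.
#' @export
preprocess_trace <- function(trace, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "physio_trace"))
  gsr_phasic <- rep(NA_real_, length(trace$gsr))
  st_smooth <- rep(NA_real_, length(trace$st))
  for (seg in trace$segments) {
    idx <- seg[1]:seg[2]
    if (length(idx) < filter_min_length(cfg$filter_order)) next
    lp <- lowpass(trace$gsr[idx], trace$fs, cfg)
    gsr_phasic[idx] <- highpass_tonic_removal(lp, trace$fs, cfg)
    st_smooth[idx] <- lowpass(trace$st[idx], trace$fs, cfg)
  }
  trace$gsr_phasic <- gsr_phasic
  trace$st_smooth <- st_smooth
  trace$preprocess <- cfg
  class(trace) <- c("filtered_trace", class(trace))
  trace
}
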