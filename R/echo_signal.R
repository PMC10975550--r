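#' A-mode echo trace
#'
#' One sampled pulse-echo trace from a single beam: the raw RF amplitude
#' sequence s(t) together with its sampling rate, the time origin of the
#' transmit pulse center, and the beam it came from.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), at least
#'   16 samples.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the pulse
#'   center frequency for the envelope to be meaningful.
#' @param emission_time Time of the transmit pulse center in seconds
#'   (default 0); detected echo times are reported relative to it.
#' @param beam_id Integer beam index, 1..3.
#' @return An object of class `echo_trace`.
#' @export
echo_trace <- function(samples, sampling_rate, emission_time = 0, beam_id = 1L) {
  samples <- as.numeric(samples)
  if (length(samples) < 16L) stop("a trace needs at least 16 samples")
  if (any(!is.finite(samples))) stop("trace contains non-finite samples")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  beam_id <- as.integer(beam_id)
  if (is.na(beam_id) || beam_id < 1L || beam_id > 3L) {
    stop("beam_id must be 1, 2 or 3")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 emission_time = as.numeric(emission_time),
                 beam_id = beam_id),
            class = "echo_trace")
}

#' @export
print.echo_trace <- function(x, ...) {
  cat(sprintf("<echo_trace> beam %d: %d samples @ %.4g MHz (%.1f us)\n",
              x$beam_id, length(x$samples), x$sampling_rate / 1e6,
              1e6 * length(x$samples) / x$sampling_rate))
  invisible(x)
}

# Discrete analytic signal: FFT, zero the negative-frequency half, double
# the positive band; DC and (for even n) the Nyquist bin are kept once.
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1
    w[2:(n / 2)] <- 2
    w[n / 2 + 1] <- 1
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Hilbert-transform envelope of an echo trace
#'
#' Demodulates the RF trace to its amplitude envelope
#' \deqn{A(t) = \sqrt{s(t)^2 + \hat s(t)^2},}
#' where `s-hat` is the discrete Hilbert transform of s, computed through
#' the analytic signal (FFT, zero negative frequencies, double the positive
#' band). The envelope of a narrowband pulse is its modulation profile, so
#' the echo arrival time becomes a simple peak of A(t).
#'
#' @param trace An [echo_trace()].
#' @param bandpass Optional length-2 numeric `c(low, high)` in Hz: apply a
#'   zero-phase 4th-order Butterworth band-pass before demodulation.
#'   `NULL` (default) leaves the trace unfiltered, matching an analog chain
#'   that filters in hardware.
#' @return An object of class `envelope`: fields `values` (nonnegative,
#'   same length as the trace), `sampling_rate`, `emission_time`, `beam_id`.
#' @examples
#' t <- seq(0, 1e-5, by = 1e-8)
#' tr <- echo_trace(cos(2 * pi * 1e6 * t), 1e8)
#' env <- hilbert_envelope(tr)
#' range(env$values[100:900])  # ~1 on the interior
#' @export
hilbert_envelope <- function(trace, bandpass = NULL) {
  stopifnot(inherits(trace, "echo_trace"))
  x <- trace$samples
  if (!is.null(bandpass)) {
    stopifnot(length(bandpass) == 2L, all(bandpass > 0),
              bandpass[2] < trace$sampling_rate / 2)
    bf <- signal::butter(4, 2 * bandpass / trace$sampling_rate, type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  structure(list(values = Mod(.analytic_signal(x)),
                 sampling_rate = trace$sampling_rate,
                 emission_time = trace$emission_time,
                 beam_id = trace$beam_id),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> beam %d: %d samples, max %.4g\n",
              x$beam_id, length(x$values), max(x$values)))
  invisible(x)
}

#' Peak-detection policy for the two-echo picker
#'
#' @param dead_zone Seconds of trace to ignore at the start (transmit
#'   ring-down). Default 5 us.
#' @param min_separation Minimum time between the two echoes in seconds.
#'   Default 2.5 us (about twice the duration of a 3 MHz pulse).
#' @param rel_threshold Peaks below this fraction of the global envelope
#'   maximum are ignored. Default 0.2.
#' @param interpolate Refine each peak with a 3-point parabolic fit for
#'   sub-sample timing (default `TRUE`).
#' @return An object of class `peak_config`.
#' @export
peak_config <- function(dead_zone = 5e-6, min_separation = 2.5e-6,
                        rel_threshold = 0.2, interpolate = TRUE) {
  if (dead_zone < 0) stop("dead_zone must be >= 0")
  if (!(rel_threshold > 0 && rel_threshold < 1)) {
    stop("rel_threshold must lie in (0, 1)")
  }
  if (min_separation <= 0) stop("min_separation must be > 0")
  structure(list(dead_zone = dead_zone, min_separation = min_separation,
                 rel_threshold = rel_threshold,
                 interpolate = isTRUE(interpolate)),
            class = "peak_config")
}

# 3-point parabolic vertex offset in samples, clipped to +/- 0.5.
.parabolic_offset <- function(y_left, y_mid, y_right) {
  denom <- y_left - 2 * y_mid + y_right
  if (denom >= 0) return(0)  # not a strict local max at this resolution
  max(-0.5, min(0.5, 0.5 * (y_left - y_right) / denom))
}

#' Detect the near- and far-wall echo times in one envelope
#'
#' Finds the two dominant local maxima of the envelope after the dead zone:
#' the earlier one is the first (near-wall) echo, the later one the second
#' (far-wall) echo. Candidates must exceed `rel_threshold` times the global
#' maximum and be separated by at least `min_separation`; when more than
#' two qualify, the two largest are kept and a warning diagnostic recorded.
#'
#' @param env An [hilbert_envelope()] result.
#' @param cfg A [peak_config()].
#' @return An object of class `echo_times`: `dt_near` and `dt_far`
#'   (round-trip seconds, measured from `emission_time`), `beam_id`, and
#'   `diagnostics` (candidate count, any warning).
#' @export
detect_two_echoes <- function(env, cfg = peak_config()) {
  stopifnot(inherits(env, "envelope"), inherits(cfg, "peak_config"))
  v <- env$values
  fs <- env$sampling_rate
  n <- length(v)
  start <- max(2L, 1L + as.integer(ceiling(cfg$dead_zone * fs)))
  if (start >= n - 1L) stop("dead zone swallows the whole trace")
  thr <- cfg$rel_threshold * max(v[start:n])
  idx <- (start):(n - 1L)
  is_peak <- v[idx] >= v[idx - 1L] & v[idx] > v[idx + 1L] & v[idx] >= thr
  peaks <- idx[is_peak]
  if (length(peaks) == 0L) {
    stop(sprintf("beam %d: no echo peaks above threshold", env$beam_id))
  }
  # greedy selection by amplitude with a minimum-separation exclusion zone
  min_sep_samp <- cfg$min_separation * fs
  ord <- peaks[order(v[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(p - kept) >= min_sep_samp)) kept <- c(kept, p)
  }
  warning_msg <- NULL
  if (length(kept) < 2L) {
    stop(sprintf("beam %d: only one qualifying echo found (missed far wall or low SNR)",
                 env$beam_id))
  }
  if (length(kept) > 2L) {
    warning_msg <- sprintf("beam %d: %d echo candidates, keeping the two largest",
                           env$beam_id, length(kept))
    kept <- kept[1:2]
  }
  kept <- sort(kept)
  t_of <- function(i) {
    off <- if (cfg$interpolate && i > 1L && i < n) {
      .parabolic_offset(v[i - 1L], v[i], v[i + 1L])
    } else 0
    (i - 1L + off) / fs
  }
  times <- vapply(kept, t_of, numeric(1)) - env$emission_time
  structure(list(dt_near = times[1], dt_far = times[2], beam_id = env$beam_id,
                 diagnostics = list(n_candidates = length(ord),
                                    warning = warning_msg)),
            class = "echo_times")
}

#' @export
print.echo_times <- function(x, ...) {
  cat(sprintf("<echo_times> beam %d: dt_near=%.4g us, dt_far=%.4g us\n",
              x$beam_id, x$dt_near * 1e6, x$dt_far * 1e6))
  invisible(x)
}

#' Round-trip time of flight to one-way range
#'
#' `distance = S * dt / 2`: an echo travels to the reflector and back, so
#' the one-way range is half the path at the speed of sound S.
#'
#' @param dt Round-trip time(s) of flight in seconds, `>= 0`.
#' @param speed_S Speed of sound in m/s, `> 0`.
#' @return Range(s) in meters.
#' @examples
#' tof_to_distance(40e-6, 1500)  # 0.03 m
#' @export
tof_to_distance <- function(dt, speed_S) {
  if (any(!is.finite(dt)) || any(dt < 0)) stop("dt must be nonnegative")
  if (!is.finite(speed_S) || speed_S <= 0) stop("speed_S must be positive")
  speed_S * dt / 2
}

#' Read / write echo traces as delimited text
#'
#' The trace file format is plain text: comment header lines
#' `# sampling_rate_hz=<float>`, `# emission_time_s=<float>`,
#' `# beam_id=<int>`, then one amplitude per line at full double precision
#' (17 significant digits), so a write/read cycle is bit-exact.
#'
#' @param trace An [echo_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   [echo_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "echo_trace"))
  header <- c(
    sprintf("# sampling_rate_hz=%.17g", trace$sampling_rate),
    sprintf("# emission_time_s=%.17g", trace$emission_time),
    sprintf("# beam_id=%d", trace$beam_id))
  writeLines(c(header, sprintf("%.17g", trace$samples)), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("trace file missing header '%s'", key))
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m))
  }
  samples <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  echo_trace(samples,
             sampling_rate = get("sampling_rate_hz"),
             emission_time = get("emission_time_s"),
             beam_id = as.integer(get("beam_id")))
}
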