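#' Transmit pulse specification
#'
#' A Gaussian-modulated sinusoid, the standard idealization of a damped
#' piezoelectric transmit pulse: carrier at `center_frequency`, Gaussian
#' amplitude envelope whose width is set by the fractional -6 dB bandwidth.
#' The envelope standard deviation in time is
#' `sigma_t = sqrt(2 log 2) / (pi * bw * fc)`.
#'
#' @param center_frequency Carrier frequency in Hz (default 3 MHz, the
#'   usual choice for a deep fluid-filled target such as the bladder).
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2).
#'   Default 0.6, typical of a damped single-element medical transducer.
#' @param amplitude Peak envelope amplitude, arbitrary units.
#' @return An object of class `pulse_spec` (also carries the derived
#'   `sigma_t` and a nominal `duration = 6 * sigma_t`).
#' @export
pulse_spec <- function(center_frequency = 3e6, fractional_bandwidth = 0.6,
                       amplitude = 1) {
  if (!is.finite(center_frequency) || center_frequency <= 0) {
    stop("center_frequency must be positive")
  }
  if (!(fractional_bandwidth > 0 && fractional_bandwidth < 2)) {
    stop("fractional_bandwidth must lie in (0, 2)")
  }
  sigma_t <- sqrt(2 * log(2)) / (pi * fractional_bandwidth * center_frequency)
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 amplitude = amplitude,
                 sigma_t = sigma_t, duration = 6 * sigma_t),
            class = "pulse_spec")
}

#' Measurement-noise specification
#'
#' Two noise mechanisms are modeled: a Gaussian range-equivalent timing
#' jitter applied independently to every echo (standing in for trigger,
#' sound-speed and surface-roughness errors), and additive white Gaussian
#' noise on the trace.
#'
#' @param timing_jitter_sigma One-way range jitter standard deviation in
#'   meters (0 = clean).
#' @param snr_db Trace signal-to-noise ratio in dB relative to the pulse
#'   amplitude; `Inf` (default) means no additive noise.
#' @param seed Integer RNG seed driving all randomness of a simulation.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(timing_jitter_sigma = 0, snr_db = Inf, seed = 1L) {
  if (!is.finite(timing_jitter_sigma) || timing_jitter_sigma < 0) {
    stop("timing_jitter_sigma must be >= 0")
  }
  structure(list(timing_jitter_sigma = timing_jitter_sigma,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Unit beam directions for a three-beam fan
#'
#' Builds three unit vectors from the probe apex whose pairwise angles are
#' `alpha` (beams 1-2), `beta` (2-3) and `gamma` (3-1), oriented so the fan
#' centroid points along +z (into the body) and the first beam lies in the
#' x-z plane with a nonnegative x component. For the symmetric case the
#' beams form a cone about the probe axis. The construction factorizes the
#' Gram matrix of pairwise cosines and is fully deterministic.
#'
#' @param alpha,beta,gamma Pairwise angles in radians, each in `[0, pi/2)`.
#' @return A 3 x 3 matrix whose rows are the beam unit vectors.
#' @export
beam_fan <- function(alpha, beta, gamma) {
  angs <- c(alpha, beta, gamma)
  if (any(!is.finite(angs)) || any(angs < 0) || any(angs >= pi / 2)) {
    stop("fan angles must lie in [0, pi/2)")
  }
  G <- rbind(c(1, cos(alpha), cos(gamma)),
             c(cos(alpha), 1, cos(beta)),
             c(cos(gamma), cos(beta), 1))
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-10) {
    stop("fan angles are not realizable by three unit vectors in 3-D")
  }
  D <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))  # rows: D %*% t(D) = G
  ctr <- colSums(D)
  ctr <- ctr / sqrt(sum(ctr^2))
  R1 <- .rotation_between(ctr, c(0, 0, 1))
  D <- D %*% t(R1)
  phi <- atan2(D[1, 2], D[1, 1])
  if (is.finite(phi) && (abs(D[1, 1]) > 1e-14 || abs(D[1, 2]) > 1e-14)) {
    cz <- cos(-phi); sz <- sin(-phi)
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    D <- D %*% t(Rz)
  }
  D / sqrt(rowSums(D^2))
}

# Rodrigues rotation taking unit vector a onto unit vector b.
.rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-14) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + K + K %*% K * ((1 - c0) / s^2)
}

# Gaussian-modulated sinusoid centered at tc, truncated at +/- 6 sigma.
.inject_pulse <- function(sig, t, tc, pulse, amp_scale) {
  win <- which(abs(t - tc) <= 6 * pulse$sigma_t)
  if (length(win) == 0L) return(sig)
  tt <- t[win] - tc
  sig[win] <- sig[win] + pulse$amplitude * amp_scale *
    exp(-tt^2 / (2 * pulse$sigma_t^2)) *
    cos(2 * pi * pulse$center_frequency * tt)
  sig
}

#' Simulate one three-beam A-mode measurement of a spherical phantom
#'
#' The in-silico analog of suspending a water-filled balloon under the
#' probe in a water tank: each beam is intersected with the phantom sphere,
#' and a Gaussian-modulated pulse is injected at the near- and far-wall
#' round-trip times `2 * (range + jitter) / S`, the far-wall pulse at 0.6
#' relative amplitude (only peak timing matters to the method, so no
#' frequency-dependent attenuation is modeled). Additive white Gaussian
#' noise is applied at `snr_db`. All randomness is driven by `noise$seed`.
#'
#' @param phantom A [phantom_spec()] (probe frame: apex at origin, +z into
#'   the body).
#' @param geometry A [beam_geometry()].
#' @param pulse A [pulse_spec()].
#' @param noise A [noise_spec()].
#' @param sampling_rate Hz; default 100 MHz.
#' @param duration Trace length in seconds; default 1.5 times the farthest
#'   round trip. An explicit duration shorter than the far round trip is a
#'   configuration error.
#' @return An object of class `simulated_measurement`: `traces` (list of
#'   three [echo_trace()]), `ground_truth` (phantom, exact near/far ranges,
#'   exact standoff `h = |OP| - R`, true volume in mL, per-beam miss flags)
#'   and `usable` (TRUE when all three beams hit the sphere).
#' @export
simulate_measurement <- function(phantom, geometry, pulse = pulse_spec(),
                                 noise = noise_spec(),
                                 sampling_rate = 1e8, duration = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(geometry, "beam_geometry"),
            inherits(pulse, "pulse_spec"), inherits(noise, "noise_spec"))
  S <- phantom$speed_of_sound
  dirs <- geometry$unit_directions
  hits <- lapply(1:3, function(i) {
    ray_sphere_intersections(c(0, 0, 0), dirs[i, ], phantom)
  })
  missed <- vapply(hits, is.null, logical(1))
  near <- vapply(hits, function(h) if (is.null(h)) NA_real_ else h[["near"]], 0)
  far <- vapply(hits, function(h) if (is.null(h)) NA_real_ else h[["far"]], 0)
  dist_center <- sqrt(sum(phantom$center^2))
  if (is.null(duration)) {
    worst <- if (all(missed)) dist_center + phantom$radius else max(far, na.rm = TRUE)
    duration <- 1.5 * 2 * worst / S
  } else if (!all(missed) && duration < 2 * max(far, na.rm = TRUE) / S) {
    stop("duration shorter than the farthest round trip; increase it or use the default")
  }
  n <- as.integer(ceiling(duration * sampling_rate))
  t <- (seq_len(n) - 1L) / sampling_rate
  set.seed(noise$seed)
  traces <- vector("list", 3L)
  for (i in 1:3) {
    jit <- stats::rnorm(2L, 0, noise$timing_jitter_sigma)
    sig <- numeric(n)
    if (!missed[i]) {
      sig <- .inject_pulse(sig, t, 2 * (near[i] + jit[1]) / S, pulse, 1.0)
      sig <- .inject_pulse(sig, t, 2 * (far[i] + jit[2]) / S, pulse, 0.6)
    }
    if (is.finite(noise$snr_db)) {
      sig <- sig + stats::rnorm(n, 0, pulse$amplitude * 10^(-noise$snr_db / 20))
    }
    traces[[i]] <- echo_trace(sig, sampling_rate, emission_time = 0, beam_id = i)
  }
  structure(
    list(traces = traces,
         ground_truth = list(
           phantom = phantom,
           near_ranges = near, far_ranges = far,
           standoff_h = dist_center - phantom$radius,
           volume_ml = sphere_volume(phantom$radius),
           missed = missed),
         usable = !any(missed)),
    class = "simulated_measurement")
}

#' @export
print.simulated_measurement <- function(x, ...) {
  cat(sprintf("<simulated_measurement> true V=%.1f mL, usable=%s\n",
              x$ground_truth$volume_ml, x$usable))
  invisible(x)
}

#' Write a simulated measurement to disk
#'
#' Writes the three trace files (`beam1.txt` .. `beam3.txt`, the
#' [write_trace()] text format) plus a `ground_truth.json` sidecar with the
#' phantom, exact ranges, standoff and true volume.
#'
#' @param sim A [simulate_measurement()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_measurement <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_measurement"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in 1:3) {
    write_trace(sim$traces[[i]], file.path(dir, sprintf("beam%d.txt", i)))
  }
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(center_m = gt$phantom$center, radius_m = gt$phantom$radius,
         speed_of_sound = gt$phantom$speed_of_sound,
         near_ranges_m = gt$near_ranges, far_ranges_m = gt$far_ranges,
         standoff_h_m = gt$standoff_h, volume_ml = gt$volume_ml,
         missed = gt$missed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Radius of a sphere with a given volume
#'
#' Inverse of [sphere_volume()]: `R = (3 V / (4 pi))^(1/3)`.
#'
#' @param volume_ml Volume in milliliters, `> 0`.
#' @return Radius in meters.
#' @export
radius_from_volume <- function(volume_ml) {
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0)) {
    stop("volume must be positive")
  }
  (3 * volume_ml * 1e-6 / (4 * pi))^(1 / 3)
}

#' Simulated sweep over a set of phantom volumes
#'
#' Emulates a bench sweep: for each requested volume a sphere of the
#' corresponding radius is centered on the probe axis with its top pole
#' `standoff_m` below the probe, `reps` noisy measurements are simulated,
#' and each is pushed through the full estimation pipeline
#' ([estimate_volume()]). Per-rep seeds are drawn once from `noise$seed`,
#' so the whole sweep is reproducible.
#'
#' @param volumes_ml Vector of true volumes in mL (may be empty).
#' @param reps Repetitions per volume (`>= 0`).
#' @param geometry A [beam_geometry()]; default symmetric 10 degree fan.
#' @param pulse A [pulse_spec()].
#' @param noise A [noise_spec()]; its `seed` drives the per-rep seed
#'   schedule.
#' @param sampling_rate Hz; default 100 MHz.
#' @param speed_of_sound m/s; default 1480 (water).
#' @param standoff_m Gap between probe and top pole of the sphere, meters;
#'   default 0.02.
#' @param config An [acquisition_config()] for the estimation side; by
#'   default built to match the simulation (same speed and angles, standoff
#'   from the mean of the first echoes).
#' @return A data frame with one row per rep: `true_volume_ml`,
#'   `est_volume_ml`, `abs_err_ml`, `rel_err_pct`, `seed`, `rep`, `ok`,
#'   `note`. Failed or unusable measurements have `ok = FALSE` and NA
#'   estimates; the attribute `n_excluded` counts them.
#' @export
batch_experiment <- function(volumes_ml, reps,
                             geometry = beam_geometry(pi / 18, pi / 18, pi / 18),
                             pulse = pulse_spec(),
                             noise = noise_spec(),
                             sampling_rate = 1e8,
                             speed_of_sound = 1480,
                             standoff_m = 0.02,
                             config = NULL) {
  if (any(volumes_ml <= 0)) stop("volumes must be positive")
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 0L) stop("reps must be a nonnegative integer")
  if (is.null(config)) {
    config <- acquisition_config(
      speed_of_sound = speed_of_sound,
      angles_deg = c(geometry$alpha, geometry$beta, geometry$gamma) * 180 / pi,
      standoff_strategy = "mean")
  }
  n_total <- length(volumes_ml) * reps
  empty <- data.frame(true_volume_ml = numeric(0), est_volume_ml = numeric(0),
                      abs_err_ml = numeric(0), rel_err_pct = numeric(0),
                      seed = integer(0), rep = integer(0),
                      ok = logical(0), note = character(0),
                      stringsAsFactors = FALSE)
  if (n_total == 0L) {
    attr(empty, "n_excluded") <- 0L
    return(empty)
  }
  set.seed(noise$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  rows <- vector("list", n_total)
  k <- 0L
  for (v in volumes_ml) {
    R <- radius_from_volume(v)
    phantom <- phantom_spec(center = c(0, 0, standoff_m + R), radius = R,
                            speed_of_sound = speed_of_sound)
    for (j in seq_len(reps)) {
      k <- k + 1L
      rep_noise <- noise_spec(noise$timing_jitter_sigma, noise$snr_db,
                              seed = rep_seeds[k])
      row <- list(true_volume_ml = v, est_volume_ml = NA_real_,
                  abs_err_ml = NA_real_, rel_err_pct = NA_real_,
                  seed = rep_seeds[k], rep = j, ok = FALSE, note = "")
      res <- tryCatch({
        sim <- simulate_measurement(phantom, geometry, pulse, rep_noise,
                                    sampling_rate)
        if (!sim$usable) stop("beam outside phantom")
        estimate_volume(sim$traces, config)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$note <- conditionMessage(res)
      } else {
        st <- error_stats(res$volume_V, v)
        row$est_volume_ml <- res$volume_V
        row$abs_err_ml <- st$abs_err_ea
        row$rel_err_pct <- st$rel_err_er
        row$ok <- TRUE
      }
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  n_excl <- sum(!out$ok)
  if (n_excl > 0L) {
    message(sprintf("batch_experiment: %d of %d measurements unusable, excluded from summaries",
                    n_excl, n_total))
  }
  attr(out, "n_excluded") <- n_excl
  out
}
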