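#' Acquisition / estimation configuration
#'
#' Everything the trace-to-volume pipeline needs to know about the
#' acquisition: the speed of sound in the coupling/bladder fluid, the
#' inter-beam angles, how to turn the three first-echo ranges into the
#' probe standoff, and the peak-detection policy.
#'
#' @param speed_of_sound m/s. Constrained to the physiological/bench range
#'   `[1400, 1650]` unless `allow_any_speed = TRUE`.
#' @param angles_deg Inter-beam angles (alpha, beta, gamma) in degrees,
#'   each in (0, 90). Degrees are the user-facing unit; radians are used
#'   internally.
#' @param standoff_strategy `"mean"` (default), `"min"` or `"fixed"`; see
#'   [estimate_standoff()].
#' @param standoff_fixed Fixed standoff in meters (required for
#'   `"fixed"`), e.g. 0.02 for a bench jig with a 2 cm gap.
#' @param peak A [peak_config()].
#' @param bandpass Optional `c(low, high)` Hz zero-phase band-pass applied
#'   before envelope extraction (see [hilbert_envelope()]); `NULL` by
#'   default, matching an analog receive chain that filters in hardware.
#' @param allow_any_speed Lift the speed-of-sound range check.
#' @return An object of class `acquisition_config` (carries a
#'   [beam_geometry()] in `geometry`).
#' @export
acquisition_config <- function(speed_of_sound = 1480,
                               angles_deg = c(10, 10, 10),
                               standoff_strategy = c("mean", "min", "fixed"),
                               standoff_fixed = NULL,
                               peak = peak_config(),
                               bandpass = NULL,
                               allow_any_speed = FALSE) {
  standoff_strategy <- match.arg(standoff_strategy)
  if (!allow_any_speed &&
      (speed_of_sound < 1400 || speed_of_sound > 1650)) {
    stop("speed_of_sound outside [1400, 1650] m/s; set allow_any_speed = TRUE to override")
  }
  if (length(angles_deg) == 1L) angles_deg <- rep(angles_deg, 3L)
  if (length(angles_deg) != 3L || any(angles_deg <= 0) || any(angles_deg >= 90)) {
    stop("angles_deg must be three angles strictly inside (0, 90) degrees")
  }
  if (standoff_strategy == "fixed" && is.null(standoff_fixed)) {
    stop("standoff_strategy 'fixed' requires standoff_fixed (meters)")
  }
  ang <- angles_deg * pi / 180
  structure(
    list(speed_of_sound = speed_of_sound,
         angles_deg = angles_deg,
         geometry = beam_geometry(ang[1], ang[2], ang[3]),
         standoff_strategy = standoff_strategy,
         standoff_fixed = standoff_fixed,
         peak = peak, bandpass = bandpass),
    class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> S=%g m/s, angles=(%g, %g, %g) deg, standoff=%s\n",
              x$speed_of_sound, x$angles_deg[1], x$angles_deg[2], x$angles_deg[3],
              if (x$standoff_strategy == "fixed")
                sprintf("fixed %.4g m", x$standoff_fixed)
              else x$standoff_strategy))
  invisible(x)
}

#' Estimate bladder volume from three A-mode traces
#'
#' The full estimation chain: per-beam Hilbert envelope, two-echo peak
#' detection, time-of-flight to near/far ranges, standoff summary, chord
#' triangle, apex localization, circumscribed-sphere solve, volume. Any
#' stage failure raises an error naming the offending beam; a silent wrong
#' number is never returned.
#'
#' @param traces List of three [echo_trace()] with distinct `beam_id`s
#'   (any order; beams are sorted by id).
#' @param config An [acquisition_config()].
#' @return An object of class `volume_estimate`: `volume_V` (mL),
#'   `radius_R` (m), and a `diagnostics` list with per-beam near/far
#'   distances (m), echo times, standoff used and strategy, chosen
#'   quadratic root, sphere residual (m) and any peak-picker warnings.
#' @export
estimate_volume <- function(traces, config = acquisition_config()) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!is.list(traces) || length(traces) != 3L ||
      !all(vapply(traces, inherits, logical(1), "echo_trace"))) {
    stop("traces must be a list of three echo_trace objects")
  }
  ids <- vapply(traces, function(x) x$beam_id, integer(1))
  if (anyDuplicated(ids) || !setequal(ids, 1:3)) {
    stop("traces must carry distinct beam_ids 1, 2, 3")
  }
  traces <- traces[order(ids)]
  times <- lapply(traces, function(tr) {
    detect_two_echoes(hilbert_envelope(tr, bandpass = config$bandpass),
                      config$peak)
  })
  near <- vapply(times, function(x) tof_to_distance(x$dt_near, config$speed_of_sound), 0)
  far <- vapply(times, function(x) tof_to_distance(x$dt_far, config$speed_of_sound), 0)
  h <- estimate_standoff(near, config$standoff_strategy, config$standoff_fixed)
  tri <- chord_lengths(far, config$geometry)
  apex <- apex_position(tri, far)
  sph <- solve_sphere(apex, tri, h, near_distances = near, far_distances = far)
  warns <- Filter(Negate(is.null), lapply(times, function(x) x$diagnostics$warning))
  structure(
    list(volume_V = sphere_volume(sph$R),
         radius_R = sph$R,
         diagnostics = list(
           near_distances_m = near, far_distances_m = far,
           dt_near_s = vapply(times, `[[`, 0, "dt_near"),
           dt_far_s = vapply(times, `[[`, 0, "dt_far"),
           standoff_m = h, standoff_strategy = config$standoff_strategy,
           root_used = sph$root_used, residual_m = sph$residual,
           q_m = sph$q, warnings = warns)),
    class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> V = %.0f mL (R = %.2f cm, residual %.2g m)\n",
              round(x$volume_V), x$radius_R * 100, x$diagnostics$residual_m))
  invisible(x)
}

#' Absolute and relative volume error
#'
#' `abs_err = |x - a|` and `rel_err = 100 * |x - a| / a` (percent), the
#' standard accuracy metrics for a volumetry bench test.
#'
#' @param measured_x Measured volume, mL.
#' @param true_a True volume, mL, `> 0`.
#' @return A list of class `error_stats`: `measured_x`, `true_a`,
#'   `abs_err_ea` (mL), `rel_err_er` (percent).
#' @examples
#' error_stats(135, 120)  # 15 mL absolute, 12.5 % relative
#' @export
error_stats <- function(measured_x, true_a) {
  if (any(!is.finite(true_a)) || any(true_a <= 0)) {
    stop("true volume must be positive")
  }
  ea <- abs(measured_x - true_a)
  structure(list(measured_x = measured_x, true_a = true_a,
                 abs_err_ea = ea, rel_err_er = 100 * ea / true_a),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> x=%.4g mL, a=%.4g mL: abs %.4g mL, rel %.4g %%\n",
              x$measured_x, x$true_a, x$abs_err_ea, x$rel_err_er))
  invisible(x)
}

#' Summarize a sweep results table
#'
#' Per-volume and overall mean/max relative error over the usable rows of
#' a [batch_experiment()] table.
#'
#' @param results A [batch_experiment()] data frame.
#' @return A list: `per_volume` (data frame with `true_volume_ml`, `n`,
#'   `mean_rel_err_pct`, `max_rel_err_pct`), `overall_mean_rel_err_pct`,
#'   `overall_max_rel_err_pct`, `n_runs`, `n_excluded`.
#' @export
experiment_summary <- function(results) {
  ok <- results[results$ok, , drop = FALSE]
  per <- if (nrow(ok) == 0L) {
    data.frame(true_volume_ml = numeric(0), n = integer(0),
               mean_rel_err_pct = numeric(0), max_rel_err_pct = numeric(0))
  } else {
    agg <- lapply(split(ok, ok$true_volume_ml), function(d) {
      data.frame(true_volume_ml = d$true_volume_ml[1], n = nrow(d),
                 mean_rel_err_pct = mean(d$rel_err_pct),
                 max_rel_err_pct = max(d$rel_err_pct))
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out[order(out$true_volume_ml), , drop = FALSE]
  }
  list(per_volume = per,
       overall_mean_rel_err_pct = if (nrow(ok)) mean(ok$rel_err_pct) else NA_real_,
       overall_max_rel_err_pct = if (nrow(ok)) max(ok$rel_err_pct) else NA_real_,
       n_runs = nrow(ok),
       n_excluded = attr(results, "n_excluded") %||% sum(!results$ok))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulated sweep and write results to disk
#'
#' Orchestrates [batch_experiment()] and writes `results.csv` (one row per
#' rep, full precision) and `summary.json` (per-volume and overall
#' mean/max relative error) into `out_dir`. Identical inputs and seed give
#' byte-identical output files.
#'
#' @param volumes_ml True volumes in mL; default the ten-balloon sweep
#'   120-480 mL in 40 mL steps. May be empty (empty outputs, no error).
#' @param reps Repetitions per volume.
#' @param jitter_mm One-way range jitter sigma in millimeters.
#' @param snr_db Additive-noise SNR in dB (`Inf` = clean).
#' @param seed Base seed for the rep-seed schedule.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param speed_of_sound,angles_deg,standoff_strategy,standoff_fixed,sampling_rate
#'   Forwarded to the simulator / [acquisition_config()].
#' @return Invisibly, a list with `results` (data frame), `summary`, and
#'   the paths written (or `NULL`).
#' @export
run_experiment <- function(volumes_ml = seq(120, 480, by = 40),
                           reps = 20, jitter_mm = 0.5, snr_db = Inf,
                           seed = 42L, out_dir = NULL,
                           speed_of_sound = 1480,
                           angles_deg = c(10, 10, 10),
                           standoff_strategy = "mean",
                           standoff_fixed = NULL,
                           sampling_rate = 1e8) {
  ang <- angles_deg * pi / 180
  if (length(ang) == 1L) ang <- rep(ang, 3L)
  geometry <- beam_geometry(ang[1], ang[2], ang[3])
  config <- acquisition_config(speed_of_sound = speed_of_sound,
                               angles_deg = angles_deg,
                               standoff_strategy = standoff_strategy,
                               standoff_fixed = standoff_fixed)
  results <- batch_experiment(
    volumes_ml, reps, geometry = geometry,
    noise = noise_spec(timing_jitter_sigma = jitter_mm * 1e-3,
                       snr_db = snr_db, seed = seed),
    sampling_rate = sampling_rate,
    speed_of_sound = speed_of_sound,
    config = config)
  summ <- experiment_summary(results)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "results.csv")
    jsn <- file.path(out_dir, "summary.json")
    df <- results
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "seed"
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summ, jsn, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
    paths <- c(results = csv, summary = jsn)
  }
  invisible(list(results = results, summary = summ, paths = paths))
}
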