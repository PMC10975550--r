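# Forward-model helpers shared across the tests: build exact three-beam
# phantom configurations and synthetic pulses independently of the code
# paths under test.

# Gaussian-modulated sinusoid sampled at fs, pulse center at tc.
make_pulse_trace <- function(centers_s, fs = 1e8, duration_s = NULL,
                             fc = 3e6, sigma_t = 1.77e-7, amps = NULL,
                             beam_id = 1L, noise_sd = 0) {
  if (is.null(duration_s)) duration_s <- max(centers_s) + 20 * sigma_t
  t <- seq(0, duration_s, by = 1 / fs)
  if (is.null(amps)) amps <- rep(1, length(centers_s))
  sig <- numeric(length(t))
  for (k in seq_along(centers_s)) {
    tt <- t - centers_s[k]
    sig <- sig + amps[k] * exp(-tt^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * tt)
  }
  if (noise_sd > 0) sig <- sig + rnorm(length(sig), 0, noise_sd)
  echo_trace(sig, fs, emission_time = 0, beam_id = beam_id)
}

# A random sphere below the probe with a three-beam fan guaranteed to hit
# it, plus every exact intermediate quantity. Probe apex at the origin,
# beams toward +z. Returns NULL if any beam misses (caller redraws).
random_hit_config <- function() {
  R <- runif(1, 0.02, 0.06)
  standoff <- runif(1, 0.01, 0.05)
  lateral <- (runif(2, -1, 1)) * 0.2 * R
  center <- c(lateral, standoff + R + runif(1, 0, 0.01))
  # a mildly asymmetric narrow fan aimed at the sphere center
  axis <- center / sqrt(sum(center^2))
  fan <- vapply(1:3, function(i) {
    phi <- 2 * pi * (i - 1) / 3 + runif(1, -0.3, 0.3)
    delta <- runif(1, 0.05, 0.12)  # half-angle, radians
    v <- c(sin(delta) * cos(phi), sin(delta) * sin(phi), cos(delta))
    Rb <- bladdervol:::.rotation_between(c(0, 0, 1), axis)
    as.numeric(Rb %*% v)
  }, numeric(3))
  fan <- t(fan)  # rows are unit beam vectors
  phantom <- phantom_spec(center, R)
  hits <- lapply(1:3, function(i) {
    ray_sphere_intersections(c(0, 0, 0), fan[i, ], phantom)
  })
  if (any(vapply(hits, is.null, logical(1)))) return(NULL)
  near <- vapply(hits, `[[`, 0, "near")
  far <- vapply(hits, `[[`, 0, "far")
  ang <- function(u, v) acos(min(1, max(-1, sum(u * v))))
  alpha <- ang(fan[1, ], fan[2, ])
  beta <- ang(fan[2, ], fan[3, ])
  gamma <- ang(fan[3, ], fan[1, ])
  pts <- lapply(1:3, function(i) far[i] * fan[i, ])       # A, B, C
  near_pts <- lapply(1:3, function(i) near[i] * fan[i, ]) # A', B', C'
  list(phantom = phantom, fan = fan,
       near = near, far = far,
       alpha = alpha, beta = beta, gamma = gamma,
       h_exact = sqrt(sum(center^2)) - R,
       far_points = pts, near_points = near_pts)
}

# Run the closed-form chain on one config; returns the sphere_solution.
solve_config <- function(cfg, h = cfg$h_exact) {
  geom <- beam_geometry(cfg$alpha, cfg$beta, cfg$gamma)
  tri <- chord_lengths(cfg$far, geom)
  apex <- apex_position(tri, cfg$far)
  solve_sphere(apex, tri, h, near_distances = cfg$near,
               far_distances = cfg$far)
}
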