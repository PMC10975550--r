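test_that("chord lengths follow the law of cosines and reject degenerate fans", {
  # isoceles right case: two unit ranges at 90 degrees give a sqrt(2) chord
  geom <- beam_geometry(pi / 2 - 1e-9, pi / 3, pi / 3)
  tri <- chord_lengths(c(1, 1, 1), geom)
  expect_equal(tri$l, sqrt(2), tolerance = 1e-6)

  # symmetric 10 degree fan at equal range d: equilateral with side 2 d sin(5 deg)
  d <- 0.08
  geom10 <- beam_geometry(pi / 18, pi / 18, pi / 18)
  tri10 <- chord_lengths(c(d, d, d), geom10)
  side <- 2 * d * sin(pi / 36)
  expect_equal(c(tri10$l, tri10$m, tri10$n), rep(side, 3), tolerance = 1e-12)
  expect_equal(tri10$theta, pi / 3, tolerance = 1e-9)
  expect_equal(tri10$circumradius_r, side / sqrt(3), tolerance = 1e-12)

  # near-coincident rays collapse a side
  expect_error(chord_lengths(c(1, 1, 1), beam_geometry(1e-13, 0.3, 0.3)),
               "degenerate")
  expect_error(chord_lengths(c(1, -1, 1), geom10), "positive")
})

test_that("apex position inverts the forward distance model", {
  # symmetric case: apex sits above the centroid of the equilateral base
  d <- 0.08
  geom10 <- beam_geometry(pi / 18, pi / 18, pi / 18)
  tri10 <- chord_lengths(c(d, d, d), geom10)
  apex <- apex_position(tri10, c(d, d, d))
  expect_equal(apex$xp, tri10$l / 2, tolerance = 1e-12)
  expect_equal(apex$yp, tri10$l / (2 * sqrt(3)), tolerance = 1e-9)

  # forward/backward round trip over random configurations
  set.seed(101)
  for (k in 1:50) {
    # apex well above a compact base triangle keeps all inter-beam
    # angles acute, as a physical probe fan requires
    A <- c(0, 0, 0)
    B <- c(runif(1, 0.02, 0.08), 0, 0)
    C <- c(runif(1, -0.04, 0.08), runif(1, 0.02, 0.08), 0)
    P <- c(runif(1, -0.02, 0.08), runif(1, -0.02, 0.08), runif(1, 0.12, 0.3))
    h <- sqrt(c(sum((P - A)^2), sum((P - B)^2), sum((P - C)^2)))
    l <- sqrt(sum((A - B)^2)); m <- sqrt(sum((B - C)^2)); n <- sqrt(sum((A - C)^2))
    ang <- function(hi, hj, side) acos((hi^2 + hj^2 - side^2) / (2 * hi * hj))
    geom <- beam_geometry(ang(h[1], h[2], l), ang(h[2], h[3], m), ang(h[3], h[1], n))
    tri <- chord_lengths(h, geom)
    expect_equal(c(tri$l, tri$m, tri$n), c(l, m, n), tolerance = 1e-9)
    got <- apex_position(tri, h)
    expect_equal(c(got$xp, got$yp, got$zp), P, tolerance = 1e-10)
    # distance equations hold
    verts <- rbind(A, B, C)
    dd <- sqrt(rowSums(sweep(verts, 2, c(got$xp, got$yp, got$zp))^2))
    expect_equal(unname(dd), h, tolerance = 1e-9)
  }

  # inconsistent distances have no real apex height
  tri <- chord_lengths(c(1, 1, 1), beam_geometry(0.6, 0.6, 0.6))
  expect_error(apex_position(tri, c(0.3, 0.3, 0.3)), "inconsistent")
})

test_that("solve_sphere recovers a known phantom from exact ranges", {
  # sphere R = 3 cm, center 5 cm below the apex, symmetric 10 degree fan
  geom <- beam_geometry(pi / 18, pi / 18, pi / 18)
  phantom <- phantom_spec(c(0, 0, 0.05), 0.03)
  hits <- apply(geom$unit_directions, 1, function(d) {
    ray_sphere_intersections(c(0, 0, 0), d, phantom)
  })
  near <- hits["near", ]; far <- hits["far", ]
  tri <- chord_lengths(far, geom)
  apex <- apex_position(tri, far)
  sol <- solve_sphere(apex, tri, standoff_h = 0.02,
                      near_distances = near, far_distances = far)
  expect_equal(sol$R, 0.03, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-9)
  # |OP| = R + h and R^2 = r^2 + q^2 close the construction
  P <- c(apex$xp, apex$yp, apex$zp)
  expect_equal(sqrt(sum((sol$center_O - P)^2)), sol$R + 0.02, tolerance = 1e-9)
  expect_equal(sol$R^2, tri$circumradius_r^2 + sol$q^2, tolerance = 1e-12)
})

test_that("solve_sphere agrees with the four-point sphere fit on random configurations", {
  set.seed(202)
  n_ok <- 0
  while (n_ok < 200) {
    cfg <- random_hit_config()
    if (is.null(cfg)) next
    n_ok <- n_ok + 1
    sol <- solve_config(cfg)
    oracle <- fit_sphere_four_points(cfg$far_points[[1]], cfg$far_points[[2]],
                                     cfg$far_points[[3]], cfg$near_points[[1]])
    expect_equal(sol$R, oracle$radius, tolerance = 1e-8)
    expect_equal(sol$R, cfg$phantom$radius, tolerance = 1e-8)
    # far-wall points (and the near point, in the probe frame) are
    # equidistant from the fitted center
    dists <- vapply(c(cfg$far_points, cfg$near_points[1]), function(p) {
      sqrt(sum((p - oracle$center)^2))
    }, numeric(1))
    expect_equal(dists, rep(oracle$radius, 4), tolerance = 1e-8)
  }
})

test_that("the reconstruction is scale equivariant", {
  set.seed(303)
  cfg <- NULL
  while (is.null(cfg)) cfg <- random_hit_config()
  sol1 <- solve_config(cfg)
  for (k in c(0.5, 2, 10)) {
    cfgk <- cfg
    cfgk$far <- k * cfg$far
    cfgk$near <- k * cfg$near
    cfgk$h_exact <- k * cfg$h_exact
    solk <- solve_config(cfgk)
    expect_equal(solk$R, k * sol1$R, tolerance = 1e-9)
    expect_equal(sphere_volume(solk$R), k^3 * sphere_volume(sol1$R),
                 tolerance = 1e-8)
  }
})

test_that("sphere_volume converts radius to milliliters", {
  expect_identical(sphere_volume(0), 0)
  expect_equal(sphere_volume(0.01), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(sphere_volume(radius_from_volume(120)), 120, tolerance = 1e-10)
  expect_error(sphere_volume(-1), "nonnegative")
  # strictly increasing in R
  r <- seq(0.01, 0.06, length.out = 25)
  expect_true(all(diff(sphere_volume(r)) > 0))
  # chord length strictly increasing in the inter-beam angle (kept within
  # the realizable range alpha <= beta + gamma)
  ls <- vapply(seq(0.05, 1.45, length.out = 25), function(a) {
    chord_lengths(c(1, 1, 1), beam_geometry(a, 0.75, 0.75))$l
  }, numeric(1))
  expect_true(all(diff(ls) > 0))
})

test_that("estimate_standoff supports mean, min and fixed strategies", {
  expect_equal(estimate_standoff(c(0.020, 0.020, 0.020), "mean"), 0.020)
  expect_equal(estimate_standoff(c(0.021, 0.020, 0.022), "min"), 0.020)
  expect_equal(estimate_standoff(strategy = "fixed", fixed_value = 0.02), 0.02)
  expect_error(estimate_standoff(c(0.02, 0.02, 0.02), "fixed"), "fixed_value")

  # axisymmetric phantom: the min-strategy slant bias is bounded by the
  # fan opening, |bias| <= (1 - cos(10 deg)) * |OP|
  geom <- beam_geometry(pi / 18, pi / 18, pi / 18)
  R <- radius_from_volume(200)
  phantom <- phantom_spec(c(0, 0, 0.02 + R), R)
  near <- apply(geom$unit_directions, 1, function(d) {
    ray_sphere_intersections(c(0, 0, 0), d, phantom)[["near"]]
  })
  h_true <- 0.02
  bias <- abs(estimate_standoff(near, "min") - h_true)
  expect_lt(bias, (1 - cos(pi / 18)) * (0.02 + R))
})

test_that("ray_sphere_intersections matches brute-force marching", {
  phantom <- phantom_spec(c(0, 0, 5), 3, speed_of_sound = 1480)
  expect_equal(ray_sphere_intersections(c(0, 0, 0), c(0, 0, 1), phantom),
               c(near = 2, far = 8))
  # tangent ray: grazes at x = 3
  expect_null(ray_sphere_intersections(c(3, 0, 0), c(0, 0, 1), phantom))
  # clear miss
  expect_null(ray_sphere_intersections(c(10, 0, 0), c(0, 0, 1), phantom))
  expect_error(ray_sphere_intersections(c(0, 0, 0), c(0, 0, 2), phantom), "unit")

  set.seed(404)
  for (k in 1:20) {
    cfg <- random_hit_config()
    if (is.null(cfg)) next
    d <- cfg$fan[1, ]
    got <- ray_sphere_intersections(c(0, 0, 0), d, cfg$phantom)
    # march along the ray and bracket the surface crossings
    ts <- seq(0, 0.5, by = 1e-7)
    inside <- sqrt(colSums((outer(d, ts) - cfg$phantom$center)^2)) < cfg$phantom$radius
    crossings <- ts[which(diff(inside) != 0)]
    expect_equal(unname(got), crossings[1:2], tolerance = 2e-6)
  }
})

test_that("fit_sphere_four_points solves the exact interpolation problem", {
  fit <- fit_sphere_four_points(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)

  set.seed(505)
  for (k in 1:25) {
    ctr <- runif(3, -1, 1)
    R <- runif(1, 0.5, 2)
    pts <- lapply(1:4, function(i) {
      v <- rnorm(3); ctr + R * v / sqrt(sum(v^2))
    })
    fit <- do.call(fit_sphere_four_points, pts)
    expect_equal(fit$center, ctr, tolerance = 1e-9)
    expect_equal(fit$radius, R, tolerance = 1e-10)
  }
  expect_error(
    fit_sphere_four_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    "coplanar")
})
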