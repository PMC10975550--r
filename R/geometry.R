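#' Beam-fan geometry of a triple-element probe
#'
#' Describes the angular layout of the three ultrasound beams leaving the
#' probe apex P: the pairwise angles between beams PA-PB (`alpha`), PB-PC
#' (`beta`) and PC-PA (`gamma`), plus the probe standoff `h` (distance from
#' the probe face to the near bladder wall).
#'
#' @param alpha,beta,gamma Pairwise inter-beam angles in radians, each in
#'   (0, pi/2). The angles must be realizable by three unit vectors in 3-D,
#'   i.e. the Gram matrix of their cosines must be positive semidefinite.
#' @param standoff_h Probe-to-bladder distance in meters, `>= 0`.
#' @return An object of class `beam_geometry` with fields `alpha`, `beta`,
#'   `gamma`, `standoff_h` and `unit_directions` (a 3 x 3 matrix whose rows
#'   are the beam unit vectors, used only by the forward simulator).
#' @seealso [beam_fan()] for the unit-vector construction.
#' @examples
#' beam_geometry(pi / 18, pi / 18, pi / 18)  # the symmetric 10 degree fan
#' @export
beam_geometry <- function(alpha, beta, gamma, standoff_h = 0) {
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= pi / 2)) {
    stop("beam angles must lie strictly inside (0, pi/2)")
  }
  if (!is.finite(standoff_h) || standoff_h < 0) {
    stop("standoff_h must be a nonnegative length in meters")
  }
  dirs <- beam_fan(alpha, beta, gamma)
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         standoff_h = standoff_h, unit_directions = dirs),
    class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<beam_geometry> alpha=%.4f beta=%.4f gamma=%.4f rad, standoff h=%.4g m\n",
    x$alpha, x$beta, x$gamma, x$standoff_h))
  invisible(x)
}

#' Chord triangle of the three far-wall reflection points
#'
#' The three far-wall echoes locate points A, B, C on the lower bladder
#' wall at ranges `h1, h2, h3` from the probe apex P. The law of cosines
#' gives the chord lengths `l = AB`, `m = BC`, `n = AC`:
#' \deqn{l^2 = h_1^2 + h_2^2 - 2 h_1 h_2 \cos\alpha}
#' and cyclically for `m` (with `beta`) and `n` (with `gamma`). The base
#' angle `theta = angle BAC` then follows from the triangle itself, and the
#' circumradius is `r = m / (2 sin theta)`.
#'
#' @param far_distances Numeric length-3, far-wall ranges `h1, h2, h3` in
#'   meters, all positive.
#' @param geometry A [beam_geometry()].
#' @return An object of class `chord_triangle` with fields `l`, `m`, `n`
#'   (meters), `theta` (radians), `circumradius_r` (meters) and
#'   `circumcenter_O1` (3-vector in the triangle frame, see Details).
#' @details The triangle frame places A at the origin, B at `(l, 0, 0)` and
#'   C at `(n cos theta, n sin theta, 0)`; the circumcenter is
#'   `(l/2, yc, 0)` with the signed ordinate `yc = (n - l cos theta) /
#'   (2 sin theta)` — its magnitude is `sqrt(r^2 - l^2/4)`, but the sign is
#'   negative for triangles whose circumcenter falls below the AB edge.
#' @export
chord_lengths <- function(far_distances, geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  h <- as.numeric(far_distances)
  if (length(h) != 3L || any(!is.finite(h)) || any(h <= 0)) {
    stop("far_distances must be three positive finite lengths in meters")
  }
  l2 <- h[1]^2 + h[2]^2 - 2 * h[1] * h[2] * cos(geometry$alpha)
  m2 <- h[2]^2 + h[3]^2 - 2 * h[2] * h[3] * cos(geometry$beta)
  n2 <- h[3]^2 + h[1]^2 - 2 * h[3] * h[1] * cos(geometry$gamma)
  sides <- sqrt(pmax(c(l2, m2, n2), 0))
  names(sides) <- c("l", "m", "n")
  tiny <- 1e-12 * max(h)
  if (any(sides <= tiny)) {
    stop(sprintf("degenerate chord triangle: side %s collapses (coincident rays)",
                 names(sides)[which.max(sides <= tiny)]))
  }
  srt <- sort(sides)
  if (srt[3] >= srt[1] + srt[2] - tiny) {
    stop(sprintf("degenerate chord triangle: side %s violates the triangle inequality",
                 names(sides)[which.max(sides)]))
  }
  l <- sides[["l"]]; m <- sides[["m"]]; n <- sides[["n"]]
  # angle at A between AB (length l) and AC (length n), opposite side m = BC
  cos_theta <- (l^2 + n^2 - m^2) / (2 * l * n)
  cos_theta <- min(1, max(-1, cos_theta))
  theta <- acos(cos_theta)
  if (sin(theta) < 1e-6) {
    stop("degenerate chord triangle: sin(theta) below tolerance (collinear A, B, C)")
  }
  r <- m / (2 * sin(theta))
  # signed circumcenter ordinate: (n - l cos theta) / (2 sin theta).
  # |yc| = sqrt(r^2 - l^2/4), but yc itself is negative when the
  # circumcenter falls below the AB edge (obtuse angle at C).
  yc <- (n - l * cos_theta) / (2 * sin(theta))
  structure(
    list(l = l, m = m, n = n, theta = theta,
         circumradius_r = r, circumcenter_O1 = c(l / 2, yc, 0)),
    class = "chord_triangle")
}

#' @export
print.chord_triangle <- function(x, ...) {
  cat(sprintf(
    "<chord_triangle> l=%.5g m=%.5g n=%.5g m, theta=%.4f rad, r=%.5g m\n",
    x$l, x$m, x$n, x$theta, x$circumradius_r))
  invisible(x)
}

#' Probe apex position from three far-wall ranges
#'
#' Places the probe apex P = (xp, yp, zp) in the triangle frame by solving
#' the three sphere equations `|P - A| = h1`, `|P - B| = h2`, `|P - C| = h3`
#' in closed form: subtracting the equations pairwise linearizes xp and yp,
#' and zp follows as the positive square root (the mirror solution zp < 0 is
#' geometrically equivalent and never returned).
#'
#' @param triangle A [chord_lengths()] result.
#' @param far_distances The same three far-wall ranges (meters) the triangle
#'   was built from.
#' @param tol Absolute tolerance in meters for the zp discriminant: values in
#'   `(-tol, tol)` are treated as a coplanar (degenerate) apex, values below
#'   `-tol` as inconsistent distances.
#' @return An object of class `apex_solution` with fields `xp`, `yp`, `zp`
#'   (meters).
#' @export
apex_position <- function(triangle, far_distances, tol = 1e-9) {
  stopifnot(inherits(triangle, "chord_triangle"))
  h <- as.numeric(far_distances)
  if (length(h) != 3L || any(!is.finite(h)) || any(h <= 0)) {
    stop("far_distances must be three positive finite lengths in meters")
  }
  l <- triangle$l; n <- triangle$n; theta <- triangle$theta
  xp <- (h[1]^2 - h[2]^2 + l^2) / (2 * l)
  yp <- (h[1]^2 - h[3]^2 + n^2 - 2 * xp * n * cos(theta)) / (2 * n * sin(theta))
  disc <- h[1]^2 - xp^2 - yp^2
  if (disc < -tol * h[1]) {
    stop("inconsistent far distances: apex has no real height above the chord plane")
  }
  zp <- sqrt(max(disc, 0))
  if (zp <= sqrt(tol * h[1])) {
    stop("degenerate apex: probe coplanar with the far-wall points A, B, C")
  }
  structure(list(xp = xp, yp = yp, zp = zp), class = "apex_solution")
}

#' @export
print.apex_solution <- function(x, ...) {
  cat(sprintf("<apex_solution> P = (%.6g, %.6g, %.6g) m\n", x$xp, x$yp, x$zp))
  invisible(x)
}

#' Circumscribed-sphere radius from apex, chord triangle and standoff
#'
#' Closes the three-point localization geometry. The sphere center O lies on
#' the axis through the circumcenter of A, B, C at `O = (l/2, yc, q)` (with
#' `yc` the signed circumcenter ordinate, `|yc| = sqrt(4r^2 - l^2)/2`), and
#' the probe sits one standoff above the near wall, so `|OP| = R + h`.
#' Expanding `|OP|^2 = (R + h)^2` and using `xp^2 + yp^2 + zp^2 = h1^2`
#' gives the affine relation
#' \deqn{q = \frac{1}{2 z_p}\left(h_1^2 - l x_p - 2 y_p y_c
#'        - 2 R h - h^2\right) = A - B R,}
#' with `B = h / zp`. Substituting into the radius constraint
#' `R^2 = r^2 + q^2` yields the quadratic
#' \deqn{(1 - B^2) R^2 + 2 A B R - (r^2 + A^2) = 0,}
#' solved in closed form.
#'
#' Root policy: candidates must have `R > 0` and `sign(q) = sign(zp)` (the
#' far-wall points lie on the cap opposite the probe, so the center sits
#' between the probe and the chord plane). If two candidates survive and
#' `near_distances` are supplied, the root whose predicted near-wall ranges
#' (ray-sphere intersection along PA, PB, PC) best match them is chosen;
#' without near distances an ambiguity error is raised.
#'
#' @param apex An [apex_position()] result.
#' @param triangle The [chord_lengths()] result.
#' @param standoff_h Probe standoff `h` in meters, `>= 0`.
#' @param near_distances Optional three near-wall ranges (meters), used only
#'   to disambiguate when both quadratic roots are admissible.
#' @param far_distances Optional three far-wall ranges (meters); required
#'   together with `near_distances` for disambiguation (they define the beam
#'   directions).
#' @return An object of class `sphere_solution` with fields `q`, `R`,
#'   `center_O`, `residual` (max absolute distance mismatch of O to A, B, C,
#'   meters) and `root_used` (1 or 2, index into the sorted real roots).
#' @export
solve_sphere <- function(apex, triangle, standoff_h,
                         near_distances = NULL, far_distances = NULL) {
  stopifnot(inherits(apex, "apex_solution"), inherits(triangle, "chord_triangle"))
  if (!is.finite(standoff_h) || standoff_h < 0) {
    stop("standoff_h must be a nonnegative length in meters")
  }
  l <- triangle$l
  r <- triangle$circumradius_r
  yc <- triangle$circumcenter_O1[2]  # signed; |yc| = sqrt(4 r^2 - l^2) / 2
  xp <- apex$xp; yp <- apex$yp; zp <- apex$zp
  h1sq <- xp^2 + yp^2 + zp^2
  A <- (h1sq - l * xp - 2 * yp * yc - standoff_h^2) / (2 * zp)
  B <- standoff_h / zp
  # (1 - B^2) R^2 + 2 A B R - (r^2 + A^2) = 0
  a2 <- 1 - B^2
  a1 <- 2 * A * B
  a0 <- -(r^2 + A^2)
  roots <- if (abs(a2) < 1e-15) {
    if (abs(a1) < 1e-15) numeric(0) else -a0 / a1
  } else {
    disc <- a1^2 - 4 * a2 * a0
    if (disc < 0) numeric(0) else (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  }
  roots <- sort(roots[is.finite(roots)])
  cand <- which(roots > 0 & sign(A - B * roots) == sign(zp))
  if (length(cand) == 0L) {
    stop("no admissible sphere: quadratic has no positive root with the center on the probe side")
  }
  pick <- cand[1]
  if (length(cand) > 1L) {
    if (is.null(near_distances) || is.null(far_distances)) {
      stop(paste("ambiguous sphere solution: two admissible radii;",
                 "supply near (and far) distances or a root policy"))
    }
    errs <- vapply(cand, function(k) {
      .near_prediction_error(roots[k], A, B, triangle, apex,
                             near_distances, far_distances)
    }, numeric(1))
    pick <- cand[which.min(errs)]
  }
  R <- roots[pick]
  q <- A - B * R
  center <- c(l / 2, yc, q)
  verts <- rbind(c(0, 0, 0),
                 c(l, 0, 0),
                 c(triangle$n * cos(triangle$theta),
                   triangle$n * sin(triangle$theta), 0))
  dists <- sqrt(rowSums(sweep(verts, 2, center)^2))
  structure(
    list(q = q, R = R, center_O = center,
         residual = max(abs(dists - R)), root_used = pick),
    class = "sphere_solution")
}

# Predicted-vs-measured near-wall mismatch for one candidate radius, used to
# break the (rare) two-positive-root tie in solve_sphere.
.near_prediction_error <- function(R, A, B, triangle, apex,
                                   near_distances, far_distances) {
  q <- A - B * R
  center <- c(triangle$l / 2, triangle$circumcenter_O1[2], q)
  P <- c(apex$xp, apex$yp, apex$zp)
  verts <- rbind(c(0, 0, 0),
                 c(triangle$l, 0, 0),
                 c(triangle$n * cos(triangle$theta),
                   triangle$n * sin(triangle$theta), 0))
  phantom <- phantom_spec(center = center, radius = R)
  err <- 0
  for (i in 1:3) {
    d <- (verts[i, ] - P) / far_distances[i]
    hit <- ray_sphere_intersections(P, d, phantom)
    if (is.null(hit)) return(Inf)
    err <- err + abs(hit[["near"]] - near_distances[i])
  }
  err
}

#' @export
print.sphere_solution <- function(x, ...) {
  cat(sprintf("<sphere_solution> R=%.6g m, q=%.6g m, residual=%.3g m\n",
              x$R, x$q, x$residual))
  invisible(x)
}

#' Sphere volume in milliliters
#'
#' `V = (4/3) pi R^3`, with R in meters and the result converted to mL
#' (1 m^3 = 1e6 mL).
#'
#' @param R Sphere radius in meters, `>= 0`.
#' @return Volume in milliliters.
#' @examples
#' sphere_volume(0.01)  # a 1 cm radius sphere: 4 pi / 3 ~ 4.19 mL
#' @export
sphere_volume <- function(R) {
  if (any(!is.finite(R)) || any(R < 0)) stop("radius must be nonnegative")
  (4 / 3) * pi * R^3 * 1e6
}

#' Probe standoff from the first-echo ranges
#'
#' The geometry solver needs the probe-to-bladder distance `h`. Because each
#' first echo returns the slant range to the near wall along its own beam,
#' `h` must be summarized from the three near ranges (or fixed externally,
#' as in a bench setup with a known 2 cm gap).
#'
#' @param near_distances Three near-wall ranges in meters (may be `NULL`
#'   when `strategy = "fixed"`).
#' @param strategy One of `"mean"` (default), `"min"`, `"fixed"`.
#' @param fixed_value Standoff in meters, required when `strategy = "fixed"`.
#' @return Standoff `h` in meters.
#' @export
estimate_standoff <- function(near_distances = NULL,
                              strategy = c("mean", "min", "fixed"),
                              fixed_value = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value) || fixed_value < 0) {
      stop("strategy 'fixed' requires a nonnegative fixed_value in meters")
    }
    return(fixed_value)
  }
  h <- as.numeric(near_distances)
  if (length(h) != 3L || any(!is.finite(h)) || any(h <= 0)) {
    stop("near_distances must be three positive finite lengths in meters")
  }
  switch(strategy, mean = mean(h), min = min(h))
}

#' Spherical phantom specification
#'
#' A sphere standing in for the urine-filled bladder, expressed in the probe
#' frame (probe apex at the origin, beams pointing toward positive z).
#'
#' @param center Sphere center, 3-vector in meters.
#' @param radius Sphere radius in meters, `> 0`.
#' @param speed_of_sound Speed of sound in the coupling/bladder fluid, m/s.
#'   Defaults to 1480 (water near 20 C); use 1540 for a soft-tissue preset.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(center, radius, speed_of_sound = 1480) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("center must be a finite 3-vector in meters")
  }
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (!is.finite(speed_of_sound) || speed_of_sound <= 0) {
    stop("speed_of_sound must be positive")
  }
  structure(list(center = center, radius = radius,
                 speed_of_sound = speed_of_sound),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> center=(%.4g, %.4g, %.4g) m, R=%.4g m (%.1f mL), S=%g m/s\n",
    x$center[1], x$center[2], x$center[3], x$radius,
    sphere_volume(x$radius), x$speed_of_sound))
  invisible(x)
}

#' Ray-sphere intersection ranges
#'
#' Solves `|origin + t * direction - center| = radius` for the two positive
#' ray parameters; with a unit direction these are the near- and far-wall
#' ranges an A-mode beam would report.
#'
#' @param origin Ray origin, 3-vector in meters.
#' @param direction Unit 3-vector.
#' @param phantom A [phantom_spec()].
#' @param tol Tangency tolerance on the discriminant (in meters^2 scale);
#'   grazing rays are reported as misses.
#' @return A named numeric `c(near =, far =)` in meters, or `NULL` if the
#'   ray misses the sphere (including tangent rays and spheres behind the
#'   origin).
#' @export
ray_sphere_intersections <- function(origin, direction, phantom, tol = 1e-12) {
  stopifnot(inherits(phantom, "phantom_spec"))
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) stop("direction must be a unit vector")
  oc <- origin - phantom$center
  b <- sum(direction * oc)
  c0 <- sum(oc^2) - phantom$radius^2
  disc <- b^2 - c0
  if (disc <= tol) return(NULL)
  s <- sqrt(disc)
  ts <- c(-b - s, -b + s)
  ts <- ts[ts > 0]
  if (length(ts) < 2L) return(NULL)
  c(near = ts[1], far = ts[2])
}

#' Sphere through four points
#'
#' Independent oracle for the closed-form solver: the unique sphere through
#' four non-coplanar points, from the linear system obtained by subtracting
#' the quadratic constraints `|p_i - c|^2 = R^2` pairwise.
#'
#' @param p1,p2,p3,p4 3-vectors in meters.
#' @return A list with `center` (3-vector) and `radius` (meters).
#' @export
fit_sphere_four_points <- function(p1, p2, p3, p4) {
  P <- rbind(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
  if (ncol(P) != 3L || any(!is.finite(P))) stop("need four finite 3-vectors")
  M <- 2 * sweep(P[2:4, , drop = FALSE], 2, P[1, ])
  rhs <- rowSums(P[2:4, ]^2) - sum(P[1, ]^2)
  if (abs(det(M)) < 1e-12 * max(abs(M), .Machine$double.eps)^3) {
    stop("coplanar or coincident points: no unique sphere")
  }
  center <- tryCatch(solve(M, rhs), error = function(e) {
    stop("coplanar or coincident points: no unique sphere")
  })
  list(center = as.numeric(center),
       radius = sqrt(sum((P[1, ] - center)^2)))
}
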