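#' Rayleigh surface-wave speed on a NITI half-space
#'
#' Computes the speed of the fundamental Rayleigh mode propagating along the
#' free surface at angle `theta` from the symmetry (fiber) axis, by
#' root-finding the surface-wave boundary condition assembled with the Stroh
#' formalism.  At each trial speed the sextic Stroh eigenproblem is solved,
#' the three partial waves decaying with depth are selected, and the real
#' determinant of the Hermitian surface-impedance matrix is evaluated; its
#' lowest-speed zero in `(0, v_upper)` is the Rayleigh speed, with
#' `v_upper = (1 - 1e-6) * min(c_S(theta), c_qS(theta))` from the bulk shear
#' branches.  The root is bracketed by a coarse scan and refined by bisection
#' to relative tolerance `rel_tol`.
#'
#' Known limits used as checks throughout the package: for an isotropic
#' incompressible material `c_R = 0.9553 sqrt(mu/rho)` at every angle; at
#' `theta = 90` degrees the speed depends on `mu` only; the speed never
#' exceeds `sqrt(G/rho)` for fast-axis materials.
#'
#' @param params A [niti_params] object.
#' @param theta Propagation angle(s) from the symmetry axis, degrees; the
#'   speed is even in `theta` and 180-degree periodic.
#' @param rel_tol Relative tolerance of the root, default 1e-8.
#' @param n_scan Points in the coarse bracketing scan, default 64.
#' @return Speeds in m/s, vectorized over `theta`.
#' @examples
#' p <- niti_params(mu = 3e3, G = 3e3, delta = 0)
#' rayleigh_speed(p, 90) / sqrt(p$mu / p$rho)  # 0.9553
#' @export
rayleigh_speed <- function(params, theta, rel_tol = 1e-8, n_scan = 64) {
  r <- rayleigh_solve(params, theta, rel_tol, n_scan)
  bad <- which(!is.finite(r$speed))
  if (length(bad))
    abort(sprintf(
      "no Rayleigh root found at theta = %s deg: the boundary determinant has no sign change in the bracket",
      paste(theta[bad], collapse = ", ")), class = "nitioce_no_root")
  r$speed
}

# vectorized solver core; returns tibble(theta_deg, speed, residual)
rayleigh_solve <- function(params, theta, rel_tol = 1e-8, n_scan = 64) {
  check_niti_params(params)
  C <- niti_stiffness(params)
  th_fold <- fold_angle_90(theta)
  out <- vapply(th_fold, function(th) {
    # closed-form shear branches bound the bracket; the solver's
    # transonic-boundary refinement absorbs the small finite-lambda
    # difference between the closed-form and exact quasi-shear speeds.
    # At the symmetry directions the out-of-sagittal-plane branch
    # decouples and does not limit the surface wave.
    v_up <- (1 - 1e-6) *
      if (th %in% c(0, 90)) shear_speed(params, th)
      else min(shear_speed(params, th), quasi_shear_speed(params, th))
    root <- rayleigh_root_cpp(C, params$rho, th * pi / 180,
                              1e-3 * v_up, v_up, rel_tol, as.integer(n_scan))
    if (root$status != 0) c(NA_real_, NA_real_)
    else c(root$speed, root$residual)
  }, numeric(2))
  tibble(theta_deg = theta, speed = out[1, ], residual = out[2, ])
}

# fold an angle to [0, 90]: speeds are even in theta and 180-deg periodic
fold_angle_90 <- function(theta) {
  th <- abs(theta) %% 180
  ifelse(th > 90, 180 - th, th)
}

# fold an orientation into (-90, 90]
fold_angle_180 <- function(a) {
  a <- (a + 90) %% 180 - 90
  ifelse(a == -90, 90, a)
}

#' Angle-resolved Rayleigh-speed curve
#'
#' Evaluates [rayleigh_speed] over a grid of scan angles, with the material
#' symmetry axis offset by `alpha` from the scan's zero direction (so the
#' model speed at scan angle `a` is the speed at material angle `a - alpha`).
#'
#' @inheritParams rayleigh_speed
#' @param angles Scan angles, degrees; default the 13-direction acquisition
#'   grid `seq(-90, 90, by = 15)`.
#' @param alpha Symmetry-axis offset from the scan zero direction, degrees.
#' @return A tibble with columns `angle_deg` (scan frame), `theta_deg`
#'   (material frame, folded to `[0, 90]`), `speed_m_s`, and the solver
#'   `residual` (boundary-determinant value at the root, normalized).
#' @examples
#' rayleigh_curve(niti_params(mu = 2e3, G = 6e3, delta = 8e3), alpha = 10)
#' @export
rayleigh_curve <- function(params, angles = default_angle_grid(), alpha = 0,
                           rel_tol = 1e-8, n_scan = 64) {
  sol <- rayleigh_solve(params, angles - alpha, rel_tol, n_scan)
  bad <- which(!is.finite(sol$speed))
  if (length(bad))
    abort(sprintf("Rayleigh solver failed at scan angle(s) %s deg",
                  paste(angles[bad], collapse = ", ")),
          class = "nitioce_no_root")
  tibble(angle_deg = angles,
         theta_deg = fold_angle_90(angles - alpha),
         speed_m_s = sol$speed,
         residual = sol$residual)
}

#' Default acquisition angle grid
#'
#' The 13 propagation directions of the angle-resolved scan protocol:
#' -90 to +90 degrees in 15-degree steps.
#'
#' @return Numeric vector of 13 angles, degrees.
#' @export
default_angle_grid <- function() seq(-90, 90, by = 15)

#' Surface-wave secular residual
#'
#' The real-valued function of trial speed `v` whose lowest zero is the
#' Rayleigh speed: the real part of the determinant of the surface-impedance
#' matrix built from the three decaying Stroh partial waves, normalized by its
#' magnitude at the bracket midpoint.  Exposed for diagnostics and
#' root-bracketing studies.
#'
#' @inheritParams rayleigh_speed
#' @param theta Propagation angle, degrees (scalar).
#' @param v Trial speed(s), m/s, in `(0, v_upper)`.
#' @return Normalized residual(s), same length as `v`.
#' @export
secular_residual <- function(params, theta, v) {
  check_niti_params(params)
  stopifnot(length(theta) == 1)
  C <- niti_stiffness(params)
  th <- fold_angle_90(theta)
  v_up <- (1 - 1e-6) * min(shear_speed(params, th),
                           christoffel_speeds(params, th)$c_qS)
  if (any(v <= 0 | v >= v_up))
    abort(sprintf("trial speeds must lie in (0, %.4g) m/s", v_up),
          class = "nitioce_bad_bracket")
  raw <- stroh_residual_cpp(C, params$rho, th * pi / 180, v)
  mid <- stroh_residual_cpp(C, params$rho, th * pi / 180, v_up / 2)
  raw / abs(mid)
}
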