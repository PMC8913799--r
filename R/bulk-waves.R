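# Bulk-wave phase velocities in the plane containing the symmetry axis.
# Geometry matches the Stroh solver: symmetry axis Z, propagation direction
# n = (0, sin theta, cos theta), theta measured from the symmetry axis.

voigt_index <- function(i, j) {
  if (i == j) return(i)
  s <- i + j
  if (s == 5L) 4L else if (s == 4L) 5L else 6L
}

# M_ik = C_ijkl u_j w_l from the 6x6 Voigt matrix
contract_voigt <- function(C, u, w) {
  M <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    s <- 0
    for (j in 1:3) for (l in 1:3)
      s <- s + C[voigt_index(i, j), voigt_index(k, l)] * u[j] * w[l]
    M[i, k] <- s
  }
  M
}

christoffel_matrix <- function(C, theta_rad) {
  n <- c(0, sin(theta_rad), cos(theta_rad))
  contract_voigt(C, n, n)
}

#' Bulk-wave phase speeds from the Christoffel equation
#'
#' Solves the Christoffel eigenproblem \eqn{\Gamma u = \rho c^2 u} with
#' \eqn{\Gamma_{ik} = C_{ijkl} n_j n_l} for propagation at angle `theta` from
#' the symmetry (fiber) axis, in the plane containing that axis.  The three
#' branches are labelled by polarization: the branch polarized normal to the
#' plane containing the propagation direction and the symmetry axis is the
#' pure shear wave `c_S`; the in-plane pair are quasi-shear `c_qS` and
#' quasi-longitudinal `c_qL`.  Small negative eigenvalues from round-off are
#' clipped to zero (tolerance `1e-9 * lambda`).
#'
#' @param params A [niti_params] object.
#' @param theta Propagation angle(s) from the symmetry axis, degrees.
#' @return A tibble with columns `theta_deg`, `c_qL`, `c_qS`, `c_S` (m/s).
#' @examples
#' christoffel_speeds(niti_params(mu = 3e3, G = 9e3), theta = c(0, 45, 90))
#' @export
christoffel_speeds <- function(params, theta) {
  check_niti_params(params)
  C <- niti_stiffness(params)
  clip <- 1e-9 * params$lambda
  rows <- lapply(theta, function(th) {
    G <- christoffel_matrix(C, th * pi / 180)
    e <- eigen(G, symmetric = TRUE)
    # pure shear: eigenvector dominated by the out-of-plane (x) component
    ix <- which.max(abs(e$vectors[1, ]))
    vals <- pmax(e$values, 0)
    vals[e$values < -clip] <- NA_real_
    c_S <- sqrt(vals[ix] / params$rho)
    rest <- sort(vals[-ix])
    tibble(theta_deg = th,
           c_qL = sqrt(rest[2] / params$rho),
           c_qS = sqrt(rest[1] / params$rho),
           c_S = c_S)
  })
  dplyr::bind_rows(rows)
}

#' Closed-form pure shear speed
#'
#' The pure shear branch, polarized normal to the plane of the propagation
#' direction and symmetry axis, has the exact closed form
#' \deqn{c_S(\theta) = \sqrt{(G\cos^2\theta + \mu\sin^2\theta)/\rho}.}
#'
#' @inheritParams christoffel_speeds
#' @return Speeds in m/s, vectorized over `theta`.
#' @examples
#' shear_speed(niti_params(mu = 3e3, G = 9e3), c(0, 90))  # sqrt(G/rho), sqrt(mu/rho)
#' @export
shear_speed <- function(params, theta) {
  check_niti_params(params)
  th <- theta * pi / 180
  sqrt((params$G * cos(th)^2 + params$mu * sin(th)^2) / params$rho)
}

#' Closed-form quasi-shear speed (incompressible limit)
#'
#' In the incompressible limit the in-plane quasi-shear branch reduces to
#' \deqn{c_{qS}(\theta) = \sqrt{(G\cos^2 2\theta + (\mu + \delta/4)\sin^2 2\theta)/\rho},}
#' which at 45 degrees equals \eqn{\sqrt{(\mu + \delta/4)/\rho}} independently
#' of `G`, and at 0 and 90 degrees equals \eqn{\sqrt{G/\rho}}.  Agreement with
#' the finite-`lambda` Christoffel solution is at the 1e-3 relative level for
#' `lambda/mu >= 1e6`.
#'
#' @inheritParams christoffel_speeds
#' @return Speeds in m/s, vectorized over `theta`.
#' @examples
#' quasi_shear_speed(niti_params(mu = 3e3, G = 9e3, delta = 6e3), 45)
#' @export
quasi_shear_speed <- function(params, theta) {
  check_niti_params(params)
  th <- theta * pi / 180
  sqrt((params$G * cos(2 * th)^2 + (params$mu + params$delta / 4) * sin(2 * th)^2) /
         params$rho)
}
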