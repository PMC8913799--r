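#' NITI material parameters
#'
#' Construct the parameter set of a nearly incompressible transversely
#' isotropic (NITI) solid: the in-plane shear modulus `mu`, the out-of-plane
#' shear modulus `G`, the tensile-anisotropy parameter `delta = Q2 - 2 Q1`,
#' and the longitudinal Lame constant `lambda` acting as the
#' near-incompressibility surrogate.  All moduli are in Pa, density in kg/m^3.
#'
#' The split of `delta` into the tensile coupling parameters `Q1` and `Q2` is
#' immaterial in the incompressible limit (every in-scope observable depends
#' on them only through `delta`), so by default `Q1 = 0`, `Q2 = delta`; both
#' can be overridden as long as `Q2 - 2*Q1 == delta`.
#'
#' `lambda` defaults to `1e5 * max(mu, G, abs(delta))`, deep enough into the
#' incompressible regime that doubling it changes derived moduli by less than
#' 1e-4 relative.  It is never a fitted quantity.
#'
#' @param mu In-plane shear modulus, Pa.
#' @param G Out-of-plane shear modulus, Pa.  Defaults to `mu` (isotropy).
#' @param delta Tensile-anisotropy parameter, Pa.  Positive for a fast-axis
#'   material such as skin.
#' @param rho Mass density, kg/m^3.  Default 1000, the standard soft-tissue
#'   assumption; wave speeds scale as `rho^(-1/2)`.
#' @param lambda Longitudinal Lame constant, Pa, or `NULL` for the default.
#' @param Q1,Q2 Optional explicit tensile parameters, Pa.
#' @return An object of class `niti_params`.
#' @examples
#' p <- niti_params(mu = 3e3, G = 9e3, delta = 6e3)
#' p
#' @export
niti_params <- function(mu, G = mu, delta = 0, rho = 1000,
                        lambda = NULL, Q1 = 0, Q2 = NULL) {
  if (is.null(Q2)) Q2 <- delta + 2 * Q1
  if (is.null(lambda)) lambda <- 1e5 * max(mu, G, abs(delta))
  p <- structure(
    list(mu = as.numeric(mu), G = as.numeric(G), delta = as.numeric(delta),
         Q1 = as.numeric(Q1), Q2 = as.numeric(Q2),
         lambda = as.numeric(lambda), rho = as.numeric(rho)),
    class = "niti_params")
  check_niti_params(p)
  p
}

check_niti_params <- function(p) {
  bad <- character()
  if (!is.finite(p$mu) || p$mu <= 0) bad <- c(bad, "mu must be > 0")
  if (!is.finite(p$G) || p$G <= 0) bad <- c(bad, "G must be > 0")
  if (!is.finite(p$rho) || p$rho <= 0) bad <- c(bad, "rho must be > 0")
  scale <- max(p$mu, p$G, abs(p$delta))
  if (!is.finite(p$lambda) || p$lambda / scale < 1e4)
    bad <- c(bad, sprintf(
      "lambda/max(mu, G, |delta|) = %.3g is below 1e4: outside the near-incompressible regime",
      p$lambda / scale))
  if (abs(p$Q2 - 2 * p$Q1 - p$delta) > 1e-9 * max(1, abs(p$delta)))
    bad <- c(bad, "Q2 - 2*Q1 must equal delta")
  if (length(bad))
    abort(c("invalid NITI parameters:", bad), class = "nitioce_invalid_params")
  invisible(p)
}

#' @export
print.niti_params <- function(x, ...) {
  cat("<niti_params>\n")
  cat(sprintf("  mu    = %.4g kPa   G = %.4g kPa   delta = %.4g kPa\n",
              x$mu / 1e3, x$G / 1e3, x$delta / 1e3))
  cat(sprintf("  rho   = %.4g kg/m^3   lambda/mu = %.3g\n", x$rho, x$lambda / x$mu))
  cat(sprintf("  G/mu  = %.3g   delta/mu = %.3g\n", x$G / x$mu, x$delta / x$mu))
  invisible(x)
}

#' Voigt stiffness matrix of a NITI material
#'
#' Assembles the 6x6 stiffness matrix (Voigt ordering, symmetry axis along Z):
#' `C11 = C22 = lambda + 2 mu`, `C12 = lambda`, `C13 = C23 = lambda + Q1`,
#' `C33 = lambda + 2 mu + Q2`, `C44 = C55 = G`, `C66 = mu`.  The transverse
#' isotropy condition `C12 = C11 - 2 C66` holds by construction.
#'
#' @param params A [niti_params] object.
#' @return A 6x6 numeric matrix, Pa.
#' @examples
#' niti_stiffness(niti_params(mu = 3e3, G = 9e3, delta = 6e3))[1:3, 1:3]
#' @export
niti_stiffness <- function(params) {
  check_niti_params(params)
  lam <- params$lambda; mu <- params$mu
  C <- matrix(0, 6, 6)
  C[1, 1] <- C[2, 2] <- lam + 2 * mu
  C[1, 2] <- C[2, 1] <- lam
  C[1, 3] <- C[3, 1] <- C[2, 3] <- C[3, 2] <- lam + params$Q1
  C[3, 3] <- lam + 2 * mu + params$Q2
  C[4, 4] <- C[5, 5] <- params$G
  C[6, 6] <- mu
  C
}

#' Engineering moduli of the incompressible-limit NITI material
#'
#' Closed-form transverse and longitudinal Young's moduli and Poisson ratios
#' in the incompressible limit:
#' \deqn{E_T = 3\mu + \mu\,\delta/(4\mu+\delta), \quad E_L = 3\mu + \delta,}
#' \deqn{\nu_{TT} = \tfrac12(1 + \delta/(4\mu+\delta)), \quad
#'       \nu_{TL} = \tfrac12(1 - \delta/(4\mu+\delta)), \quad \nu_{LT} = \tfrac12.}
#' The identities \eqn{\nu_{TT} + \nu_{TL} = 1} and, for `delta = 0`,
#' \eqn{E = 3\mu} with all ratios 1/2, follow directly.
#'
#' @param params A [niti_params] object.
#' @return A one-row tibble with columns `E_T`, `E_L` (Pa), `nu_TT`, `nu_TL`,
#'   `nu_LT`.
#' @examples
#' engineering_moduli(niti_params(mu = 1e3, delta = 4e3, G = 3e3))
#' @export
engineering_moduli <- function(params) {
  check_niti_params(params)
  mu <- params$mu; d <- params$delta
  if (4 * mu + d <= 0)
    abort("degenerate denominator: 4*mu + delta must be positive",
          class = "nitioce_degenerate")
  r <- d / (4 * mu + d)
  tibble(
    E_T = 3 * mu + mu * r,
    E_L = 3 * mu + d,
    nu_TT = 0.5 * (1 + r),
    nu_TL = 0.5 * (1 - r),
    nu_LT = 0.5)
}

#' Engineering moduli read from the compliance matrix
#'
#' Independent route to the engineering moduli: invert a 6x6 Voigt stiffness
#' matrix and read Young's moduli and Poisson ratios from compliance entries
#' (`E_L = 1/S33`, `E_T = 1/S11`, `nu_LT = -S13/S33`, `nu_TT = -S12/S11`,
#' `nu_TL = -S13/S11`).  Used as the numerical cross-check of
#' [engineering_moduli] at large `lambda`.
#'
#' @param stiffness A 6x6 positive-definite stiffness matrix, Pa.
#' @return A one-row tibble with the same columns as [engineering_moduli].
#' @examples
#' moduli_from_compliance(niti_stiffness(niti_params(mu = 1e3, delta = 4e3,
#'                                                   lambda = 1e8 * 1e3)))
#' @export
moduli_from_compliance <- function(stiffness) {
  stopifnot(is.matrix(stiffness), all(dim(stiffness) == c(6, 6)))
  S <- tryCatch(solve(stiffness), error = function(e)
    abort("stiffness matrix is singular", class = "nitioce_singular"))
  if (rcond(stiffness) < 1e-15)
    abort("stiffness matrix is singular", class = "nitioce_singular")
  tibble(
    E_T = 1 / S[1, 1],
    E_L = 1 / S[3, 3],
    nu_TT = -S[1, 2] / S[1, 1],
    nu_TL = -S[1, 3] / S[1, 1],
    nu_LT = -S[1, 3] / S[3, 3])
}

#' Physical-validity check of NITI parameters
#'
#' Diagnoses a parameter set against the physical constraints that a
#' fast-axis, incompressible-limit NITI material must satisfy:
#' `E_L > E_T/2`, `E_L > mu`, `E_T > 2 mu`, all Poisson ratios positive, and,
#' when `delta > 0`, `3 mu < E_T < 4 mu` (the transverse Young's modulus is
#' confined to that band however large `delta` grows).
#'
#' @param params A [niti_params] object.
#' @return A tibble with columns `constraint` and `detail`; zero rows when all
#'   constraints hold.
#' @examples
#' nrow(validate_niti(niti_params(mu = 1e3, G = 3e3, delta = 4e3)))  # 0
#' validate_niti(niti_params(mu = 1e3, delta = -2.5e3))
#' @export
validate_niti <- function(params) {
  check_niti_params(params)
  mu <- params$mu; d <- params$delta
  out <- list()
  fail <- function(constraint, detail) out[[length(out) + 1L]] <<-
      tibble(constraint = constraint, detail = detail)
  if (4 * mu + d <= 0) {
    fail("4*mu + delta > 0",
         sprintf("4*mu + delta = %.4g Pa: moduli undefined", 4 * mu + d))
    return(dplyr::bind_rows(out))
  }
  m <- engineering_moduli(params)
  if (!(m$E_L > m$E_T / 2))
    fail("E_L > E_T/2", sprintf("E_L = %.4g, E_T/2 = %.4g Pa", m$E_L, m$E_T / 2))
  if (!(m$E_L > mu))
    fail("E_L > mu", sprintf("E_L = %.4g, mu = %.4g Pa", m$E_L, mu))
  if (!(m$E_T > 2 * mu))
    fail("E_T > 2*mu", sprintf("E_T = %.4g, 2*mu = %.4g Pa", m$E_T, 2 * mu))
  for (nm in c("nu_TT", "nu_TL", "nu_LT"))
    if (!(m[[nm]] > 0))
      fail(paste0(nm, " > 0"), sprintf("%s = %.4g", nm, m[[nm]]))
  if (d > 0) {
    if (!(m$E_T > 3 * mu))
      fail("E_T > 3*mu (delta > 0)", sprintf("E_T = %.4g, 3*mu = %.4g Pa", m$E_T, 3 * mu))
    if (!(m$E_T < 4 * mu))
      fail("E_T < 4*mu (delta > 0)", sprintf("E_T = %.4g, 4*mu = %.4g Pa", m$E_T, 4 * mu))
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble(constraint = character(), detail = character())
}
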