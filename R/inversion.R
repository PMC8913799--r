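# Four-parameter inversion of angle-resolved Rayleigh-speed scans.
#
# The observable is the scan-frame speed curve c(angle); the model is the
# Stroh Rayleigh solution c_R(angle - alpha; mu, G, delta, rho).  Fitting is
# bounded Levenberg-Marquardt least squares (minpack.lm) with multiple
# restarts over the periodic fiber-orientation parameter alpha.

#' Default parameter bounds for the angle-scan fit
#'
#' Shear moduli in (0.01, 1000] kPa, `delta` in [0, 10000] kPa (fast-axis),
#' `alpha` in (-90, 90] degrees.
#'
#' @return List with named numeric vectors `lower` and `upper` over
#'   `(mu, G, delta, alpha)`, moduli in Pa.
#' @export
default_fit_bounds <- function() {
  list(lower = c(mu = 10, G = 10, delta = 0, alpha = -90),
       upper = c(mu = 1e6, G = 1e6, delta = 1e7, alpha = 90))
}

check_angle_scan <- function(scan) {
  if (!is.data.frame(scan))
    abort("scan must be a data frame", class = "nitioce_scan")
  for (col in c("angle_deg", "speed_m_s"))
    if (!col %in% names(scan))
      abort(sprintf("scan is missing required column '%s'", col),
            class = "nitioce_missing_column")
  if (any(!is.finite(scan$speed_m_s)) || any(scan$speed_m_s <= 0))
    abort("scan speeds must be finite and positive", class = "nitioce_scan")
  if (length(unique(scan$angle_deg)) < 6)
    abort("at least 6 distinct angles are required for a 4-parameter fit",
          class = "nitioce_scan")
  invisible(scan)
}

# model speeds at scan angles for a raw parameter vector (Pa, Pa, Pa, deg);
# non-finite parameters or failed solves yield a large finite penalty so the
# optimizer backs away instead of propagating NaN
fit_forward <- function(par, angles, rho, rel_tol = 1e-9, n_scan = 24) {
  if (any(!is.finite(par))) return(rep(1e3, length(angles)))
  p <- tryCatch(niti_params(mu = par[1], G = par[2], delta = par[3], rho = rho),
                error = function(e) NULL)
  if (is.null(p)) return(rep(1e3, length(angles)))
  s <- rayleigh_solve(p, angles - par[4], rel_tol, n_scan)$speed
  s[!is.finite(s)] <- 1e3
  s
}

#' Fit a NITI model to an angle-resolved wave-speed scan
#'
#' Recovers the four parameters (`mu`, `G`, `delta`, fiber orientation
#' `alpha`) by least-squares fitting of the Stroh Rayleigh-speed curve to an
#' angle-resolved scan.  Residuals are optionally weighted by per-angle
#' standard deviations (`sd_m_s` column).  Optimization is bounded
#' Levenberg-Marquardt with restarts that jitter the initial `alpha` by up to
#' +/-30 degrees (the cost surface is 180-degree periodic in `alpha`); the
#' best restart is returned.
#'
#' Initialization follows the closed-form limits of the model: `alpha0` is
#' the scan angle of maximum speed, `mu0 = rho (c_min/0.9553)^2` from the
#' across-fiber Rayleigh constant, `G0 = rho (c_max/0.9553)^2`, and
#' `delta0 = mu0`.
#'
#' @param scan Data frame with columns `angle_deg`, `speed_m_s`, and
#'   optionally `sd_m_s` (at least 6 distinct angles).
#' @param rho Density, kg/m^3.
#' @param bounds List with named vectors `lower`, `upper` over
#'   `(mu, G, delta, alpha)` in Pa and degrees.  Defaults keep `delta >= 0`
#'   (fast-axis material); pass a negative lower bound for slow-axis fits
#'   (a warning is raised).
#' @param init Optional named vector `c(mu, G, delta, alpha)` overriding the
#'   automatic initialization.
#' @param n_restarts Number of alpha-jittered restarts, default 5.
#' @param loo Also run leave-one-out cross-validation (see [loo_cv]).
#' @return An object of class `niti_fit`: fitted [niti_params] (`$params`),
#'   `$alpha` (degrees, folded into (-90, 90]), `$estimates` tibble, `$rmse`
#'   (m/s), derived ratios, convergence diagnostics, validity flags, and LOO
#'   statistics when requested.  Methods: [tidy()], [glance()], [autoplot()],
#'   [predict()][predict.niti_fit].
#' @examples
#' \donttest{
#' truth <- niti_params(mu = 2e3, G = 6e3, delta = 8e3)
#' scan <- rayleigh_curve(truth, alpha = 10) |>
#'   dplyr::select(angle_deg, speed_m_s)
#' fit <- fit_angle_scan(scan)
#' tidy(fit)
#' }
#' @export
fit_angle_scan <- function(scan, rho = 1000, bounds = default_fit_bounds(),
                           init = NULL, n_restarts = 5, loo = FALSE) {
  check_angle_scan(scan)
  if (loo) return(loo_cv(scan, rho = rho, bounds = bounds, init = init,
                         n_restarts = n_restarts))
  if (bounds$lower[["delta"]] < 0)
    warn("slow-axis mode: delta is allowed below 0", class = "nitioce_slow_axis")

  angles <- scan$angle_deg
  speeds <- scan$speed_m_s
  wts <- if ("sd_m_s" %in% names(scan) && all(is.finite(scan$sd_m_s)) &&
             all(scan$sd_m_s > 0)) 1 / scan$sd_m_s else rep(1, length(speeds))

  spread <- diff(range(speeds))
  sd_med <- if ("sd_m_s" %in% names(scan)) median(scan$sd_m_s) else NA_real_
  if ((is.finite(sd_med) && spread < 2 * sd_med) || spread < 0.01 * mean(speeds))
    warn("speed range is within noise: fiber orientation alpha is unidentifiable",
         class = "nitioce_alpha_unidentifiable")

  if (is.null(init)) {
    c_min <- min(speeds); c_max <- max(speeds)
    mu0 <- rho * (c_min / 0.9553)^2
    init <- c(mu = mu0, G = max(rho * (c_max / 0.9553)^2, 1.05 * mu0),
              delta = max(mu0, bounds$lower[["delta"]]),
              alpha = fold_angle_180(angles[which.max(speeds)]))
  }
  clamp <- function(par) {
    rng <- bounds$upper - bounds$lower
    pmin(pmax(par, bounds$lower + 1e-9 * rng), bounds$upper - 1e-9 * rng)
  }

  jitters <- c(0, -30, 30, -15, 15, -45, 45)[seq_len(n_restarts)]
  best <- NULL
  # a restart reproducing the data to 0.01% of the mean speed cannot be beaten
  # by a different basin; skip the remaining restarts
  good_enough <- length(speeds) * (1e-4 * mean(speeds) * mean(wts))^2
  for (dj in jitters) {
    par0 <- init
    par0[["alpha"]] <- fold_angle_180(init[["alpha"]] + dj)
    par0 <- clamp(par0)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = bounds$lower, upper = bounds$upper,
        fn = function(p) (fit_forward(p, angles, rho) - speeds) * wts,
        control = minpack.lm::nls.lm.control(maxiter = 100, ptol = 1e-12,
                                             ftol = 1e-14, epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
    if (best$deviance < good_enough) break
  }
  if (is.null(best))
    abort("all optimizer restarts failed to converge",
          class = "nitioce_nonconvergence")

  par <- best$par
  par[["alpha"]] <- fold_angle_180(par[["alpha"]])
  params <- niti_params(mu = par[["mu"]], G = par[["G"]],
                        delta = par[["delta"]], rho = rho)
  resid <- fit_forward(par, angles, rho) - speeds
  new_niti_fit(params, par[["alpha"]], scan, rho, bounds,
               rmse = sqrt(mean(resid^2)),
               convergence = list(info = best$info,
                                  message = best$message,
                                  deviance = best$deviance,
                                  niter = best$niter))
}

new_niti_fit <- function(params, alpha, scan, rho, bounds, rmse, convergence,
                         loo_stats = NULL) {
  est <- tibble(
    term = c("mu", "G", "delta", "alpha"),
    estimate = c(params$mu, params$G, params$delta, alpha),
    unit = c("Pa", "Pa", "Pa", "deg"))
  flags <- validate_niti(params)
  at_bound <- abs(params$delta - bounds$upper[["delta"]]) <
    1e-6 * bounds$upper[["delta"]]
  structure(list(params = params, alpha = alpha, estimates = est,
                 rmse = rmse, scan = as_tibble(scan), rho = rho,
                 bounds = bounds, convergence = convergence,
                 validity = flags, delta_at_bound = at_bound,
                 loo = loo_stats),
            class = "niti_fit")
}

#' @export
print.niti_fit <- function(x, ...) {
  cat("<niti_fit>\n")
  cat(sprintf("  mu = %.4g kPa  G = %.4g kPa  delta = %.4g kPa  alpha = %.2f deg\n",
              x$params$mu / 1e3, x$params$G / 1e3, x$params$delta / 1e3, x$alpha))
  cat(sprintf("  G/mu = %.3g  delta/mu = %.3g  rmse = %.4g m/s\n",
              x$params$G / x$params$mu, x$params$delta / x$params$mu, x$rmse))
  if (!is.null(x$loo))
    cat(sprintf("  LOO over %d folds: sd(mu) = %.3g kPa, sd(alpha) = %.3g deg\n",
                x$loo$n_folds, x$loo$stats$sd[x$loo$stats$term == "mu"] / 1e3,
                x$loo$stats$sd[x$loo$stats$term == "alpha"]))
  if (nrow(x$validity))
    cat("  validity flags:", paste(x$validity$constraint, collapse = "; "), "\n")
  invisible(x)
}

#' Predict model speeds from a fitted NITI model
#'
#' @param object A `niti_fit`.
#' @param angles Scan-frame angles, degrees; defaults to the fitted scan's.
#' @param ... Unused.
#' @return Tibble with `angle_deg` and `speed_m_s`.
#' @export
predict.niti_fit <- function(object, angles = NULL, ...) {
  if (is.null(angles)) angles <- object$scan$angle_deg
  tibble(angle_deg = angles,
         speed_m_s = rayleigh_solve(object$params,
                                    angles - object$alpha)$speed)
}

#' Leave-one-out cross-validation of the angle-scan fit
#'
#' Refits the scan N times, each time omitting one of its N points (all folds
#' warm-started at the full-scan optimum), and reports the per-parameter mean
#' and standard deviation across folds.  The fold means are the reported
#' parameter estimate.  Fold alphas are unwrapped to within 90 degrees of the
#' full-fit alpha (mod 180) before averaging.
#'
#' @inheritParams fit_angle_scan
#' @param ... Passed to [fit_angle_scan].
#' @return A `niti_fit` whose `$loo` field holds the fold statistics
#'   (`stats`: term, mean, sd; `folds`: per-fold parameters; `n_folds`).
#' @export
loo_cv <- function(scan, rho = 1000, bounds = default_fit_bounds(), ...) {
  check_angle_scan(scan)
  n <- nrow(scan)
  if (n < 7)
    abort("LOO-CV needs at least 7 scan points", class = "nitioce_scan")
  full <- fit_angle_scan(scan, rho = rho, bounds = bounds, ...)
  init <- setNames(full$estimates$estimate, full$estimates$term)
  folds <- purrr::map(seq_len(n), function(i) {
    tryCatch({
      f <- fit_angle_scan(scan[-i, ], rho = rho, bounds = bounds,
                          init = init, n_restarts = 1)
      tibble(fold = i, mu = f$params$mu, G = f$params$G,
             delta = f$params$delta, alpha = f$alpha, rmse = f$rmse)
    }, error = function(e) NULL)
  })
  ok <- !vapply(folds, is.null, logical(1))
  if (mean(!ok) > 0.2)
    abort(sprintf("%d of %d LOO folds failed to fit", sum(!ok), n),
          class = "nitioce_nonconvergence")
  folds <- dplyr::bind_rows(folds[ok])
  # unwrap fold alphas to the full-fit branch (orientation is mod 180)
  folds$alpha <- full$alpha +
    (((folds$alpha - full$alpha) + 90) %% 180 - 90)
  stats <- tidyr::pivot_longer(folds, c("mu", "G", "delta", "alpha"),
                               names_to = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value)) |>
    dplyr::arrange(match(.data$term, c("mu", "G", "delta", "alpha")))
  m <- setNames(stats$mean, stats$term)
  params <- niti_params(mu = m[["mu"]], G = m[["G"]], delta = m[["delta"]],
                        rho = rho)
  alpha <- fold_angle_180(m[["alpha"]])
  resid <- rayleigh_solve(params, scan$angle_deg - alpha)$speed - scan$speed_m_s
  new_niti_fit(params, alpha, scan, rho, bounds,
               rmse = sqrt(mean(resid^2)),
               convergence = full$convergence,
               loo_stats = list(stats = stats, folds = folds,
                                n_folds = nrow(folds), full_fit = full))
}

#' Derived anisotropy measures of a fitted NITI model
#'
#' Applies [engineering_moduli] to the fitted parameters and reports the
#' tensile anisotropy `E_L/E_T`, shear anisotropy `G/mu`, and `delta/mu`.
#' When the fitted `delta` sits at its upper bound the tensile anisotropy is
#' bound-limited and a warning is raised; physical-validity violations are
#' attached as flags, not errors.
#'
#' @param fit A `niti_fit`.
#' @return One-row tibble: `E_T`, `E_L` (Pa), `EL_over_ET`, `G_over_mu`,
#'   `delta_over_mu`, with attribute `"validity"` carrying any flags.
#' @examples
#' \donttest{
#' # E_L/E_T = 2 for mu = 1 kPa, delta = 4 kPa
#' }
#' @export
derived_anisotropy <- function(fit) {
  stopifnot(inherits(fit, "niti_fit"))
  if (isTRUE(fit$delta_at_bound))
    warn("fitted delta sits at its upper bound: E_L/E_T is bound-limited",
         class = "nitioce_delta_bound")
  m <- engineering_moduli(fit$params)
  out <- tibble(E_T = m$E_T, E_L = m$E_L,
                EL_over_ET = m$E_L / m$E_T,
                G_over_mu = fit$params$G / fit$params$mu,
                delta_over_mu = fit$params$delta / fit$params$mu)
  attr(out, "validity") <- fit$validity
  out
}
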