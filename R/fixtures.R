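# Synthetic-subject generator: one ground truth drives both the mechanical
# (wavefield) and optical (Stokes-volume) observables, so the full pipeline
# can be exercised end-to-end and the two symmetry-axis estimates compared.

#' Generate a synthetic subject
#'
#' Builds the paired acquisition of one synthetic subject from a single
#' ground truth: 13 surface wavefields at scan angles -90 to +90 degrees in
#' 15-degree steps, each propagating at the Rayleigh speed of the truth
#' parameters at that angle, and a PS-OCT Stokes volume whose dermal optic
#' axis equals the mechanical fiber orientation `alpha`, beneath a
#' non-birefringent surface layer.  All randomness derives deterministically
#' from `seed` (per-artifact sub-seeds are recorded in the manifest), so the
#' same seed reproduces every artifact exactly.
#'
#' @param params Ground-truth [niti_params].
#' @param alpha Fiber orientation, degrees from the scan zero direction.
#' @param wavefield_noise_sd Additive noise sd in the wavefields (noiseless
#'   peak amplitude is 1).
#' @param stokes_noise_sd Gaussian noise sd on Stokes components.
#' @param n_x,n_t Wavefield grid (positions x frames); defaults 256 x 512.
#' @param psoct_grid Lateral PS-OCT grid size, `c(nx, ny)`.
#' @param n_surface,n_dermis Depth steps of the non-birefringent surface
#'   layer and of the birefringent dermis.
#' @param retardance Dermal round-trip retardance per depth step, degrees.
#' @param seed Master seed.
#' @param dir Optional directory: when given, all artifacts and the manifest
#'   are written there as plain-text containers.
#' @return A list of class `synthetic_subject`: `truth` (params + alpha),
#'   `scan` (true speeds per angle), `wavefields` (named list), `psoct`
#'   (long tibble of Stokes states), `manifest`.
#' @examples
#' \donttest{
#' subj <- make_synthetic_subject(niti_params(mu = 2e3, G = 6e3, delta = 8e3),
#'                                alpha = 10, seed = 1)
#' subj$scan
#' }
#' @export
make_synthetic_subject <- function(params, alpha,
                                   wavefield_noise_sd = 0,
                                   stokes_noise_sd = 0,
                                   n_x = 256, n_t = 512,
                                   psoct_grid = c(8, 8),
                                   n_surface = 20, n_dermis = 120,
                                   retardance = 6,
                                   seed = 1, dir = NULL) {
  check_niti_params(params)
  angles <- default_angle_grid()
  curve <- rayleigh_curve(params, angles, alpha = alpha)
  sub_seed <- function(i) as.integer((as.numeric(seed) * 10007 + i) %% 2147483647)

  wavefields <- purrr::imap(setNames(curve$speed_m_s,
                                     sprintf("angle_%+04d", angles)),
    function(speed, nm) {
      i <- match(nm, sprintf("angle_%+04d", angles))
      simulate_wavefield(speed = speed, n_x = n_x, n_t = n_t,
                         noise_sd = wavefield_noise_sd,
                         seed = if (wavefield_noise_sd > 0) sub_seed(i) else NULL)
    })

  psi_profile <- c(rep(0, n_surface), rep(alpha, n_dermis))
  ret_profile <- c(rep(0, n_surface), rep(retardance, n_dermis))
  grid <- tidyr::expand_grid(x = seq_len(psoct_grid[1]),
                             y = seq_len(psoct_grid[2]))
  psoct <- purrr::pmap_dfr(grid, function(x, y) {
    tr <- simulate_stokes_trajectory(
      psi = psi_profile, retardance = ret_profile,
      noise_sd = stokes_noise_sd,
      seed = if (stokes_noise_sd > 0)
        sub_seed(100 + (x - 1) * psoct_grid[2] + y) else NULL)
    dplyr::mutate(as_tibble(tr), x = x, y = y, .before = 1)
  })

  manifest <- list(
    schema = SCHEMA$manifest, seed = seed,
    truth = list(mu_Pa = params$mu, G_Pa = params$G, delta_Pa = params$delta,
                 rho_kg_m3 = params$rho, lambda_Pa = params$lambda,
                 alpha_deg = alpha),
    noise = list(wavefield_sd = wavefield_noise_sd,
                 stokes_sd = stokes_noise_sd),
    geometry = list(angles_deg = angles, n_x = n_x, n_t = n_t,
                    psoct_grid = psoct_grid, n_surface = n_surface,
                    n_dermis = n_dermis, retardance_deg = retardance),
    sub_seeds = list(wavefields = vapply(seq_along(angles), sub_seed,
                                         integer(1))))

  subj <- structure(
    list(truth = list(params = params, alpha = alpha),
         scan = dplyr::select(curve, "angle_deg", "speed_m_s"),
         wavefields = wavefields, psoct = psoct, manifest = manifest),
    class = "synthetic_subject")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_angle_scan(subj$scan, file.path(dir, "true_scan.csv"))
    purrr::iwalk(wavefields, function(wf, nm)
      write_wavefield(wf, file.path(dir, nm)))
    write_stokes_volume(psoct, file.path(dir, "psoct"),
                        meta = manifest$geometry)
  }
  subj
}

#' Run the full analysis pipeline on a synthetic subject
#'
#' Estimates the group velocity of each of the 13 wavefields, fits the NITI
#' model to the resulting angle scan (optionally with LOO-CV), estimates the
#' PS-OCT axis map from the Stokes volume, and compares the mechanical and
#' optical symmetry axes.
#'
#' @param subj A `synthetic_subject`.
#' @param loo Run leave-one-out cross-validation in the fit.
#' @param ... Passed to [fit_angle_scan].
#' @return List with `scan` (estimated speeds), `fit` (`niti_fit`),
#'   `axis_map`, `psi_optical` (map circular mean, degrees), and
#'   `axis_difference_deg` (acute OCE-vs-PS-OCT angle).
#' @export
analyze_subject <- function(subj, loo = FALSE, ...) {
  stopifnot(inherits(subj, "synthetic_subject"))
  angles <- subj$manifest$geometry$angles_deg
  scan <- tibble(
    angle_deg = angles,
    speed_m_s = vapply(subj$wavefields, function(wf)
      suppressWarnings(estimate_group_velocity(wf))$speed, numeric(1)))
  fit <- fit_angle_scan(scan, rho = subj$truth$params$rho, loo = loo, ...)
  profiles <- subj$psoct |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::group_modify(~ estimate_axis_profile(.x)) |>
    dplyr::ungroup()
  axis_map <- depth_averaged_axis(profiles)
  psi_opt <- circular_axis_mean(axis_map$psi_deg)
  list(scan = scan, fit = fit, axis_map = axis_map,
       psi_optical = psi_opt,
       axis_difference_deg = compare_axes(fit$alpha, psi_opt))
}
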