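# broom-style tidiers

#' Tidy a fitted NITI model
#'
#' @param x A `niti_fit`.
#' @param ... Unused.
#' @return One row per parameter (`mu`, `G`, `delta` in Pa, `alpha` in
#'   degrees) with `estimate`, and `loo_mean` / `loo_sd` when leave-one-out
#'   statistics are available.
#' @method tidy niti_fit
#' @export
tidy.niti_fit <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$loo)) {
    s <- x$loo$stats
    out$loo_mean <- s$mean[match(out$term, s$term)]
    out$loo_sd <- s$sd[match(out$term, s$term)]
  }
  out
}

#' Glance at a fitted NITI model
#'
#' @param x A `niti_fit`.
#' @param ... Unused.
#' @return One-row tibble: `rmse` (m/s), anisotropy ratios, number of scan
#'   points, optimizer diagnostics, validity flag count.
#' @method glance niti_fit
#' @export
glance.niti_fit <- function(x, ...) {
  tibble(rmse = x$rmse,
         G_over_mu = x$params$G / x$params$mu,
         delta_over_mu = x$params$delta / x$params$mu,
         EL_over_ET = with(engineering_moduli(x$params), E_L / E_T),
         n_angles = nrow(x$scan),
         n_loo_folds = if (is.null(x$loo)) NA_integer_ else x$loo$n_folds,
         optimizer_info = x$convergence$info,
         n_validity_flags = nrow(x$validity))
}

#' Tidy a group-velocity estimate
#'
#' @param x A `group_velocity`.
#' @param ... Unused.
#' @return The per-position arrival-time table (`x_m`, `t_arrival_s`,
#'   `used`).
#' @method tidy group_velocity
#' @export
tidy.group_velocity <- function(x, ...) x$arrivals

#' Glance at a group-velocity estimate
#'
#' @param x A `group_velocity`.
#' @param ... Unused.
#' @return One-row tibble: `speed` (m/s), `intercept` (s), `r_squared`,
#'   `method`, `n_used`.
#' @method glance group_velocity
#' @export
glance.group_velocity <- function(x, ...) {
  tibble(speed = x$speed, intercept = x$intercept,
         r_squared = x$r_squared, method = x$method,
         n_used = sum(x$arrivals$used))
}
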