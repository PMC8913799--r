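# Depth-resolved optic-axis estimation from Stokes trajectories.
#
# A linear retarder with physical axis psi rotates polarization states on the
# Poincare sphere about the equatorial axis (cos 2 psi, sin 2 psi, 0).  As
# light accumulates retardance with depth, the measured output states trace a
# circle about that axis; a sliding-window plane fit (SVD) recovers the
# circle's normal and hence psi.

#' Simulate a Stokes trajectory through a retarder stack
#'
#' Propagates an input polarization state through a stack of depth steps,
#' each a linear retarder with (depth-dependent) physical axis orientation
#' `psi` and round-trip retardance `retardance` per step: the Stokes vector
#' is rotated about the equatorial Poincare axis `(cos 2 psi, sin 2 psi, 0)`
#' by the retardance angle.  Optional Gaussian noise is added and states are
#' re-normalized to the sphere.  Deterministic for a given `seed`.
#'
#' @param psi Axis orientation(s), degrees: a scalar (uniform stack of
#'   `n_steps`) or a vector giving the axis at every step.
#' @param retardance Round-trip retardance per step, degrees; scalar or
#'   per-step vector (use 0 for non-birefringent layers).
#' @param n_steps Number of depth steps when `psi` is scalar.
#' @param depth_step Depth increment per step, um (default 1.5, a typical
#'   spectral-domain OCT axial pixel).
#' @param input_state Incident Stokes 3-vector `(Q, U, V)`; default circular
#'   polarization `(0, 0, 1)`.
#' @param noise_sd Gaussian noise sd added to each component before
#'   re-normalization.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A `stokes_trajectory`: tibble with columns `depth_um`, `Q`, `U`,
#'   `V` (`n_steps + 1` rows including the input state), carrying the
#'   generation settings as attributes.
#' @examples
#' traj <- simulate_stokes_trajectory(psi = 30, retardance = 10, n_steps = 50)
#' head(traj, 3)
#' @export
simulate_stokes_trajectory <- function(psi, retardance, n_steps = length(psi),
                                       depth_step = 1.5,
                                       input_state = c(0, 0, 1),
                                       noise_sd = 0, seed = NULL) {
  if (length(psi) == 1) psi <- rep(psi, n_steps)
  if (length(retardance) == 1) retardance <- rep(retardance, n_steps)
  stopifnot(length(psi) == n_steps, length(retardance) == n_steps)
  if (any(retardance < 0))
    abort("retardance must be non-negative", class = "nitioce_invalid_params")
  s <- input_state / sqrt(sum(input_state^2))
  states <- matrix(NA_real_, n_steps + 1, 3)
  states[1, ] <- s
  for (k in seq_len(n_steps)) {
    ax <- c(cos(2 * psi[k] * pi / 180), sin(2 * psi[k] * pi / 180), 0)
    s <- rotate_about(s, ax, retardance[k] * pi / 180)
    states[k + 1, ] <- s
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required when noise_sd > 0",
                             class = "nitioce_invalid_params")
    states <- states + with_seed(seed, matrix(rnorm(length(states),
                                                    sd = noise_sd),
                                              nrow(states), 3))
    states <- states / sqrt(rowSums(states^2))
  }
  out <- tibble(depth_um = (0:n_steps) * depth_step,
                Q = states[, 1], U = states[, 2], V = states[, 3])
  attr(out, "psi") <- psi
  attr(out, "retardance") <- retardance
  attr(out, "seed") <- seed
  class(out) <- c("stokes_trajectory", class(out))
  out
}

# Rodrigues rotation of v about unit axis k by angle a (right-handed)
rotate_about <- function(v, k, a) {
  v * cos(a) + cross3(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Depth-resolved optic-axis profile from a Stokes trajectory
#'
#' Slides a window of `window` adjacent output states along depth and fits
#' the best plane through the centered states by singular value decomposition
#' (the plane normal is the smallest-scatter principal direction).  The axis
#' orientation is `psi = atan2(n_U, n_Q) / 2`, folded into (-90, 90].  The
#' normal's sign is fixed by requiring consecutive states to advance
#' right-handedly about it (positive retardance), resolving the 90-degree
#' ambiguity of an unsigned normal.  Windows whose states span an arc shorter
#' than `arc_min` are masked invalid — the non-birefringent case, in which
#' the trajectory carries no axis information (e.g. amorphous tissue at the
#' skin surface).
#'
#' @param traj A `stokes_trajectory` (or any data frame with `depth_um`,
#'   `Q`, `U`, `V`); states are normalized internally (unit-norm tolerance
#'   1e-6 after normalization).
#' @param window Number of adjacent states per fit, default 3 (a plane is
#'   exact through 3 points; larger windows use the same scatter
#'   decomposition).
#' @param arc_min Minimum trajectory arc per window, degrees on the sphere;
#'   default 1.
#' @return Tibble with columns `depth_um` (window center), `psi_deg`, and
#'   `valid`.  A warning is raised when every window is masked.
#' @examples
#' traj <- simulate_stokes_trajectory(psi = 30, retardance = 10, n_steps = 50)
#' summary(estimate_axis_profile(traj)$psi_deg)
#' @export
estimate_axis_profile <- function(traj, window = 3, arc_min = 1) {
  stopifnot(all(c("depth_um", "Q", "U", "V") %in% names(traj)))
  if (window < 3)
    abort("window must be at least 3 states", class = "nitioce_window")
  S <- as.matrix(traj[, c("Q", "U", "V")])
  if (nrow(S) < window)
    abort(sprintf("trajectory has %d states, fewer than window = %d",
                  nrow(S), window), class = "nitioce_window")
  S <- S / sqrt(rowSums(S^2))
  n_win <- nrow(S) - window + 1
  out <- vapply(seq_len(n_win), function(i) {
    W <- S[i:(i + window - 1), , drop = FALSE]
    steps <- W[-1, , drop = FALSE] - W[-nrow(W), , drop = FALSE]
    arc <- sum(asin(pmin(1, sqrt(rowSums(steps^2)) / 2)) * 2) * 180 / pi
    if (!is.finite(arc) || arc < arc_min) return(c(NA_real_, 0))
    Wc <- sweep(W, 2, colMeans(W))
    sv <- svd(Wc)
    n <- sv$v[, 3]
    # right-handed advance about +n fixes the sign (positive retardance)
    hand <- sum(vapply(seq_len(nrow(W) - 1), function(j)
      sum(cross3(W[j, ], W[j + 1, ]) * n), numeric(1)))
    if (hand < 0) n <- -n
    c(fold_angle_180(atan2(n[2], n[1]) * 90 / pi), 1)
  }, numeric(2))
  valid <- out[2, ] == 1
  if (!any(valid))
    warn("all windows masked: trajectory is non-birefringent",
         class = "nitioce_all_masked")
  centers <- vapply(seq_len(n_win), function(i)
    mean(traj$depth_um[i:(i + window - 1)]), numeric(1))
  tibble(depth_um = centers, psi_deg = out[1, ], valid = valid)
}

#' Depth-averaged optic-axis map
#'
#' Averages valid per-depth axis orientations with doubled-angle circular
#' statistics, `psi_bar = atan2(mean sin 2 psi, mean cos 2 psi) / 2`,
#' per lateral position (any grouping columns present besides `depth_um`,
#' `psi_deg`, `valid` are treated as position identifiers).
#'
#' @param profiles Tibble of axis profiles, e.g. row-bound outputs of
#'   [estimate_axis_profile] with added position columns.
#' @param depth_range Optional `c(min, max)` depth window, um.
#' @return Tibble with the position columns, `psi_deg` (circular mean,
#'   folded into (-90, 90]), and `n_valid`; positions with no valid window
#'   are masked (`NA`).
#' @export
depth_averaged_axis <- function(profiles, depth_range = NULL) {
  stopifnot(all(c("depth_um", "psi_deg", "valid") %in% names(profiles)))
  if (!is.null(depth_range)) {
    profiles <- dplyr::filter(profiles, .data$depth_um >= depth_range[1],
                              .data$depth_um <= depth_range[2])
    if (nrow(profiles) == 0)
      abort("no windows in the requested depth range", class = "nitioce_window")
  }
  pos_cols <- setdiff(names(profiles), c("depth_um", "psi_deg", "valid"))
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pos_cols))) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      psi_deg = circular_axis_mean(.data$psi_deg[.data$valid]),
      .groups = "drop")
}

# doubled-angle circular mean of 180-deg-periodic orientations, degrees
circular_axis_mean <- function(psi) {
  psi <- psi[is.finite(psi)]
  if (!length(psi)) return(NA_real_)
  a <- 2 * psi * pi / 180
  fold_angle_180(atan2(mean(sin(a)), mean(cos(a))) * 90 / pi)
}

#' Directivity histogram of an axis map
#'
#' @param axis_map Output of [depth_averaged_axis].
#' @param binwidth Bin width, degrees.
#' @return Tibble with `bin_center` (degrees) and `count`.
#' @export
axis_directivity <- function(axis_map, binwidth = 5) {
  psi <- axis_map$psi_deg[is.finite(axis_map$psi_deg)]
  breaks <- seq(-90, 90, by = binwidth)
  h <- graphics::hist(psi, breaks = breaks, plot = FALSE)
  tibble(bin_center = h$mids, count = h$counts)
}

#' Acute angle between two axis orientations
#'
#' Both inputs are 180-degree-periodic orientations; the result is the acute
#' angle between them, in `[0, 90]` degrees.  Used to compare the mechanical
#' symmetry axis from the wave-speed fit with the optical axis from PS-OCT.
#'
#' @param a,b Orientations, degrees (vectorized).
#' @return Acute angular difference(s), degrees.
#' @examples
#' compare_axes(85, -85)  # 10
#' compare_axes(0, 90)    # 90
#' @export
compare_axes <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
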