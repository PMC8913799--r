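# Synthetic surface wavefields and group-velocity estimation.
#
# A wavefield is the space-time map of vertical surface velocity recorded by
# the OCE scan: 256 lateral positions (54.7 um step) x 512 time frames
# (46.5 kHz A-line rate) by default, mirroring the M-B acquisition format.

#' Construct a wavefield container
#'
#' @param x Lateral positions, m (uniform step).
#' @param t Time samples, s (uniform step).
#' @param v Matrix of vertical-velocity samples, `length(x)` rows by
#'   `length(t)` columns, arbitrary units.
#' @param meta Named list of generation metadata (kept as-is).
#' @return An object of class `wavefield`.
#' @export
wavefield <- function(x, t, v, meta = list()) {
  stopifnot(is.matrix(v), nrow(v) == length(x), ncol(v) == length(t))
  if (length(x) > 1 && diff(range(diff(x))) > 1e-9 * mean(diff(x)))
    abort("lateral grid must be uniform", class = "nitioce_grid")
  if (diff(range(diff(t))) > 1e-9 * mean(diff(t)))
    abort("time grid must be uniform", class = "nitioce_grid")
  structure(list(x = x, t = t, v = v, meta = meta), class = "wavefield")
}

#' @export
print.wavefield <- function(x, ...) {
  cat(sprintf("<wavefield> %d positions x %d frames, dx = %.3g um, fs = %.4g kHz\n",
              length(x$x), length(x$t), diff(x$x[1:2]) * 1e6,
              1 / diff(x$t[1:2]) / 1e3))
  invisible(x)
}

#' @export
as_tibble.wavefield <- function(x, ...) {
  tibble(x_m = rep(x$x, times = length(x$t)),
         t_s = rep(x$t, each = length(x$x)),
         v = as.vector(x$v))
}

#' Simulate a propagating surface-wave field
#'
#' Generates `v(x, t) = a(x) * s(t - t0 - x/speed)` with a Gaussian-enveloped
#' tone-burst pulse `s`, optional cylindrical-spreading amplitude decay
#' `a(x) = 1/sqrt(x + x0)`, and additive Gaussian noise.  Deterministic for a
#' given `seed`.  The default pulse (1.5 kHz center, 4 kHz full bandwidth at
#' -6 dB) matches the excitation band of an air-coupled micro-tapping push;
#' the default grid matches the acquisition format (256 x 512, 54.7 um,
#' 46.5 kHz).
#'
#' @param speed Propagation speed, m/s.
#' @param n_x,n_t Grid sizes (positions, time frames).
#' @param dx Lateral step, m.
#' @param fs Temporal sampling rate, Hz.
#' @param center_freq Pulse center frequency, Hz.
#' @param bandwidth Full -6 dB bandwidth of the pulse, Hz; must not exceed
#'   the Nyquist frequency `fs/2`.
#' @param t0 Pulse peak time at `x = 0`, s.
#' @param geometric_decay Apply `1/sqrt(x + x0)` spreading decay.
#' @param x0 Decay regularization offset, m.
#' @param noise_sd Additive Gaussian noise standard deviation (units of `v`;
#'   the noiseless peak amplitude at `x = 0` is 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A [wavefield] with pulse parameters recorded in `$meta`.
#' @examples
#' wf <- simulate_wavefield(speed = 3, noise_sd = 0.05, seed = 1)
#' wf
#' @export
simulate_wavefield <- function(speed, n_x = 256, n_t = 512, dx = 54.7e-6,
                               fs = 46500, center_freq = 1500, bandwidth = 4000,
                               t0 = 1e-3, geometric_decay = TRUE, x0 = 1e-3,
                               noise_sd = 0, seed = NULL) {
  if (speed <= 0) abort("speed must be positive", class = "nitioce_invalid_params")
  if (center_freq + bandwidth / 2 > fs / 2)
    abort(sprintf("pulse band extends to %.3g Hz, beyond Nyquist %.3g Hz",
                  center_freq + bandwidth / 2, fs / 2), class = "nitioce_aliasing")
  x <- (seq_len(n_x) - 1) * dx
  t <- (seq_len(n_t) - 1) / fs
  # -6 dB (amplitude 1/2) full width `bandwidth` of a Gaussian spectrum
  sigma <- sqrt(2 * log(2)) / (pi * bandwidth)
  tau <- outer(-x / speed, t - t0, "+")        # t - t0 - x/speed
  v <- cos(2 * pi * center_freq * tau) * exp(-tau^2 / (2 * sigma^2))
  if (geometric_decay) v <- v / sqrt((x + x0) / x0)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required when noise_sd > 0",
                             class = "nitioce_invalid_params")
    v <- v + with_seed(seed, matrix(rnorm(n_x * n_t, sd = noise_sd), n_x, n_t))
  }
  wavefield(x, t, v,
            meta = list(speed = speed, center_freq = center_freq,
                        bandwidth = bandwidth, sigma = sigma, t0 = t0,
                        noise_sd = noise_sd, seed = seed))
}

# run code with a fixed seed, preserving the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# analytic-signal envelope of each row of a (n_x x n_t) matrix, FFT-based
envelope <- function(v) {
  n <- ncol(v)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  V <- mvfft(t(v))
  t(abs(mvfft(V * h, inverse = TRUE) / n))
}

# sub-sample peak location by 3-point parabolic interpolation
refine_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  d <- (y[i - 1] - y[i + 1]) / 2 / (y[i - 1] - 2 * y[i] + y[i + 1])
  i + max(-0.5, min(0.5, d))
}

#' Estimate group velocity from a wavefield
#'
#' Picks an arrival time at each lateral position — the analytic-signal
#' envelope maximum (`method = "envelope"`, sub-sample via 3-point parabolic
#' interpolation) or the lag of the peak cross-correlation against the first
#' trace (`method = "xcorr"`) — and fits the least-squares line `t(x)`.  The
#' group velocity is the inverse slope.  Positions within one pulse width of
#' the earliest arrival are excluded from the fit by default (near-field
#' contamination); a warning is raised when the fit quality falls below
#' `r2_threshold`.
#'
#' @param wf A [wavefield].
#' @param method Arrival picker, `"envelope"` (default) or `"xcorr"`.
#' @param r2_threshold Coefficient-of-determination threshold below which a
#'   low-fit-quality warning is raised.  Default 0.9.
#' @param exclude_near Near-field exclusion window, s: positions whose
#'   arrival is within this of the earliest arrival are dropped.  `NULL`
#'   (default) uses one pulse FWHM when the wavefield carries pulse metadata,
#'   else 0.
#' @return An object of class `group_velocity` with fields `speed` (m/s),
#'   `intercept` (s), `r_squared`, `arrivals` (tibble of `x_m`,
#'   `t_arrival_s`, `used`), and `method`.
#' @examples
#' wf <- simulate_wavefield(speed = 3)
#' estimate_group_velocity(wf)$speed
#' @export
estimate_group_velocity <- function(wf, method = c("envelope", "xcorr"),
                                    r2_threshold = 0.9, exclude_near = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(wf, "wavefield"))
  if (max(abs(wf$v)) == 0)
    abort("wavefield is identically zero: no arrival to pick",
          class = "nitioce_no_arrival")
  dt <- diff(wf$t[1:2])
  if (method == "envelope") {
    env <- envelope(wf$v)
    idx <- apply(env, 1, which.max)
    t_arr <- vapply(seq_len(nrow(env)), function(i)
      wf$t[1] + (refine_peak(env[i, ], idx[i]) - 1) * dt, numeric(1))
  } else {
    ref <- wf$v[1, ]
    n <- length(ref)
    m <- 2L^ceiling(log2(2L * n))
    R <- fft(c(ref, rep(0, m - n)))
    t_arr <- vapply(seq_len(nrow(wf$v)), function(i) {
      X <- fft(c(wf$v[i, ], rep(0, m - n)))
      cc <- Re(fft(X * Conj(R), inverse = TRUE)) / m
      cc <- c(cc[(m - n + 2):m], cc[1:n])      # lags -(n-1) .. (n-1)
      k <- which.max(cc)
      lag <- refine_peak(cc, k) - n
      lag * dt
    }, numeric(1))
    t_arr <- t_arr + wf$t[1]
  }
  if (is.null(exclude_near))
    exclude_near <- if (!is.null(wf$meta$sigma))
      2 * sqrt(2 * log(2)) * wf$meta$sigma else 0
  used <- (t_arr - min(t_arr)) >= exclude_near
  if (sum(used) < 3) used <- rep(TRUE, length(t_arr))
  fit <- lm(t_arr[used] ~ wf$x[used])
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0)
    abort("arrival times do not increase with distance: no consistent outgoing wave",
          class = "nitioce_bad_slope")
  r2 <- summary(fit)$r.squared
  if (is.finite(r2) && r2 < r2_threshold)
    warn(sprintf("low fit quality: R^2 = %.3f < %.2f", r2, r2_threshold),
         class = "nitioce_low_r2")
  structure(list(speed = 1 / slope, intercept = coef(fit)[[1]],
                 r_squared = r2,
                 arrivals = tibble(x_m = wf$x, t_arrival_s = t_arr, used = used),
                 method = method),
            class = "group_velocity")
}

#' @export
print.group_velocity <- function(x, ...) {
  cat(sprintf("<group_velocity> %.4g m/s (R^2 = %.4f, %s picker, %d/%d positions)\n",
              x$speed, x$r_squared, x$method, sum(x$arrivals$used),
              nrow(x$arrivals)))
  invisible(x)
}

#' Sliding-kernel local speed map
#'
#' Applies [estimate_group_velocity] to contiguous windows of `kernel`
#' lateral positions sliding with stride 1 across each wavefield row,
#' yielding `n_x - kernel` local speed estimates per row (window `j` spans
#' positions `j .. j + kernel - 1`; the count contract reproduces the
#' 100-position / 20-pixel / 80-estimate arithmetic of scar-mapping scans).
#'
#' @param rows A [wavefield] or list of wavefields (one per slow-axis row).
#' @param kernel Window length in positions; must be smaller than `n_x`.
#' @param ... Passed to [estimate_group_velocity] (near-field exclusion is
#'   disabled inside windows; fit-quality warnings are collected, not raised).
#' @return A tibble with columns `row`, `window`, `center_x_m`, `speed_m_s`,
#'   `r_squared`.
#' @examples
#' wf <- simulate_wavefield(speed = 2, n_x = 100)
#' nrow(local_speed_map(wf, kernel = 20))  # 80
#' @export
local_speed_map <- function(rows, kernel = 20, ...) {
  if (inherits(rows, "wavefield")) rows <- list(rows)
  purrr::imap_dfr(rows, function(wf, irow) {
    n_x <- length(wf$x)
    if (kernel >= n_x)
      abort(sprintf("kernel (%d) must be smaller than the number of positions (%d)",
                    kernel, n_x), class = "nitioce_kernel")
    starts <- seq_len(n_x - kernel)
    purrr::map_dfr(starts, function(j) {
      sel <- j:(j + kernel - 1)
      sub <- wavefield(wf$x[sel], wf$t, wf$v[sel, , drop = FALSE], wf$meta)
      est <- tryCatch(
        suppressWarnings(estimate_group_velocity(sub, exclude_near = 0, ...)),
        error = function(e) NULL)
      tibble(row = irow, window = j,
             center_x_m = mean(wf$x[sel]),
             speed_m_s = if (is.null(est)) NA_real_ else est$speed,
             r_squared = if (is.null(est)) NA_real_ else est$r_squared)
    })
  })
}
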