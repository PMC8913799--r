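# shared fixtures: representative material parameter sets (Pa)

iso_pars <- function(mu = 3e3, lambda_over_mu = 1e6)
  niti_params(mu = mu, G = mu, delta = 0, lambda = lambda_over_mu * mu)

skin_pars <- function(mu = 2e3, G = 6e3, delta = 8e3, ...)
  niti_params(mu = mu, G = G, delta = delta, ...)

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  code
}

# independent pulse-train wavefield builder (deliberately not
# simulate_wavefield): Gaussian-windowed tone bursts placed at prescribed
# per-position arrival times, so estimator tests do not share code with the
# package generator
arrivals_wavefield <- function(t_arrival, n_t = 512, fs = 46500,
                               dx = 54.7e-6, f0 = 1500, sigma = 2e-4) {
  x <- (seq_along(t_arrival) - 1) * dx
  t <- (seq_len(n_t) - 1) / fs
  v <- t(vapply(t_arrival, function(ta) {
    tau <- t - ta
    cos(2 * pi * f0 * tau) * exp(-tau^2 / (2 * sigma^2))
  }, numeric(n_t)))
  wavefield(x, t, v, meta = list(sigma = sigma))
}
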