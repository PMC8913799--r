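make_scan <- function(mu, G, delta, alpha, angles = default_angle_grid()) {
  p <- niti_params(mu = mu, G = G, delta = delta)
  rayleigh_curve(p, angles, alpha = alpha)[, c("angle_deg", "speed_m_s")]
}

test_that("noiseless scans round-trip all four parameters within 1%", {
  grid <- expand.grid(mu = c(1e3, 2e3, 4e3), gm = c(1.5, 3, 6),
                      dm = c(0.5, 2, 6))
  alphas <- rep(c(-60, 10, 45), length.out = nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; G <- grid$gm[i] * mu; delta <- grid$dm[i] * mu
    scan <- make_scan(mu, G, delta, alphas[i])
    fit <- suppressWarnings(fit_angle_scan(scan))
    expect_equal(fit$params$mu, mu, tolerance = 0.01)
    expect_equal(fit$params$G, G, tolerance = 0.01)
    expect_equal(fit$params$delta, delta, tolerance = 0.01)
    expect_lt(compare_axes(fit$alpha, alphas[i]), 1)
  }
})

test_that("no better optimum is missed: cost at the truth bounds the fitted cost", {
  scan <- make_scan(2e3, 6e3, 8e3, 10)
  fit <- fit_angle_scan(scan)
  cost <- function(mu, G, delta, alpha) {
    m <- rayleigh_curve(niti_params(mu = mu, G = G, delta = delta),
                        scan$angle_deg, alpha = alpha)$speed_m_s
    sum((m - scan$speed_m_s)^2)
  }
  expect_lte(fit$convergence$deviance,
             cost(2e3, 6e3, 8e3, 10) + 1e-10)
})

test_that("fiber orientation is recovered modulo 180 degrees", {
  s1 <- make_scan(2e3, 6e3, 8e3, 40)
  s2 <- make_scan(2e3, 6e3, 8e3, 40 + 180)
  expect_equal(s1$speed_m_s, s2$speed_m_s, tolerance = 1e-9)
  f1 <- fit_angle_scan(s1); f2 <- fit_angle_scan(s2)
  expect_lt(compare_axes(f1$alpha, f2$alpha), 0.01)
})

test_that("an isotropic scan yields G/mu near 1, delta near 0, and an alpha warning", {
  scan <- rayleigh_curve(iso_pars(mu = 3e3))[, c("angle_deg", "speed_m_s")]
  expect_warning(fit <- fit_angle_scan(scan),
                 class = "nitioce_alpha_unidentifiable")
  expect_equal(fit$params$G / fit$params$mu, 1, tolerance = 0.05)
  expect_lt(fit$params$delta / fit$params$mu, 0.05)
})

test_that("scan validation rejects unusable inputs", {
  expect_error(fit_angle_scan(data.frame(angle_deg = c(0, 15, 30),
                                         speed_m_s = c(1, 2, 3))),
               class = "nitioce_scan")
  expect_error(fit_angle_scan(data.frame(angle_deg = 0:12)),
               class = "nitioce_missing_column")
  bad <- make_scan(2e3, 6e3, 8e3, 0)
  bad$speed_m_s[3] <- -1
  expect_error(fit_angle_scan(bad), class = "nitioce_scan")
})

test_that("leave-one-out runs exactly N refits with vanishing spread on noiseless data", {
  scan <- make_scan(2e3, 6e3, 8e3, 10)
  lf <- loo_cv(scan)
  expect_identical(lf$loo$n_folds, 13L)
  rel_sd <- lf$loo$stats$sd / abs(lf$loo$stats$mean)
  expect_true(all(rel_sd < 1e-4))
  # LOO mean agrees with the full fit
  full <- fit_angle_scan(scan)
  expect_equal(lf$params$mu, full$params$mu, tolerance = 1e-4)
  expect_lt(compare_axes(lf$alpha, full$alpha), 0.01)
  # 6 angles are enough for a plain fit but not for LOO (needs N >= 7)
  expect_error(loo_cv(make_scan(2e3, 6e3, 8e3, 0,
                                angles = seq(-90, 60, 30))),
               class = "nitioce_scan")
})

test_that("LOO spread on a noisy scan matches the seeded Monte-Carlo spread in order of magnitude", {
  base <- make_scan(2e3, 6e3, 8e3, 10)
  noisy <- function(s) {
    sc <- base
    sc$speed_m_s <- sc$speed_m_s * (1 + with_seed_test(s, rnorm(13, sd = 0.02)))
    sc
  }
  lf <- suppressWarnings(loo_cv(noisy(1), n_restarts = 1))
  mc_alpha <- vapply(1:8, function(s)
    suppressWarnings(fit_angle_scan(noisy(s), n_restarts = 1))$alpha, numeric(1))
  loo_sd <- lf$loo$stats$sd[lf$loo$stats$term == "alpha"]
  mc_sd <- sd(mc_alpha)
  expect_gt(loo_sd, mc_sd / 30)
  expect_lt(loo_sd, mc_sd * 30)
})

test_that("derived anisotropy reports the closed-form ratios and bound flags", {
  fit <- fit_angle_scan(make_scan(1e3, 3e3, 4e3, 0))
  da <- derived_anisotropy(fit)
  expect_equal(da$EL_over_ET, 2.0, tolerance = 0.02)
  iso <- suppressWarnings(fit_angle_scan(
    rayleigh_curve(iso_pars())[, c("angle_deg", "speed_m_s")]))
  expect_equal(derived_anisotropy(iso)$EL_over_ET, 1, tolerance = 0.02)
  # delta driven onto a tight upper bound raises the bound-limited warning
  b <- default_fit_bounds(); b$upper[["delta"]] <- 2e3
  capped <- suppressWarnings(fit_angle_scan(make_scan(2e3, 6e3, 8e3, 10),
                                            bounds = b))
  expect_warning(derived_anisotropy(capped), class = "nitioce_delta_bound")
})

test_that("sd columns weight the fit without breaking recovery", {
  scan <- make_scan(2e3, 6e3, 8e3, 10)
  scan$sd_m_s <- rep(0.05, 13)
  fit <- fit_angle_scan(scan)
  expect_equal(fit$params$mu, 2e3, tolerance = 0.01)
  expect_identical(nrow(tidy(fit)), 4L)
  expect_identical(ncol(glance(fit)), 8L)
})
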