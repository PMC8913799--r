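test_that("pulse kinematics: the envelope peak travels at the requested speed", {
  wf <- simulate_wavefield(speed = 2, geometric_decay = FALSE)
  # envelope peak at x = 5.47 mm arrives exactly 2.735 ms after the x = 0 peak
  i <- which.min(abs(wf$x - 5.47e-3))
  t_peak <- function(row) wf$t[which.max(abs(row))]
  # use analytic arrival times from the estimator for sub-sample precision
  est <- estimate_group_velocity(wf, exclude_near = 0)
  lag <- est$arrivals$t_arrival_s[i] - est$arrivals$t_arrival_s[1]
  expect_equal(lag, 2.735e-3, tolerance = 1e-3)
})

test_that("doubling the speed halves the arrival-time slope", {
  s1 <- estimate_group_velocity(simulate_wavefield(speed = 2))
  s2 <- estimate_group_velocity(simulate_wavefield(speed = 4))
  expect_equal((1 / s2$speed) / (1 / s1$speed), 0.5, tolerance = 1e-3)
})

test_that("a fixed seed reproduces the field bit-for-bit", {
  a <- simulate_wavefield(speed = 3, noise_sd = 0.1, seed = 11)
  b <- simulate_wavefield(speed = 3, noise_sd = 0.1, seed = 11)
  expect_identical(a$v, b$v)
  c <- simulate_wavefield(speed = 3, noise_sd = 0.1, seed = 12)
  expect_false(identical(a$v, c$v))
})

test_that("generator rejects aliasing pulses and non-uniform grids", {
  expect_error(simulate_wavefield(speed = 2, center_freq = 22e3,
                                  bandwidth = 4e3),
               class = "nitioce_aliasing")
  expect_error(wavefield(c(0, 1e-3, 3e-3), (0:9) / 46500, matrix(0, 3, 10)),
               class = "nitioce_grid")
})

test_that("group-velocity estimation is accurate and unbiased across speeds", {
  for (sp in c(0.5, 1, 3, 10)) {
    # keep every arrival inside the record: aperture scales with speed
    n_x <- min(256, floor(sp * (512 / 46500 - 2.5e-3) / 54.7e-6))
    wf <- simulate_wavefield(speed = sp, n_x = n_x)
    est <- estimate_group_velocity(wf)
    expect_equal(est$speed, sp, tolerance = 5e-3)
    estx <- estimate_group_velocity(wf, method = "xcorr")
    expect_equal(estx$speed, sp, tolerance = 5e-3)
  }
})

test_that("the estimate is invariant to amplitude scaling", {
  wf <- simulate_wavefield(speed = 3, noise_sd = 0.02, seed = 5)
  wf2 <- wf; wf2$v <- wf$v * 137
  expect_identical(estimate_group_velocity(wf)$speed,
                   estimate_group_velocity(wf2)$speed)
})

test_that("estimation works on independently constructed pulse trains", {
  # arrival times laid down directly, not via the package generator
  x <- (0:99) * 54.7e-6
  wf <- arrivals_wavefield(2e-3 + x / 2.5)
  est <- estimate_group_velocity(wf, exclude_near = 0)
  expect_equal(est$speed, 2.5, tolerance = 5e-3)
  expect_gt(est$r_squared, 0.999)
})

test_that("degenerate fields are rejected", {
  flat <- wavefield((0:9) * 54.7e-6, (0:63) / 46500, matrix(0, 10, 64))
  expect_error(estimate_group_velocity(flat), class = "nitioce_no_arrival")
  # inward-travelling wave: arrivals decrease with x
  x <- (0:49) * 54.7e-6
  wf <- arrivals_wavefield(5e-3 - x / 2)
  expect_error(estimate_group_velocity(wf, exclude_near = 0),
               class = "nitioce_bad_slope")
})

test_that("noisy fields yield a low-quality warning below the R^2 threshold", {
  wf <- simulate_wavefield(speed = 3, noise_sd = 0.9, seed = 3,
                           geometric_decay = TRUE)
  expect_warning(try(estimate_group_velocity(wf, r2_threshold = 0.999),
                     silent = TRUE), class = "nitioce_low_r2")
})

test_that("sliding-kernel map honours the count contract n_x - kernel", {
  wf <- simulate_wavefield(speed = 2, n_x = 100)
  sm <- local_speed_map(wf, kernel = 20)
  expect_identical(nrow(sm), 80L)
  expect_identical(unique(sm$row), 1L)
  expect_error(local_speed_map(wf, kernel = 100), class = "nitioce_kernel")
})

test_that("a homogeneous field maps to a uniform speed", {
  wf <- simulate_wavefield(speed = 2, n_x = 100)
  sm <- local_speed_map(wf, kernel = 20)
  expect_true(all(abs(sm$speed_m_s - 2) / 2 < 0.01))
})

test_that("a two-region field resolves both speeds away from the interface", {
  x <- (0:99) * 54.7e-6
  x_if <- x[50]
  t_arr <- ifelse(x <= x_if, x / 1.5, x_if / 1.5 + (x - x_if) / 3)
  wf <- arrivals_wavefield(1e-3 + t_arr)
  sm <- local_speed_map(wf, kernel = 20)
  left <- sm$speed_m_s[sm$window + 19 <= 50]   # windows fully in region 1
  right <- sm$speed_m_s[sm$window > 50]        # windows fully in region 2
  expect_true(all(abs(left - 1.5) / 1.5 < 0.02))
  expect_true(all(abs(right - 3) / 3 < 0.02))
})

test_that("20 dB SNR leaves the median speed error under 2%", {
  # noise sd a tenth of the weakest trace's peak amplitude (~0.27 after
  # spreading decay over the 14 mm aperture)
  errs <- vapply(1:25, function(s) {
    wf <- simulate_wavefield(speed = 3, noise_sd = 0.027, seed = s)
    abs(suppressWarnings(estimate_group_velocity(wf))$speed - 3) / 3
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})
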