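test_that("a zero-retardance stack leaves the polarization state untouched", {
  tr <- simulate_stokes_trajectory(psi = 30, retardance = 0, n_steps = 20)
  expect_true(all(abs(tr$Q - 0) < 1e-12 & abs(tr$V - 1) < 1e-12))
})

test_that("one 90-degree step about a 30-degree axis lands where the rotation says", {
  tr <- simulate_stokes_trajectory(psi = 30, retardance = 90, n_steps = 1)
  # rotating (0,0,1) by 90 deg about (cos60, sin60, 0) gives (sin60, -cos60, 0)
  expect_equal(unlist(tr[2, c("Q", "U", "V")]),
               c(Q = sin(pi / 3), U = -cos(pi / 3), V = 0), tolerance = 1e-12)
})

test_that("states stay on the unit sphere over long stacks", {
  tr <- simulate_stokes_trajectory(psi = 17, retardance = 23, n_steps = 500)
  expect_true(all(abs(tr$Q^2 + tr$U^2 + tr$V^2 - 1) < 1e-9))
})

test_that("axis recovery is exact to 0.1 degree over orientation and retardance grids", {
  for (ret in c(2, 10, 60)) for (psi in seq(-85, 90, by = 5)) {
    tr <- simulate_stokes_trajectory(psi = psi, retardance = ret, n_steps = 10)
    pr <- estimate_axis_profile(tr)
    expect_true(all(pr$valid))
    expect_true(all(compare_axes(pr$psi_deg, psi) <= 0.1))
  }
})

test_that("non-birefringent trajectories are fully masked with a warning", {
  tr <- simulate_stokes_trajectory(psi = 30, retardance = 0, n_steps = 20)
  expect_warning(pr <- estimate_axis_profile(tr), class = "nitioce_all_masked")
  expect_true(all(!pr$valid))
})

test_that("a two-layer stack masks the surface and recovers the dermal axis", {
  tr <- simulate_stokes_trajectory(psi = c(rep(0, 15), rep(-40, 30)),
                                   retardance = c(rep(0, 15), rep(8, 30)))
  pr <- estimate_axis_profile(tr)
  surface <- pr$depth_um < 15 * 1.5 - 1.5
  expect_true(all(!pr$valid[surface]))
  deep <- pr$valid & pr$depth_um > 16 * 1.5
  expect_gt(sum(deep), 20)
  expect_true(all(compare_axes(pr$psi_deg[deep], -40) < 0.1))
})

test_that("estimates are invariant to rotating the input state about the generating axis", {
  ax <- c(cos(2 * 25 * pi / 180), sin(2 * 25 * pi / 180), 0)
  rot <- function(v, k, a) v * cos(a) + c(k[2] * v[3] - k[3] * v[2],
                                          k[3] * v[1] - k[1] * v[3],
                                          k[1] * v[2] - k[2] * v[1]) * sin(a) +
    k * sum(k * v) * (1 - cos(a))
  for (a0 in c(0.4, 1.5)) {
    s0 <- rot(c(0, 0, 1), ax, a0)
    tr <- simulate_stokes_trajectory(psi = 25, retardance = 12, n_steps = 12,
                                     input_state = s0)
    pr <- estimate_axis_profile(tr)
    expect_true(all(compare_axes(pr$psi_deg[pr$valid], 25) < 1e-6))
  }
})

test_that("generating with psi and psi + 180 yields identical estimates", {
  t1 <- simulate_stokes_trajectory(psi = 70, retardance = 9, n_steps = 15)
  t2 <- simulate_stokes_trajectory(psi = 70 + 180, retardance = 9, n_steps = 15)
  expect_equal(estimate_axis_profile(t1)$psi_deg,
               estimate_axis_profile(t2)$psi_deg, tolerance = 1e-9)
})

test_that("doubled-angle circular averaging folds wrap-around orientations correctly", {
  prof <- tibble::tibble(x = 1, depth_um = c(10, 20), psi_deg = c(85, -85),
                         valid = TRUE)
  expect_equal(depth_averaged_axis(prof)$psi_deg, 90)
  prof2 <- tibble::tibble(x = 1:3, depth_um = 10, psi_deg = 30, valid = TRUE)
  expect_equal(depth_averaged_axis(prof2)$psi_deg, rep(30, 3))
  expect_error(depth_averaged_axis(prof, depth_range = c(100, 200)),
               class = "nitioce_window")
})

test_that("noisy volumes recover the generating axis within 2 degrees", {
  ests <- vapply(1:40, function(s) {
    tr <- simulate_stokes_trajectory(psi = 35, retardance = 10, n_steps = 40,
                                     noise_sd = 0.05, seed = s)
    pr <- estimate_axis_profile(tr)
    circ_mean <- atan2(mean(sin(2 * pr$psi_deg[pr$valid] * pi / 180)),
                       mean(cos(2 * pr$psi_deg[pr$valid] * pi / 180))) * 90 / pi
    circ_mean
  }, numeric(1))
  expect_lt(compare_axes(atan2(mean(sin(2 * ests * pi / 180)),
                               mean(cos(2 * ests * pi / 180))) * 90 / pi, 35), 2)
})

test_that("masked fraction grows to one as retardance vanishes", {
  frac <- vapply(c(8, 2, 0.5, 0.05), function(ret) {
    tr <- simulate_stokes_trajectory(psi = 20, retardance = ret, n_steps = 30)
    pr <- suppressWarnings(estimate_axis_profile(tr))
    mean(!pr$valid)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_identical(frac[4], 1)
})

test_that("axis comparison returns the acute angle between orientations", {
  expect_identical(compare_axes(10.6, 10.6), 0)
  expect_equal(compare_axes(85, -85), 10)
  expect_equal(compare_axes(0, 90), 90)
  expect_equal(compare_axes(-30, 150), 0)
})
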