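test_that("isotropic reduction gives the Lame stiffness matrix", {
  mu <- 3e3; lam <- 1e6 * mu
  C <- niti_stiffness(niti_params(mu = mu, G = mu, delta = 0, lambda = lam))
  expected <- matrix(0, 6, 6)
  expected[1:3, 1:3] <- lam
  diag(expected)[1:3] <- lam + 2 * mu
  diag(expected)[4:6] <- mu
  expect_equal(C, expected)
})

test_that("transverse-isotropy symmetry C12 = C11 - 2 C66 holds for random valid parameters", {
  set.seed(7)
  for (i in 1:20) {
    p <- niti_params(mu = runif(1, 0.5, 10) * 1e3,
                     G = runif(1, 0.5, 10) * 1e3,
                     delta = runif(1, -1, 20) * 1e3,
                     Q1 = runif(1, -2, 2) * 1e3,
                     Q2 = NULL)
    C <- niti_stiffness(p)
    expect_identical(C[1, 2], C[1, 1] - 2 * C[6, 6])
    expect_identical(C, t(C))
  }
})

test_that("stiffness of a stiff fast-axis material is positive definite", {
  C <- niti_stiffness(niti_params(mu = 3e3, G = 9e3, delta = 6e3, lambda = 1e9))
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("parameter invariants are enforced with named violations", {
  expect_error(niti_params(mu = -1, G = 1e3), "mu must be > 0",
               class = "nitioce_invalid_params")
  expect_error(niti_params(mu = 1e3, G = 1e3, lambda = 1e3),
               "near-incompressible", class = "nitioce_invalid_params")
  expect_error(niti_params(mu = 1e3, delta = 2e3, Q1 = 1e3, Q2 = 1e3),
               "Q2 - 2\\*Q1", class = "nitioce_invalid_params")
})

test_that("engineering moduli reduce to E = 3 mu, nu = 1/2 at delta = 0", {
  m <- engineering_moduli(niti_params(mu = 2.5e3))
  expect_equal(m$E_T, 3 * 2.5e3)
  expect_equal(m$E_L, 3 * 2.5e3)
  expect_equal(m$nu_TT, 0.5)
  expect_equal(m$nu_TL, 0.5)
  expect_equal(m$nu_LT, 0.5)
})

test_that("engineering moduli match the closed-form worked example mu = 1 kPa, delta = 4 kPa", {
  m <- engineering_moduli(niti_params(mu = 1e3, delta = 4e3, G = 3e3))
  expect_equal(m$E_T, 3.5e3)
  expect_equal(m$E_L, 7e3)
  expect_equal(m$nu_TT, 0.75)
  expect_equal(m$nu_TL, 0.25)
  expect_equal(m$E_L / m$E_T, 2.0)
})

test_that("transverse Young's modulus saturates at 4 mu for extreme delta", {
  m <- engineering_moduli(niti_params(mu = 1e3, delta = 1e8 * 1e3,
                                      G = 1e3, lambda = 1e16))
  expect_equal(m$E_T / 1e3, 4, tolerance = 1e-6)
})

test_that("nu_TT + nu_TL = 1 to machine precision across parameter grid", {
  for (dm in c(0, 0.5, 1, 4, 20)) for (gm in c(0.2, 1, 10)) {
    m <- engineering_moduli(niti_params(mu = 1e3, delta = dm * 1e3, G = gm * 1e3))
    expect_identical(m$nu_TT + m$nu_TL, 1)
  }
})

test_that("E_T increases monotonically in delta, bounded by 4 mu; E_L is affine", {
  mu <- 1e3
  d <- seq(0, 20e3, by = 1e3)
  m <- dplyr::bind_rows(lapply(d, function(dd)
    engineering_moduli(niti_params(mu = mu, delta = dd))))
  expect_true(all(diff(m$E_T) > 0))
  expect_true(all(m$E_T < 4 * mu))
  expect_equal(m$E_L, 3 * mu + d)
})

test_that("compliance-matrix route agrees with closed forms over the parameter grid", {
  for (dm in c(0, 1, 5, 20)) for (gm in c(0.2, 1, 10)) {
    p <- niti_params(mu = 1e3, delta = dm * 1e3, G = gm * 1e3, lambda = 1e8 * 1e3)
    closed <- engineering_moduli(p)
    oracle <- moduli_from_compliance(niti_stiffness(p))
    for (col in names(closed))
      expect_equal(oracle[[col]], closed[[col]], tolerance = 1e-4)
  }
})

test_that("compliance route rejects a singular matrix", {
  C <- niti_stiffness(iso_pars())
  C[3, ] <- 0; C[, 3] <- 0
  expect_error(moduli_from_compliance(C), class = "nitioce_singular")
})

test_that("doubling lambda leaves derived moduli unchanged to 1e-4 relative", {
  p1 <- skin_pars()
  p2 <- skin_pars(lambda = 2 * p1$lambda)
  m1 <- moduli_from_compliance(niti_stiffness(p1))
  m2 <- moduli_from_compliance(niti_stiffness(p2))
  expect_equal(m2$E_T, m1$E_T, tolerance = 1e-4)
  expect_equal(m2$E_L, m1$E_L, tolerance = 1e-4)
})

test_that("validity diagnostics pass physical materials and flag negative-ratio ones", {
  expect_identical(nrow(validate_niti(niti_params(mu = 1e3, delta = 4e3, G = 3e3))), 0L)
  expect_identical(nrow(validate_niti(niti_params(mu = 1e3, G = 1e3, delta = 0))), 0L)
  v <- validate_niti(niti_params(mu = 1e3, delta = -2.5e3))
  expect_true(any(grepl("nu_TT", v$constraint)))
  # nu_TT = (1/2)(1 + (-2.5)/(4 - 2.5)) = -1/3
  expect_match(v$detail[grepl("nu_TT", v$constraint)], "-0.333")
})

test_that("parameter JSON interface round-trips in kPa units", {
  p <- skin_pars(rho = 1100)
  path <- withr::local_tempfile(fileext = ".json")
  write_niti_params(p, path)
  q <- read_niti_params(path)
  expect_equal(q[c("mu", "G", "delta", "rho", "lambda", "Q1")],
               p[c("mu", "G", "delta", "rho", "lambda", "Q1")])
})
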