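test_that("proposed correlation reproduces hand evaluation on a reference row", {
  # omega, Mw, Vc of the choline chloride : urea (1:2) pseudo-component
  u <- speed_proposed(0.6509, 86.58, 254.37, 298.15)
  expect_equal(u, 1799.055084, tolerance = 1e-8)
})

test_that("proposed correlation collapses to the intercept when omega and Vc vanish", {
  for (mw in c(0, 50, 300)) {
    for (t in c(278.15, 298.15, 338.15)) {
      expect_identical(speed_proposed(0, mw, 0, t), 2514.2)
    }
  }
})

test_that("temperature slope of the proposed correlation is -2.012 * omega", {
  for (omega in c(0.2, 0.6509, 1.3)) {
    u1 <- speed_proposed(omega, 120, 300, 298.15)
    u2 <- speed_proposed(omega, 120, 300, 308.15)
    expect_equal((u2 - u1) / 10, -2.012 * omega, tolerance = 1e-12)
  }
})

test_that("proposed correlation is linear in T, Vc and affine in omega*Mw", {
  k <- proposed_coefficients()
  # analytic partials via symmetric differences
  f <- function(om, mw, vc, t) speed_proposed(om, mw, vc, t)
  expect_equal((f(0.5, 100, 300, 310) - f(0.5, 100, 300, 290)) / 20,
               0.5 * k[["omega_t"]])
  expect_equal((f(0.5, 100, 320, 300) - f(0.5, 100, 280, 300)) / 40,
               k[["vc"]])
  expect_equal((f(0.5, 140, 300, 300) - f(0.5, 60, 300, 300)) / 80,
               0.5 * k[["omega_mw"]])
})

test_that("Curl-Pitzer surface tension matches hand arithmetic and limits", {
  # frozen hand evaluation on the choline chloride : urea pseudo-component
  expect_equal(surface_tension(644.44, 49.54, 0.6509, 298.15),
               52.006375, tolerance = 1e-7)
  # sigma -> 0 at the critical point
  expect_lt(surface_tension(644.44, 49.54, 0.6509, 644.44 - 1e-6), 1e-6)
  # strictly decreasing in T
  ts <- seq(280, 640, by = 20)
  sig <- surface_tension(644.44, 49.54, 0.6509, ts)
  expect_true(all(diff(sig) < 0))
  expect_error(surface_tension(644.44, 49.54, 0.6509, 700), "critical")
  expect_error(surface_tension(644.44, 49.54, 3.7, 298.15), "validity")
})

test_that("Gardas-Coutinho model obeys its logarithmic algebra", {
  expect_equal(speed_gardas(30, 1.1, list(alpha = 1, beta = 0)), 33)
  expect_equal(speed_gardas(5, 2, list(alpha = 0, beta = 2.5)), 10^2.5)
  a <- 0.87
  expect_equal(speed_gardas(60, 1.2, list(alpha = a, beta = 0.3)),
               2^a * speed_gardas(30, 1.2, list(alpha = a, beta = 0.3)))
  expect_error(speed_gardas(30, 1.1, list(alpha = NULL, beta = 1)),
               "transcribe")
})

test_that("Singh-Singh model mirrors the same contract", {
  expect_equal(speed_singh(30, 1.1, list(psi = 1, xi = 0)), 33)
  expect_equal(speed_singh(9, 9, list(psi = 0, xi = 3)), 1000)
  p <- 1.4
  expect_equal(speed_singh(80, 1, list(psi = p, xi = -0.1)),
               2^p * speed_singh(40, 1, list(psi = p, xi = -0.1)))
  expect_error(speed_singh(30, 1.1, list(psi = 1)), "xi")
})

test_that("Hekayati-Esmaeilzadeh model reduces and evaluates correctly", {
  zero <- list(a = 0, b = 0, c = 0, d = 0, e = 0, f = 0)
  expect_equal(speed_hekayati(30, 1.1, 100, 298.15, zero), 1)
  # with b = c = d = e = 0 it is the Gardas form in natural logarithm
  k <- list(a = 0.9, b = 0, c = 0, d = 0, e = 0, f = 0.4)
  expect_equal(speed_hekayati(25, 1.2, 100, 298.15, k),
               exp(0.9 * log(25 * 1.2) + 0.4))
  # randomized input against independent arithmetic
  kk <- list(a = 0.5, b = 0.002, c = 0.01, d = -1e-5, e = 0.003, f = 1.2)
  got <- speed_hekayati(41.7, 1.13, 123.4, 305.2, kk)
  expect_equal(got, exp((0.5 + 0.002 * 123.4) * log(41.7 * 1.13) +
                          0.01 * 123.4 - 1e-5 * 123.4^2 -
                          0.003 * 305.2 + 1.2))
  # quotient reading switch
  kq <- c(kk, list(mw_term = "inverse"))
  expect_equal(speed_hekayati(41.7, 1.13, 123.4, 305.2, kq),
               exp((0.5 + 0.002 / 123.4) * log(41.7 * 1.13) +
                     0.01 * 123.4 - 1e-5 * 123.4^2 - 0.003 * 305.2 + 1.2))
})

test_that("atomic-contribution model accumulates increments linearly", {
  zero <- list(dA = list(C = 0, H = 0), dB = list(C = 0, H = 0))
  expect_equal(speed_haghbakhsh(c(C = 2, H = 6), 300, zero), 0)
  k <- list(dA = list(C = 0.3, H = 0.05), dB = list(C = -0.01, H = 0.002))
  u1 <- speed_haghbakhsh(c(C = 1), 300, k, mw_g_mol = 12.011)
  u2 <- speed_haghbakhsh(c(C = 2), 300, k, mw_g_mol = 12.011)
  # doubling the single atom count doubles both A and B
  expect_equal(u2, 2 * u1)
  # worked case against a brute-force summation oracle
  counts <- c(C = 2, H = 6, O = 1)
  k2 <- list(dA = list(C = 0.21, H = 0.033, O = 0.6),
             dB = list(C = -0.004, H = 0.0011, O = -0.02))
  a <- 2 * 0.21 + 6 * 0.033 + 1 * 0.6
  b <- 2 * -0.004 + 6 * 0.0011 + 1 * -0.02
  mw <- molecular_weight(counts)
  expect_equal(speed_haghbakhsh(counts, 310, k2), a * mw + b * 310)
  expect_error(speed_haghbakhsh(c(C = 1, S = 2), 300, k), "S")
})

test_that("high-level prediction runs all models on registry DESs", {
  consts <- literature_constants()
  consts$gardas <- list(alpha = 0.65, beta = 1.0)
  consts$singh <- list(psi = 1.2, xi = -0.3)
  consts$hekayati <- list(a = 0.7, b = 1e-4, c = 1e-3, d = -1e-6,
                          e = 1e-3, f = 2.0, mw_term = "product")
  consts$haghbakhsh <- list(
    dA = list(C = 0.5, H = 0.1, O = 0.4, N = 0.4, Cl = 0.2, S = 0.3),
    dB = list(C = -0.05, H = -0.01, O = -0.04, N = -0.04, Cl = -0.02,
              S = -0.03),
    mw_term = "product"
  )
  pred <- predict_speed(
    c("DES20", "DES21", "DES31"), t_k = c(278.15, 298.15, 338.15),
    models = c("proposed", "gardas", "hekayati", "singh", "haghbakhsh"),
    constants = consts, density = density_constant(1.1)
  )
  expect_equal(nrow(pred), 3 * 3 * 5)
  expect_true(all(is.finite(pred$u_ms)))
  expect_true(all(pred$u_ms > 0))
})

test_that("density-dependent models demand a density provider", {
  expect_error(predict_speed("DES21", 298.15, models = "gardas"),
               "density")
})

test_that("mixture formulas are mole-fraction-weighted atom counts", {
  f <- mixture_formula("DES21")
  # (1 * C5H14ClNO + 2 * CH4N2O) / 3
  expect_equal(f[["C"]], (5 + 2) / 3)
  expect_equal(f[["N"]], (1 + 4) / 3)
  expect_equal(f[["Cl"]], 1 / 3)
  expect_equal(molecular_weight(f), 86.58, tolerance = 0.02 / 86.58)
})
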