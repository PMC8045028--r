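test_that("ionic strength: 1:1 identity, Na5TPP expansion, z^2 symmetry", {
  expect_equal(ionic_strength(salt_species("NaCl", 0.1)), 0.1)
  # 11 mM fully dissociated pentasodium TPP: 55 mM Na+ + 11 mM TPP(5-)
  expect_equal(ionic_strength(salt_species("Na5TPP", 0.011)), 0.165)
  expect_equal(ionic_strength(c(0.01, 0.01), c(3, -3)),
               ionic_strength(c(0.01, 0.01), c(-3, 3)))
  # additive over species lists and homogeneous of degree 1
  a <- salt_species("NaCl", 0.05)
  b <- salt_species("Na4PP", 0.002)
  expect_equal(ionic_strength(rbind(a, b)),
               ionic_strength(a) + ionic_strength(b))
  expect_equal(ionic_strength(rbind(a, b) |> transform(conc = conc * 3)),
               3 * ionic_strength(rbind(a, b)))
  expect_error(salt_species("KCl2", 0.1), "unknown salt")
  expect_equal(ionic_strength(salt_species("custom", 0.01, n_cation = 2,
                                           z_anion = -2)),
               0.5 * (0.02 + 0.01 * 4))
})

test_that("anion-per-protein ratio arithmetic", {
  expect_equal(cs_cp(1.713, 5.2, 3036), 1, tolerance = 1e-3)
  # equal molarities give 1; doubling protein halves the ratio
  expect_equal(cs_cp(1, 3036.3 / 1000, 3036.3), 1)
  expect_equal(cs_cp(2, 5.2), 2 * cs_cp(1, 5.2))
  expect_equal(cs_cp(1, 10.4), cs_cp(1, 5.2) / 2)
  expect_error(cs_cp(1, 0), "> 0")
})

test_that("boundary detection recovers constructed crossings", {
  # V-shaped series with known 95% crossings at 1.5 and 12 mM
  c0 <- 5.2
  thr <- 0.95 * c0
  x <- c(0.5, 1.0, 1.5, 2.5, 4, 8, 12, 20, 40)
  y <- c(c0, c0, thr, 1.4, 1.0, 1.1, thr, c0, c0)
  ser <- precipitation_series(x, y, c0)
  b <- detect_boundaries(ser)
  expect_equal(b$c_star, 1.5)
  expect_equal(b$c_double_star, 12)
  expect_equal(b$c_max, 4)
  expect_equal(unname(b$ratios["c_max"]), cs_cp(4, c0))
  # scaling invariance: boundaries scale with the concentration axis
  b2 <- detect_boundaries(precipitation_series(7 * x, y, c0))
  expect_equal(b2$c_star, 7 * b$c_star)
  expect_equal(b2$c_double_star, 7 * b$c_double_star)
})

test_that("one-sided and degenerate series are handled", {
  c0 <- 5
  flat <- precipitation_series(c(1, 2, 4, 8), rep(c0, 4), c0)
  bf <- detect_boundaries(flat)
  expect_true(is.na(bf$c_star) && is.na(bf$c_double_star) && is.na(bf$c_max))
  # condensation without recovery: C* found, C** absent
  onesided <- precipitation_series(c(1, 2, 4, 8, 16), c(5, 5, 3, 1, 0.8), c0)
  bo <- detect_boundaries(onesided)
  expect_false(is.na(bo$c_star))
  expect_true(is.na(bo$c_double_star))
  expect_error(precipitation_series(c(1, 3, 2, 4), rep(5, 4), c0),
               "increasing")
  expect_error(detect_boundaries(precipitation_series(c(1, 2, 3),
                                                      rep(5, 3), c0)),
               "at least 4")
})

test_that("boundary-line fit recovers slope and intercept", {
  cp <- c(0.5, 1, 2, 3, 4) * 1e-3        # mol/L
  cstar <- 0.762 * cp + 0.000355
  fit <- fit_cstar_line(cp, cstar)
  expect_equal(fit$m_star, 0.762, tolerance = 1e-12)
  expect_equal(fit$c_f, 0.355, tolerance = 1e-12)
  expect_equal(fit$n_points, 5)
  # two points: exact interpolation
  fit2 <- fit_cstar_line(cp[c(1, 5)], cstar[c(1, 5)])
  expect_equal(fit2$m_star, 0.762, tolerance = 1e-12)
  expect_error(fit_cstar_line(rep(1e-3, 3), c(1, 2, 3) * 1e-3), "distinct")
})

test_that("charge contribution multiplies m* by the anion valence magnitude", {
  expect_equal(charge_contribution(0.762, -5), 3.81)
  expect_equal(charge_contribution(0.723, 5), 3.615)
  expect_equal(charge_contribution(0, -5), 0)
  expect_error(charge_contribution(-1, 5), "m_star")
})

test_that("NaCl equivalence: identity, background subtraction, round trip", {
  expect_equal(nacl_equivalent(0.16), 0.16)
  bg <- salt_species("Na5TPP", 0.002)     # I = 0.03
  expect_equal(nacl_equivalent(0.16, bg), 0.16 - ionic_strength(bg))
  # self-consistency: adding the result reproduces the target
  for (target in c(0.08, 0.16, 0.36)) {
    c_nacl <- nacl_equivalent(target, bg)
    expect_equal(ionic_strength(rbind(bg, salt_species("NaCl", c_nacl))),
                 target, tolerance = 1e-12)
  }
  expect_error(nacl_equivalent(0.01, bg), "below the background")
})
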