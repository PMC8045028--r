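test_that("hard-sphere potential is infinite below contact and zero at it", {
  expect_identical(hard_sphere_pair(3.9, 2, 2), Inf)
  expect_identical(hard_sphere_pair(4.0, 2, 2), 0)   # contact allowed
  expect_identical(hard_sphere_pair(100, 2, 2), 0)
})

test_that("Debye-Hueckel reduces to Coulomb at kappa = 0", {
  ff <- forcefield(kappa = 0)
  # two unit charges one Bjerrum length apart interact with exactly 1 kT
  lB <- bjerrum_length(ff$temperature, ff$dielectric)
  expect_equal(lB, 7.149, tolerance = 1e-3)
  expect_equal(debye_huckel_pair(1, 1, lB, ff), 1.0, tolerance = 1e-12)
  expect_equal(debye_huckel_pair(0, 0, 5, ff), 0)
  expect_equal(debye_huckel_pair(0, 3, 5, ff), 0)
})

test_that("Debye-Hueckel sign rule and screened decay", {
  ff <- forcefield(ionic_strength = 0.1)
  for (r in c(4.5, 7, 12, 30))
    expect_lt(debye_huckel_pair(1, -5, r, ff), 0)
  # u(2r)/u(r) = exp(-kappa r)/2 exactly for this functional form
  for (r in c(5, 10, 20)) {
    u1 <- debye_huckel_pair(1, 1, r, ff)
    u2 <- debye_huckel_pair(1, 1, 2 * r, ff)
    expect_lt(u2, u1 * exp(-ff$kappa * r) / 2 * 1.001)
    expect_equal(u2, u1 * exp(-ff$kappa * r) / 2, tolerance = 1e-9)
  }
  expect_error(debye_huckel_pair(1, 1, 0, ff), "r > 0")
})

test_that("short-range term gives 8 kT at Arg-ion contact across room temperature", {
  for (T in c(293, 295, 298)) {
    ff <- forcefield(temperature = T)
    u <- abs(short_range_pair(4, 8.0e4, ff))
    expect_gte(u, 7.85)
    expect_lte(u, 8.15)
  }
  ff <- forcefield()
  expect_equal(short_range_pair(4, 0, ff), 0)
  # r^-6 scaling: halving the distance multiplies the magnitude by 64
  expect_equal(short_range_pair(2, 8e4, ff) / short_range_pair(4, 8e4, ff),
               64, tolerance = 1e-12)
  # generic default gives the 0.6 kT bead-bead contact attraction
  expect_equal(abs(short_range_pair(4, ff$epsilon_generic, ff)), 0.6,
               tolerance = 2e-3)
})

test_that("bond potential: equilibrium, symmetry, unit conversion", {
  ff <- forcefield(temperature = 298.15)
  expect_equal(bond_pair(4.1, ff), 0)
  for (d in c(0.1, 0.5, 2))
    expect_equal(bond_pair(4.1 + d, ff), bond_pair(4.1 - d, ff))
  # 0.4 N/m = 0.4e-20 J/A^2 -> x N_A / 1000 = 2.409 kJ/mol/A^2
  k_kJ <- 0.4 * 1e-20 * 6.02214076e23 / 1000
  expect_equal(k_kJ, 2.409, tolerance = 1e-3)
  expect_equal(ff$k_bond_kT, k_kJ / (8.314462618e-3 * 298.15),
               tolerance = 1e-9)
  expect_equal(ff$k_bond_kT, 0.97, tolerance = 0.01)
})

test_that("Debye kappa: closed form, zero limit, sqrt(I) scaling", {
  expect_equal(debye_kappa(0), 0)
  # 0.1 M 1:1 salt at 298.15 K: Debye length ~ 9.6 A
  expect_equal(1 / debye_kappa(0.1, 298.15, 78.4), 9.61, tolerance = 1e-2)
  expect_equal(debye_kappa(0.4), 2 * debye_kappa(0.1), tolerance = 1e-12)
  expect_error(debye_kappa(-1), ">= 0")
})

test_that("total energy matches the brute-force double-loop oracle", {
  ff <- forcefield(ionic_strength = 0.02)
  for (s in 1:10) {
    st <- random_state(s)
    expect_equal(total_energy(st, ff), oracle_total_energy(st, ff),
                 tolerance = 1e-11, info = paste("seed", s))
  }
})

test_that("total energy equals the sum of the exposed pair operations", {
  # pairwise additivity, assembled from the R-level pair functions
  ff <- forcefield(ionic_strength = 0.05)
  st <- random_state(77)
  d <- pair_distances(st)
  n <- nrow(st$coords)
  U <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    U <- U + hard_sphere_pair(d[i, j], st$radius[i], st$radius[j])
    U <- U + debye_huckel_pair(st$charge[i], st$charge[j], d[i, j], ff,
                               st$radius[i], st$radius[j])
    eps <- if (st$is_ion[i] || st$is_ion[j]) {
      if ((st$is_arg[i] && st$is_polyion[j]) ||
          (st$is_arg[j] && st$is_polyion[i])) ff$epsilon_arg_ion else 0
    } else (st$eps[i] + st$eps[j]) / 2
    U <- U + short_range_pair(d[i, j], eps, ff)
  }
  for (b in seq_len(nrow(st$bonds)))
    U <- U + bond_pair(d[st$bonds[b, 1], st$bonds[b, 2]], ff)
  expect_equal(total_energy(st, ff), U, tolerance = 1e-11)
})

test_that("total energy is invariant under rigid translation and ion relabeling", {
  ff <- forcefield()
  st <- random_state(5)
  u0 <- total_energy(st, ff)
  st2 <- st
  st2$coords <- sweep(st$coords, 2, c(137.2, -41.8, 402.1), "+")
  expect_equal(total_energy(st2, ff), u0, tolerance = 1e-9)
  # permute the identical TPP ions
  ions <- which(st$species == "TPP")
  perm <- seq_len(nrow(st$coords))
  perm[ions] <- rev(ions)
  st3 <- st
  st3$coords <- st$coords[perm, ]
  expect_equal(total_energy(st3, ff), u0, tolerance = 1e-9)
})

test_that("isolated neutral bead has zero energy; overlaps give Inf", {
  ff <- forcefield()
  one <- system_state(matrix(c(1, 2, 3), 1), "G", 0, 2, periodic = FALSE)
  expect_equal(total_energy(one, ff), 0)
  two <- system_state(rbind(c(0, 0, 0), c(3.5, 0, 0)), c("G", "G"),
                      c(0, 0), c(2, 2), periodic = FALSE)
  expect_identical(total_energy(two, ff), Inf)
})
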