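test_that("Metropolis rule: downhill always, overlap never, e^-1 at 1 kT", {
  expect_true(metropolis_accept(-1, 0.999999))
  expect_true(metropolis_accept(0, 0.999999))
  expect_false(metropolis_accept(Inf, 1e-12))
  set.seed(4)
  n <- 1e5
  frac <- mean(metropolis_accept(rep(1, n), runif(n)))
  p <- exp(-1)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("chain translation and pivot are isometries of the chain", {
  ff <- forcefield()
  st <- gen_system(load_sequence(hst5_sequence), c(), seed = 2, ff = ff)
  d0 <- pair_distances(st)
  idx <- which(!st$is_ion)
  set.seed(1)
  tr <- propose_move(st, "chain_translate", ff, amplitude = 8)
  expect_equal(pair_distances(tr)[idx, idx], d0[idx, idx], tolerance = 1e-9)
  pv <- propose_move(st, "pivot", ff, amplitude = pi / 2)
  b <- st$bonds
  bl <- function(s) sqrt(rowSums((s$coords[b[, 1], ] - s$coords[b[, 2], ])^2))
  expect_equal(bl(pv), bl(st), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(pv$coords, st$coords)))
})

test_that("slither preserves chain length and species multiset", {
  ff <- forcefield()
  st <- gen_system(load_sequence(hst5_sequence), c(TPP = 5), seed = 3, ff = ff)
  set.seed(11)
  for (k in 1:200) {
    sl <- propose_move(st, "slither", ff)
    expect_identical(dim(sl$coords), dim(st$coords))
    expect_identical(sl$species, st$species)
    # interior coordinates are a shift of the old chain positions
    idx <- which(!st$is_ion)
    shared <- sum(sl$coords[idx, 1] %in% st$coords[idx, 1])
    expect_gte(shared, length(idx) - 1)
    st <- sl
  }
})

test_that("runs are deterministic in the seed and echo their config", {
  ff <- forcefield()
  st <- gen_system(load_sequence(hst5_sequence), c(TPP = 5), seed = 8, ff = ff)
  cfg <- mc_config(n_equilibration = 2000, n_production = 4000,
                   sample_interval = 100, seed = 21)
  t1 <- run_mc(st, ff, cfg)
  t2 <- run_mc(st, ff, cfg)
  expect_identical(t1$energies, t2$energies)
  expect_identical(t1$frames[[length(t1$frames)]],
                   t2$frames[[length(t2$frames)]])
  t3 <- run_mc(st, ff, mc_config(n_equilibration = 2000, n_production = 4000,
                                 sample_interval = 100, seed = 22))
  expect_false(identical(t1$energies, t3$energies))

  empty <- run_mc(st, ff, mc_config(n_equilibration = 100, n_production = 0,
                                    sample_interval = 100, seed = 1))
  expect_length(empty$frames, 0)
  expect_equal(empty$config$n_production, 0L)
})

test_that("no recorded frame contains a hard-sphere overlap", {
  ff <- forcefield()
  st <- gen_system(load_sequence(hst5_sequence), c(TPP = 8), seed = 9, ff = ff)
  tr <- run_mc(st, ff, mc_config(n_equilibration = 2000, n_production = 10000,
                                 sample_interval = 200, seed = 5))
  for (k in seq_along(tr$frames)) {
    fs <- frame_state(tr, k)
    d <- pair_distances(fs)
    diag(d) <- Inf
    sig <- outer(fs$radius, fs$radius, "+")
    expect_true(all(d >= sig - 1e-9), info = paste("frame", k))
  }
  # recorded energies agree with recomputation from the frames
  k <- length(tr$frames)
  expect_equal(tr$energies[k], total_energy(frame_state(tr, k), ff),
               tolerance = 1e-8)
})

test_that("slither-only sampling preserves the bond-length distribution", {
  # detailed-balance check for the regrown-bond reptation move: with only
  # slither moves, a two-bead dumbbell must still sample
  # P(r) ~ r^2 exp(-U_bond) truncated at hard-sphere contact
  ff <- forcefield(kappa = 0)
  st <- system_state(rbind(c(0, 0, 0), c(4.1, 0, 0)), c("G", "G"), c(0, 0),
                     c(2, 2), chain_id = c(1L, 1L), bonds = cbind(1, 2),
                     box_length = 250)
  cfg <- mc_config(n_equilibration = 1000, n_production = 4e4,
                   sample_interval = 2, seed = 13,
                   move_weights = c(single = 0, pivot = 0, chain = 0,
                                    slither = 1))
  tr <- run_mc(st, ff, cfg)
  r <- vapply(tr$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)), 0)
  edges <- c(seq(4, 7, by = 0.5), Inf)
  p <- bond_bin_probs(edges, ff$k_bond_kT, ff$r0)
  obs <- table(cut(r, edges, include.lowest = TRUE))
  expect_gt(stats::chisq.test(as.integer(obs), p = p)$p.value, 0.01)
})

test_that("ideal-chain limit reproduces the freely jointed end-to-end distance", {
  # electrostatics and short-range off, vanishing bead radius:
  # <Ree^2> = (N-1) <b^2> for a 10-bead chain
  ff <- forcefield(kappa = 0, epsilon_generic = 0)
  st <- gen_system(load_sequence("GGGGGGGGGG", pH = 7), c(),
                   box_length = 250, seed = 5, ff = ff)
  st$radius[] <- 0.01
  st$charge[] <- 0
  tr <- run_mc(st, ff, mc_config(n_equilibration = 5e4, n_production = 1e6,
                                 sample_interval = 100, seed = 9))
  ree2 <- vapply(tr$frames, function(f) sum((f[1, ] - f[10, ])^2), 0)
  dens <- function(x) x^2 * exp(-0.5 * ff$k_bond_kT * (x - ff$r0)^2)
  b2 <- stats::integrate(function(x) x^2 * dens(x), 0, Inf)$value /
    stats::integrate(dens, 0, Inf)$value
  expect_equal(mean(ree2), 9 * b2, tolerance = 0.05)
})

test_that("initial overlaps are rejected up front", {
  ff <- forcefield()
  bad <- system_state(rbind(c(0, 0, 0), c(1, 0, 0)), c("G", "G"), c(0, 0),
                      c(2, 2), chain_id = c(1L, 1L), bonds = cbind(1, 2))
  expect_error(run_mc(bad, ff, mc_config(n_equilibration = 10,
                                         n_production = 10, seed = 1)),
               "overlap")
})

test_that("trajectory export writes XYZ frames", {
  ff <- forcefield()
  st <- gen_system(load_sequence("GGG", pH = 7), c(TPP = 2), seed = 4, ff = ff)
  tr <- run_mc(st, ff, mc_config(n_equilibration = 100, n_production = 300,
                                 sample_interval = 100, seed = 2))
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  lines <- readLines(f)
  expect_length(lines, length(tr$frames) * (nrow(st$coords) + 2))
  expect_equal(as.integer(lines[1]), nrow(st$coords))
  unlink(f)
})
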