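rod_state <- function(n = 24, b = 4.1, box = 250) {
  co <- cbind(seq(0, by = b, length.out = n), 0, 0)
  system_state(co, rep("G", n), rep(0, n), rep(2, n),
               chain_id = rep(1L, n), bonds = cbind(1:(n - 1), 2:n),
               box_length = box, periodic = TRUE)
}

test_that("radius of gyration: closed forms for point, pair and rod", {
  one <- system_state(matrix(c(5, 5, 5), 1), "G", 0, 2,
                      chain_id = 1L, periodic = FALSE)
  expect_equal(radius_of_gyration(one), 0)
  two <- system_state(rbind(c(0, 0, 0), c(10, 0, 0)), c("G", "G"), c(0, 0),
                      c(2, 2), chain_id = c(1L, 1L), bonds = cbind(1, 2),
                      periodic = FALSE)
  expect_equal(radius_of_gyration(two), 5)
  # straight rod of N beads at spacing b: Rg = b sqrt((N^2-1)/12)
  st <- rod_state()
  expect_equal(radius_of_gyration(st), 4.1 * sqrt((24^2 - 1) / 12),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(st, chain_id = 9), "unknown chain")
})

test_that("Rg is invariant under rigid motion and periodic wrapping", {
  st <- rod_state()
  rg0 <- radius_of_gyration(st)
  # rigid translation + rotation
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  st2 <- st
  st2$coords <- sweep(st$coords %*% Rz, 2, c(90, -30, 11), "+")
  expect_equal(radius_of_gyration(st2), rg0, tolerance = 1e-9)
  # wrap individual beads by whole box lengths: bond-walk unwrap undoes it
  st3 <- st
  st3$coords[5, ] <- st3$coords[5, ] + c(250, 0, 0)
  st3$coords[17, ] <- st3$coords[17, ] - c(0, 500, 0)
  expect_equal(radius_of_gyration(st3), rg0, tolerance = 1e-9)
})

test_that("block-averaged SEM behaves like 1/sqrt(n) on white noise", {
  set.seed(2)
  v <- rnorm(4000)
  s <- observable_series(v, block_size = 40)
  expect_equal(s$mean, mean(v))
  expect_gt(s$sem, 0)
  expect_equal(s$sem, 1 / sqrt(4000), tolerance = 0.35)
  s2 <- observable_series(v[1:1000], block_size = 40)
  expect_equal(s2$sem / s$sem, 2, tolerance = 0.5)
})

test_that("arg-ion contacts match a brute-force double loop", {
  ff <- forcefield()
  st0 <- system_state(rbind(c(0, 0, 0), c(4, 0, 0)), c("R", "TPP"),
                      c(1, -5), c(2, 2), is_ion = c(FALSE, TRUE),
                      chain_id = c(1L, NA), periodic = FALSE)
  expect_equal(arg_ion_contacts(st0, 4.5), 1)
  expect_equal(arg_ion_contacts(st0, 3.9), 0)
  no_ion <- system_state(matrix(0, 1, 3), "R", 1, 2, chain_id = 1L)
  expect_equal(arg_ion_contacts(no_ion), 0)
  for (s in 1:5) {
    st <- random_state(s)
    d <- pair_distances(st)
    brute <- 0
    for (i in which(st$is_arg)) for (j in which(st$is_polyion))
      if (d[i, j] <= 4.5) brute <- brute + 1
    expect_equal(arg_ion_contacts(st, 4.5), brute, info = paste("seed", s))
  }
})

test_that("cluster sizes: singles, pairs and ion bridges", {
  mk <- function(coords, ion_at = NULL) {
    n <- nrow(coords)
    ion <- seq_len(n) %in% ion_at
    system_state(coords, ifelse(ion, "TPP", "G"),
                 ifelse(ion, -5, 0), rep(2, n), is_ion = ion,
                 chain_id = ifelse(ion, NA, rep(c(1L, 2L),
                                                each = (n - length(ion_at)) / 2)),
                 box_length = 250, periodic = TRUE)
  }
  single <- system_state(rbind(c(0, 0, 0), c(4.1, 0, 0)), c("G", "G"),
                         c(0, 0), c(2, 2), chain_id = c(1L, 1L))
  expect_equal(cluster_sizes(single), 1L)
  # two 2-bead chains far apart
  far <- mk(rbind(c(0, 0, 0), c(4.1, 0, 0), c(100, 0, 0), c(104.1, 0, 0)))
  expect_equal(cluster_sizes(far, 4.5), c(1L, 1L))
  # direct contact
  close_ <- mk(rbind(c(0, 0, 0), c(4.1, 0, 0), c(8.2, 0, 0), c(12.3, 0, 0)))
  expect_equal(cluster_sizes(close_, 4.5), 2L)
  # bridged only through a shared ion 4 A from each chain end
  bridged <- mk(rbind(c(0, 0, 0), c(4.1, 0, 0),
                      c(12.1, 0, 0), c(16.2, 0, 0),
                      c(8.1, 0, 0)), ion_at = 5)
  expect_equal(cluster_sizes(bridged, 4.5), 2L)
  expect_equal(cluster_sizes(bridged, 3.0), c(1L, 1L))
})

test_that("Debye scattering: closed forms and Guinier consistency", {
  q <- seq(0.01, 0.5, by = 0.01)
  one <- system_state(matrix(0, 1, 3), "G", 0, 2, chain_id = 1L)
  tr1 <- fake_trajectory(list(one$coords), one)
  cv1 <- debye_scattering(tr1, q)
  expect_equal(cv1$intensity, rep(1, length(q)))
  # rigid pair at distance d: I(q) = (1 + sinc(qd)) / 2
  d <- 7.3
  two <- system_state(rbind(c(0, 0, 0), c(d, 0, 0)), c("G", "G"), c(0, 0),
                      c(2, 2), chain_id = c(1L, 1L), bonds = cbind(1, 2))
  cv2 <- debye_scattering(fake_trajectory(list(two$coords), two), q)
  expect_equal(cv2$intensity, 0.5 * (1 + sin(q * d) / (q * d)),
               tolerance = 1e-12)
  # Guinier fit of a fixed compact frame recovers that frame's Rg within 1%
  ff <- forcefield()
  st <- gen_system(load_sequence(hst5_sequence), c(), seed = 14, ff = ff)
  rg <- radius_of_gyration(st)
  qg <- seq(0.002, 0.9 / rg, length.out = 60)
  cv <- debye_scattering(fake_trajectory(list(st$coords), st), qg)
  fit <- guinier_fit(cv)
  expect_equal(fit$rg, rg, tolerance = 0.01)
  # monotone non-increasing on the Guinier window for a globule-like frame
  win <- cv$q * rg < 1.2
  expect_true(all(diff(cv$intensity[win]) <= 1e-12))
  expect_error(debye_scattering(fake_trajectory(list(), st), qg), "empty")
})
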