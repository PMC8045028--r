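# Independent oracles used across the suite. These re-derive the model
# from first principles (inline formulas, plain double loops) and never
# call the compiled path they are used to check.

# brute-force total energy: double loop over pairs + bonds
oracle_total_energy <- function(st, ff) {
  n <- nrow(st$coords)
  L <- st$box_length
  mi <- function(d) if (st$periodic) d - L * round(d / L) else d
  kT_kJ <- 8.314462618e-3 * ff$temperature
  lB <- 1.602176634e-19^2 /
    (4 * pi * 8.8541878128e-12 * ff$dielectric * 1.380649e-23 *
       ff$temperature) * 1e10
  kb <- ff$k_bond * 1e-20 / (1.380649e-23 * ff$temperature)
  U <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum(mi(st$coords[i, ] - st$coords[j, ])^2))
    sig <- st$radius[i] + st$radius[j]
    if (r < sig) return(Inf)
    qq <- st$charge[i] * st$charge[j]
    if (qq != 0)
      U <- U + qq * lB / r * exp(-ff$kappa * (r - sig)) /
        ((1 + ff$kappa * st$radius[i]) * (1 + ff$kappa * st$radius[j]))
    eps <- if (st$is_ion[i] || st$is_ion[j]) {
      if ((st$is_arg[i] && st$is_polyion[j]) ||
          (st$is_arg[j] && st$is_polyion[i])) ff$epsilon_arg_ion else 0
    } else (st$eps[i] + st$eps[j]) / 2
    if (eps != 0) U <- U - eps / kT_kJ / r^6
  }
  if (nrow(st$bonds) > 0) for (b in seq_len(nrow(st$bonds))) {
    i <- st$bonds[b, 1]; j <- st$bonds[b, 2]
    r <- sqrt(sum(mi(st$coords[i, ] - st$coords[j, ])^2))
    U <- U + 0.5 * kb * (r - ff$r0)^2
  }
  U
}

# random overlap-free 20-site state: a 10-bead chain with two arginines,
# 5 polyvalent ions and 5 monovalent ions
random_state <- function(seed, box = 60) {
  set.seed(seed)
  n_chain <- 10
  coords <- matrix(NA_real_, 20, 3)
  radius <- rep(2, 20)
  place_ok <- function(k, p) {
    if (k == 1) return(TRUE)
    prev <- coords[seq_len(k - 1), , drop = FALSE]
    d <- sweep(prev, 2, p)
    d <- d - box * round(d / box)
    all(rowSums(d^2) >= (radius[seq_len(k - 1)] + radius[k])^2)
  }
  for (k in 1:20) {
    repeat {
      p <- if (k > 1 && k <= n_chain)
        coords[k - 1, ] + runif(1, 4.05, 5.5) * local({
          v <- rnorm(3); v / sqrt(sum(v^2))
        })
      else runif(3, 0, box)
      if (place_ok(k, p)) { coords[k, ] <- p; break }
    }
  }
  codes <- c("D", "R", "H", "K", "G", "R", "E", "Y", "K", "S",
             rep("TPP", 5), rep("Na", 5))
  system_state(coords, codes,
               charge = c(-1, 1, 0, 1, 0, 1, -1, 0, 1, 0, rep(-5, 5), rep(1, 5)),
               radius = radius,
               eps = c(rep(6.1e3, n_chain), rep(0, 10)),
               is_ion = c(rep(FALSE, n_chain), rep(TRUE, 10)),
               chain_id = c(rep(1L, n_chain), rep(NA_integer_, 10)),
               bonds = cbind(1:(n_chain - 1), 2:n_chain),
               box_length = box, periodic = TRUE)
}

# minimal trajectory wrapper around explicit frames, for observables
fake_trajectory <- function(frames, state) {
  structure(list(frames = frames, energies = rep(0, length(frames)),
                 state = state,
                 config = mc_config(n_equilibration = 0, n_production = 0)),
            class = "trajectory")
}

# normalised bond-length density of a two-bead hard-sphere dumbbell,
# P(r) ~ r^2 exp(-k/2 (r - r0)^2) on (contact, Inf)
bond_bin_probs <- function(edges, k, r0, lower = 4) {
  dens <- function(x) x^2 * exp(-0.5 * k * (x - r0)^2)
  Z <- stats::integrate(dens, lower, Inf)$value
  vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(dens, edges[i], edges[i + 1])$value / Z, 0)
}

# smallest convenience: minimum-image pair distances of a state
pair_distances <- function(st) {
  n <- nrow(st$coords)
  out <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- st$coords[i, ] - st$coords[j, ]
    if (st$periodic) d <- d - st$box_length * round(d / st$box_length)
    out[i, j] <- out[j, i] <- sqrt(sum(d^2))
  }
  out
}
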