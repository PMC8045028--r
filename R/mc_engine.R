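#' Monte Carlo run configuration
#'
#' Canonical-ensemble Metropolis sampling settings. The default move mix
#' gives single-particle displacements (protein beads and explicit ions
#' alike) 20 times the frequency of each of the three chain moves
#' (pivot, whole-chain translation, slithering). "Steps" are single
#' proposed moves, not sweeps.
#'
#' @param n_equilibration equilibration steps, discarded (default 5e5)
#' @param n_production production steps (default 1e6)
#' @param seed integer master seed
#' @param sample_interval production steps between recorded frames
#' @param move_amplitudes named vector: `single` and `chain` maximum
#'   displacements (A), `pivot` maximum rotation (rad). Starting values;
#'   auto-tuned during equilibration when `tune = TRUE`.
#' @param move_weights named relative frequencies for
#'   `single`, `pivot`, `chain`, `slither`
#' @param tune tune amplitudes toward 30-50 % acceptance during
#'   equilibration, then freeze for production (tuning during production
#'   would break detailed balance)
#' @param tune_interval attempts per tuning window
#' @param revalidate_interval steps between full-energy revalidation of
#'   the incremental bookkeeping (tolerance 1e-6 kT relative)
#' @return object of class `mc_config`
#' @export
mc_config <- function(n_equilibration = 5e5, n_production = 1e6, seed = 1L,
                      sample_interval = 1000L,
                      move_amplitudes = c(single = 1, chain = 10, pivot = pi / 2),
                      move_weights = c(single = 20, pivot = 1, chain = 1,
                                       slither = 1),
                      tune = TRUE, tune_interval = 500L,
                      revalidate_interval = 10000L) {
  stopifnot(n_equilibration >= 0, n_production >= 0, sample_interval >= 1,
            all(move_weights >= 0), any(move_weights > 0),
            all(move_amplitudes > 0))
  cfg <- list(n_equilibration = as.integer(n_equilibration),
              n_production = as.integer(n_production),
              seed = as.integer(seed),
              sample_interval = as.integer(sample_interval),
              move_amplitudes = move_amplitudes,
              move_weights = move_weights,
              tune = isTRUE(tune),
              tune_interval = as.integer(tune_interval),
              revalidate_interval = as.integer(revalidate_interval))
  class(cfg) <- "mc_config"
  cfg
}

#' Metropolis acceptance rule
#'
#' Accept a proposed move with energy change `delta_u` (kT) given a
#' uniform(0,1) draw: accepted iff `delta_u <= 0` or
#' `rng_draw < exp(-delta_u)`. An infinite `delta_u` (hard-sphere
#' overlap) is never accepted.
#'
#' @param delta_u energy change in kT (may be +/-Inf)
#' @param rng_draw uniform(0,1) random number
#' @return logical
#' @export
metropolis_accept <- function(delta_u, rng_draw) {
  delta_u <= 0 | rng_draw < exp(-delta_u)
}

# ordered site indices of each chain, as a list
.chain_list <- function(state) {
  ids <- sort(unique(stats::na.omit(state$chain_id)))
  lapply(ids, function(id) which(state$chain_id == id))
}

#' Propose a single Monte Carlo move
#'
#' Reference implementation of the symmetric proposal kernels used by
#' [run_mc()] (the sampling loop itself runs compiled): uniform cube
#' displacement of one site, pivot rotation of the shorter arm about a
#' random internal hinge, rigid whole-chain translation, and a
#' slithering (reptation) move that slides the chain one bond along its
#' contour, regrowing the terminal bond with a length drawn from the
#' bond Boltzmann distribution (in [run_mc()] the matching
#' Metropolis-Hastings correction cancels the regrown and removed bond
#' energies, so acceptance is decided by the remaining terms). Uses the
#' current RNG state.
#'
#' @param state a [system_state()]
#' @param move_type one of `"single_bead"`, `"pivot"`,
#'   `"chain_translate"`, `"slither"`, `"ion_translate"`
#' @param ff a [forcefield()] (supplies `r0` for slither)
#' @param amplitude maximum displacement (A) or rotation (rad)
#' @param chain chain id for chain moves (default first chain)
#' @return the proposed `system_state`
#' @export
propose_move <- function(state, move_type = c("single_bead", "pivot",
                                              "chain_translate", "slither",
                                              "ion_translate"),
                         ff = forcefield(), amplitude = 1, chain = NULL) {
  move_type <- match.arg(move_type)
  chains <- .chain_list(state)
  pick_chain <- function(min_len = 2) {
    ok <- which(vapply(chains, length, 1L) >= min_len)
    if (length(ok) == 0) stop("no chain eligible for move '", move_type, "'")
    ci <- if (is.null(chain)) ok[sample.int(length(ok), 1)] else chain
    chains[[ci]]
  }
  co <- state$coords
  if (move_type %in% c("single_bead", "ion_translate")) {
    pool <- if (move_type == "single_bead") which(!state$is_ion) else which(state$is_ion)
    if (length(pool) == 0) stop("no site available for move '", move_type, "'")
    i <- pool[sample.int(length(pool), 1)]
    co[i, ] <- co[i, ] + stats::runif(3, -amplitude, amplitude)
  } else if (move_type == "chain_translate") {
    idx <- pick_chain(1)
    co[idx, ] <- sweep(co[idx, , drop = FALSE], 2,
                       stats::runif(3, -amplitude, amplitude), "+")
  } else if (move_type == "pivot") {
    idx <- pick_chain(3)
    len <- length(idx)
    h <- 1 + sample.int(len - 2, 1)      # internal hinge position
    left <- seq_len(h - 1)
    right <- seq(h + 1, len)
    arm <- if (length(left) < length(right)) left
           else if (length(right) < length(left)) right
           else if (stats::runif(1) < 0.5) left else right
    axis <- .rand_unit()
    theta <- stats::runif(1, -amplitude, amplitude)
    hinge <- co[idx[h], ]
    co[idx[arm], ] <- t(apply(co[idx[arm], , drop = FALSE], 1, function(p)
      .rotate_about(p, hinge, axis, theta)))
  } else {  # slither
    idx <- pick_chain(2)
    len <- length(idx)
    u <- .rand_unit()
    rb <- .bond_boltzmann_length(ff)
    old <- co[idx, , drop = FALSE]
    if (stats::runif(1) < 0.5) {
      co[idx[-len], ] <- old[-1, ]
      co[idx[len], ] <- old[len, ] + rb * u
    } else {
      co[idx[-1], ] <- old[-len, ]
      co[idx[1], ] <- old[1, ] + rb * u
    }
  }
  state$coords <- co
  state
}

# bond length from P(r) ~ r^2 exp(-k/2 (r - r0)^2), by rejection
.bond_boltzmann_length <- function(ff) {
  sigma <- 1 / sqrt(ff$k_bond_kT)
  rcap <- ff$r0 + 6 * sigma
  repeat {
    r <- stats::rnorm(1, ff$r0, sigma)
    if (r > 0 && r < rcap && stats::runif(1) <= (r / rcap)^2) return(r)
  }
}

.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

.rotate_about <- function(p, origin, axis, theta) {
  v <- p - origin
  origin + v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

# 3-vector cross product (tiny enough to keep local)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Samples the canonical ensemble of a [system_state()] under a
#' [forcefield()]. Energy bookkeeping is incremental (only terms
#' involving moved sites are recomputed) and periodically revalidated
#' against a full [total_energy()] evaluation. Identical
#' `(initial, ff, cfg)` give an identical trajectory.
#'
#' @param initial an overlap-free [system_state()]
#' @param ff a [forcefield()]
#' @param cfg an [mc_config()]
#' @return object of class `trajectory`: list with `frames` (coordinate
#'   matrices recorded every `sample_interval` production steps),
#'   `energies` (kT, per frame), `acceptance` (per-move-type
#'   accepted/attempted counts over production), `amplitudes` (the
#'   frozen post-tuning move amplitudes), `state` (template with final
#'   coordinates), and `config`
#' @export
run_mc <- function(initial, ff, cfg = mc_config()) {
  stopifnot(inherits(initial, "system_state"), inherits(ff, "forcefield"),
            inherits(cfg, "mc_config"))
  a <- .cpp_args(initial, ff)
  chains0 <- lapply(.chain_list(initial), function(ix) as.integer(ix - 1L))
  w <- cfg$move_weights[c("single", "pivot", "chain", "slither")]
  amp <- cfg$move_amplitudes[c("single", "chain", "pivot")]
  res <- with_seed(cfg$seed,
    run_mc_cpp(a$coords, a$q, a$radius, a$eps_kT, a$is_arg, a$is_ion,
               a$is_poly, a$bonds0, a$box, a$periodic, a$lB, a$kappa,
               a$kbond, a$r0, a$eps_arg, chains0,
               cfg$n_equilibration, cfg$n_production, cfg$sample_interval,
               as.numeric(w), as.numeric(amp), cfg$tune, cfg$tune_interval,
               cfg$revalidate_interval))
  final <- initial
  final$coords <- res$final_coords
  acc <- data.frame(move = c("single", "pivot", "chain", "slither"),
                    accepted = res$acceptance[, 1],
                    attempted = res$acceptance[, 2])
  acc$rate <- ifelse(acc$attempted > 0, acc$accepted / acc$attempted, NA)
  traj <- list(frames = res$frames, energies = as.numeric(res$energies),
               acceptance = acc,
               amplitudes = stats::setNames(as.numeric(res$amplitudes),
                                            c("single", "chain", "pivot")),
               state = final, config = cfg)
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames of %d sites (%d production steps, seed %d)\n",
              length(x$frames), nrow(x$state$coords),
              x$config$n_production, x$config$seed))
  if (length(x$energies))
    cat(sprintf("  energy: mean %.2f kT over frames\n", mean(x$energies)))
  for (k in seq_len(nrow(x$acceptance)))
    with(x$acceptance[k, ], cat(sprintf("  %-8s %8d / %8d accepted (%.0f%%)\n",
                                        move, accepted, attempted,
                                        100 * rate)))
  invisible(x)
}

#' Extract one frame of a trajectory as a system state
#'
#' @param traj a `trajectory`
#' @param k frame index
#' @return a [system_state()] with that frame's coordinates
#' @export
frame_state <- function(traj, k) {
  stopifnot(k >= 1, k <= length(traj$frames))
  st <- traj$state
  st$coords <- traj$frames[[k]]
  st
}

#' Write trajectory frames as multi-model XYZ
#'
#' One model per frame; species labels as atom names.
#'
#' @param traj a `trajectory`
#' @param path output file
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sp <- traj$state$species
  for (fr in traj$frames) {
    writeLines(c(as.character(nrow(fr)), "argphos frame"), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", sp, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Write a system state as PDB (CA-trace style)
#'
#' @param state a [system_state()]
#' @param path output file
#' @export
write_frame_pdb <- function(state, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("PDB export requires the bio3d package")
  n <- nrow(state$coords)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(state$coords)),
                   resno = seq_len(n), resid = state$species,
                   elety = rep("CA", n),
                   chain = ifelse(is.na(state$chain_id), "I",
                                  LETTERS[pmin(state$chain_id, 26L)]))
  invisible(path)
}
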