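# minimum-image displacement of a coordinate difference matrix
.min_image <- function(d, box, periodic) {
  if (periodic) d - box * round(d / box) else d
}

# unwrap a chain across periodic images by bond-walking: each bead is
# placed at the minimum-image position relative to its predecessor
# (bonds ~4 A << box, so this is unambiguous)
.unwrap_chain <- function(coords, box, periodic) {
  if (!periodic || nrow(coords) < 2) return(coords)
  out <- coords
  for (i in 2:nrow(coords)) {
    step <- .min_image(coords[i, ] - coords[i - 1, ], box, periodic)
    out[i, ] <- out[i - 1, ] + step
  }
  out
}

#' Radius of gyration of one chain
#'
#' Uniform bead masses; the chain is unwrapped across periodic images
#' before computing \eqn{R_g = \sqrt{\langle |r_i - r_{cm}|^2 \rangle}}.
#'
#' @param state a [system_state()] (or a frame via [frame_state()])
#' @param chain_id which chain (default 1)
#' @return Rg in Angstrom
#' @examples
#' # two beads 10 A apart -> Rg = 5
#' st <- system_state(rbind(c(0, 0, 0), c(10, 0, 0)), c("G", "G"),
#'                    c(0, 0), c(2, 2), chain_id = c(1L, 1L),
#'                    bonds = cbind(1, 2), periodic = FALSE)
#' radius_of_gyration(st)
#' @export
radius_of_gyration <- function(state, chain_id = 1) {
  idx <- which(!is.na(state$chain_id) & state$chain_id == chain_id)
  if (length(idx) == 0) stop("unknown chain id: ", chain_id)
  xyz <- .unwrap_chain(state$coords[idx, , drop = FALSE],
                       state$box_length, state$periodic)
  cm <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, cm)^2)))
}

#' Per-frame observable series with block-averaged error
#'
#' @param values numeric per-frame values
#' @param name label
#' @param block_size frames per block for the standard error of the mean
#'   (default: 20 blocks)
#' @return object of class `observable_series` with `mean` and `sem`
#' @export
observable_series <- function(values, name = "observable",
                              block_size = NULL) {
  n <- length(values)
  if (is.null(block_size)) block_size <- max(1L, n %/% 20L)
  nb <- n %/% block_size
  if (nb < 2) {
    sem <- if (n > 1) stats::sd(values) / sqrt(n) else 0
  } else {
    bm <- vapply(seq_len(nb), function(b)
      mean(values[((b - 1) * block_size + 1):(b * block_size)]), 0)
    sem <- stats::sd(bm) / sqrt(nb)
  }
  out <- list(name = name, values = values, mean = mean(values),
              sem = sem, block_size = block_size)
  class(out) <- "observable_series"
  out
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("<observable_series> %s: %.4g +/- %.2g (%d frames, block %d)\n",
              x$name, x$mean, x$sem, length(x$values), x$block_size))
  invisible(x)
}

#' Radius-of-gyration series over a trajectory
#'
#' @param traj a `trajectory`
#' @param chain_id which chain
#' @param block_size passed to [observable_series()]
#' @return an `observable_series` of Rg (Angstrom)
#' @export
rg_series <- function(traj, chain_id = 1, block_size = NULL) {
  vals <- vapply(seq_along(traj$frames), function(k)
    radius_of_gyration(frame_state(traj, k), chain_id), 0)
  observable_series(vals, name = sprintf("Rg(chain %s)", chain_id),
                    block_size = block_size)
}

#' Count arginine / polyvalent-ion contacts
#'
#' Number of (Arg bead, polyvalent ion) pairs within `cutoff`
#' (minimum-image distance).
#'
#' @param state a [system_state()]
#' @param cutoff contact distance, Angstrom (default 4.5: the 4 A
#'   contact separation plus a 0.5 A skin)
#' @return integer count
#' @export
arg_ion_contacts <- function(state, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  ai <- which(state$is_arg & !state$is_ion)
  pi_ <- which(state$is_polyion)
  if (length(ai) == 0 || length(pi_) == 0) return(0L)
  cnt <- 0L
  for (a in ai) {
    d <- .min_image(sweep(state$coords[pi_, , drop = FALSE], 2,
                          state$coords[a, ]),
                    state$box_length, state$periodic)
    cnt <- cnt + sum(sqrt(rowSums(d^2)) <= cutoff)
  }
  cnt
}

#' Chain cluster size distribution
#'
#' Chains are linked into one cluster if any inter-chain bead pair is
#' within `cutoff`, or if an ion lies within `cutoff` of beads of both
#' chains (ion bridging). Returns the multiset of connected-component
#' sizes.
#'
#' @param state a [system_state()]
#' @param cutoff Angstrom
#' @return integer vector of cluster sizes (sorted decreasing)
#' @export
cluster_sizes <- function(state, cutoff = 4.5) {
  ids <- sort(unique(stats::na.omit(state$chain_id)))
  if (length(ids) == 0) stop("cluster_sizes requires at least one chain")
  nch <- length(ids)
  near <- function(i_set, j_set) {
    for (i in i_set) {
      d <- .min_image(sweep(state$coords[j_set, , drop = FALSE], 2,
                            state$coords[i, ]),
                      state$box_length, state$periodic)
      if (any(rowSums(d^2) <= cutoff^2)) return(TRUE)
    }
    FALSE
  }
  chain_sites <- lapply(ids, function(id) which(state$chain_id == id))
  edges <- matrix(integer(0), ncol = 2)
  if (nch > 1) {
    for (a in 1:(nch - 1)) for (b in (a + 1):nch)
      if (near(chain_sites[[a]], chain_sites[[b]]))
        edges <- rbind(edges, c(a, b))
    # ion bridges: an ion within cutoff of beads from several chains
    for (ion in which(state$is_ion)) {
      touching <- which(vapply(chain_sites, function(cs)
        near(ion, cs), TRUE))
      if (length(touching) > 1)
        edges <- rbind(edges, t(utils::combn(touching, 2)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nch - igraph::vcount(g)))
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}

#' Ensemble-averaged Debye scattering curve
#'
#' Intramolecular scattering of identical point scatterers,
#' \eqn{I(q) = N^{-2} \sum_{ij} \sin(q r_{ij}) / (q r_{ij})},
#' averaged over frames and chains and normalised so \eqn{I(0) = 1} per
#' chain; the q->0 limit is handled analytically.
#'
#' @param traj a `trajectory`
#' @param q_grid positive ascending scattering vectors, 1/Angstrom
#' @param chain_id chain to use, or `NULL` for the average over chains
#' @return a [saxs_curve()]
#' @export
debye_scattering <- function(traj, q_grid, chain_id = NULL) {
  if (length(traj$frames) == 0) stop("empty trajectory")
  stopifnot(all(q_grid > 0), !is.unsorted(q_grid))
  ids <- if (is.null(chain_id))
    sort(unique(stats::na.omit(traj$state$chain_id))) else chain_id
  acc <- numeric(length(q_grid))
  m <- 0L
  for (k in seq_along(traj$frames)) {
    st <- frame_state(traj, k)
    for (id in ids) {
      acc <- acc + .debye_chain(st, id, q_grid)
      m <- m + 1L
    }
  }
  saxs_curve(q_grid, acc / m, label = "Debye scattering (simulation)")
}

.debye_chain <- function(state, chain_id, q_grid) {
  idx <- which(!is.na(state$chain_id) & state$chain_id == chain_id)
  xyz <- .unwrap_chain(state$coords[idx, , drop = FALSE],
                       state$box_length, state$periodic)
  n <- nrow(xyz)
  if (n == 1) return(rep(1, length(q_grid)))
  r <- as.numeric(stats::dist(xyz))
  vapply(q_grid, function(q) {
    x <- q * r
    (n + 2 * sum(ifelse(x == 0, 1, sin(x) / x))) / n^2
  }, 0)
}

#' Write an observable series as CSV
#'
#' @param series an `observable_series`
#' @param path output file
#' @export
write_observable_csv <- function(series, path) {
  utils::write.csv(data.frame(frame = seq_along(series$values),
                              value = series$values),
                   path, row.names = FALSE)
  invisible(path)
}
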