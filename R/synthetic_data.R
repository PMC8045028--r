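# per-site property table for chains + ions, with terminal charges
# folded into the first/last residue bead (the termini are co-located
# point charges; see the methods vignette)
.site_table <- function(topologies, n_ions, ff) {
  sp <- ch <- numeric(0)
  species <- character(0)
  rad <- eps <- numeric(0)
  arg <- logical(0)
  chain <- integer(0)
  bonds <- matrix(integer(0), ncol = 2)
  offset <- 0L
  for (ci in seq_along(topologies)) {
    tp <- topologies[[ci]]
    res <- !tp$is_terminal
    qres <- tp$charge[res]
    nres <- sum(res)
    qres[1] <- qres[1] + sum(tp$charge[tp$code == "NT"])
    qres[nres] <- qres[nres] + sum(tp$charge[tp$code == "CT"])
    species <- c(species, tp$code[res])
    ch <- c(ch, qres)
    rad <- c(rad, tp$radius[res])
    eps <- c(eps, rep(ff$epsilon_generic, nres))
    arg <- c(arg, tp$is_arginine[res])
    chain <- c(chain, rep(ci, nres))
    bonds <- rbind(bonds, cbind(offset + 1:(nres - 1), offset + 2:nres))
    offset <- offset + nres
  }
  n_ions <- n_ions[n_ions > 0]
  for (ion in names(n_ions)) {
    if (!ion %in% names(ff$ion_charges))
      stop("no valence configured for ion species: ", ion)
    z <- ff$ion_charges[[ion]]
    k <- n_ions[[ion]]
    species <- c(species, rep(ion, k))
    ch <- c(ch, rep(z, k))
    rad <- c(rad, rep(ff$bead_radius, k))
    eps <- c(eps, rep(0, k))
    arg <- c(arg, rep(FALSE, k))
    chain <- c(chain, rep(NA_integer_, k))
  }
  n_bead <- sum(!is.na(chain))
  list(species = species, charge = ch, radius = rad, eps = eps,
       is_arg = arg, is_ion = c(rep(FALSE, n_bead),
                                rep(TRUE, length(species) - n_bead)),
       chain_id = chain, bonds = bonds)
}

#' Generate an initial simulation configuration
#'
#' Protein chains are grown as self-avoiding random walks with bond
#' length `ff$r0`; explicit ions are placed uniformly; hard-sphere
#' overlaps are rejected with bounded retries. Terminal charges are
#' folded onto the first/last bead of each chain.
#'
#' @param topologies list of [load_sequence()] chain topologies
#' @param n_ions named counts of explicit ions, e.g. `c(TPP = 10)`;
#'   valences from `ff$ion_charges`
#' @param box_length cubic box edge, Angstrom (default 250)
#' @param seed integer seed; identical inputs give identical output
#' @param ff a [forcefield()]
#' @param max_retries placement attempts per site before giving up
#' @return an overlap-free [system_state()]
#' @export
gen_system <- function(topologies, n_ions = c(), box_length = 250,
                       seed = 1L, ff = forcefield(), max_retries = 200L) {
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  tab <- .site_table(topologies, n_ions, ff)
  n <- length(tab$species)
  with_seed(seed, {
    coords <- matrix(NA_real_, n, 3)
    placed <- 0L
    overlaps <- function(p, r) {
      if (placed == 0L) return(FALSE)
      d <- .min_image(sweep(coords[seq_len(placed), , drop = FALSE], 2, p),
                      box_length, TRUE)
      any(rowSums(d^2) < (tab$radius[seq_len(placed)] + r)^2)
    }
    for (ci in seq_along(topologies)) {
      idx <- which(!is.na(tab$chain_id) & tab$chain_id == ci)
      for (attempt in seq_len(max_retries)) {
        ok <- TRUE
        start <- placed
        coords[idx[1], ] <- stats::runif(3, 0, box_length)
        if (overlaps(coords[idx[1], ], tab$radius[idx[1]])) { ok <- FALSE }
        else {
          placed <- placed + 1L
          for (k in idx[-1]) {
            found <- FALSE
            for (try in seq_len(50L)) {
              p <- coords[k - 1L, ] + ff$r0 * .rand_unit()
              if (!overlaps(p, tab$radius[k])) {
                coords[k, ] <- p
                placed <- placed + 1L
                found <- TRUE
                break
              }
            }
            if (!found) { ok <- FALSE; break }
          }
        }
        if (ok) break
        placed <- start            # restart this chain
        if (attempt == max_retries)
          stop("could not place chain ", ci, " without overlaps ",
               "(box too crowded?)")
      }
    }
    for (k in which(tab$is_ion)) {
      found <- FALSE
      for (try in seq_len(max_retries)) {
        p <- stats::runif(3, 0, box_length)
        if (!overlaps(p, tab$radius[k])) {
          coords[k, ] <- p
          placed <- placed + 1L
          found <- TRUE
          break
        }
      }
      if (!found) stop("could not place ion ", k, " without overlaps")
    }
    system_state(coords, tab$species, tab$charge, tab$radius, tab$eps,
                 is_arg = tab$is_arg, is_ion = tab$is_ion,
                 chain_id = tab$chain_id, bonds = tab$bonds,
                 box_length = box_length, periodic = TRUE)
  })
}

#' Generate a synthetic Guinier-regime SAXS curve
#'
#' \eqn{I(q) = I_0 \exp(-q^2 R_g^2/3)} with mean-preserving
#' multiplicative lognormal noise of coefficient of variation
#' `noise_cv`; the sigma column is `noise_cv * I_ideal` (absent when
#' `noise_cv = 0`).
#'
#' @param rg true radius of gyration, Angstrom
#' @param i0 true forward scattering
#' @param q_grid scattering vectors, 1/Angstrom
#' @param noise_cv coefficient of variation of the noise (fraction)
#' @param seed integer seed
#' @return a [saxs_curve()] with attributes `true_rg`, `true_i0`, `seed`
#' @export
gen_guinier_curve <- function(rg, i0, q_grid = seq(0.008, 0.25, by = 0.004),
                              noise_cv = 0, seed = 1L) {
  stopifnot(rg > 0, i0 > 0, noise_cv >= 0)
  ideal <- i0 * exp(-q_grid^2 * rg^2 / 3)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    I <- with_seed(seed,
      ideal * stats::rlnorm(length(q_grid), -sdlog^2 / 2, sdlog))
    cv <- saxs_curve(q_grid, I, sigma = noise_cv * ideal,
                     label = sprintf("synthetic Guinier (Rg %.3g)", rg))
  } else {
    cv <- saxs_curve(q_grid, ideal,
                     label = sprintf("synthetic Guinier (Rg %.3g)", rg))
  }
  attr(cv, "true_rg") <- rg
  attr(cv, "true_i0") <- i0
  attr(cv, "seed") <- seed
  cv
}

#' Generate synthetic precipitation series with known boundaries
#'
#' For each protein concentration the condensation boundary is placed
#' at \eqn{C^* = m^* c_p + c^f} (all molar) and the decondensation
#' boundary at \eqn{C^{**} = C^* \cdot} `window_width_ratio`. The
#' condensation well between them is piecewise-linear in
#' log-concentration, passing exactly through the retention threshold
#' at C* and C** and through a flat floor at `depth`, so that the
#' boundaries recovered by [detect_boundaries()] are exact in the
#' noiseless case. Additive Gaussian noise (sd `noise_sd`) is truncated
#' at zero.
#'
#' @param m_star ions bound per protein at the boundary (slope)
#' @param c_f free-ion concentration, mM (intercept)
#' @param protein_concs protein mass concentrations, mg/mL. The default
#'   range spans anion-per-protein ratios at the condensation boundary
#'   from 1.1 (lowest concentration) to 0.9 (highest), the regime in
#'   which the boundary is observed experimentally.
#' @param window_width_ratio C**/C* (> 1)
#' @param depth supernatant concentration at maximum precipitation,
#'   mg/mL (applies where `depth` < protein concentration)
#' @param noise_sd additive noise standard deviation, mg/mL
#' @param seed integer seed
#' @param mw protein molecular weight, Da
#' @param retention fraction of the initial concentration defining the
#'   boundary (matches the threshold used in detection)
#' @param shoulder multiplicative width of the linear shoulders (> 1)
#' @param n_grid points in the background log-spaced titration grid
#' @return list of [precipitation_series()] with attribute `truth`
#'   (list with `m_star`, `c_f`, and per-series `c_star`,
#'   `c_double_star`, `c_max` in mM)
#' @export
gen_precipitation <- function(m_star = 0.762, c_f = 0.355,
                              protein_concs = c(3.2, 4.3, 5.2, 6.5, 7.8),
                              window_width_ratio = 6.6, depth = 1,
                              noise_sd = 0, seed = 1L, mw = 3036.3,
                              retention = 0.95, shoulder = 1.6,
                              n_grid = 25L) {
  stopifnot(m_star >= 0, c_f >= 0, all(protein_concs > 0),
            depth >= 0, depth <= min(protein_concs), noise_sd >= 0,
            shoulder > 1)
  if (window_width_ratio <= 1)
    stop("window_width_ratio must exceed 1")
  truth <- list(m_star = m_star, c_f = c_f,
                c_star = numeric(0), c_double_star = numeric(0),
                c_max = numeric(0))
  out <- vector("list", length(protein_concs))
  for (si in seq_along(protein_concs)) {
    cp <- protein_concs[si]
    cp_mM <- cp / mw * 1000
    cstar <- m_star * cp_mM + c_f
    cdstar <- cstar * window_width_ratio
    f <- min(shoulder, sqrt(window_width_ratio) * 0.98)
    # each crossing is locally steep and symmetric about the threshold
    # point, so that under additive noise the interpolated crossing is
    # perturbed symmetrically (no systematic shift of the boundary)
    s_loc <- min(1.05, sqrt(f))
    h <- 0.8 * (1 - retention) * cp
    d <- min(depth, cp)
    thr_y <- retention * cp
    knots_x <- c(cstar / shoulder,
                 cstar / s_loc, cstar, cstar * s_loc,
                 cstar * f, cdstar / f,
                 cdstar / s_loc, cdstar, cdstar * s_loc,
                 cdstar * shoulder)
    knots_y <- c(cp,
                 thr_y + h, thr_y, max(thr_y - h, d),
                 d, d,
                 max(thr_y - h, d), thr_y, thr_y + h,
                 cp)
    grid <- sort(unique(c(
      exp(seq(log(min(knots_x) / 4), log(max(knots_x) * 4),
              length.out = n_grid)),
      knots_x)))
    sn <- stats::approx(log(knots_x), knots_y, xout = log(grid),
                        rule = 2)$y
    if (noise_sd > 0)
      sn <- pmax(0, pmin(sn + with_seed(seed + si,
                                        stats::rnorm(length(sn), 0, noise_sd)),
                         cp * 1.049))
    out[[si]] <- precipitation_series(grid, sn, cp, protein_mw = mw)
    truth$c_star <- c(truth$c_star, cstar)
    truth$c_double_star <- c(truth$c_double_star, cdstar)
    truth$c_max <- c(truth$c_max, cstar * f)
  }
  attr(out, "truth") <- truth
  out
}
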