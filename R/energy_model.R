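#' Coarse-grained force field
#'
#' Parameters of the bead-necklace model: hard-sphere excluded volume,
#' screened (extended Debye-Hueckel) electrostatics, a short-ranged
#' \eqn{-\epsilon/r^6} attraction whose strength reflects amino-acid
#' excess polarizability, harmonic bonds, and a stronger specific
#' attraction between arginine beads and polyvalent anions.
#'
#' @param bead_radius hard-sphere radius of amino-acid beads, Angstrom
#' @param r0 equilibrium bond separation, Angstrom
#' @param k_bond bond force constant, N/m
#' @param epsilon_generic generic amino-acid short-range strength,
#'   kJ A^6/mol; the default gives a 0.6 kT bead-bead contact attraction
#'   at 298 K
#' @param epsilon_arg_ion arginine/polyvalent-anion short-range strength,
#'   kJ A^6/mol (default 8.0e4, an 8 kT attraction at contact)
#' @param temperature K
#' @param dielectric relative permittivity of the solvent
#' @param ionic_strength implicit background (buffer + 1:1 salt) ionic
#'   strength, mol/L; sets `kappa` unless `kappa` is given directly.
#'   Explicit ions in a [system_state()] do not contribute to `kappa`.
#' @param kappa inverse Debye screening length, 1/Angstrom
#' @param ion_charges named valences for explicit ion species
#' @return an object of class `forcefield` (a list; also caches the
#'   Bjerrum length `lB` in Angstrom, the thermal energy `kT_kJ` in
#'   kJ/mol and the bond constant `k_bond_kT` in kT/A^2)
#' @examples
#' ff <- forcefield(ionic_strength = 0.01)
#' 1 / ff$kappa  # Debye length, about 30 A at 10 mM
#' @export
forcefield <- function(bead_radius = 2, r0 = 4.1, k_bond = 0.4,
                       epsilon_generic = 6.1e3, epsilon_arg_ion = 8.0e4,
                       temperature = 298.15, dielectric = 78.4,
                       ionic_strength = 0.010, kappa = NULL,
                       ion_charges = c(citrate = -3, PP = -4, TPP = -5,
                                       Na = 1, Cl = -1)) {
  stopifnot(bead_radius > 0, r0 > 0, k_bond > 0, epsilon_generic >= 0,
            epsilon_arg_ion >= 0, temperature > 0, dielectric > 0)
  if (is.null(kappa)) kappa <- debye_kappa(ionic_strength, temperature, dielectric)
  stopifnot(kappa >= 0)
  ff <- list(
    bead_radius = bead_radius, r0 = r0, k_bond = k_bond,
    epsilon_generic = epsilon_generic, epsilon_arg_ion = epsilon_arg_ion,
    temperature = temperature, dielectric = dielectric,
    ionic_strength = ionic_strength, kappa = kappa,
    ion_charges = ion_charges,
    lB = bjerrum_length(temperature, dielectric),
    kT_kJ = kT_kJmol(temperature),
    k_bond_kT = spring_kT(k_bond, temperature)
  )
  class(ff) <- "forcefield"
  ff
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield> T = %.2f K, eps_r = %.1f, kappa = %.4g 1/A (Debye length %.1f A)\n",
              x$temperature, x$dielectric, x$kappa,
              if (x$kappa > 0) 1 / x$kappa else Inf))
  cat(sprintf("  beads: R = %g A, bond r0 = %g A, k = %g N/m (%.3f kT/A^2)\n",
              x$bead_radius, x$r0, x$k_bond, x$k_bond_kT))
  cat(sprintf("  short range: generic %.3g, Arg-polyion %.3g kJ A^6/mol\n",
              x$epsilon_generic, x$epsilon_arg_ion))
  invisible(x)
}

#' Hard-sphere pair potential
#'
#' Infinite below contact, zero at and beyond contact.
#'
#' @param r centre-to-centre distance, Angstrom
#' @param Ri,Rj sphere radii, Angstrom
#' @return energy in kT: `Inf` if `r < Ri + Rj`, else 0
#' @export
hard_sphere_pair <- function(r, Ri, Rj) {
  stopifnot(all(r >= 0))
  ifelse(r < Ri + Rj, Inf, 0)
}

#' Extended Debye-Hueckel pair potential
#'
#' Screened Coulomb interaction with the hard-core (finite ion size)
#' correction:
#' \deqn{u(r)/kT = z_i z_j \frac{\lambda_B}{r}
#'   \frac{e^{\kappa(R_i+R_j)}}{(1+\kappa R_i)(1+\kappa R_j)} e^{-\kappa r}}
#' which reduces to the bare Coulomb form when `kappa = 0`.
#'
#' @param zi,zj valences
#' @param r distance, Angstrom (> 0)
#' @param ff a [forcefield()]
#' @param Ri,Rj hard-core radii entering the correction (default the
#'   force field's bead radius)
#' @return energy in kT
#' @export
debye_huckel_pair <- function(zi, zj, r, ff, Ri = ff$bead_radius,
                              Rj = ff$bead_radius) {
  if (any(r <= 0)) stop("debye_huckel_pair requires r > 0")
  k <- ff$kappa
  zi * zj * ff$lB / r * exp(-k * (r - Ri - Rj)) / ((1 + k * Ri) * (1 + k * Rj))
}

#' Short-range attractive pair potential
#'
#' \eqn{u(r) = -\epsilon / r^6}, with \eqn{\epsilon} in kJ A^6/mol,
#' converted to kT at the force field's temperature. For amino-acid
#' pairs the effective \eqn{\epsilon} is the arithmetic mean of the two
#' sites' values; arginine/polyvalent-anion pairs use
#' `ff$epsilon_arg_ion` instead (see [total_energy()]).
#'
#' @param r distance, Angstrom (> 0)
#' @param epsilon interaction strength, kJ A^6/mol
#' @param ff a [forcefield()]
#' @return energy in kT (negative, attractive)
#' @examples
#' ff <- forcefield()
#' abs(short_range_pair(4, 8.0e4, ff))  # about 8 kT at contact
#' @export
short_range_pair <- function(r, epsilon, ff) {
  if (any(r <= 0)) stop("short_range_pair requires r > 0")
  -epsilon / r^6 / ff$kT_kJ
}

#' Harmonic bond potential
#'
#' \eqn{u(r) = \frac{k}{2}(r - r_0)^2} with the force constant converted
#' from N/m to kT/A^2.
#'
#' @param r bond length, Angstrom
#' @param ff a [forcefield()]
#' @return energy in kT
#' @export
bond_pair <- function(r, ff) {
  stopifnot(all(r >= 0))
  0.5 * ff$k_bond_kT * (r - ff$r0)^2
}

#' Inverse Debye screening length
#'
#' \deqn{\kappa = \sqrt{2 N_A e^2 \cdot 10^3 I / (\epsilon_0 \epsilon_r k_B T)}}
#'
#' @param ionic_strength mol/L (>= 0)
#' @param temperature K
#' @param dielectric relative permittivity
#' @return kappa in 1/Angstrom; 0 at zero ionic strength
#' @export
debye_kappa <- function(ionic_strength, temperature = 298.15,
                        dielectric = 78.4) {
  if (any(ionic_strength < 0)) stop("ionic strength must be >= 0")
  with(codata,
       sqrt(2 * N_A * e^2 * ionic_strength * 1e3 /
              (eps0 * dielectric * kB * temperature))) * 1e-10
}

#' Construct a simulation system state
#'
#' Coordinates and per-site properties of protein beads and explicit
#' ions in a (periodic) cubic box. Coordinates are stored continuously
#' (not wrapped); all pair distances use the minimum image convention.
#'
#' @param coords n x 3 numeric matrix, Angstrom
#' @param species per-site labels (residue code or ion species)
#' @param charge per-site valences
#' @param radius per-site hard-sphere radii, Angstrom
#' @param eps per-site generic short-range strength, kJ A^6/mol
#' @param is_arg logical, arginine beads
#' @param is_ion logical, explicit ions
#' @param is_polyion logical, polyvalent ions (|z| >= 2)
#' @param chain_id integer chain membership; `NA` for ions
#' @param bonds 2-column matrix of bonded site indices (1-based)
#' @param box_length Angstrom
#' @param periodic logical
#' @return object of class `system_state`
#' @export
system_state <- function(coords, species, charge, radius,
                         eps = rep(0, length(species)),
                         is_arg = species == "R",
                         is_ion = rep(FALSE, length(species)),
                         is_polyion = is_ion & abs(charge) >= 2,
                         chain_id = rep(NA_integer_, length(species)),
                         bonds = NULL,
                         box_length = 250, periodic = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3, length(species) == n, length(charge) == n,
            length(radius) == n, length(eps) == n, box_length > 0)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  st <- list(coords = coords, species = as.character(species),
             charge = as.numeric(charge), radius = as.numeric(radius),
             eps = as.numeric(eps), is_arg = as.logical(is_arg),
             is_ion = as.logical(is_ion), is_polyion = as.logical(is_polyion),
             chain_id = as.integer(chain_id), bonds = bonds,
             box_length = box_length, periodic = isTRUE(periodic))
  class(st) <- "system_state"
  st
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d sites (%d protein beads in %d chain(s), %d ions), box %g A%s\n",
              nrow(x$coords), sum(!x$is_ion),
              length(unique(stats::na.omit(x$chain_id))), sum(x$is_ion),
              x$box_length, if (x$periodic) ", periodic" else ""))
  invisible(x)
}

# flatten a system_state + forcefield into the argument list of the C++ core
.cpp_args <- function(state, ff) {
  list(coords = state$coords,
       q = state$charge,
       radius = state$radius,
       eps_kT = state$eps / ff$kT_kJ,
       is_arg = as.integer(state$is_arg),
       is_ion = as.integer(state$is_ion),
       is_poly = as.integer(state$is_polyion),
       bonds0 = matrix(as.integer(state$bonds - 1L), ncol = 2),
       box = state$box_length,
       periodic = state$periodic,
       lB = ff$lB, kappa = ff$kappa,
       kbond = ff$k_bond_kT, r0 = ff$r0,
       eps_arg = ff$epsilon_arg_ion / ff$kT_kJ)
}

#' Total potential energy of a configuration
#'
#' Sum over all unordered site pairs of hard-sphere, screened-Coulomb
#' and short-range terms, plus harmonic bond terms, with minimum-image
#' distances in a periodic box. The short-range strength of a pair is
#' the arithmetic mean of the two sites' `eps`, except that any pair of
#' an arginine bead with a polyvalent ion uses `ff$epsilon_arg_ion`, and
#' all other pairs involving an ion have no short-range term.
#'
#' @param state a [system_state()]
#' @param ff a [forcefield()]
#' @return energy in kT; `Inf` if and only if any hard-sphere overlap
#' @export
total_energy <- function(state, ff) {
  a <- .cpp_args(state, ff)
  total_energy_cpp(a$coords, a$q, a$radius, a$eps_kT, a$is_arg, a$is_ion,
                   a$is_poly, a$bonds0, a$box, a$periodic, a$lB, a$kappa,
                   a$kbond, a$r0, a$eps_arg)
}
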