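#' Total ionic strength of a species list
#'
#' \eqn{I = \frac12 \sum_i c_i z_i^2}. Counterions must be listed
#' explicitly; use [salt_species()] to expand a dissolved salt into its
#' fully dissociated ions.
#'
#' @param species data frame with columns `conc` (mol/L) and `z`
#'   (valence), e.g. from [salt_species()]; or a numeric vector of
#'   concentrations with `z` given separately
#' @param z valences, when `species` is a plain concentration vector
#' @return ionic strength, mol/L
#' @examples
#' ionic_strength(salt_species("NaCl", 0.1))     # 0.1
#' ionic_strength(salt_species("Na5TPP", 0.011)) # 0.165
#' @export
ionic_strength <- function(species, z = NULL) {
  if (is.data.frame(species)) {
    conc <- species$conc
    z <- species$z
  } else {
    conc <- species
  }
  stopifnot(length(conc) == length(z), all(conc >= 0))
  0.5 * sum(conc * z^2)
}

# stoichiometry of the supported sodium salts: n monovalent cations per
# anion of the given valence
.salts <- list(
  NaCl    = c(n_cation = 1, z_anion = -1),
  Na3Cit  = c(n_cation = 3, z_anion = -3),
  Na4PP   = c(n_cation = 4, z_anion = -4),
  SPP     = c(n_cation = 4, z_anion = -4),
  Na5TPP  = c(n_cation = 5, z_anion = -5),
  STPP    = c(n_cation = 5, z_anion = -5)
)

#' Expand a dissolved salt into its dissociated ion species
#'
#' Convenience expander: e.g. 11 mM pentasodium tripolyphosphate gives
#' 55 mM Na+ and 11 mM TPP(5-).
#'
#' @param salt a known salt name (`"NaCl"`, `"Na3Cit"`, `"Na4PP"`/
#'   `"SPP"`, `"Na5TPP"`/`"STPP"`), or `"custom"`
#' @param conc salt concentration, mol/L
#' @param n_cation,z_anion stoichiometry for `"custom"` (monovalent
#'   cation assumed)
#' @return data frame with columns `species`, `conc` (mol/L), `z`
#' @export
salt_species <- function(salt, conc, n_cation = NULL, z_anion = NULL) {
  stopifnot(all(conc >= 0))
  if (salt != "custom") {
    st <- .salts[[salt]]
    if (is.null(st)) stop("unknown salt: ", salt,
                          " (use salt = 'custom' with n_cation, z_anion)")
    n_cation <- st[["n_cation"]]
    z_anion <- st[["z_anion"]]
  }
  data.frame(species = c("cation", salt),
             conc = c(conc * n_cation, conc),
             z = c(1, z_anion))
}

#' Molar anion-to-protein ratio Cs/Cp
#'
#' @param anion_conc anion concentration, mM
#' @param protein_conc protein mass concentration, mg/mL
#' @param mw protein molecular weight, Da (default: the Hst5 monomer)
#' @return the molar ratio of anions per protein molecule
#' @examples
#' cs_cp(1.713, 5.2, 3036.3)  # about 1
#' @export
cs_cp <- function(anion_conc, protein_conc, mw = 3036.3) {
  stopifnot(all(anion_conc > 0), mw > 0)
  if (any(protein_conc <= 0)) stop("protein concentration must be > 0")
  anion_conc / (protein_conc / mw * 1000)
}

#' Construct a precipitation series
#'
#' An anion titration at fixed initial protein concentration: the
#' protein remaining in the supernatant after centrifugation as a
#' function of anion concentration.
#'
#' @param anion_conc ascending anion concentrations, mM
#' @param supernatant_conc supernatant protein concentrations, mg/mL
#' @param protein_conc_initial initial protein concentration, mg/mL
#' @param protein_mw Da
#' @param anion_label e.g. `"TPP"`
#' @return object of class `precipitation_series`
#' @export
precipitation_series <- function(anion_conc, supernatant_conc,
                                 protein_conc_initial, protein_mw = 3036.3,
                                 anion_label = "TPP") {
  stopifnot(length(anion_conc) == length(supernatant_conc),
            protein_conc_initial > 0)
  if (is.unsorted(anion_conc, strictly = TRUE))
    stop("anion concentrations must be strictly increasing")
  if (any(supernatant_conc < 0) ||
      any(supernatant_conc > protein_conc_initial * 1.05))
    stop("supernatant concentrations outside [0, 1.05 * initial]")
  out <- list(anion_conc = anion_conc, supernatant_conc = supernatant_conc,
              protein_conc_initial = protein_conc_initial,
              protein_mw = protein_mw, anion_label = anion_label)
  class(out) <- "precipitation_series"
  out
}

#' @export
print.precipitation_series <- function(x, ...) {
  cat(sprintf("<precipitation_series> %s: %d points, %.3g-%.3g mM, protein %g mg/mL\n",
              x$anion_label, length(x$anion_conc), min(x$anion_conc),
              max(x$anion_conc), x$protein_conc_initial))
  invisible(x)
}

#' Detect condensation and decondensation boundaries
#'
#' A titration point is classified as condensed when its supernatant
#' concentration falls below `retention_threshold` of the initial
#' protein concentration. The condensation boundary C* is located by
#' linear interpolation of the threshold crossing between the last
#' soluble and first condensed point on the rising side; the
#' decondensation boundary C** likewise on the recovery side; C_max is
#' the anion concentration of maximum precipitation (ties resolved
#' toward the lower concentration). A boundary that is not crossed is
#' reported as `NA`, not zero.
#'
#' @param series a [precipitation_series()]
#' @param retention_threshold fraction of the initial concentration
#'   (default 0.95)
#' @return object of class `phase_boundaries`: list with `c_star`,
#'   `c_double_star`, `c_max` (mM) and `ratios` (the same three as
#'   anion-per-protein molar ratios)
#' @export
detect_boundaries <- function(series, retention_threshold = 0.95) {
  stopifnot(inherits(series, "precipitation_series"),
            retention_threshold > 0, retention_threshold < 1)
  x <- series$anion_conc
  y <- series$supernatant_conc
  if (length(x) < 4) stop("need at least 4 titration points")
  thr <- retention_threshold * series$protein_conc_initial
  cond <- y < thr
  c_star <- c_dstar <- c_max <- NA_real_
  if (any(cond)) {
    imin <- which.min(y)                 # ties go to the lower concentration
    c_max <- x[imin]
    # rising side: last soluble point before the precipitation minimum
    # (isolated sub-threshold noise dips further out are not a boundary)
    sol_before <- which(!cond[seq_len(imin)])
    if (length(sol_before) > 0) {
      i1 <- max(sol_before)              # cond[i1 + 1] holds by construction
      c_star <- x[i1] + (y[i1] - thr) / (y[i1] - y[i1 + 1]) *
        (x[i1 + 1] - x[i1])
    }
    # recovery side: first soluble point after the minimum
    sol_after <- which(!cond[imin:length(x)]) + imin - 1L
    if (length(sol_after) > 0) {
      i2 <- min(sol_after) - 1L          # last condensed before recovery
      c_dstar <- x[i2] + (thr - y[i2]) / (y[i2 + 1] - y[i2]) *
        (x[i2 + 1] - x[i2])
    }
  }
  ratio <- function(cc) if (is.na(cc)) NA_real_ else
    cs_cp(cc, series$protein_conc_initial, series$protein_mw)
  out <- list(c_star = c_star, c_double_star = c_dstar, c_max = c_max,
              ratios = c(c_star = ratio(c_star),
                         c_double_star = ratio(c_dstar),
                         c_max = ratio(c_max)),
              retention_threshold = retention_threshold)
  class(out) <- "phase_boundaries"
  out
}

#' @export
print.phase_boundaries <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.4g mM", v)
  cat(sprintf("<phase_boundaries> C* = %s, C_max = %s, C** = %s (threshold %g%%)\n",
              fmt(x$c_star), fmt(x$c_max), fmt(x$c_double_star),
              100 * x$retention_threshold))
  invisible(x)
}

#' Fit the linear condensation-boundary relation
#'
#' Ordinary least squares of \eqn{c^* = m^* c_p + c^f}: the boundary
#' salt concentration against protein concentration. The slope m* is
#' the critical number of bound ions per protein and the intercept c^f
#' the free-ion concentration in equilibrium with the protein-ion
#' complex.
#'
#' @param protein_conc protein molar concentrations, mol/L (or a
#'   2-column data frame / matrix of both variables)
#' @param c_star boundary concentrations, mol/L
#' @return object of class `phase_fit_result` with `m_star` (ions per
#'   protein), `c_f` (mM), standard errors `m_star_err`, `c_f_err`,
#'   `n_points`, and the underlying `fit`
#' @export
fit_cstar_line <- function(protein_conc, c_star = NULL) {
  if (is.null(c_star)) {
    c_star <- protein_conc[[2]]
    protein_conc <- protein_conc[[1]]
  }
  ok <- is.finite(protein_conc) & is.finite(c_star)
  protein_conc <- protein_conc[ok]
  c_star <- c_star[ok]
  if (length(protein_conc) < 2 || length(unique(protein_conc)) < 2)
    stop("need at least 2 distinct protein concentrations")
  fit <- stats::lm(c_star ~ protein_conc)
  # summary.lm warns on an exactly collinear (noiseless) fit; the NaN
  # standard errors it returns are handled below
  co <- suppressWarnings(summary(fit)$coefficients)
  se <- function(term, col) if (nrow(co) == 2 && ncol(co) >= 2 &&
                                is.finite(co[term, col])) co[term, col] else NA_real_
  out <- list(m_star = unname(stats::coef(fit)["protein_conc"]),
              c_f = unname(stats::coef(fit)["(Intercept)"]) * 1e3,
              m_star_err = se("protein_conc", 2),
              c_f_err = se("(Intercept)", 2) * 1e3,
              n_points = length(protein_conc),
              fit = fit)
  class(out) <- "phase_fit_result"
  out
}

#' @export
print.phase_fit_result <- function(x, ...) {
  cat(sprintf("<phase_fit_result> m* = %.3f +/- %.3f ions/protein, c^f = %.3g +/- %.2g mM (%d points)\n",
              x$m_star, x$m_star_err, x$c_f, x$c_f_err, x$n_points))
  invisible(x)
}

#' Charge contribution of bound ions at the condensation boundary
#'
#' The valence neutralised per protein when m* ions of the given
#' valence are bound: `|z| * m_star`.
#'
#' @param m_star bound ions per protein (>= 0)
#' @param anion_valence anion valence (sign ignored)
#' @return valence units per protein
#' @examples
#' charge_contribution(0.762, -5)  # 3.81
#' @export
charge_contribution <- function(m_star, anion_valence) {
  stopifnot(all(m_star >= 0))
  abs(anion_valence) * m_star
}

#' NaCl concentration equivalent to a target ionic strength
#'
#' The 1:1 salt concentration that raises a background electrolyte to
#' the target ionic strength (for NaCl, I increases by c).
#'
#' @param target_I target ionic strength, mol/L
#' @param background optional species data frame (as for
#'   [ionic_strength()]) already in solution
#' @return NaCl concentration, mol/L
#' @export
nacl_equivalent <- function(target_I, background = NULL) {
  I_bg <- if (is.null(background)) 0 else ionic_strength(background)
  if (target_I < I_bg - 1e-12)
    stop("target ionic strength below the background (",
         signif(I_bg, 4), " mol/L)")
  max(target_I - I_bg, 0)
}

#' Detect boundaries for several series and fit the boundary line
#'
#' Convenience wrapper for the full phase-diagram analysis: boundary
#' detection per titration followed by the linear fit of the chosen
#' boundary against protein concentration.
#'
#' @param series_list list of [precipitation_series()] at different
#'   protein concentrations
#' @param boundary `"c_star"` or `"c_double_star"`
#' @param retention_threshold passed to [detect_boundaries()]
#' @return a [fit_cstar_line()] result
#' @export
fit_phase_boundaries <- function(series_list, boundary = c("c_star", "c_double_star"),
                                 retention_threshold = 0.95) {
  boundary <- match.arg(boundary)
  cp <- vapply(series_list, function(s)
    s$protein_conc_initial / s$protein_mw, 0)           # mol/L
  cb <- vapply(series_list, function(s)
    detect_boundaries(s, retention_threshold)[[boundary]] / 1e3, 0)
  fit_cstar_line(cp, cb)
}
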