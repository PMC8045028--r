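---
title: "Modelling arginine-phosphate driven re-entrant condensation of histatin 5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arginine-phosphate driven re-entrant condensation of histatin 5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argphos)
```

## The system and the questions

Histatin 5 (Hst5) is a 24-residue cationic, intrinsically disordered
saliva peptide (net charge +5 at pH 8.4 with neutral histidines). In
the presence of the polyvalent anion tripolyphosphate (TPP, z = -5 at
pH 8.4) its solutions show re-entrant condensation (RC): a condensed
regime between two critical anion concentrations, the condensation
boundary C\* and the decondensation boundary C\*\*. Electrostatic charge
neutralisation and inversion explain the existence of the window, but
not why polyphosphates condense the protein while citrate — of similar
charge and size — does not. The missing ingredient is a specific,
short-ranged attraction between arginine side chains (guanidinium) and
phosphate groups.

`argphos` implements the two computational halves of that story:

1. a coarse-grained ("bead-necklace") Metropolis Monte Carlo model of
   Hst5 with explicit polyvalent anions and an optional Arg-anion
   attraction term, with the observables needed to compare against
   small-angle X-ray scattering (SAXS): radius of gyration, Debye
   scattering curves, Arg-ion contacts, chain clusters;
2. the data analyses around the experiments: Guinier and Kratky
   analysis of SAXS curves, association numbers from calibrated forward
   scattering, condensation-boundary detection from precipitation
   titrations, the linear boundary relation c\* = m\* c_p + c^f, ionic
   strength and NaCl-equivalence arithmetic.

A synthetic-data module generates every input with known ground truth,
so the full pipeline is testable without downloads.

## The coarse-grained model

Each amino acid is one hard sphere of radius 2 Å (the excluded volume
including hydration), connected by harmonic bonds

$$u_{bond}(r) = \tfrac{k}{2}\,(r - r_0)^2, \qquad
  r_0 = 4.1\ \mathrm{\AA},\quad k = 0.4\ \mathrm{N/m}
  \;(\approx 0.97\ kT/\mathrm{\AA^2\ at\ 298\ K}).$$

Every bead carries the charge of its amino acid; the N- and C-terminal
charges are kept as explicit entries of the chain topology. Nonbonded
interactions are pairwise additive over all sites:

* **Hard sphere**: infinite below contact $R_i + R_j$, zero at and
  beyond it. Contact itself is allowed, which is what makes the quoted
  contact energies attainable.
* **Extended Debye-Hückel**: a screened Coulomb potential with the
  hard-core (finite ion size) correction
  $$\frac{u_{el}(r)}{kT} = z_i z_j \,\frac{\lambda_B}{r}\,
    \frac{e^{\kappa(R_i+R_j)}}{(1+\kappa R_i)(1+\kappa R_j)}\,
    e^{-\kappa r},$$
  with Bjerrum length $\lambda_B = e^2/(4\pi\varepsilon_0\varepsilon_r
  k_B T) \approx 7.15$ Å in water at 298 K. It reduces to bare Coulomb
  at $\kappa = 0$; the $\kappa R$ factors are what "extended" denotes.
* **Short-ranged attraction**: $u_{sr}(r) = -\epsilon/r^6$, where
  $\epsilon$ reflects the excess polarizability of the amino acid. For
  amino-acid pairs the pair strength is the arithmetic mean of the two
  sites' $\epsilon$ (averaging over $\epsilon$ rather than
  $\sqrt\epsilon$; the alternative reading changes pair strengths by
  under 2 % for near-equal values and is not exposed as a default).
* **Arg-polyvalent anion attraction**: the same $r^{-6}$ form with
  $\epsilon = 8.0\times 10^4$ kJ Å⁶/mol, which is an 8.0 kT attraction
  at the 4 Å contact. This single term is the package's scientific
  centrepiece: switching it off recovers the purely electrostatic
  model.

Explicit ions are hard spheres of the same 2 Å radius carrying the
anion's net charge (defaults: citrate -3, pyrophosphate -4,
tripolyphosphate -5). Ion-protein pairs interact only through hard
sphere and electrostatics unless the bead is an arginine and the ion is
polyvalent. The TPP valence deserves a note: the analysis text of the
source study multiplies m\* by 4, yet its own tabulated charge
contributions (0.762 × |z| = 3.81) and the ionic strengths it reports
at C\*\* only reproduce with |z| = 5, the fully deprotonated value at
pH 8.4. The package therefore treats the valence as data everywhere
and defaults TPP to -5.

Two modelling conventions are worth stating explicitly:

* **Terminal charges.** The topology keeps NT/CT as explicit
  zero-radius charge sites co-located with the first/last bead; when a
  simulation state is built, their charges are folded onto those beads.
  A co-located point charge differs from a folded one only through the
  hard-core correction factor (radius 0 vs 2 Å), a small per-pair
  factor at the 10 mM ionic strengths used and exactly zero without
  screening, and folding avoids singular zero-distance pairs.
* **Screening bookkeeping.** $\kappa$ is computed from the *implicit*
  background only (buffer and any 1:1 salt, via $I = \tfrac12\sum_i
  c_i z_i^2$); explicit ions in the box do not also contribute to
  $\kappa$, which would double-count their screening.

Energies are handled internally in kT at the force field's temperature
(default 298.15 K); all conversions from kJ/mol and N/m are centralised
in one constants unit pinned to CODATA values.

## Monte Carlo sampling

`run_mc()` samples the canonical ensemble with four move classes:
single-site displacements (protein beads and ions share this class),
pivot rotations of the shorter arm about a random internal hinge,
rigid whole-chain translations, and a slithering (reptation) move.
Single-site moves are attempted 20 times as often as each of the other
three. "Steps" are single proposed moves, not sweeps. The default run
lengths are 5×10⁵ equilibration and 10⁶ production steps in a periodic
250 Å box with minimum-image truncation.

Design choices that were genuinely open:

* **Move amplitudes** are not part of the model definition; they are
  auto-tuned toward 30-50 % acceptance during equilibration and then
  frozen, since tuning during production would break detailed balance.
  The frozen values are reported in the trajectory object.
* **Slither regrowth.** Re-inserting the terminal bead at exactly
  $r_0$ looks symmetric but is not for flexible bonds: it maps any
  terminal bond length to one fixed length, a proposal that detailed
  balance cannot undo, and it measurably skews the bond-length
  distribution (two-bead mean 4.875 Å against 5.018 Å from quadrature).
  The package instead draws the regrown bond length from the bond
  Boltzmann distribution $P(r)\propto r^2 e^{-u_{bond}(r)/kT}$ and
  cancels the regrown/removed bond energies in the acceptance ratio;
  the two-bead histogram then matches the quadrature oracle
  (chi-squared p ≈ 0.13 at 10⁵ decorrelated samples).
* **Energy bookkeeping** is incremental (only terms involving moved
  sites are recomputed) and revalidated against a full recomputation
  every 10⁴ steps with a 10⁻⁶ kT relative tolerance; drift beyond the
  tolerance is an error, not a warning.
* **Coordinates are never wrapped**; all distances use minimum image.
  This keeps pivot and rigid-body moves exact isometries and makes
  chain unwrapping for the radius of gyration trivial (bond-walking,
  unambiguous because bonds of ~4 Å are far below the 250 Å box).
* Ions are displaced through the single-particle move class (the move
  list of the source protocol names only protein moves; ions must
  nevertheless equilibrate). Explicit neutralising counterions are off
  by default and available through the ion configuration.

The reproduction setup for the conformational-ensemble comparison uses
one Hst5 chain with 10 explicit TPP ions (an anion-per-protein ratio of
10 at the single-chain box concentration of 0.106 mM) over a 10 mM
implicit monovalent background, against (i) the same system with the
Arg-anion term switched off and (ii) the chain alone in the monovalent
background. The acceptance suite runs each condition at the full
protocol; the mean radii of gyration order as expected — specific
attraction most compact, electrostatic-only intermediate, monovalent
salt most extended — with gaps resolved beyond block-averaged standard
errors.

## SAXS analysis

`guinier_fit()` performs the standard low-q analysis: weighted linear
regression of ln I on q² restricted to the window q·Rg < 0.8. Because
the window depends on the fitted Rg, the fit iterates from a
deterministic initial window (first 10 points) to a fixed point, with
a two-window cycle broken toward the larger window and the final
window re-checked against the fitted Rg. When uncertainties are
present the weights are $1/\sigma_{\ln I}^2$ with $\sigma_{\ln I} =
\sigma/I$; otherwise the fit is unweighted. A positive Guinier slope
is reported as an error, never as NaN. A sign-runs test on the final
residuals flags a systematic low-q trend (e.g. aggregation) as a
warning field, not a rejection — screening, not gatekeeping.

Forward-scattering calibration follows the ratio method:
$N_{ass} = (I_0/c)_{sample} / (I_0/c)_{ref} \cdot M_{ref}/M_{monomer}$,
with the reference mass a required argument (no default is asserted
for the standard's molecular weight). The Kratky transform returns
plain (q, q²I) with no dimensionless rescaling. `debye_scattering()`
bridges simulation to SAXS through the Debye formula over identical
point scatterers, normalised to I(0) = 1 per chain.

## Phase-boundary analysis

A titration point is *condensed* when its supernatant concentration
falls below 95 % of the initial protein concentration. C\* is located
by linear interpolation of the threshold crossing between the last
soluble and first condensed point on the rising side of the
precipitation well, C\*\* likewise on the recovery side, and C_max is
the grid point of maximum precipitation (ties toward the lower
concentration). The rising/recovery transitions are anchored to the
precipitation minimum, so an isolated sub-threshold noise dip far from
the well is not mistaken for a boundary. Boundaries that are not
crossed are reported as missing (`NA`), never as zero.

The boundary line $c^* = m^* c_p + c^f$ is fitted by ordinary least
squares (the source figures show an unweighted linear fit); the slope
is the critical number of bound ions per protein, the intercept the
free-ion concentration in equilibrium with the protein-ion complex.
Concentrations enter in mol/L and $c^f$ is reported in mM, matching
how those quantities are usually quoted. The charge contribution is
|z|·m\* and the NaCl equivalent of a target ionic strength is the 1:1
salt concentration that tops up the background, both one-liners kept
as named operations because they carry the units reasoning.

## What the synthetic data emulate — and what they do not

`gen_system()` grows chains as self-avoiding random walks at bond
length $r_0$ and scatters ions uniformly, rejecting overlaps.
`gen_guinier_curve()` produces exact Guinier-regime curves with
mean-preserving multiplicative lognormal noise (σ column = cv × ideal
intensity). `gen_precipitation()` builds titrations whose ground truth
is the pair (m\*, c^f): for each protein concentration the boundaries
are placed at $C^* = m^* c_p + c^f$ and $C^{**} = C^*\cdot$
`window_width_ratio`, with the supernatant floor at 1 mg/mL (the
residual solubility observed at maximum precipitation) and additive
Gaussian noise truncated at zero.

The well shape between the boundaries is a construction choice, since
nothing downstream depends on it. It is piecewise-linear in
log-concentration with two properties chosen deliberately:

* the titration grid contains the boundary concentrations themselves,
  where the curve passes exactly through the 95 % threshold — so the
  noiseless round trip (generate → detect → fit) recovers (m\*, c^f)
  to machine precision *by construction*;
* each crossing is locally steep and symmetric about the threshold
  point. An asymmetric crossing (shallow approach on the soluble side,
  steep drop on the condensed side) biases the interpolated boundary
  under noise by several percent; the symmetric geometry removes the
  first-order bias, and the noisy round trip is statistically unbiased
  at the default noise of 0.1 mg/mL.

The default protein concentrations (3.2-7.8 mg/mL) are derived from
the observed phase behaviour rather than picked freely: anion-per-
protein ratios at the condensation boundary run from 1.1 at the lowest
investigated concentration to 0.9 at the highest, which with
m\* = 0.762 and c^f = 0.355 mM solves to exactly this range. Below
~2 mg/mL the 5 % retention margin falls to the size of the assay noise
and the boundary is no longer measurable — one reason such
concentrations are not part of the experimental design.

What the generators do *not* emulate: instrument-specific noise
spectra, incoherent backgrounds and absolute SAXS units;
interparticle structure factors at high concentration; slow
precipitation kinetics (each titration point is an equilibrium
snapshot); polydispersity of the condensed phase. Tests passing on
synthetic data therefore demonstrate the correctness of the estimators
and of the sampling machinery under the stated noise models, not the
fidelity of those noise models to any particular beamline or plate
reader.

## Numerical choices and degenerate inputs

* Constants are CODATA 2018; energies in kT at the configured
  temperature; Debye $\kappa$ from $I$ in mol/L.
* The generic amino-acid $\epsilon$ defaults to 6.1×10³ kJ Å⁶/mol,
  set so that the bead-bead contact attraction is 0.6 kT at 298 K; it
  is configurable because the underlying model family calibrates it
  against atomistic data rather than printing it.
* Hard-sphere contact (r exactly $R_i+R_j$) is legal; the Metropolis
  rule never accepts an infinite energy change; the initial state must
  be overlap-free or `run_mc()` refuses to start.
* `guinier_fit()` requires three admissible points and stops with an
  explanatory error on non-decaying curves; `detect_boundaries()`
  requires four points and a strictly increasing grid; `fit_cstar_line()`
  requires two distinct protein concentrations and returns `NA`
  standard errors for an exact two-point fit.
* Reproducibility: every stochastic function takes a seed and is a
  pure function of it; `run_mc()` runs are bitwise reproducible for a
  fixed (initial state, force field, config).

Problem sizes used by the shipped test-suite and acceptance checks,
chosen as the smallest sizes at which each statistical check is
well-powered: two-bead sampling checks use 10⁵ samples taken every 50
steps; the energy-oracle comparison uses 50 random 20-site states; the
Guinier recovery study uses 20 seeds at 5 % noise; the boundary-fit
recovery uses 100 seeds at 0.1 mg/mL noise; the three-condition
conformational comparison runs the full 5×10⁵ + 10⁶ step protocol per
condition.

## Known limitations

The model is a single-bead-per-residue description with implicit
water and linearised screening: it cannot resolve guanidinium-phosphate
geometry (the 8 kT term is an effective strength), ignores charge
regulation beyond the fixed-pH charge assignment, and truncates
electrostatics by minimum image rather than Ewald summation — adequate
at 10-160 mM screening in a 250 Å box, questionable for much larger
boxes at very low salt. The phase analysis treats the condensed phase
as a black box: it locates boundaries and fits their protein-
concentration dependence but contains no thermodynamic model of the
dense phase. Simulation error bars use block averaging with 20 blocks
by default; strongly ion-bound states relax slowly, and the
conformational comparisons should always be run at the full protocol
lengths rather than short exploratory settings.
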