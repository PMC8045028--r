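#' Physical constants (CODATA 2018)
#'
#' All unit conversions in the package funnel through these values:
#' energies are handled internally in units of kT at the force field's
#' temperature, lengths in Angstrom, concentrations in mol/L unless a
#' function states otherwise.
#'
#' @format A named list with elements
#'   \describe{
#'     \item{e}{elementary charge, C}
#'     \item{eps0}{vacuum permittivity, F/m}
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{N_A}{Avogadro constant, 1/mol}
#'     \item{R_kJ}{molar gas constant, kJ/(mol K)}
#'   }
#' @export
codata <- list(
  e    = 1.602176634e-19,
  eps0 = 8.8541878128e-12,
  kB   = 1.380649e-23,
  N_A  = 6.02214076e23,
  R_kJ = 8.314462618e-3
)

#' Thermal energy in kJ/mol
#'
#' @param temperature temperature in K
#' @return kT expressed as kJ/mol (i.e. R*T)
#' @export
kT_kJmol <- function(temperature) codata$R_kJ * temperature

#' Bjerrum length
#'
#' Distance at which two unit charges interact with thermal energy kT.
#'
#' @param temperature temperature in K
#' @param dielectric relative permittivity of the medium
#' @return Bjerrum length in Angstrom (about 7.1 A for water at 298 K)
#' @export
bjerrum_length <- function(temperature, dielectric) {
  with(codata, e^2 / (4 * pi * eps0 * dielectric * kB * temperature)) * 1e10
}

#' Convert a spring constant from N/m to kT per square Angstrom
#'
#' @param k_Nm force constant in N/m
#' @param temperature temperature in K
#' @return force constant in kT/A^2
#' @export
spring_kT <- function(k_Nm, temperature) {
  # 1 N/m = 1 J/m^2 = 1e-20 J/A^2
  k_Nm * 1e-20 / (codata$kB * temperature)
}
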