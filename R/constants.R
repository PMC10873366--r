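#' Physical constants and unit conventions
#'
#' The package works in GROMACS-style units throughout: lengths in nm,
#' energies in kJ/mol, time in ps, masses in amu (g/mol), charges in units
#' of the elementary charge.  Temperatures are in K.  The thermodynamic
#' reference temperature for interaction strengths quoted in units of
#' \eqn{k_B T} is 300 K, at which \eqn{k_B T \approx 2.494} kJ/mol (so that
#' 0.16 \eqn{k_B T \approx 0.4} kJ/mol).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/(mol K).}
#'   \item{T_ref}{Reference temperature, K.}
#'   \item{kT_ref}{\eqn{k_B T} at the reference temperature, kJ/mol.}
#'   \item{ke}{Coulomb prefactor \eqn{1/(4\pi\epsilon_0)} in
#'     kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.}
#'   \item{e}{Elementary charge, C.}
#'   \item{NA_const}{Avogadro constant, 1/mol.}
#'   \item{eps0}{Vacuum permittivity, C\eqn{^2} J\eqn{^{-1}} m\eqn{^{-1}}.}
#'   \item{kB_SI}{Boltzmann constant, J/K.}
#' }
#' @export
cg_constants <- list(
  kB       = 0.008314462618,   # kJ/(mol K)
  T_ref    = 300,
  kT_ref   = 0.008314462618 * 300,
  ke       = 138.935458,       # kJ mol^-1 nm e^-2
  e        = 1.602176634e-19,  # C
  NA_const = 6.02214076e23,
  eps0     = 8.8541878128e-12, # C^2 J^-1 m^-1
  kB_SI    = 1.380649e-23      # J/K
)

#' Thermal energy in kJ/mol
#'
#' @param temperature Temperature in K.
#' @return \eqn{k_B T} in kJ/mol.
#' @export
kT <- function(temperature = cg_constants$T_ref) {
  cg_constants$kB * temperature
}
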