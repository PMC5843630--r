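#' Physical constants in the package unit system
#'
#' The package works throughout in the MD unit system kJ/mol (energy),
#' nm (length), ps (time), atomic mass unit (mass) and elementary charge
#' (charge). In these units the Coulomb prefactor \eqn{1/(4\pi\epsilon_0)}
#' is approximately 138.935 kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}: two unit
#' charges 1 nm apart have an interaction energy of 138.935 kJ/mol.
#'
#' @return A list with components
#'   \item{coulomb_factor}{\eqn{1/(4\pi\epsilon_0)} in kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.}
#'   \item{vacuum_permittivity}{\eqn{\epsilon_0} in e\eqn{^2} mol kJ\eqn{^{-1}} nm\eqn{^{-1}}.}
#'   \item{kB}{Boltzmann constant in kJ mol\eqn{^{-1}} K\eqn{^{-1}}.}
#'   \item{amu_per_g_mol}{mass conversion: 1 u expressed in g/mol (identity).}
#' @examples
#' pc <- physical_constants()
#' pc$coulomb_factor / 0.5  # energy of two +1e charges at 0.5 nm, kJ/mol
#' @export
physical_constants <- function() {
  coul <- 138.935458
  list(
    coulomb_factor = coul,
    vacuum_permittivity = 1 / (4 * pi * coul),
    kB = 0.008314462618,
    amu_per_g_mol = 1
  )
}

# internal shorthands
.coul <- 138.935458
.kB <- 0.008314462618
# Avogadro-based conversion: density [g/cm^3] = N * M[g/mol] * .mass_conv / V[nm^3]
.mass_conv <- 1 / 602.214076  # = 1e21 / N_A
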