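#' Physical constants used throughout the package
#'
#' Frozen CODATA-2018 values, SI units. Every function in the package draws
#' its constants from this single list, so `beta = 1/(kB*T)`-type products are
#' consistent everywhere.
#'
#' @return Named list with components:
#' \describe{
#'   \item{e0}{elementary charge (C)}
#'   \item{eps0}{vacuum permittivity (F/m)}
#'   \item{kB}{Boltzmann constant (J/K)}
#'   \item{NA}{Avogadro number (1/mol)}
#'   \item{debye}{one Debye in C m}
#' }
#' @examples
#' mlpb_constants()$e0
#' @export
mlpb_constants <- function() {
  list(
    e0    = 1.602176634e-19,
    eps0  = 8.8541878128e-12,
    kB    = 1.380649e-23,
    N_A   = 6.02214076e23,
    debye = 3.33564e-30
  )
}

# mol/l -> number density (1/m^3)
.mol_per_l_to_m3 <- function(c_mol_l) c_mol_l * 1e3 * mlpb_constants()$N_A
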