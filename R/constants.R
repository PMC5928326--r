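## Physical constants (CODATA 2018) in the GROMOS/GROMACS unit system:
## length nm, energy kJ/mol, time ps, charge e, temperature K, pressure bar.

#' Physical constants used throughout the package
#'
#' A named list of CODATA 2018 constants expressed in the internal unit
#' system (nm, kJ/mol, ps, e, K, bar).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{h}{Planck constant, J s}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{e}{elementary charge, C}
#'   \item{eps0}{vacuum permittivity, C^2/(J m)}
#'   \item{enm_to_debye}{conversion factor, 1 e nm in Debye}
#' }
#' @export
aromring_constants <- list(
  kB   = 1.380649e-23,
  R    = 8.31446261815324,
  h    = 6.62607015e-34,
  "N_A" = 6.02214076e23,
  e    = 1.602176634e-19,
  eps0 = 8.8541878128e-12,
  enm_to_debye = 48.0321
)

## RT in kJ/mol at temperature T (K)
rt_kj <- function(T) aromring_constants$R * T / 1000
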