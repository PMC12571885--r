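#' Physical constants and unit conversions
#'
#' All unit handling in the package is routed through this single table.
#' The internal unit system is Angstrom / femtosecond / electronvolt / amu /
#' Debye; every derived constant is computed once from SI definitions
#' (CODATA 2018 exact values where available).
#'
#' @return A named list of constants:
#' \describe{
#'   \item{acc_ev_A_amu}{conversion from force/mass in eV A^-1 amu^-1 to
#'     acceleration in A fs^-2 (equivalently, eV to amu A^2 fs^-2).}
#'   \item{kB_eV}{Boltzmann constant, eV/K.}
#'   \item{c_cm_fs}{speed of light, cm/fs (converts fs^-1 to cm^-1).}
#'   \item{eA_to_debye}{dipole conversion, e*Angstrom to Debye.}
#'   \item{rad_fs_to_cm1}{angular frequency rad/fs to wavenumber cm^-1,
#'     i.e. 1/(2*pi*c).}
#' }
#' @examples
#' uc <- unit_constants()
#' # harmonic diatomic: k = 1 eV/A^2, masses 1 amu -> mu = 0.5 amu
#' sqrt(1 * uc$acc_ev_A_amu / 0.5) * uc$rad_fs_to_cm1  # ~737.5 cm^-1
#' @export
unit_constants <- function() .mdirspec_const

# SI definitions (exact where CODATA fixes them)
.mdirspec_const <- local({
  e_charge <- 1.602176634e-19      # C (exact)
  amu_kg   <- 1.66053906660e-27    # kg
  c_m_s    <- 2.99792458e8         # m/s (exact)
  kB_J     <- 1.380649e-23         # J/K (exact)
  debye_Cm <- 1e-21 / c_m_s        # C m: 1 D = 1e-18 statC cm
  # 1 eV/A force on 1 amu -> m/s^2 -> A/fs^2 (1 m/s^2 = 1e-20 A/fs^2)
  acc <- (e_charge / 1e-10) / amu_kg * 1e-20
  list(
    acc_ev_A_amu  = acc,
    kB_eV         = kB_J / e_charge,
    c_cm_fs       = c_m_s * 100 * 1e-15,
    eA_to_debye   = e_charge * 1e-10 / debye_Cm,
    rad_fs_to_cm1 = 1 / (2 * pi * c_m_s * 100 * 1e-15)
  )
})

#' Atomic masses for the supported elements
#'
#' @param symbols character vector of element symbols (subset of H, C, N, O).
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(symbols) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
  unknown <- setdiff(unique(symbols), names(tab))
  if (length(unknown) > 0)
    stop("unsupported element symbol(s): ", paste(unknown, collapse = ", "))
  unname(tab[symbols])
}
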