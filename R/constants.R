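#' Physical constants used throughout the package
#'
#' CODATA 2018 values. Returned as a named list so that every derived
#' quantity (resonance fields, Larmor frequencies, the point-dipole
#' prefactor) is computed from the same source rather than from hardcoded
#' composites.
#'
#' @return Named list with elements `h` (Planck constant, J s), `mu_B`
#'   (Bohr magneton, J/T), `mu_N` (nuclear magneton, J/T), `mu_0` (vacuum
#'   permeability, N/A^2) and `g_e_free` (free-electron g-factor).
#' @export
#' @examples
#' epr_constants()$h
epr_constants <- function() {
  list(
    h       = 6.62607015e-34,     # exact (SI definition)
    mu_B    = 9.2740100783e-24,
    mu_N    = 5.0507837461e-27,
    mu_0    = 1.25663706212e-6,
    g_e_free = 2.00231930436256
  )
}

# Nuclear g-factors for the nuclei the HYSCORE layer supports.
# Extensible: I = 1 nuclei need quadrupole terms the ridge model does not
# include, so only I = 1/2 entries ship.
.nuclear_g_factors <- c(
  "1H" = 5.5856946893
)

.supported_nuclei <- function() names(.nuclear_g_factors)
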