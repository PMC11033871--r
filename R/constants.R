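## Internal unit system: lengths nm, time ps, temperature K, energy kJ/mol,
## masses g/mol.  With these units kJ/mol = g/mol * nm^2 / ps^2, so no
## conversion factors appear inside the integrator.

#' Physical constants used by pacsmd
#'
#' Boltzmann constant in the internal unit system, the gas constant in
#' kcal/(mol K) used for binding free energies, the kJ/kcal conversion
#' factor, and the standard-state volume per molecule at 1 M.
#'
#' @format A named list with elements `kB` (kJ/(mol K)), `R_kcal`
#'   (kcal/(mol K)), `kJ_per_kcal`, and `V0_nm3` (nm^3).
#' @export
pacs_constants <- list(
  kB          = 0.0083144621,      # kJ/(mol K)
  R_kcal      = 1.98720425864e-3,  # kcal/(mol K)
  kJ_per_kcal = 4.184,
  V0_nm3      = 1.661              # volume per molecule at 1 M standard state
)

#' @keywords internal
kBT <- function(temperature) pacs_constants$kB * temperature
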