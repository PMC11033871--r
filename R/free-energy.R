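## Free-energy analysis: potential of mean force from a stationary
## distribution, volume-corrected standard binding free energy, and the
## thermodynamic/kinetic conversions used to compare with experiment.

#' Potential of mean force from stationary populations
#'
#' F_i = -kB T ln(pi_i), shifted so the minimum over populated bins is
#' zero.  Zero-probability states are excluded, not reported as -Inf.
#'
#' @param pi Stationary probabilities (on the connected state set).
#' @param centers Bin centers in feature units (1-D).
#' @param temperature Temperature (K).
#' @return Object of class `free_energy_profile` with `centers` (sorted
#'   ascending) and `F` (kJ/mol, min-shifted).
#' @export
free_energy_profile <- function(pi, centers, temperature = 300) {
  centers <- as.numeric(centers)
  stopifnot(length(pi) == length(centers))
  keep <- pi > 0
  centers <- centers[keep]; pi <- pi[keep]
  ord <- order(centers)
  F <- -kBT(temperature) * log(pi[ord])
  F <- F - min(F)
  structure(list(centers = centers[ord], F = F,
                 temperature = temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "free-energy profile: %d bins over [%.3g, %.3g], max %.2f kJ/mol (T = %g K)\n",
    length(x$F), min(x$centers), max(x$centers), max(x$F),
    x$temperature))
  invisible(x)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$centers, x$F, type = "l", xlab = "feature",
                 ylab = "free energy (kJ/mol)", ...)
  invisible(x)
}

#' Volume-corrected standard binding free energy
#'
#' From a 1-D PMF along the inter-COM distance: the unbinding cost is
#' the plateau free energy minus the bound-minimum free energy, and the
#' finite volume the unbound ligand actually samples (estimated as the
#' convex-hull volume of its COM positions in the unbound shell) is
#' corrected to the standard-state volume V0 = 1.661 nm^3 per molecule:
#'
#'   dG0 = -dW - R T ln(V_sim / V0)
#'
#' reported in kcal/mol.
#'
#' @param profile A [free_energy_profile()] along the inter-COM
#'   distance.
#' @param unbound_points M x 3 matrix of ligand COM positions in the
#'   unbound shell (M >= 4, non-degenerate).
#' @param temperature Temperature (K); default the profile's.
#' @param plateau_fraction Fraction of the distance range (from the far
#'   end) that must be flat; default 0.2.
#' @param plateau_tol Maximum allowed free-energy variation over the
#'   plateau (kJ/mol); default 0.5.
#' @return dG0 in kcal/mol, with attributes `dW_kJ` (plateau minus
#'   bound minimum), `V_sim_nm3` and `correction_kcal`.
#' @export
standard_binding_dG <- function(profile, unbound_points,
                                temperature = NULL,
                                plateau_fraction = 0.2,
                                plateau_tol = 0.5) {
  temperature <- temperature %||% profile$temperature
  ctr <- profile$centers; F <- profile$F
  lo <- min(ctr); hi <- max(ctr)
  in_plateau <- ctr >= hi - plateau_fraction * (hi - lo)
  if (sum(in_plateau) < 2L || diff(range(F[in_plateau])) > plateau_tol)
    stop("no unbound plateau detected: profile varies ",
         sprintf("%.2f", diff(range(F[in_plateau]))),
         " kJ/mol over the last ", plateau_fraction * 100,
         "% of the range")
  dW <- mean(F[in_plateau]) - min(F)
  hull <- convex_hull(as.matrix(unbound_points))
  V_sim <- hull$volume
  RT_kJ <- kBT(temperature)
  dG_kJ <- -dW - RT_kJ * log(V_sim / pacs_constants$V0_nm3)
  out <- dG_kJ / pacs_constants$kJ_per_kcal
  attr(out, "dW_kJ") <- dW
  attr(out, "V_sim_nm3") <- V_sim
  attr(out, "correction_kcal") <-
    -RT_kJ * log(V_sim / pacs_constants$V0_nm3) /
    pacs_constants$kJ_per_kcal
  out
}

#' Dissociation constant to standard binding free energy
#'
#' dG0 = R T ln(KD / c0) with c0 = 1 M, in kcal/mol.
#'
#' @param KD Dissociation constant (molar).
#' @param temperature Temperature (K).
#' @return dG0 in kcal/mol (negative for sub-molar KD).
#' @export
kd_to_dG <- function(KD, temperature = 300) {
  if (any(KD <= 0)) stop("KD must be > 0")
  pacs_constants$R_kcal * temperature * log(KD)
}

#' Standard binding free energy to dissociation constant
#' @param dG dG0 in kcal/mol.
#' @param temperature Temperature (K).
#' @return KD in molar.
#' @export
dG_to_kd <- function(dG, temperature = 300) {
  exp(dG / (pacs_constants$R_kcal * temperature))
}

#' Acceleration of event sampling relative to real time
#'
#' The acceleration of a rare-event simulation is the experimentally
#' observed timescale of the event (1 / k_off) divided by the total
#' simulation time needed to observe it.  Orders of magnitude are
#' reported as 10^floor(log10 x), the convention in which 375 s is "of
#' order 10^2 s".
#'
#' @param k_off Dissociation rate (1/s).
#' @param simulation_time Simulation time needed to observe the event
#'   (s).
#' @return List with `event_time` (s), `event_time_order`, `ratio` and
#'   `order` (both dimensionless).
#' @export
acceleration_ratio <- function(k_off, simulation_time) {
  if (k_off <= 0 || simulation_time <= 0)
    stop("k_off and simulation_time must be > 0")
  event <- 1 / k_off
  ratio <- event / simulation_time
  list(event_time = event,
       event_time_order = 10^floor(log10(event)),
       ratio = ratio,
       order = 10^floor(log10(ratio)))
}
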