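# Kinetic constraints and regime logic: Ghose-Tyagi glycerol uptake,
# logistic acetate secretion ceiling, regime-dependent death constants and
# objective weight switching at the glycerol threshold.

#' Kinetic parameters of the dynamic model
#'
#' Container for the eight kinetic constants of the dynamic model plus the
#' glycerol threshold separating the limitation and excess regimes.
#' Defaults are the fitted values for *Clostridium* sp IBUN 158B grown on
#' glycerol: basal and maximal acetate secretion fluxes `v0_aa` = 0.1578 and
#' `vinf_aa` = 11.50 mmol/gDW/h with accumulation rate `R_aa` = 0.0859
#' g·h/mmol; death constants `kd_lim` = 0.0350 and `kd_exc` = 0.0105 1/h at
#' glycerol limitation and excess; Ghose-Tyagi uptake constants
#' `vmax_gly` = 174.86 mmol/gDW/h, `ks_gly` = 482.1 mM and
#' `ki_gly` = 755.4 mM; regime switch at 15 g/L glycerol.
#'
#' @param v0_aa basal acetate secretion flux (mmol/gDW/h)
#' @param vinf_aa maximal acetate secretion flux (mmol/gDW/h)
#' @param R_aa accumulation rate of the acetate ceiling (g·h/mmol)
#' @param kd_lim death constant at glycerol limitation (1/h)
#' @param kd_exc death constant at glycerol excess (1/h)
#' @param vmax_gly maximal glycerol uptake flux (mmol/gDW/h)
#' @param ks_gly glycerol affinity constant (mM)
#' @param ki_gly glycerol inhibition constant (mM)
#' @param switch_gly glycerol concentration (g/L) separating the limitation
#'   (below) and excess (at or above) regimes
#' @return an object of class `kinetic_params`
#' @export
kinetic_params <- function(v0_aa = 0.1578, vinf_aa = 11.50, R_aa = 0.0859,
                           kd_lim = 0.0350, kd_exc = 0.0105,
                           vmax_gly = 174.86, ks_gly = 482.1,
                           ki_gly = 755.4, switch_gly = 15) {
  for (nm in c("v0_aa", "vinf_aa", "R_aa", "kd_lim", "kd_exc", "vmax_gly",
               "ks_gly", "ki_gly", "switch_gly"))
    .chk_pos(get(nm), nm)
  if (ks_gly >= ki_gly) stop("'ks_gly' must be smaller than 'ki_gly'")
  if (v0_aa >= vinf_aa) stop("'v0_aa' must be smaller than 'vinf_aa'")
  structure(list(v0_aa = v0_aa, vinf_aa = vinf_aa, R_aa = R_aa,
                 kd_lim = kd_lim, kd_exc = kd_exc, vmax_gly = vmax_gly,
                 ks_gly = ks_gly, ki_gly = ki_gly, switch_gly = switch_gly),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters of the DFBA model:\n")
  v <- unlist(unclass(x))
  print(v)
  invisible(x)
}

#' Glycerol uptake flux (Ghose-Tyagi substrate inhibition)
#'
#' `vmax * G/(ks + G) * (1 - G/ki)`, clamped at zero for `G >= ki`:
#' Monod saturation with linear substrate inhibition vanishing at the
#' inhibition concentration.
#'
#' @param glycerol_mM extracellular glycerol in mM (non-negative)
#' @param p a [kinetic_params()] object
#' @return uptake flux in mmol/gDW/h
#' @export
glycerol_uptake_bound <- function(glycerol_mM, p = kinetic_params()) {
  if (any(glycerol_mM < 0)) stop("negative glycerol concentration")
  v <- p$vmax_gly * glycerol_mM / (p$ks_gly + glycerol_mM) *
    (1 - glycerol_mM / p$ki_gly)
  pmax(v, 0)
}

#' Acetate secretion ceiling (logistic in the glycerol uptake flux)
#'
#' `vinf*v0*exp(R*v) / (vinf + v0*(exp(R*v) - 1))`: rises from the basal
#' flux `v0_aa` at zero uptake toward the maximum `vinf_aa` as the glycerol
#' uptake flux grows.
#'
#' @param v_gly glycerol uptake flux in mmol/gDW/h (non-negative)
#' @param p a [kinetic_params()] object
#' @return upper bound of the acetate secretion flux (mmol/gDW/h)
#' @export
acetate_secretion_bound <- function(v_gly, p = kinetic_params()) {
  if (any(v_gly < 0)) stop("negative glycerol uptake flux")
  e <- exp(p$R_aa * v_gly)
  p$vinf_aa * p$v0_aa * e / (p$vinf_aa + p$v0_aa * (e - 1))
}

#' Objective weight by glycerol regime
#'
#' Returns the weight `w` of the instantaneous objective: 1 at glycerol
#' limitation (below the switch threshold) and 0.04 at glycerol excess (at
#' or above it).
#'
#' @param glycerol_gL extracellular glycerol in g/L
#' @param p a [kinetic_params()] object
#' @return objective weight (dimensionless)
#' @export
objective_weight <- function(glycerol_gL, p = kinetic_params()) {
  if (any(glycerol_gL < 0)) stop("negative glycerol concentration")
  ifelse(glycerol_gL >= p$switch_gly, 0.04, 1)
}

#' Death rate by glycerol regime
#'
#' `kd_lim` below the switch threshold, `kd_exc` at or above it (the same
#' boundary convention as [objective_weight()]).
#'
#' @inheritParams objective_weight
#' @return first-order death constant (1/h)
#' @export
death_rate <- function(glycerol_gL, p = kinetic_params()) {
  if (any(glycerol_gL < 0)) stop("negative glycerol concentration")
  ifelse(glycerol_gL >= p$switch_gly, p$kd_exc, p$kd_lim)
}

# regime label used in trajectories
.regime <- function(glycerol_gL, p) {
  ifelse(glycerol_gL >= p$switch_gly, "excess", "limitation")
}
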