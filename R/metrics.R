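# Performance metrics of a simulated culture.

#' Production metrics of a trajectory
#'
#' Final PDO titer, volumetric productivity `Q_PDO` (final PDO
#' concentration over the culture time), PDO-on-glycerol yields in mol/mol
#' and g/g (on consumed glycerol), the mass conversion on fed glycerol
#' (fed-batch), residual glycerol, and the culture time.  The culture time
#' is the first time glycerol falls below `exhaustion` (g/L), or the end of
#' the horizon if it never does.
#'
#' @param traj a `dfba_trajectory`
#' @param exhaustion glycerol level (g/L) counted as depletion
#' @return an object of class `dfba_metrics` (a named list)
#' @export
trajectory_metrics <- function(traj, exhaustion = 0.1) {
  stopifnot(inherits(traj, "dfba_trajectory"))
  s <- traj$states
  n <- nrow(s)
  V0 <- s$V[1]; Vf <- s$V[n]
  final_pdo <- s$pdo[n]

  idx <- which(s$glycerol < exhaustion)
  culture_time <- if (length(idx)) s$time[idx[1]] - s$time[1]
                  else s$time[n] - s$time[1]
  q_pdo <- if (culture_time > 0) final_pdo / culture_time else 0

  # glycerol mass balance (g): initial + fed = residual + consumed
  fed <- 0
  if (!is.null(traj$spec$feed)) {
    sf_gly <- traj$spec$feed$S_F["glycerol"]
    if (is.na(sf_gly)) sf_gly <- 0
    fed <- unname((Vf - V0) * sf_gly)
  }
  gly_consumed <- s$glycerol[1] * V0 + fed - s$glycerol[n] * Vf
  pdo_mass <- final_pdo * Vf - s$pdo[1] * V0

  if (gly_consumed <= 1e-9) {
    warning("no glycerol consumed; yields undefined")
    y_mass <- NA_real_; y_mol <- NA_real_
  } else {
    y_mass <- pdo_mass / gly_consumed
    y_mol <- (pdo_mass / .MM[["pdo"]]) / (gly_consumed / .MM[["glycerol"]])
  }
  conv_fed <- if (fed + s$glycerol[1] * V0 > 0)
    pdo_mass / (s$glycerol[1] * V0 + fed) else NA_real_

  structure(list(final_pdo = final_pdo, q_pdo = q_pdo,
                 yield_mol = y_mol, yield_mass = y_mass,
                 mass_conversion_fed = conv_fed,
                 residual_glycerol = s$glycerol[n],
                 culture_time = culture_time,
                 final_biomass = s$X[n], final_volume = Vf,
                 glycerol_fed = fed, glycerol_consumed = gly_consumed),
            class = "dfba_metrics")
}

#' @export
print.dfba_metrics <- function(x, ...) {
  cat(sprintf("  final PDO        %8.2f g/L\n", x$final_pdo))
  cat(sprintf("  Q_PDO            %8.3f g/L/h  (culture time %.1f h)\n",
              x$q_pdo, x$culture_time))
  cat(sprintf("  Y_PDO/S          %8.3f mol/mol (%.3f g/g)\n",
              x$yield_mol, x$yield_mass))
  if (!is.na(x$mass_conversion_fed))
    cat(sprintf("  mass conversion  %8.3f g/g fed\n", x$mass_conversion_fed))
  cat(sprintf("  residual glycerol %7.2f g/L; final biomass %.2f g/L\n",
              x$residual_glycerol, x$final_biomass))
  invisible(x)
}
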