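# Design-space scans of culture conditions: a batch factorial over initial
# biomass and glycerol, and fed-batch grids over feed glycerol content and
# the feeding constant (constant flow or pH-coupled), with the outcome
# classification used to select optima.

#' Batch factorial scan over initial conditions
#'
#' Simulates every combination of initial biomass and initial glycerol,
#' collects the production metrics, and marks the productivity optimum.
#'
#' @param X0_grid initial biomass levels (gDW/L); default 15 levels,
#'   0.01-0.15 (inoculum at exponential phase caps near 0.12)
#' @param glycerol_grid initial glycerol levels (g/L); default 13 levels,
#'   5-65
#' @param network,kinetics model components
#' @param tf horizon (h; long enough for exhaustion on the slowest grid
#'   point)
#' @param G grid intervals for the SOA integrator
#' @param approach solution approach (SOA default for speed)
#' @return an object of class `scan_result` whose `table` has one row per
#'   grid point (metrics + class)
#' @export
batch_factorial_scan <- function(X0_grid = seq(0.01, 0.15, length.out = 15),
                                 glycerol_grid = seq(5, 65, by = 5),
                                 network = reduced_network(),
                                 kinetics = kinetic_params(),
                                 tf = 120, G = 150, approach = "soa") {
  grid <- expand.grid(X0 = X0_grid, glycerol0 = glycerol_grid)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- tryCatch({
      sp <- dfba_spec(network = network, kinetics = kinetics,
                      glycerol0 = grid$glycerol0[i], X0 = grid$X0[i],
                      tf = tf, G = G, approach = approach)
      suppressWarnings(trajectory_metrics(dfba(sp)))
    }, error = function(e) NULL)
    rows[[i]] <- if (is.null(m)) {
      data.frame(final_pdo = NA_real_, q_pdo = NA_real_,
                 yield_mol = NA_real_, yield_mass = NA_real_,
                 residual_glycerol = NA_real_, culture_time = NA_real_)
    } else {
      data.frame(final_pdo = m$final_pdo, q_pdo = m$q_pdo,
                 yield_mol = m$yield_mol, yield_mass = m$yield_mass,
                 residual_glycerol = m$residual_glycerol,
                 culture_time = m$culture_time)
    }
  }
  tab <- cbind(grid, do.call(rbind, rows))
  tab$class <- ifelse(is.na(tab$final_pdo), "infeasible", "suboptimal")
  feas <- which(tab$class != "infeasible")
  if (length(feas)) {
    opt <- feas[which.max(tab$q_pdo[feas])]
    tab$class[opt] <- "optimal"
  }
  structure(list(table = tab, mode = "batch",
                 optimum = tab[tab$class == "optimal", , drop = FALSE]),
            class = "scan_result")
}

#' Classify a fed-batch outcome
#'
#' `infeasible` when the simulation failed, made (almost) no PDO, or - in
#' constant-feed mode - left more residual glycerol than allowed
#' (overfeeding or glycerol overload); `unconsumed_glycerol` when the
#' residual exceeds the limit in pH-coupled mode; otherwise `suboptimal`
#' (the scan later promotes the selected frontier point to `optimal`).
#'
#' @param metrics a [trajectory_metrics()] result or NULL (failed run)
#' @param mode `"constant"` or `"ph_coupled"`
#' @param constraints list with `min_conversion` (mass conversion on fed
#'   glycerol) and `max_residual` (g/L)
#' @return character class
#' @export
classify_fedbatch_outcome <- function(metrics, mode = "constant",
                                      constraints = list(min_conversion = 0.45,
                                                         max_residual = 5)) {
  if (is.null(metrics) || is.na(metrics$final_pdo) ||
      metrics$final_pdo < 0.5)
    return("infeasible")
  if (metrics$residual_glycerol > constraints$max_residual)
    return(if (mode == "ph_coupled") "unconsumed_glycerol" else "infeasible")
  "suboptimal"
}

#' Fed-batch design-space scan
#'
#' Simulates a grid of fed-batch cultures over the feed glycerol content
#' (mass %) and the feeding constant (`alpha` for constant flow, `beta`
#' for pH-coupled flow), classifies every point, and selects the optimum:
#' in constant mode the maximum-production point of the feasible frontier;
#' in pH-coupled mode the maximum-production point among cultures meeting
#' the selection constraints (mass conversion on fed glycerol >=
#' `min_conversion`, residual glycerol <= `max_residual`).
#'
#' @param mode `"constant"` or `"ph_coupled"`
#' @param pct_grid feed glycerol mass percentages (default 5-30 %)
#' @param rate_grid feeding constants: L/h (`alpha`) or L/mmol (`beta`);
#'   log-spaced defaults bracketing the under- and over-feeding regimes
#' @param glycerol0,X0,V0,tf base culture (defaults: the batch optimum
#'   initial state, 1 L in a 1.5 L reactor, 72 h horizon)
#' @param V_max reactor capacity (L)
#' @param network,kinetics model components
#' @param G grid intervals for the SOA integrator
#' @param constraints selection constraints, see
#'   [classify_fedbatch_outcome()]
#' @return a `scan_result` with per-point metrics and classes
#' @export
fedbatch_scan <- function(mode = c("constant", "ph_coupled"),
                          pct_grid = seq(5, 30, by = 5),
                          rate_grid = NULL,
                          glycerol0 = 46, X0 = 0.12, V0 = 1, V_max = 1.5,
                          tf = 72, network = reduced_network(),
                          kinetics = kinetic_params(), G = 240,
                          constraints = list(min_conversion = 0.45,
                                             max_residual = 5)) {
  mode <- match.arg(mode)
  if (is.null(rate_grid))
    rate_grid <- if (mode == "constant")
      exp(seq(log(0.003), log(0.03), length.out = 9))
    else exp(seq(log(1e-4), log(3e-3), length.out = 9))
  grid <- expand.grid(rate = rate_grid, pct = pct_grid)
  rows <- vector("list", nrow(grid))
  classes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    feed <- if (mode == "constant")
      feed_policy("constant", alpha = grid$rate[i],
                  glycerol_pct = grid$pct[i], V_max = V_max)
    else
      feed_policy("ph_coupled", beta = grid$rate[i],
                  glycerol_pct = grid$pct[i], V_max = V_max)
    m <- tryCatch({
      sp <- dfba_spec(network = network, kinetics = kinetics,
                      glycerol0 = glycerol0, X0 = X0, tf = tf, G = G,
                      approach = "soa", feed = feed, V0 = V0)
      suppressWarnings(trajectory_metrics(dfba(sp)))
    }, error = function(e) NULL)
    classes[i] <- classify_fedbatch_outcome(m, mode, constraints)
    rows[[i]] <- data.frame(
      final_pdo = if (is.null(m)) NA_real_ else m$final_pdo,
      q_pdo = if (is.null(m)) NA_real_ else m$q_pdo,
      yield_mol = if (is.null(m)) NA_real_ else m$yield_mol,
      yield_mass = if (is.null(m)) NA_real_ else m$yield_mass,
      mass_conversion_fed = if (is.null(m)) NA_real_
                            else m$mass_conversion_fed,
      residual_glycerol = if (is.null(m)) NA_real_
                          else m$residual_glycerol,
      culture_time = if (is.null(m)) NA_real_ else m$culture_time)
  }
  tab <- cbind(grid, do.call(rbind, rows))
  tab$class <- classes
  cand <- which(tab$class == "suboptimal")
  if (mode == "ph_coupled")
    cand <- cand[!is.na(tab$mass_conversion_fed[cand]) &
                   tab$mass_conversion_fed[cand] >= constraints$min_conversion]
  if (length(cand)) {
    opt <- cand[which.max(tab$final_pdo[cand])]
    tab$class[opt] <- "optimal"
  }
  structure(list(table = tab, mode = mode,
                 optimum = tab[tab$class == "optimal", , drop = FALSE]),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Design-space scan (%s): %d grid points\n", x$mode,
              nrow(x$table)))
  print(table(x$table$class))
  if (nrow(x$optimum)) {
    cat("optimum:\n")
    print(x$optimum, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.scan_result <- function(x, metric = "q_pdo", ...) {
  tab <- x$table
  ax <- setdiff(names(tab), c("final_pdo", "q_pdo", "yield_mol",
                              "yield_mass", "mass_conversion_fed",
                              "residual_glycerol", "culture_time",
                              "class"))
  cols <- c(infeasible = "#d73027", suboptimal = "#4575b4",
            unconsumed_glycerol = "#fee090", optimal = "#1a9850")
  graphics::plot(tab[[ax[1]]], tab[[ax[2]]],
                 cex = 0.5 + 2 * tab[[metric]] / max(tab[[metric]],
                                                     na.rm = TRUE),
                 pch = 19, col = cols[tab$class],
                 xlab = ax[1], ylab = ax[2],
                 log = if (x$mode == "batch") "" else "x", ...)
  graphics::legend("topright", names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}
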