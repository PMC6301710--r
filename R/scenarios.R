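# Bundled culture scenarios used throughout the package: the conditions of
# the reference fermentation campaign (two glycerol-limited, two
# glycerol-excess) and the base culture for the design-space scans.

#' Bundled culture scenarios
#'
#' Returns the specification of a named bundled scenario:
#' * `"batch_limited"` - glycerol-limited batch (10 g/L glycerol,
#'   0.1 g/L inoculum, 12 h): stays in the limitation regime throughout,
#'   so all three solution approaches (including DOA) apply;
#' * `"batch_limited2"` - second limited culture (13 g/L, 0.08 g/L, 16 h);
#' * `"batch_excess"` - first glycerol-excess batch (40 g/L, 0.1 g/L,
#'   28 h, covering glycerol exhaustion with margin): crosses the 15 g/L
#'   switch late in the run; reference culture for the sensitivity
#'   analyses and the population balance model;
#' * `"batch_excess2"` - second excess culture (30 g/L, 0.12 g/L, 20 h);
#' * `"batch_optimum"` - the scan optimum (46 g/L, 0.12 g/L, 40 h).
#'
#' @param name scenario name
#' @param network,kinetics model components (bundled defaults if omitted)
#' @param approach solution approach
#' @param G number of grid intervals
#' @return a [dfba_spec()]
#' @export
scenario <- function(name = c("batch_limited", "batch_limited2",
                              "batch_excess", "batch_excess2",
                              "batch_optimum"),
                     network = reduced_network(),
                     kinetics = kinetic_params(),
                     approach = "da", G = 100) {
  name <- match.arg(name)
  par <- switch(name,
    batch_limited  = list(gly = 10, X0 = 0.10, tf = 12),
    batch_limited2 = list(gly = 13, X0 = 0.08, tf = 16),
    batch_excess   = list(gly = 40, X0 = 0.10, tf = 28),
    batch_excess2  = list(gly = 30, X0 = 0.12, tf = 20),
    batch_optimum  = list(gly = 46, X0 = 0.12, tf = 40))
  dfba_spec(network = network, kinetics = kinetics, glycerol0 = par$gly,
            X0 = par$X0, tf = par$tf, G = G, approach = approach)
}
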