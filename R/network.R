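# The reduced stoichiometric model of anaerobic glycerol metabolism:
# a reductive branch (glycerol -> 3-HPA -> PDO, 1 NADH per PDO), an
# oxidative branch (glycerol -> DHAP -> PEP -> pyruvate, net +1 ATP and
# +2 NADH), pyruvate:ferredoxin oxidoreductase feeding acetate, butyrate,
# ethanol and butanol branches, lactate, hydrogenase/NADH:ferredoxin
# oxidoreductase, and a lumped biomass reaction parameterized by the
# biomass composition.

.FLUX_SENTINEL <- 1000  # mmol/gDW/h for otherwise unbounded reactions

#' Build the bundled reduced metabolic network
#'
#' Constructs the lumped anaerobic glycerol network of *Clostridium
#' butyricum*: glycerol enters through a single exchange; the reductive
#' branch converts glycerol and one NADH to 1,3-propanediol; the oxidative
#' branch converts glycerol to pyruvate with a net gain of one ATP and two
#' NADH; pyruvate is split by pyruvate:ferredoxin oxidoreductase into
#' acetyl-CoA, CO2 and reduced ferredoxin, which is disposed of as H2 or
#' recycled to NADH; acetyl-CoA leaves as acetate (+1 ATP), butyrate
#' (+1 ATP per two acetyl-CoA, consuming two NADH), ethanol or butanol;
#' pyruvate can also leave as lactate.  NADH, ATP, reduced ferredoxin and
#' CoA are balanced intracellular carriers (CoA carries no carbon in the
#' bookkeeping; acetyl-CoA counts its two acetyl carbons).
#'
#' @param composition a [biomass_composition()] object parameterizing the
#'   lumped biomass reaction (default composition if omitted)
#' @param ngam non-growth-associated maintenance ATP demand
#'   (mmol/gDW/h), the lower bound of the ATP hydrolysis reaction; 0 by
#'   default
#' @return an object of class `metabolic_network`
#' @export
reduced_network <- function(composition = biomass_composition(), ngam = 0) {
  mets <- data.frame(
    id = c("glyc_c", "pyr_c", "accoa_c", "coa_c", "nadh_c", "fdred_c",
           "atp_c",
           "glyc_e", "pdo_e", "ac_e", "but_e", "lac_e", "eth_e", "buoh_e",
           "h2_e", "co2_e", "biomass_e"),
    compartment = c(rep("c", 7), rep("e", 10)),
    molar_mass = c(92.09, 88.06, 43.04, 0, 0, 0, 0,
                   .MM[["glycerol"]], .MM[["pdo"]], .MM[["acetate"]],
                   .MM[["butyrate"]], .MM[["lactate"]], .MM[["ethanol"]],
                   .MM[["butanol"]], .MM[["h2"]], .MM[["co2"]], 1000),
    carbon = c(3, 3, 2, 0, 0, 0, 0, 3, 3, 2, 4, 3, 2, 4, 0, 1, NA),
    stringsAsFactors = FALSE)

  d <- .biomass_drains(composition)
  mw <- biomass_molecular_weight(composition)
  mets$molar_mass[mets$id == "biomass_e"] <- mw * 1000  # g/mol
  mets$carbon[mets$id == "biomass_e"] <- d$carbon

  rx <- list(
    GLYt   = c(glyc_e = -1, glyc_c = 1),
    PDOR   = c(glyc_c = -1, nadh_c = -1, pdo_e = 1),
    GLYOX  = c(glyc_c = -1, pyr_c = 1, nadh_c = 2, atp_c = 1),
    PFOR   = c(pyr_c = -1, coa_c = -1, accoa_c = 1, fdred_c = 1, co2_e = 1),
    HYD    = c(fdred_c = -1, h2_e = 1),
    NFOR   = c(fdred_c = -1, nadh_c = 1),
    ACK    = c(accoa_c = -1, coa_c = 1, ac_e = 1, atp_c = 1),
    BUK    = c(accoa_c = -2, nadh_c = -2, coa_c = 2, but_e = 1, atp_c = 1),
    LDH    = c(pyr_c = -1, nadh_c = -1, lac_e = 1),
    ETOH   = c(accoa_c = -1, nadh_c = -2, coa_c = 1, eth_e = 1),
    BUOH   = c(accoa_c = -2, nadh_c = -4, coa_c = 2, buoh_e = 1),
    BIOMASS = c(pyr_c = -d$pyr, accoa_c = -d$accoa, coa_c = d$accoa,
                atp_c = -d$atp, nadh_c = -d$nadh, biomass_e = 1),
    ATPM   = c(atp_c = -1),
    EX_glyc = c(glyc_e = -1),
    EX_pdo  = c(pdo_e = -1),
    EX_ac   = c(ac_e = -1),
    EX_but  = c(but_e = -1),
    EX_lac  = c(lac_e = -1),
    EX_eth  = c(eth_e = -1),
    EX_buoh = c(buoh_e = -1),
    EX_h2   = c(h2_e = -1),
    EX_co2  = c(co2_e = -1),
    EX_biomass = c(biomass_e = -1))

  S <- matrix(0, nrow(mets), length(rx),
              dimnames = list(mets$id, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]]), j] <- rx[[j]]

  rxns <- data.frame(
    id = names(rx),
    lb = c(rep(0, 13), -.FLUX_SENTINEL, rep(0, 9)),
    ub = .FLUX_SENTINEL,
    is_exchange = grepl("^EX_", names(rx)),
    atp_production = 0,
    stringsAsFactors = FALSE)
  rxns$lb[rxns$id == "ATPM"] <- ngam
  rxns$ub[rxns$id == "EX_glyc"] <- 0  # uptake only
  # capacity caps on minor fermentation routes: lactate, ethanol and
  # butanol are trace products of C. butyricum glycerol fermentations,
  # so their lumped dehydrogenase capacities are bounded at the scale
  # observed experimentally rather than left at the sentinel
  rxns$ub[rxns$id == "LDH"] <- 0.5
  rxns$ub[rxns$id == "ETOH"] <- 1
  rxns$ub[rxns$id == "BUOH"] <- 0.5
  # butyrate-branch capacity: thiolase activity does not rise with glycerol
  # uptake, capping the butyrate route at the observed secretion scale
  rxns$ub[rxns$id == "BUK"] <- 3
  # v_ATPprod: the regulable substrate-level phosphorylation steps
  # (acid-forming kinases); the glycolytic ATP of the oxidative lump is
  # stoichiometrically tied to carbon oxidation and not counted
  rxns$atp_production[rxns$id %in% c("ACK", "BUK")] <- 1

  net <- structure(list(
    S = S, mets = mets, rxns = rxns,
    biomass_id = "BIOMASS",
    composition = composition,
    ngam = ngam,
    atp_flux_ids = c("ACK", "BUK"),
    exchange_map = c(glyc_e = "EX_glyc", pdo_e = "EX_pdo", ac_e = "EX_ac",
                     but_e = "EX_but", lac_e = "EX_lac", eth_e = "EX_eth",
                     buoh_e = "EX_buoh", h2_e = "EX_h2", co2_e = "EX_co2",
                     biomass_e = "EX_biomass")),
    class = "metabolic_network")
  qr_t <- qr(t(S))
  net$S_rank_rows <- sort(qr_t$pivot[seq_len(qr_t$rank)])
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks dimensional consistency of the stoichiometric matrix, bound
#' ordering, that every intracellular metabolite takes part in at least one
#' reaction (no orphan rows), that every extracellular metabolite has
#' exactly one exchange reaction, and that the biomass reaction exists.
#'
#' @param net a `metabolic_network`
#' @return the network, invisibly usable in a pipeline; errors on violation
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!identical(dim(net$S), c(nrow(net$mets), nrow(net$rxns))))
    stop("stoichiometric matrix dimensions inconsistent")
  if (any(net$rxns$lb > net$rxns$ub)) stop("lower bound exceeds upper bound")
  orphan <- rowSums(net$S != 0) == 0
  if (any(orphan))
    stop("orphan metabolite: ", paste(net$mets$id[orphan], collapse = ", "))
  if (!(net$biomass_id %in% net$rxns$id)) stop("missing biomass reaction")
  ex_mets <- net$mets$id[net$mets$compartment == "e"]
  for (m in ex_mets) {
    n_ex <- sum(net$S[m, net$rxns$is_exchange] != 0)
    if (n_ex != 1L)
      stop("extracellular metabolite ", m, " has ", n_ex,
           " exchange reactions (expected exactly 1)")
  }
  net
}

#' Replace the biomass composition of a network
#'
#' Rebuilds the lumped biomass reaction from a new composition; the rest of
#' the network is unchanged.
#'
#' @param net a `metabolic_network`
#' @param composition a [biomass_composition()] object
#' @return the updated network
#' @export
set_biomass_composition <- function(net, composition) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(composition, "biomass_composition"))
  if (any(composition$precursor_coeffs < 0))
    stop("negative precursor coefficient")
  d <- .biomass_drains(composition)
  S <- net$S
  S[, net$biomass_id] <- 0
  S[c("pyr_c", "accoa_c", "coa_c", "atp_c", "nadh_c", "biomass_e"),
    net$biomass_id] <- c(-d$pyr, -d$accoa, d$accoa, -d$atp, -d$nadh, 1)
  net$S <- S
  net$composition <- composition
  mw <- biomass_molecular_weight(composition)
  net$mets$molar_mass[net$mets$id == "biomass_e"] <- mw * 1000
  net$mets$carbon[net$mets$id == "biomass_e"] <- d$carbon
  net
}

# index helpers
.rxn_idx <- function(net, id) match(id, net$rxns$id)

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("Reduced metabolic network: %d metabolites (%d intracellular), %d reactions (%d exchanges)\n",
              nrow(x$mets), sum(x$mets$compartment == "c"),
              nrow(x$rxns), sum(x$rxns$is_exchange)))
  cat(sprintf("Biomass reaction '%s'; biomass MW %.4f g/mmol; NGAM %.3g mmol/gDW/h\n",
              x$biomass_id,
              x$mets$molar_mass[x$mets$id == "biomass_e"] / 1000, x$ngam))
  invisible(x)
}
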