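# Reading and writing metabolic networks: a versioned JSON serialization
# of the bundled reduced network, and an import hook for SBML Level 3
# models carrying the flux-balance (fbc) package.

#' Write a network to JSON
#'
#' Serializes metabolites (with compartments, molar masses and carbon
#' counts), reactions (stoichiometry, bounds, ATP-production weights), the
#' biomass reaction id and the biomass composition block.
#'
#' @param net a `metabolic_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  rx <- lapply(seq_len(nrow(net$rxns)), function(j) {
    sto <- net$S[, j]
    sto <- sto[sto != 0]
    list(id = net$rxns$id[j], stoichiometry = as.list(sto),
         lower_bound = net$rxns$lb[j], upper_bound = net$rxns$ub[j],
         atp_production = net$rxns$atp_production[j])
  })
  comp <- net$composition
  obj <- list(
    format = "reduced-network/1",
    biomass_reaction = net$biomass_id,
    ngam = net$ngam,
    metabolites = net$mets,
    reactions = rx,
    composition = list(precursor_coeffs = as.list(comp$precursor_coeffs),
                       macro_fractions = as.list(comp$macro_fractions),
                       gam = comp$gam))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Load a metabolic network
#'
#' Reads a network from the package's JSON serialization or imports an
#' SBML Level 3 file with the fbc package (species, reactions,
#' stoichiometry, flux bounds and the active objective).  Unbounded fluxes
#' are mapped to the +-1000 mmol/gDW/h sentinel.  The returned network is
#' validated: missing biomass reactions, orphan intracellular metabolites
#' and inconsistent stoichiometry are errors.
#'
#' @param path file path
#' @param format `"json"` or `"sbml"` (guessed from the extension by
#'   default)
#' @return a `metabolic_network`
#' @export
load_network <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") .load_network_json(path) else .load_network_sbml(path)
}

.load_network_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure: ",
                                           conditionMessage(e)))
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment,
               molar_mass = as.numeric(m$molar_mass),
               carbon = as.numeric(m$carbon))))
  rx_ids <- vapply(obj$reactions, function(r) r$id, "")
  S <- matrix(0, nrow(mets), length(rx_ids),
              dimnames = list(mets$id, rx_ids))
  for (r in obj$reactions)
    for (m in names(r$stoichiometry))
      S[m, r$id] <- as.numeric(r$stoichiometry[[m]])
  sent <- .FLUX_SENTINEL
  rxns <- do.call(rbind, lapply(obj$reactions, function(r)
    data.frame(id = r$id,
               lb = max(as.numeric(r$lower_bound), -sent),
               ub = min(as.numeric(r$upper_bound), sent),
               is_exchange = grepl("^EX_", r$id),
               atp_production = as.numeric(r$atp_production %||% 0))))
  comp <- if (!is.null(obj$composition)) {
    biomass_composition(
      precursor_coeffs = unlist(obj$composition$precursor_coeffs),
      macro_fractions = unlist(obj$composition$macro_fractions),
      gam = obj$composition$gam)
  } else biomass_composition()
  ex_mets <- mets$id[mets$compartment == "e"]
  ex_map <- vapply(ex_mets, function(m) {
    j <- which(S[m, ] != 0 & rxns$is_exchange)
    if (length(j) != 1)
      stop("extracellular metabolite ", m, " needs exactly one exchange")
    rxns$id[j]
  }, "")
  net <- structure(list(S = S, mets = mets, rxns = rxns,
                        biomass_id = obj$biomass_reaction,
                        composition = comp,
                        ngam = obj$ngam %||% 0,
                        atp_flux_ids =
                          rxns$id[rxns$atp_production > 0],
                        exchange_map = ex_map),
                   class = "metabolic_network")
  qr_t <- qr(t(S))
  net$S_rank_rows <- sort(qr_t$pivot[seq_len(qr_t$rank)])
  validate_network(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal SBML L3 + fbc reader
.load_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("no species found (is this SBML Level 3?)")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = ifelse(grepl("_e$|ext", xml2::xml_attr(sp, "compartment")),
                         "e", "c"),
    molar_mass = 0, carbon = 0)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- mets[!boundary, ]

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rs <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rs)) stop("no reactions found")
  rx_ids <- xml2::xml_attr(rs, "id")
  S <- matrix(0, nrow(mets), length(rx_ids),
              dimnames = list(mets$id, rx_ids))
  sent <- .FLUX_SENTINEL
  lb <- numeric(length(rs)); ub <- numeric(length(rs))
  for (j in seq_along(rs)) {
    r <- rs[[j]]
    for (sr in xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)) {
      m <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (m %in% rownames(S)) S[m, j] <- S[m, j] - st
    }
    for (sr in xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)) {
      m <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (m %in% rownames(S)) S[m, j] <- S[m, j] + st
    }
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    rev <- xml2::xml_attr(r, "reversible") %in% "true"
    lb[j] <- if (!is.na(lbid) && lbid %in% names(pval))
      max(pval[[lbid]], -sent) else if (rev) -sent else 0
    ub[j] <- if (!is.na(ubid) && ubid %in% names(pval))
      min(pval[[ubid]], sent) else sent
  }
  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  biomass_id <- if (!inherits(obj_ref, "xml_missing"))
    xml2::xml_attr(obj_ref, "reaction")
  else rx_ids[grepl("biomass", rx_ids, ignore.case = TRUE)][1]
  if (is.na(biomass_id) || is.null(biomass_id) || !length(biomass_id))
    stop("missing biomass reaction (no fbc objective, no 'biomass' id)")

  is_ex <- colSums(S != 0) == 1 &
    colSums(S[mets$compartment == "e", , drop = FALSE] != 0) == 1
  rxns <- data.frame(id = rx_ids, lb = lb, ub = ub, is_exchange = is_ex,
                     atp_production = 0)
  ex_mets <- mets$id[mets$compartment == "e"]
  ex_map <- vapply(ex_mets, function(m) {
    j <- which(S[m, ] != 0 & is_ex)
    if (length(j) != 1)
      stop("extracellular metabolite ", m, " needs exactly one exchange")
    rx_ids[j]
  }, "")
  net <- structure(list(S = S, mets = mets, rxns = rxns,
                        biomass_id = biomass_id,
                        composition = biomass_composition(), ngam = 0,
                        atp_flux_ids = character(0),
                        exchange_map = ex_map),
                   class = "metabolic_network")
  qr_t <- qr(t(S))
  net$S_rank_rows <- sort(qr_t$pivot[seq_len(qr_t$rank)])
  validate_network(net)
}

#' Write a trajectory to CSV files
#'
#' Writes the tidy culture-state table (time, volume, biomass, one column
#' per medium species, growth rate, regime) and a long-format flux table
#' keyed by time and reaction.
#'
#' @param traj a `dfba_trajectory`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return paths of the written files, invisibly
#' @export
write_trajectory <- function(traj, dir, prefix = "trajectory") {
  stopifnot(inherits(traj, "dfba_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, paste0(prefix, "_states.csv"))
  utils::write.csv(traj$states, f1, row.names = FALSE)
  fx <- data.frame(time = rep(traj$states$time, ncol(traj$fluxes)),
                   reaction = rep(colnames(traj$fluxes),
                                  each = nrow(traj$fluxes)),
                   flux = as.vector(traj$fluxes))
  f2 <- file.path(dir, paste0(prefix, "_fluxes.csv"))
  utils::write.csv(fx, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
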