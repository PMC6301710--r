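# Biomass composition: 44 precursors grouped into macromolecule classes,
# plus three polymeric macromolecules without explicit precursors
# (carbohydrate, peptidoglycan, teichoic acid).  The composition
# parameterizes the lumped biomass reaction of the reduced network.

# Precursor table.  molfrac is the molar share within the macromolecule
# class; molar_mass in g/mol; carbon = atoms per molecule.  atp/nadh are
# lumped synthesis plus polymerization costs (mmol per mmol precursor).
.precursor_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- .build_precursor_table()
    cache
  }
})

.build_precursor_table <- function() {
  aa <- data.frame(
    id = c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his",
           "ile", "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp",
           "tyr", "val"),
    class = "amino_acid", macromolecule = "protein",
    molar_mass = c(89.09, 174.20, 132.12, 133.10, 121.16, 146.15, 147.13,
                   75.07, 155.15, 131.17, 131.17, 146.19, 149.21, 165.19,
                   115.13, 105.09, 119.12, 204.23, 181.19, 117.15),
    carbon = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
    molfrac = c(0.109, 0.041, 0.041, 0.041, 0.013, 0.037, 0.037, 0.109,
                0.013, 0.051, 0.079, 0.061, 0.022, 0.033, 0.039, 0.038,
                0.045, 0.010, 0.024, 0.075),
    atp = 4.3, nadh = 0.5, route = "pyr",
    stringsAsFactors = FALSE)
  rna <- data.frame(
    id = c("amp", "gmp", "cmp", "ump"),
    class = "nucleotide", macromolecule = "rna",
    molar_mass = c(347.22, 363.22, 323.20, 324.18),
    carbon = c(10, 10, 9, 9),
    molfrac = c(0.26, 0.32, 0.20, 0.22),
    atp = 9.2, nadh = 1.5, route = "pyr",
    stringsAsFactors = FALSE)
  dna <- data.frame(
    id = c("damp", "dtmp", "dgmp", "dcmp"),
    class = "nucleotide", macromolecule = "dna",
    molar_mass = c(331.22, 322.21, 347.22, 307.20),
    carbon = c(10, 10, 10, 9),
    molfrac = c(0.36, 0.36, 0.14, 0.14),
    atp = 10.2, nadh = 2.0, route = "pyr",
    stringsAsFactors = FALSE)
  # fatty acids and polar lipids together make up the lipid fraction;
  # molfracs chosen so the acyl pool is about 60 % of lipid mass
  fa <- data.frame(
    id = c("fa120", "fa140", "fa160", "fa161", "fa180", "fa181", "fa17cyc"),
    class = "fatty_acid", macromolecule = "lipid",
    molar_mass = c(200.32, 228.37, 256.42, 254.41, 284.48, 282.46, 268.43),
    carbon = c(12, 14, 16, 16, 18, 18, 17),
    molfrac = 0.83 * c(0.05, 0.10, 0.30, 0.15, 0.10, 0.25, 0.05),
    atp = c(6, 7, 8, 8, 9, 9, 9), nadh = c(10, 12, 14, 13, 16, 15, 14),
    route = "accoa", stringsAsFactors = FALSE)
  pl <- data.frame(
    id = c("pe", "pg", "clpn"),
    class = "polar_lipid", macromolecule = "lipid",
    molar_mass = c(715.9, 748.9, 1403.0),
    carbon = c(39, 40, 77),
    molfrac = 0.17 * c(0.45, 0.35, 0.20),
    atp = c(20, 20, 38), nadh = c(28, 29, 56), route = "accoa",
    stringsAsFactors = FALSE)
  cof <- data.frame(
    id = c("nad", "nadp", "fad", "coenzA", "sam", "tpp"),
    class = "cofactor", macromolecule = "trace",
    molar_mass = c(663.43, 743.41, 785.55, 767.53, 398.44, 425.31),
    carbon = c(21, 21, 27, 21, 15, 12),
    molfrac = c(0.30, 0.15, 0.15, 0.20, 0.10, 0.10),
    atp = 25, nadh = 2, route = "pyr",
    stringsAsFactors = FALSE)
  rbind(aa, rna, dna, fa, pl, cof)
}

# polymeric macromolecules that carry mass without an explicit precursor
.polymer_table <- function() {
  data.frame(
    id = c("carbohydrate", "peptidoglycan", "teichoic"),
    molar_mass = c(162.14, 980.0, 154.10),
    carbon = c(6, 38, 3),
    atp = c(2.1, 15, 4), nadh = c(0, 1, 0), route = "pyr",
    stringsAsFactors = FALSE)
}

.default_macro_fractions <- function() {
  c(protein = 0.520, rna = 0.160, dna = 0.030, lipid = 0.076,
    teichoic = 0.030, peptidoglycan = 0.080, carbohydrate = 0.090,
    trace = 0.014)
}

# Split the carbon of a precursor exactly into pyruvate (3 C) and
# acetyl-CoA (2 C) units so that every biomass drain conserves carbon.
.carbon_split <- function(n, route) {
  if (route == "accoa") {
    if (n %% 2 == 0) c(pyr = 0, accoa = n / 2)
    else c(pyr = 1, accoa = (n - 3) / 2)
  } else {
    r <- n %% 3
    if (r == 0) c(pyr = n / 3, accoa = 0)
    else if (r == 1) c(pyr = (n - 4) / 3, accoa = 2)
    else c(pyr = (n - 2) / 3, accoa = 1)
  }
}

#' Biomass composition of the reduced model
#'
#' Builds the biomass composition object: 44 precursor coefficients (7 fatty
#' acids, 20 amino acids, 8 nucleotides, 3 polar lipids, 6 cofactors; in
#' mmol/gDW) and 8 macromolecule mass fractions (protein, RNA, DNA, lipid,
#' teichoic acid, peptidoglycan, carbohydrate, trace pool).  At the default
#' composition the macromolecule fractions sum to one and the biomass
#' molecular weight is exactly 1 g/mmol (the usual FBA normalization).
#'
#' Sampled or user-supplied macromolecule fractions are renormalized to sum
#' to one when the composition is applied to a network (mass fractions of a
#' gram of cells cannot do otherwise); precursor coefficients perturb the
#' within-class make-up freely.
#'
#' @param precursor_coeffs optional named vector of 44 precursor
#'   coefficients (mmol/gDW) overriding the defaults
#' @param macro_fractions optional named vector of 8 macromolecule mass
#'   fractions
#' @param gam growth-associated maintenance ATP (mmol ATP/gDW) added to the
#'   precursor synthesis costs in the lumped biomass reaction
#' @return an object of class `biomass_composition`
#' @export
biomass_composition <- function(precursor_coeffs = NULL,
                                macro_fractions = NULL, gam = 85) {
  tab <- .precursor_table()
  pol <- .polymer_table()
  fr <- .default_macro_fractions()
  # default coefficient: class mass fraction split by molar shares
  coeff <- numeric(nrow(tab))
  for (g in unique(tab$macromolecule)) {
    i <- tab$macromolecule == g
    mf <- tab$molfrac[i] / sum(tab$molfrac[i])
    coeff[i] <- fr[[g]] * mf / sum(mf * tab$molar_mass[i]) * 1000
  }
  names(coeff) <- tab$id
  pol_coeff <- fr[pol$id] * 1000 / pol$molar_mass
  names(pol_coeff) <- pol$id

  if (!is.null(precursor_coeffs)) {
    if (any(precursor_coeffs < 0)) stop("negative precursor coefficient")
    miss <- setdiff(names(precursor_coeffs), names(coeff))
    if (length(miss)) stop("unknown precursors: ", paste(miss, collapse = ", "))
    coeff[names(precursor_coeffs)] <- precursor_coeffs
  }
  if (!is.null(macro_fractions)) {
    if (any(macro_fractions < 0)) stop("negative macromolecule fraction")
    miss <- setdiff(names(macro_fractions), names(fr))
    if (length(miss)) stop("unknown macromolecules: ", paste(miss, collapse = ", "))
    fr[names(macro_fractions)] <- macro_fractions
  }

  structure(list(precursors = tab, precursor_coeffs = coeff,
                 polymers = pol, polymer_coeffs = pol_coeff,
                 macro_fractions = fr, gam = gam),
            class = "biomass_composition")
}

# Effective coefficients after applying (renormalized) macromolecule
# fractions as class-level scalings relative to the default fractions.
.effective_coeffs <- function(comp) {
  fr <- comp$macro_fractions / sum(comp$macro_fractions)
  fr0 <- .default_macro_fractions()
  scal <- fr / fr0[names(fr)]
  pre <- comp$precursor_coeffs * scal[comp$precursors$macromolecule]
  pol <- comp$polymer_coeffs * scal[c("carbohydrate", "peptidoglycan", "teichoic")]
  list(pre = as.numeric(pre), pol = as.numeric(pol), fr = fr)
}

#' Biomass molecular weight
#'
#' Mass-weighted sum of the (effective) precursor and polymer coefficients,
#' in g/mmol.  Equals 1.000 for the unperturbed default composition.
#'
#' @param composition a [biomass_composition()] object
#' @return biomass molecular weight in g/mmol
#' @export
biomass_molecular_weight <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  eff <- .effective_coeffs(composition)
  mw <- sum(eff$pre * composition$precursors$molar_mass / 1000) +
    sum(eff$pol * composition$polymers$molar_mass / 1000)
  if (mw == 0) warning("all-zero biomass composition")
  mw
}

# Aggregate drains of the lumped biomass reaction (per gDW): pyruvate,
# acetyl-CoA, ATP, NADH and total carbon.
.biomass_drains <- function(comp) {
  eff <- .effective_coeffs(comp)
  tabs <- rbind(
    data.frame(coeff = eff$pre, carbon = comp$precursors$carbon,
               route = comp$precursors$route, atp = comp$precursors$atp,
               nadh = comp$precursors$nadh),
    data.frame(coeff = eff$pol, carbon = comp$polymers$carbon,
               route = comp$polymers$route, atp = comp$polymers$atp,
               nadh = comp$polymers$nadh))
  sp <- t(mapply(.carbon_split, tabs$carbon, tabs$route))
  list(pyr = sum(tabs$coeff * sp[, "pyr"]),
       accoa = sum(tabs$coeff * sp[, "accoa"]),
       atp = sum(tabs$coeff * tabs$atp) + comp$gam,
       nadh = sum(tabs$coeff * tabs$nadh),
       carbon = sum(tabs$coeff * tabs$carbon))
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("Biomass composition: 44 precursors + 3 polymeric macromolecules\n")
  fr <- x$macro_fractions / sum(x$macro_fractions)
  cat("Macromolecule mass fractions:\n")
  print(round(fr, 4))
  cat(sprintf("Biomass molecular weight: %.4f g/mmol\n",
              biomass_molecular_weight(x)))
  d <- .biomass_drains(x)
  cat(sprintf("Drains per gDW: %.2f pyr, %.2f acCoA, %.1f ATP, %.1f NADH, %.1f mmol C\n",
              d$pyr, d$accoa, d$atp, d$nadh, d$carbon))
  invisible(x)
}
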