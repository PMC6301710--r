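# Internal helpers: unit conversions and small utilities.
# All unit conversions are centralized here.

# molar masses in g/mol of the species handled in the medium
.MM <- c(glycerol = 92.09, pdo = 76.09, acetate = 60.05, butyrate = 88.11,
         lactate = 90.08, ethanol = 46.07, butanol = 74.12, h2 = 2.016,
         co2 = 44.01)

#' Convert glycerol between g/L and mM
#'
#' The uptake kinetics are parameterized in mM (as the affinity and
#' inhibition constants are reported), while culture concentrations are
#' carried in g/L; these two helpers are the single point of conversion.
#'
#' @param x concentration (g/L for `gl_to_mM`, mM for `mM_to_gl`)
#' @param molar_mass molar mass in g/mol (default glycerol, 92.09)
#' @return the converted concentration
#' @export
gl_to_mM <- function(x, molar_mass = 92.09) x * 1000 / molar_mass

#' @rdname gl_to_mM
#' @export
mM_to_gl <- function(x, molar_mass = 92.09) x * molar_mass / 1000

# positive scalar check
.chk_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("'%s' must be a %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

# derive a stream-specific RNG seed from a base seed, kept below 2^31
.sub_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483587L
}
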