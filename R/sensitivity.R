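# Global sensitivity analysis of the dynamic model: Monte-Carlo parameter
# ensembles over the 60 input parameters (44 biomass precursors, 8
# macromolecule fractions, 3 acetate-secretion constants, 2 death
# constants, 3 glycerol-uptake constants), classified by mean squared
# error against a reference culture (MPSA, Kolmogorov-Smirnov statistic)
# and correlated by partial rank correlation coefficients (PRCC).

#' Parameter groups of the dynamic model
#'
#' @return named list of parameter-name vectors: `precursors44`,
#'   `macromolecules8`, `acetate3`, `death2`, `glycerol3`, and the
#'   combined `all57` (everything except the glycerol uptake kinetics)
#' @export
parameter_groups <- function() {
  pre <- .precursor_table()$id
  mac <- paste0("frac_", names(.default_macro_fractions()))
  ace <- c("v0_aa", "vinf_aa", "R_aa")
  dth <- c("kd_lim", "kd_exc")
  gly <- c("vmax_gly", "ks_gly", "ki_gly")
  list(precursors44 = pre, macromolecules8 = mac, acetate3 = ace,
       death2 = dth, glycerol3 = gly, all57 = c(pre, mac, dth, ace))
}

#' Base values of the 60 input parameters
#'
#' @param network a `metabolic_network` (for the biomass composition)
#' @param kinetics a [kinetic_params()]
#' @return named numeric vector of length 60
#' @export
base_parameters <- function(network = reduced_network(),
                            kinetics = kinetic_params()) {
  comp <- network$composition
  mac <- comp$macro_fractions
  names(mac) <- paste0("frac_", names(mac))
  kin <- unlist(unclass(kinetics))
  kin <- kin[c("v0_aa", "vinf_aa", "R_aa", "kd_lim", "kd_exc",
               "vmax_gly", "ks_gly", "ki_gly")]
  c(comp$precursor_coeffs, mac, kin)
}

#' Apply a parameter vector to the model
#'
#' Rebuilds the network's biomass reaction and the kinetic parameter set
#' from a (possibly perturbed) 60-parameter vector; unnamed parameters keep
#' their base values.
#'
#' @param values named numeric vector (a subset of the 60 parameters)
#' @param network,kinetics the base model components
#' @return list with elements `network` and `kinetics`
#' @export
apply_parameters <- function(values, network = reduced_network(),
                             kinetics = kinetic_params()) {
  grp <- parameter_groups()
  pre <- values[names(values) %in% grp$precursors44]
  mac <- values[names(values) %in% grp$macromolecules8]
  kin_names <- c(grp$acetate3, grp$death2, grp$glycerol3)
  kin_vals <- values[names(values) %in% kin_names]

  if (length(pre) || length(mac)) {
    comp <- network$composition
    coeff <- comp$precursor_coeffs
    if (length(pre)) coeff[names(pre)] <- pre
    fr <- comp$macro_fractions
    if (length(mac)) {
      nm <- sub("^frac_", "", names(mac))
      fr[nm] <- mac
    }
    network <- set_biomass_composition(
      network, biomass_composition(precursor_coeffs = coeff,
                                   macro_fractions = fr, gam = comp$gam))
  }
  if (length(kin_vals)) {
    args <- unclass(kinetics)
    args[names(kin_vals)] <- kin_vals
    kinetics <- do.call(kinetic_params, args[names(args) != ""])
  }
  list(network = network, kinetics = kinetics)
}

#' Sample a Monte-Carlo parameter ensemble
#'
#' Draws `K` independent copies of the input parameters from normal
#' distributions centred on the base values, with per-parameter relative
#' standard deviations given by `rsd_map` (default: 20 % for the three
#' glycerol-uptake constants, 30 % for everything else).  Non-positive
#' draws are resampled so every sampled value is strictly positive.
#'
#' @param base named base-value vector (see [base_parameters()])
#' @param rsd_map named vector of relative standard deviations; names not
#'   listed fall back to `rsd_default`
#' @param K ensemble size (>= 2)
#' @param seed RNG seed (reproducible ensembles)
#' @param rsd_default fallback RSD
#' @return an object of class `parameter_ensemble` with a `K x length(base)`
#'   sample matrix
#' @export
sample_parameter_ensemble <- function(base = base_parameters(),
                                      rsd_map = NULL, K = 2280,
                                      seed = 1, rsd_default = 0.30) {
  if (K < 2) stop("'K' must be at least 2")
  grp <- parameter_groups()
  rsd <- stats::setNames(rep(rsd_default, length(base)), names(base))
  rsd[names(rsd) %in% grp$glycerol3] <- 0.20
  if (!is.null(rsd_map)) {
    if (any(rsd_map < 0)) stop("negative RSD")
    rsd[names(rsd_map)] <- rsd_map
  }
  set.seed(as.integer(seed) %% 2147483587L)
  samples <- matrix(NA_real_, K, length(base),
                    dimnames = list(NULL, names(base)))
  for (j in seq_along(base)) {
    s <- base[j] * rsd[j]
    x <- stats::rnorm(K, base[j], s)
    tries <- 0
    while (any(x <= 0) && s > 0 && tries < 100) {
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), base[j], s)
      tries <- tries + 1
    }
    if (any(x <= 0)) x[x <= 0] <- base[j]
    samples[, j] <- x
  }
  structure(list(base = base, samples = samples, rsd = rsd, seed = seed),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat(sprintf("Parameter ensemble: K = %d draws of %d parameters (seed %s)\n",
              nrow(x$samples), ncol(x$samples), format(x$seed)))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Mean squared error between predicted and observed series
#'
#' `sum((obs - pred)^2) / n` by default; `mean = FALSE` restores the raw
#' sum of squared errors.
#'
#' @param predicted,observed equal-length numeric vectors
#' @param mean divide by the number of points? (default TRUE)
#' @return squared-error statistic
#' @export
mse_profile <- function(predicted, observed, mean = TRUE) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (!length(predicted)) stop("empty series")
  s <- sum((observed - predicted)^2)
  if (mean) s / length(predicted) else s
}

#' Default MPSA classification thresholds
#'
#' Error-propagation thresholds on the per-observation mean squared error:
#' (6 g/L)^2 for the PDO profile, (0.057 g/L·h)^2 for the productivity and
#' (0.052 mol/mol)^2 for the PDO yield.
#'
#' @return named numeric vector of squared thresholds
#' @export
mpsa_thresholds <- function() {
  c(pdo = 6^2, q_pdo = 0.057^2, y_pdo_s = 0.052^2)
}

#' Classify profiles as acceptable or unacceptable
#'
#' A profile is *unacceptable* for an output when its MSE is strictly
#' greater than the threshold; MSE equal to the threshold is acceptable.
#'
#' @param mse numeric matrix (K x outputs) or vector of MSE values
#' @param thresholds named thresholds per output (default
#'   [mpsa_thresholds()])
#' @return logical matrix of acceptability flags
#' @export
classify_profiles <- function(mse, thresholds = mpsa_thresholds()) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  mse <- as.matrix(mse)
  if (is.null(colnames(mse)) && ncol(mse) == length(thresholds))
    colnames(mse) <- names(thresholds)
  th <- thresholds[colnames(mse)]
  ok <- !sweep(mse, 2, th, ">")
  ok
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the empirical cumulative distribution
#' functions of the two samples (the statistic only; no p-value).
#'
#' @param x,y numeric samples
#' @return statistic in [0, 1]; `NA` (with a warning) if either sample is
#'   empty - the parameter is then not classifiable
#' @export
ks_statistic <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) {
    warning("one class is empty; K-S statistic undefined (not classifiable)")
    return(NA_real_)
  }
  br <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(br)
  Fy <- stats::ecdf(y)(br)
  max(abs(Fx - Fy))
}

#' Critical value of the K-S statistic
#'
#' `1.36 / sqrt(K)` at the 5 % significance level; a parameter whose K-S
#' statistic stays below this value has statistically indistinguishable
#' acceptable and unacceptable distributions.
#'
#' @param K number of Monte-Carlo profiles
#' @return critical value
#' @export
ks_critical_value <- function(K) {
  if (any(K < 1)) stop("'K' must be at least 1")
  1.36 / sqrt(K)
}

# ---------------------------------------------------------------------------

# default simulator factory: runs the bundled glycerol-excess batch and
# returns the outputs MPSA/PRCC score
#' Simulator closure for the sensitivity analyses
#'
#' Returns a function that maps a named parameter vector to the outputs of
#' the reference culture: the PDO profile at `times`, the volumetric
#' productivity and the molar PDO yield.
#'
#' @param network,kinetics base model
#' @param spec_template a [dfba_spec()] simulated for each draw (the
#'   bundled glycerol-excess batch by default, at SOA resolution `G = 48`)
#' @param times observation times (h) at which the PDO profile is read
#' @return `function(values) -> list(pdo, q_pdo, y_pdo_s)`
#' @export
dfba_output_simulator <- function(network = reduced_network(),
                                  kinetics = kinetic_params(),
                                  spec_template = NULL,
                                  times = seq(4, 24, by = 4)) {
  if (is.null(spec_template))
    spec_template <- scenario("batch_excess", network = network,
                              kinetics = kinetics, approach = "soa", G = 48)
  function(values) {
    mod <- apply_parameters(values, network, kinetics)
    sp <- spec_template
    sp$network <- mod$network
    sp$kinetics <- mod$kinetics
    tr <- dfba(sp)
    m <- trajectory_metrics(tr)
    pdo <- stats::approx(tr$states$time, tr$states$pdo, xout = times,
                         rule = 2)$y
    list(pdo = pdo, q_pdo = m$q_pdo, y_pdo_s = m$yield_mol)
  }
}

# observed summary statistics from an observation table (or a list)
.observed_stats <- function(observed) {
  if (is.data.frame(observed)) {
    n <- nrow(observed)
    t_end <- observed$time[n]
    q <- observed$pdo[n] / t_end
    gly_cons <- observed$glycerol[1] - observed$glycerol[n]
    y <- if (gly_cons > 0)
      (observed$pdo[n] / .MM[["pdo"]]) / (gly_cons / .MM[["glycerol"]])
      else NA_real_
    list(time = observed$time, pdo = observed$pdo, q_pdo = q, y_pdo_s = y)
  } else observed
}

#' Multi-parametric sensitivity analysis (MPSA)
#'
#' Simulates every draw of the ensemble, scores each draw's outputs
#' against the reference observations (PDO-profile MSE, squared errors of
#' productivity and yield), classifies draws as acceptable or unacceptable
#' per output, and computes the K-S distance between the acceptable and
#' unacceptable parameter distributions for every (parameter, output)
#' pair.
#'
#' @param ensemble a [sample_parameter_ensemble()]
#' @param simulator function mapping a named parameter vector to
#'   `list(pdo, q_pdo, y_pdo_s)`; see [dfba_output_simulator()]
#' @param observed observation table (data.frame with `time`, `pdo`,
#'   `glycerol` columns) or a list with elements `time`, `pdo`, `q_pdo`,
#'   `y_pdo_s`
#' @param thresholds classification thresholds (default
#'   [mpsa_thresholds()])
#' @return an object of class `mpsa_result`: K-S matrix (parameter x
#'   output), acceptability flags, `d_crit`, and the failure count
#' @export
run_mpsa <- function(ensemble, simulator, observed,
                     thresholds = mpsa_thresholds()) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  obs <- .observed_stats(observed)
  K <- nrow(ensemble$samples)
  mse <- matrix(NA_real_, K, 3,
                dimnames = list(NULL, c("pdo", "q_pdo", "y_pdo_s")))
  failures <- 0L
  for (k in seq_len(K)) {
    out <- tryCatch(simulator(ensemble$samples[k, ]),
                    error = function(e) NULL)
    if (is.null(out)) { failures <- failures + 1L; next }
    mse[k, "pdo"] <- mse_profile(out$pdo, obs$pdo)
    mse[k, "q_pdo"] <- (out$q_pdo - obs$q_pdo)^2
    mse[k, "y_pdo_s"] <- (out$y_pdo_s - obs$y_pdo_s)^2
  }
  ok_rows <- stats::complete.cases(mse)
  acc <- classify_profiles(mse[ok_rows, , drop = FALSE], thresholds)
  X <- ensemble$samples[ok_rows, , drop = FALSE]
  ks <- matrix(NA_real_, ncol(X), ncol(acc),
               dimnames = list(colnames(X), colnames(acc)))
  for (o in colnames(acc)) {
    a <- acc[, o]
    for (j in colnames(X)) {
      ks[j, o] <- if (all(a) || !any(a)) NA_real_
                  else suppressWarnings(ks_statistic(X[a, j], X[!a, j]))
    }
  }
  structure(list(ks = ks, acceptable = acc, mse = mse,
                 thresholds = thresholds,
                 d_crit = ks_critical_value(sum(ok_rows)),
                 failures = failures, K = K),
            class = "mpsa_result")
}

#' @export
print.mpsa_result <- function(x, ...) {
  cat(sprintf("MPSA: K = %d profiles (%d failures), D_crit = %.4f\n",
              x$K, x$failures, x$d_crit))
  cat("acceptable fractions:",
      paste(sprintf("%s %.2f", colnames(x$acceptable),
                    colMeans(x$acceptable)), collapse = ", "), "\n")
  top <- sort(x$ks[, "pdo"], decreasing = TRUE)
  top <- top[!is.na(top)]
  cat("top K-S (PDO profile):\n")
  print(round(utils::head(top, 8), 4))
  invisible(x)
}

#' @export
plot.mpsa_result <- function(x, output = "pdo", ...) {
  v <- x$ks[, output]
  graphics::barplot(v, las = 2, cex.names = 0.5,
                    ylab = paste("K-S statistic,", output), ...)
  graphics::abline(h = x$d_crit, col = "blue", lwd = 2)
  invisible(x)
}

#' Partial rank correlation coefficients (PRCC)
#'
#' Rank-transforms the sampled parameters and each output, then computes
#' the partial correlation of every parameter with the output controlling
#' for all other parameters (via the precision matrix of the rank
#' correlations).  A `method = "pearson"` mode skips the rank transform.
#'
#' @param ensemble a [sample_parameter_ensemble()]
#' @param outputs numeric matrix (K x m) or vector of output values, e.g.
#'   productivity and yield per draw
#' @param method `"prcc"` (rank-based, default) or `"pearson"`
#' @return an object of class `prcc_result` with the parameter x output
#'   coefficient matrix
#' @export
run_prcc <- function(ensemble, outputs, method = c("prcc", "pearson")) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  method <- match.arg(method)
  Y <- as.matrix(outputs)
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("output", seq_len(ncol(Y)))
  K <- nrow(ensemble$samples)
  if (K < 10) stop("at least 10 draws are required")
  if (nrow(Y) != K) stop("outputs must have one row per draw")
  keep <- stats::complete.cases(Y)
  X <- ensemble$samples[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X) + 2)
    stop("K must exceed the number of parameters + 2 for PRCC")
  tr <- if (method == "prcc") function(v) rank(v) else identity
  Xr <- apply(X, 2, tr)
  out <- matrix(0, ncol(X), ncol(Y),
                dimnames = list(colnames(X), colnames(Y)))
  for (o in seq_len(ncol(Y))) {
    y <- Y[, o]
    if (stats::sd(y) == 0) {
      warning("constant output '", colnames(Y)[o],
              "'; correlations reported as 0")
      next
    }
    M <- cbind(Xr, y = tr(y))
    C <- stats::cor(M)
    # guard against numerically singular correlation matrices
    P <- tryCatch(solve(C), error = function(e)
      solve(C + diag(1e-8, nrow(C))))
    iy <- ncol(M)
    out[, o] <- -P[seq_len(ncol(X)), iy] /
      sqrt(P[cbind(seq_len(ncol(X)), seq_len(ncol(X)))] * P[iy, iy])
  }
  structure(list(prcc = out, method = method, K = nrow(X)),
            class = "prcc_result")
}

#' @export
print.prcc_result <- function(x, ...) {
  cat(sprintf("PRCC (%s, K = %d): strongest coefficients\n", x$method, x$K))
  for (o in colnames(x$prcc)) {
    v <- sort(x$prcc[, o], decreasing = TRUE)
    cat(" ", o, ": ",
        paste(sprintf("%s %+0.2f", names(utils::head(v, 3)),
                      utils::head(v, 3)), collapse = ", "),
        " ... ",
        paste(sprintf("%s %+0.2f", names(utils::tail(v, 2)),
                      utils::tail(v, 2)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Long-format export of sensitivity results
#'
#' @param x an `mpsa_result` or `prcc_result`
#' @return data.frame (parameter, output, statistic, value, significant)
#' @export
sensitivity_table <- function(x) {
  if (inherits(x, "mpsa_result")) {
    df <- expand.grid(parameter = rownames(x$ks), output = colnames(x$ks),
                      stringsAsFactors = FALSE)
    df$statistic <- "ks"
    df$value <- as.vector(x$ks)
    df$significant <- as.vector(x$ks) > x$d_crit
  } else if (inherits(x, "prcc_result")) {
    df <- expand.grid(parameter = rownames(x$prcc),
                      output = colnames(x$prcc), stringsAsFactors = FALSE)
    df$statistic <- x$method
    df$value <- as.vector(x$prcc)
    df$significant <- abs(as.vector(x$prcc)) > 2 / sqrt(x$K)
  } else stop("unsupported object")
  df
}
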