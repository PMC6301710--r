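# Instantaneous flux problem: maximize the growth-per-flux objective
#   Z = mu / (w * sum_j v_j^2 + (1-w) * v_ATPprod^2)
# over S v = 0 and flux bounds.  Solved globally by Dinkelbach's parametric
# scheme (the numerator is linear and the denominator a positive definite
# quadratic, so every subproblem is a convex QP); a literal product reading
# of the objective is available as a local-search fallback.

#' Objective specification for the instantaneous flux problem
#'
#' @param w weight in [0, 1]; 1 selects the glycerol-limitation objective,
#'   0.04 the glycerol-excess objective
#' @param atp_flux_ids reaction ids whose summed (stoichiometry-weighted)
#'   ATP production defines `v_ATPprod`; defaults to the network's
#'   substrate-level phosphorylation steps
#' @param form `"ratio"` (default) for growth per squared flux, or
#'   `"product"` for the literal product reading
#' @return an object of class `objective_spec`
#' @export
objective_spec <- function(w = 1, atp_flux_ids = NULL, form = c("ratio", "product")) {
  if (w < 0 || w > 1) stop("'w' must lie in [0, 1]")
  form <- match.arg(form)
  structure(list(w = w, atp_flux_ids = atp_flux_ids, form = form),
            class = "objective_spec")
}

# ATP-production coefficient vector a: a_j = ATP produced per unit flux
.atp_vector <- function(net, atp_flux_ids = NULL) {
  ids <- if (is.null(atp_flux_ids)) net$atp_flux_ids else atp_flux_ids
  a <- numeric(nrow(net$rxns))
  if (!length(ids) || !("atp_c" %in% rownames(net$S))) return(a)
  j <- match(ids, net$rxns$id)
  a[j] <- pmax(net$S["atp_c", j], 0)
  a
}

.objective_value <- function(v, a, mu, w, form) {
  den <- w * sum(v^2) + (1 - w) * sum(a * v)^2
  if (form == "product") mu * den else if (den == 0) 0 else mu / den
}

#' Solve the instantaneous flux state
#'
#' Maximizes `Z = mu / (w*sum(v^2) + (1-w)*v_ATPprod^2)` subject to
#' `S v = 0` and the flux bounds (with `dynamic_bounds` overrides, e.g. the
#' kinetic glycerol uptake and acetate ceiling).  For the default ratio
#' form the optimum is found by Dinkelbach's parametric algorithm, whose
#' convex-QP subproblems make each solve globally optimal; the solve is
#' repeated from three deterministic starting points and the best result
#' kept.  If only the all-zero flux vector is feasible (or no growth is
#' possible), `Z` is defined as 0.
#'
#' @param net a `metabolic_network`
#' @param objective an [objective_spec()]
#' @param dynamic_bounds named list `id = c(lb, ub)` of bound overrides
#' @param warm_start optional flux vector used as solver starting point
#' @return an object of class `flux_state` with elements `fluxes` (named,
#'   mmol/gDW/h), `mu` (1/h), `objective_value` (Z) and solver diagnostics
#' @export
solve_flux_state <- function(net, objective = objective_spec(),
                             dynamic_bounds = NULL, warm_start = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  lb <- net$rxns$lb
  ub <- net$rxns$ub
  if (!is.null(dynamic_bounds)) {
    for (id in names(dynamic_bounds)) {
      j <- .rxn_idx(net, id)
      if (is.na(j)) stop("unknown reaction in dynamic_bounds: ", id)
      lb[j] <- dynamic_bounds[[id]][1]
      ub[j] <- dynamic_bounds[[id]][2]
    }
  }
  if (any(lb > ub)) stop("inconsistent bounds after overrides")
  a <- .atp_vector(net, objective$atp_flux_ids)
  bio <- .rxn_idx(net, net$biomass_id)
  Sr <- .row_reduced_S(net)

  if (objective$form == "product")
    return(.solve_product_form(net, objective, lb, ub, a, bio))

  # deterministic multistart: cold, warm (if given), and a mid-bounds seed.
  # A valid warm start short-circuits the multistart: the Dinkelbach
  # subproblems are convex, so every start reaches the same global optimum
  # (asserted by the test suite), and dynamic simulations re-solve the
  # problem thousands of times.
  starts <- if (is.null(warm_start)) {
    list(NULL, pmin(pmax((lb + ub) / 2, lb), ub), pmax(lb, pmin(0, ub)))
  } else list(warm_start)
  best <- NULL
  for (s in starts) {
    res <- .flux_opt_cpp(Sr, lb, ub, bio, objective$w, a,
                         if (is.null(s)) NULL else as.numeric(s))
    if (res$status == "infeasible")
      stop("infeasible constraint set in flux problem")
    if (is.null(best) || isTRUE(res$Z > best$Z + 1e-12)) best <- res
  }
  if (best$status == "maxit")
    warning("flux NLP did not converge within the iteration budget")

  v <- as.numeric(best$fluxes)
  names(v) <- net$rxns$id
  structure(list(fluxes = v, mu = best$mu, objective_value = best$Z,
                 w = objective$w, status = best$status,
                 iterations = best$iters),
            class = "flux_state")
}

# Literal product reading: maximize mu * denominator.  Non-convex; local
# search from multiple feasible seeds via projected penalized optimization.
.solve_product_form <- function(net, objective, lb, ub, a, bio) {
  w <- objective$w
  n <- length(lb)
  Sr <- .row_reduced_S(net)
  # feasible seeds from the ratio solver machinery (min-norm + growth-max)
  seed0 <- .qp_solve_cpp(diag(n), numeric(n), Sr, lb, ub)$x
  cmu <- numeric(n); cmu[bio] <- 1
  seed1 <- .qp_solve_cpp(2e-4 * diag(n), cmu, Sr, lb, ub)$x
  NS <- .null_space(net$S)
  obj <- function(th, v0) {
    v <- v0 + NS %*% th
    pen <- sum(pmax(lb - v, 0)^2) + sum(pmax(v - ub, 0)^2)
    -(v[bio] * (w * sum(v^2) + (1 - w) * sum(a * v)^2)) + 1e6 * pen
  }
  best <- NULL
  for (v0 in list(seed0, seed1, (seed0 + seed1) / 2)) {
    opt <- stats::optim(numeric(ncol(NS)), obj, v0 = v0, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    v <- as.numeric(v0 + NS %*% opt$par)
    v <- pmin(pmax(v, lb), ub)
    val <- v[bio] * (w * sum(v^2) + (1 - w) * sum(a * v)^2)
    if (is.null(best) || val > best$val) best <- list(v = v, val = val)
  }
  v <- best$v
  names(v) <- net$rxns$id
  structure(list(fluxes = v, mu = v[[net$biomass_id]],
                 objective_value = best$val, w = w, status = "local",
                 iterations = NA_integer_),
            class = "flux_state")
}

# drop linearly dependent rows of S (e.g. the CoA row mirrors acetyl-CoA)
# so the solver's KKT systems are nonsingular; the row choice is cached on
# the network (the dependence pattern is structural, not value-dependent)
.row_reduced_S <- function(net) {
  rows <- net$S_rank_rows
  if (is.null(rows)) {
    qr_t <- qr(t(net$S))
    rows <- sort(qr_t$pivot[seq_len(qr_t$rank)])
  }
  net$S[rows, , drop = FALSE]
}

.null_space <- function(S, tol = 1e-10) {
  sv <- svd(S, nv = ncol(S))
  r <- sum(sv$d > tol * max(sv$d))
  sv$v[, seq(r + 1, ncol(S)), drop = FALSE]
}

#' Solve the flux state at a given culture condition
#'
#' Convenience wrapper: derives the kinetic bounds (glycerol uptake
#' equality, acetate ceiling) and the regime objective weight from the
#' extracellular glycerol concentration, then calls [solve_flux_state()].
#' The uptake is applied as an equality at the Ghose-Tyagi rate, optionally
#' scaled down by `uptake_scale` (used near substrate exhaustion).
#'
#' @param net a `metabolic_network`
#' @param glycerol_gL extracellular glycerol (g/L)
#' @param p a [kinetic_params()] object
#' @param uptake_scale multiplier in [0, 1] on the kinetic uptake rate
#' @param warm_start optional starting flux vector
#' @param form objective form, see [objective_spec()]
#' @return a `flux_state`
#' @export
flux_state_at <- function(net, glycerol_gL, p = kinetic_params(),
                          uptake_scale = 1, warm_start = NULL,
                          form = "ratio") {
  if (form == "ratio") {
    ctx <- .dfba_ctx(net, p)
    r <- .flux_solve(ctx, glycerol_gL, uptake_scale = uptake_scale,
                     warm = warm_start)
    v <- as.numeric(r$fluxes)
    names(v) <- net$rxns$id
    return(structure(list(fluxes = v, mu = r$mu,
                          objective_value = r$Z, w = r$w,
                          status = r$status, iterations = r$iters),
                     class = "flux_state"))
  }
  U <- glycerol_uptake_bound(gl_to_mM(glycerol_gL), p) * uptake_scale
  w <- objective_weight(glycerol_gL, p)
  cap <- acetate_secretion_bound(U, p)
  solve_flux_state(net, objective_spec(w = w, form = form),
                   dynamic_bounds = list(EX_glyc = c(-U, -U),
                                         ACK = c(0, cap)),
                   warm_start = warm_start)
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("Flux state (w = %g, status %s): mu = %.4f 1/h, Z = %.4g\n",
              x$w, x$status, x$mu, x$objective_value))
  sec <- x$fluxes[grepl("^EX_", names(x$fluxes))]
  sec <- sec[abs(sec) > 1e-9]
  if (length(sec)) {
    cat("Nonzero exchange fluxes (mmol/gDW/h):\n")
    print(round(sec, 4))
  }
  invisible(x)
}
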