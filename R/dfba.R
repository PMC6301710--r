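# Dynamic flux balance analysis engine: the extracellular mass balances
#   dz_i/dt = v_i * X * MW_i       (batch; concentrations in g/L)
#   d(V z)/dt = F S_F + v MW (V X),  d(V X)/dt = V (mu - kd) X,  dV/dt = F
# coupled at every instant to the flux optimization of the network, solved
# by the static optimization approach (SOA: explicit stepping), the direct
# approach (DA: adaptive integration with the optimization embedded in the
# right-hand side), or the dynamic optimization approach (DOA: orthogonal
# collocation over the whole horizon).

# species tracked in the medium, in trajectory column order
.species_map <- c(glycerol = "glyc_e", pdo = "pdo_e", acetate = "ac_e",
                  butyrate = "but_e", lactate = "lac_e", ethanol = "eth_e",
                  butanol = "buoh_e", h2 = "h2_e", co2 = "co2_e")

#' Feed policy for fed-batch cultures
#'
#' Constant feeding (`F = alpha`) or feeding coupled to pH control
#' (`F = beta * vH+ * X * V`, with `vH+` the summed proton-coupled acid
#' secretion flux: acetate + butyrate + lactate).  Feeding stops when the
#' reactor reaches `V_max`.
#'
#' @param mode `"constant"` or `"ph_coupled"`
#' @param alpha constant feed rate (L/h), used in constant mode
#' @param beta proportionality constant (L/mmol) between the volumetric
#'   proton secretion rate (mmol/h) and the feed rate, used in pH mode
#' @param glycerol_pct glycerol mass percentage of the feed; converted to
#'   g/L with unit solution density (`S_F = 10 * glycerol_pct`)
#' @param S_F optional named vector of feed concentrations (g/L),
#'   overriding `glycerol_pct`
#' @param V_max maximum reactor volume (L)
#' @return an object of class `feed_policy`
#' @export
feed_policy <- function(mode = c("constant", "ph_coupled"), alpha = 0,
                        beta = 0, glycerol_pct = NULL, S_F = NULL,
                        V_max = 1.5) {
  mode <- match.arg(mode)
  if (is.null(S_F)) {
    if (is.null(glycerol_pct)) stop("give either 'glycerol_pct' or 'S_F'")
    S_F <- c(glycerol = 10 * glycerol_pct)
  }
  if (any(S_F < 0)) stop("negative feed concentration")
  bad <- setdiff(names(S_F), names(.species_map))
  if (length(bad)) stop("unknown feed species: ", paste(bad, collapse = ", "))
  if (mode == "constant" && alpha < 0) stop("'alpha' must be non-negative")
  if (mode == "ph_coupled" && beta < 0) stop("'beta' must be non-negative")
  structure(list(mode = mode, alpha = alpha, beta = beta, S_F = S_F,
                 V_max = V_max),
            class = "feed_policy")
}

#' Simulation specification
#'
#' Bundles everything a DFBA run needs: the network, the kinetic
#' parameters, the initial culture state, the horizon and its
#' discretization, the solution approach and an optional feed policy.
#'
#' @param network a `metabolic_network` (default: the bundled reduced
#'   network)
#' @param kinetics a [kinetic_params()] object
#' @param glycerol0 initial glycerol (g/L)
#' @param X0 initial viable biomass (g/L)
#' @param z0 optional named vector of further initial concentrations (g/L)
#' @param t0,tf start and end of the simulated culture (h)
#' @param G number of time intervals of the discretization grid
#' @param approach `"da"`, `"soa"` or `"doa"`
#' @param feed optional [feed_policy()] for fed-batch operation
#' @param V0 initial reactor volume (L)
#' @param collocation list with `family` and `n_points` for the DOA
#' @return an object of class `dfba_spec`
#' @export
dfba_spec <- function(network = reduced_network(),
                      kinetics = kinetic_params(), glycerol0, X0,
                      z0 = NULL, t0 = 0, tf, G = 100,
                      approach = c("da", "soa", "doa"), feed = NULL,
                      V0 = 1,
                      collocation = list(family = "legendre", n_points = 6)) {
  approach <- match.arg(approach)
  if (tf <= t0) stop("'tf' must exceed 't0'")
  if (G < 1) stop("'G' must be at least 1")
  if (is.null(collocation$n_points) || collocation$n_points < 2)
    stop("at least 2 collocation points are required")
  .chk_pos(glycerol0, "glycerol0", strict = FALSE)
  .chk_pos(X0, "X0", strict = FALSE)
  z <- stats::setNames(numeric(length(.species_map)), names(.species_map))
  z["glycerol"] <- glycerol0
  if (!is.null(z0)) {
    bad <- setdiff(names(z0), names(z))
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    if (any(z0 < 0)) stop("negative initial concentration")
    z[names(z0)] <- z0
  }
  if (!is.null(feed) && !inherits(feed, "feed_policy"))
    stop("'feed' must be a feed_policy object")
  if (!is.null(feed) && V0 > feed$V_max) stop("V0 exceeds V_max")
  structure(list(network = network, kinetics = kinetics, z0 = z, X0 = X0,
                 t0 = t0, tf = tf, G = G, approach = approach, feed = feed,
                 V0 = V0, collocation = collocation),
            class = "dfba_spec")
}

# ---------------------------------------------------------------------------
# lean flux-solving context shared by all integrators

.dfba_ctx <- function(net, p) {
  rid <- net$rxns$id
  ex_cols <- match(net$exchange_map[.species_map], rid)
  list(net = net, p = p,
       Sr = .row_reduced_S(net),
       a = .atp_vector(net),
       bio = match(net$biomass_id, rid),
       lb0 = net$rxns$lb, ub0 = net$rxns$ub,
       jg = match("EX_glyc", rid),
       jack = match("ACK", rid),
       jac_ex = match("EX_ac", rid), jbut_ex = match("EX_but", rid),
       jlac_ex = match("EX_lac", rid),
       ex_cols = ex_cols,
       mw = net$mets$molar_mass[match(.species_map, net$mets$id)] / 1000,
       nrxn = length(rid),
       env = new.env(parent = emptyenv()))
}

# Largest glycerol uptake the network can process: an exact max-uptake LP
# (active-set solve from a feasible interior point) with the acetate
# ceiling made self-consistent by fixed-point iteration; returns NULL when
# the LP fails to converge (a continuation fallback then takes over).
.uptake_capacity <- function(ctx, solve_at, hi) {
  base <- NULL
  for (f in c(0.5, 0.25, 0.1, 0.02)) {
    rp <- solve_at(hi * f, maxit = 4000L, warm_at = NULL)
    if (!identical(rp$status, "infeasible")) { base <- rp$fluxes; break }
  }
  if (is.null(base)) return(NULL)
  lb <- ctx$lb0; ub <- ctx$ub0
  lb[ctx$jg] <- -1000; ub[ctx$jg] <- 0
  n <- ctx$nrxn
  H <- diag(2e-4, n)
  cv <- numeric(n); cv[ctx$jg] <- -1
  Ucap <- -base[ctx$jg]
  for (i in 1:3) {
    ub[ctx$jack] <- acetate_secretion_bound(Ucap, ctx$p)
    r <- .qp_solve_cpp(H, cv, ctx$Sr, lb, ub, warm = base)
    if (!isTRUE(r$converged) || r$residual > 1e-7) return(NULL)
    x <- r$x
    if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) return(NULL)
    Ucap <- max(-x[ctx$jg], 0)
  }
  # verify: the clipped uptake must actually be processable
  ok <- !identical(solve_at(Ucap * 0.995, maxit = 6000L,
                            warm_at = x * 0.995)$status, "infeasible")
  if (!ok) return(NULL)
  Ucap * 0.995
}

# one instantaneous solve; glycerol in g/L; returns C++ result plus U
.flux_solve <- function(ctx, glycerol_gL, uptake_scale = 1, warm = NULL,
                        w = NULL) {
  p <- ctx$p
  G <- max(glycerol_gL, 0)
  U <- glycerol_uptake_bound(gl_to_mM(G), p) * uptake_scale
  if (is.null(w)) w <- objective_weight(G, p)
  # the kinetic uptake can exceed the network's disposal capacity (e.g.
  # under a perturbed acetate ceiling): the cell then consumes at the
  # largest processable rate, determined once per context and cached
  if (!is.null(ctx$env$Ucap)) U <- min(U, ctx$env$Ucap)
  # rescale the warm start to the new uptake: scaling a feasible flux
  # vector keeps S v = 0 exactly, so the previous step's solution remains
  # a valid interior start after the uptake equality moves
  if (!is.null(warm)) {
    Uw <- -warm[[ctx$jg]]
    if (is.finite(Uw) && Uw > 1e-9 && U > 1e-9) warm <- warm * (U / Uw)
    else if (U <= 1e-9) warm <- NULL
  }
  lb <- ctx$lb0; ub <- ctx$ub0
  solve_at <- function(U, maxit = 20000L, warm_at = warm) {
    lb[ctx$jg] <- -U; ub[ctx$jg] <- -U
    ub[ctx$jack] <- acetate_secretion_bound(U, p)
    .flux_opt_cpp(ctx$Sr, lb, ub, ctx$bio, w, ctx$a, warm_at,
                  maxit_admm = maxit)
  }
  r <- solve_at(U)
  if (identical(r$status, "infeasible")) {
    if (is.null(ctx$env$Ucap)) {
      ctx$env$Ucap <- .uptake_capacity(ctx, solve_at, min(U, p$vmax_gly))
    }
    if (is.null(ctx$env$Ucap)) {
      # fallback: largest processable uptake by continuation from below:
      # every probe is warm-seeded by rescaling the last feasible probe,
      # so the feasibility oracle stays reliable at a small budget (the
      # acetate ceiling is re-evaluated consistently at every probe)
      hi <- min(U, p$vmax_gly)
      lo <- 0; wlo <- NULL
      for (f in c(0.5, 0.25, 0.1, 0.02)) {
        rp <- solve_at(hi * f, maxit = 4000L, warm_at = NULL)
        if (!identical(rp$status, "infeasible")) {
          lo <- hi * f; wlo <- rp$fluxes
          break
        }
      }
      while (lo > 0 && lo < hi - 1e-9) {
        mid <- min(lo * 1.06, hi)
        rp <- solve_at(mid, maxit = 1500L, warm_at = wlo * (mid / lo))
        if (identical(rp$status, "infeasible")) break
        lo <- mid; wlo <- rp$fluxes
      }
      ctx$env$Ucap <- lo * 0.995
    }
    U <- min(U, ctx$env$Ucap)
    r <- solve_at(U)
    # last resort: shrink further until feasible
    while (identical(r$status, "infeasible") && U > 1e-6) {
      U <- U / 2
      ctx$env$Ucap <- U
      r <- solve_at(U)
    }
  }
  r$U <- U
  r$w <- w
  r
}

# ---------------------------------------------------------------------------

#' Run a dynamic flux balance analysis simulation
#'
#' Dispatches on the approach in the specification: `"soa"` (explicit
#' forward-Euler stepping, flux problem re-optimized each step), `"da"`
#' (adaptive integration with the flux optimization embedded in the
#' right-hand side and event handling at the regime switch), or `"doa"`
#' (orthogonal collocation over the whole horizon; refuses scenarios whose
#' objective regime changes inside the horizon).  Fed-batch operation
#' (a [feed_policy()] in the spec) is supported by SOA and DA.
#'
#' @param spec a [dfba_spec()]
#' @return an object of class `dfba_trajectory`: per-grid-time culture
#'   states (time, volume, biomass, concentrations in g/L, growth rate,
#'   regime) plus the flux distribution at every grid time
#' @export
dfba <- function(spec) {
  stopifnot(inherits(spec, "dfba_spec"))
  switch(spec$approach,
         soa = .simulate_soa(spec),
         da = .simulate_da(spec),
         doa = .simulate_doa(spec))
}

#' @rdname dfba
#' @param ... arguments passed to [dfba_spec()]
#' @export
simulate_soa <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- dfba_spec(..., approach = "soa")
  spec$approach <- "soa"
  dfba(spec)
}

#' @rdname dfba
#' @export
simulate_da <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- dfba_spec(..., approach = "da")
  spec$approach <- "da"
  dfba(spec)
}

#' @rdname dfba
#' @export
simulate_doa <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- dfba_spec(..., approach = "doa")
  spec$approach <- "doa"
  dfba(spec)
}

#' @rdname dfba
#' @export
simulate_fedbatch <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- dfba_spec(...)
  if (is.null(spec$feed)) stop("fed-batch simulation requires a feed policy")
  if (spec$approach == "doa") stop("fed-batch is supported by SOA and DA")
  dfba(spec)
}

# assemble the trajectory object
.make_trajectory <- function(spec, times, V, X, Z, MU, W, KD, FLUX,
                             diagnostics = list()) {
  states <- data.frame(time = times, V = V, X = X, Z,
                       mu = MU, w = W, kd = KD,
                       regime = ifelse(W >= 1, "limitation", "excess"))
  structure(list(states = states, fluxes = FLUX, approach = spec$approach,
                 spec = spec, diagnostics = diagnostics),
            class = "dfba_trajectory")
}

# ---------------------------------------------------------------------------
# SOA: forward Euler; also the fed-batch explicit integrator

.simulate_soa <- function(spec) {
  ctx <- .dfba_ctx(spec$network, spec$kinetics)
  p <- spec$kinetics
  G <- spec$G
  dt <- (spec$tf - spec$t0) / G
  ns <- length(.species_map)
  fed <- !is.null(spec$feed)

  times <- spec$t0 + dt * (0:G)
  Z <- matrix(0, G + 1, ns, dimnames = list(NULL, names(.species_map)))
  V <- numeric(G + 1); X <- numeric(G + 1)
  MU <- numeric(G + 1); W <- numeric(G + 1); KD <- numeric(G + 1)
  FLUX <- matrix(0, G + 1, ctx$nrxn,
                 dimnames = list(NULL, spec$network$rxns$id))
  z <- spec$z0; x <- spec$X0; vol <- spec$V0
  warm <- NULL
  fails <- 0L

  for (g in 0:G) {
    gl <- z[["glycerol"]]
    w <- objective_weight(max(gl, 0), p)
    kd <- death_rate(max(gl, 0), p)
    # substrate-exhaustion handling: rescale the uptake bound so the step
    # cannot drive glycerol negative
    scale <- 1
    if (x > 0 && g < G) {
      U0 <- glycerol_uptake_bound(gl_to_mM(max(gl, 0)), p)
      need <- U0 * x * ctx$mw[1] * dt
      if (need > gl && need > 0) scale <- max(gl, 0) / need
    }
    r <- tryCatch(.flux_solve(ctx, gl, uptake_scale = scale, warm = warm),
                  error = function(e) NULL)
    if (is.null(r)) {  # retry once with halved step contribution
      fails <- fails + 1L
      r <- .flux_solve(ctx, gl, uptake_scale = scale / 2, warm = NULL)
    }
    warm <- r$fluxes
    v_ex <- r$fluxes[ctx$ex_cols]
    Z[g + 1, ] <- z; V[g + 1] <- vol; X[g + 1] <- x
    MU[g + 1] <- r$mu; W[g + 1] <- w; KD[g + 1] <- kd
    FLUX[g + 1, ] <- r$fluxes
    if (g == G) break

    if (fed) {
      f <- spec$feed
      Fr <- if (f$mode == "constant") f$alpha else {
        vh <- r$fluxes[ctx$jac_ex] + r$fluxes[ctx$jbut_ex] +
          r$fluxes[ctx$jlac_ex]
        f$beta * vh * x * vol
      }
      if (vol >= f$V_max) Fr <- 0
      Fr <- min(Fr, max(f$V_max - vol, 0) / dt)  # stop at V_max
      sf <- stats::setNames(numeric(ns), names(.species_map))
      sf[names(f$S_F)] <- f$S_F
      M <- z * vol + (sf * Fr + v_ex * ctx$mw * x * vol) * dt
      B <- x * vol + (r$mu - kd) * x * vol * dt
      vol <- vol + Fr * dt
      z <- pmax(M / vol, 0)
      x <- max(B / vol, 0)
    } else {
      z <- pmax(z + v_ex * ctx$mw * x * dt, 0)
      x <- max(x + (r$mu - kd) * x * dt, 0)
    }
  }
  .make_trajectory(spec, times, V, X, Z, MU, W, KD, FLUX,
                   diagnostics = list(step_failures = fails))
}

# ---------------------------------------------------------------------------
# DA: adaptive integration (lsodar) with regime-switch roots

.simulate_da <- function(spec) {
  ctx <- .dfba_ctx(spec$network, spec$kinetics)
  p <- spec$kinetics
  fed <- !is.null(spec$feed)
  ns <- length(.species_map)
  env <- new.env()
  env$warm <- NULL

  grid <- seq(spec$t0, spec$tf, length.out = spec$G + 1)

  rhs_batch <- function(t, y, pars) {
    z <- pmax(y[seq_len(ns)], 0)
    x <- max(y[ns + 1], 0)
    r <- .flux_solve(ctx, z[1], warm = env$warm, w = pars$w)
    env$warm <- r$fluxes
    dz <- r$fluxes[ctx$ex_cols] * ctx$mw * x
    list(c(dz, (r$mu - pars$kd) * x))
  }
  rhs_fed <- function(t, y, pars) {
    vol <- max(y[ns + 2], 1e-9)
    z <- pmax(y[seq_len(ns)] / vol, 0)
    x <- max(y[ns + 1] / vol, 0)
    r <- .flux_solve(ctx, z[1], warm = env$warm, w = pars$w)
    env$warm <- r$fluxes
    f <- spec$feed
    Fr <- if (f$mode == "constant") f$alpha else {
      vh <- r$fluxes[ctx$jac_ex] + r$fluxes[ctx$jbut_ex] +
        r$fluxes[ctx$jlac_ex]
      f$beta * vh * x * vol
    }
    if (vol >= f$V_max - 1e-9) Fr <- 0
    sf <- stats::setNames(numeric(ns), names(.species_map))
    sf[names(f$S_F)] <- f$S_F
    dM <- sf * Fr + r$fluxes[ctx$ex_cols] * ctx$mw * x * vol
    dB <- (r$mu - pars$kd) * x * vol
    list(c(dM, dB, Fr))
  }

  # regime switch root (and V_max root for fed-batch)
  rootfun <- function(t, y, pars) {
    gl <- if (fed) y[1] / max(y[ns + 2], 1e-9) else y[1]
    out <- gl - p$switch_gly
    if (fed) out <- c(out, y[ns + 2] - spec$feed$V_max)
    out
  }

  y <- if (fed) c(spec$z0 * spec$V0, spec$X0 * spec$V0, spec$V0)
       else c(spec$z0, spec$X0)
  t_cur <- spec$t0
  rows <- NULL
  seg <- 0L
  while (t_cur < spec$tf - 1e-9 && seg < 60L) {
    seg <- seg + 1L
    gl_cur <- if (fed) y[1] / max(y[ns + 2], 1e-9) else y[1]
    pars <- list(w = objective_weight(max(gl_cur, 0), p),
                 kd = death_rate(max(gl_cur, 0), p))
    tt <- unique(c(t_cur, grid[grid > t_cur + 1e-12], spec$tf))
    sol <- deSolve::lsodar(y, tt, if (fed) rhs_fed else rhs_batch, pars,
                           rtol = 1e-6, atol = 1e-8, rootfunc = rootfun,
                           maxsteps = 50000)
    rows <- rbind(rows, cbind(sol, w = pars$w, kd = pars$kd))
    t_end <- sol[nrow(sol), 1]
    y <- sol[nrow(sol), 1 + seq_len(length(y))]
    if (t_end >= spec$tf - 1e-9) break
    # stopped at a root: nudge across the switch and continue
    t_cur <- t_end + 1e-9
  }

  tms <- rows[, 1]
  keep <- !duplicated(round(tms, 10))
  rows <- rows[keep, , drop = FALSE]
  tms <- rows[, 1]
  if (fed) {
    vol <- rows[, 1 + ns + 2]
    Zm <- sweep(rows[, 1 + seq_len(ns), drop = FALSE], 1, vol, "/")
    Xv <- rows[, 1 + ns + 1] / vol
  } else {
    vol <- rep(spec$V0, nrow(rows))
    Zm <- rows[, 1 + seq_len(ns), drop = FALSE]
    Xv <- rows[, 1 + ns + 1]
  }
  Zm <- pmax(Zm, 0)
  colnames(Zm) <- names(.species_map)

  # flux snapshots at the reported times
  FLUX <- matrix(0, nrow(rows), ctx$nrxn,
                 dimnames = list(NULL, spec$network$rxns$id))
  MU <- numeric(nrow(rows))
  warm <- NULL
  for (i in seq_len(nrow(rows))) {
    r <- .flux_solve(ctx, Zm[i, 1], warm = warm, w = rows[i, "w"])
    warm <- r$fluxes
    FLUX[i, ] <- r$fluxes
    MU[i] <- r$mu
  }
  .make_trajectory(spec, tms, vol, Xv, Zm, MU, rows[, "w"], rows[, "kd"],
                   FLUX, diagnostics = list(segments = seg))
}

# ---------------------------------------------------------------------------
# DOA: orthogonal collocation over the whole horizon, solved in reduced
# space (states at the collocation nodes are the unknowns; at every node
# the instantaneous flux problem is solved to global optimality; Newton
# iteration drives the collocation residuals of the mass balances to zero;
# the attained objective is the sum of Z over the reporting grid)

.simulate_doa <- function(spec) {
  if (!is.null(spec$feed)) stop("fed-batch is supported by SOA and DA")
  ctx <- .dfba_ctx(spec$network, spec$kinetics)
  p <- spec$kinetics
  ns <- length(.species_map)

  # refuse horizons that cross the objective switch
  pre_spec <- spec; pre_spec$approach <- "soa"
  pre_spec$G <- max(spec$G, 120)
  pre <- .simulate_soa(pre_spec)
  regs <- unique(pre$states$regime)
  if (length(regs) > 1)
    stop("DOA cannot be employed in scenarios with change of objective ",
         "function: the glycerol regime switches inside the horizon")
  w_fix <- pre$states$w[1]
  kd_fix <- pre$states$kd[1]

  n <- spec$collocation$n_points
  fam <- if (is.null(spec$collocation$family)) "legendre"
         else spec$collocation$family
  tau <- collocation_nodes(fam, n, interval = c(spec$t0, spec$tf))
  pts <- c(spec$t0, tau)
  D <- lagrange_derivative_matrix(pts)
  y0 <- c(spec$z0, spec$X0)

  # initial node states from the SOA pre-run
  interp_cols <- cbind(pre$states[names(.species_map)], X = pre$states$X)
  Y <- sapply(seq_len(ns + 1), function(j)
    stats::approx(pre$states$time, interp_cols[[j]], xout = tau)$y)

  rhs_at <- function(state) {
    z <- pmax(state[seq_len(ns)], 0)
    x <- max(state[ns + 1], 0)
    r <- .flux_solve(ctx, z[1], w = w_fix)
    c(r$fluxes[ctx$ex_cols] * ctx$mw * x, (r$mu - kd_fix) * x)
  }
  resid <- function(Yv) {
    Y <- matrix(Yv, n, ns + 1)
    Yfull <- rbind(y0, Y)
    R <- D[-1, , drop = FALSE] %*% Yfull -
      t(apply(Y, 1, rhs_at))
    as.numeric(R)
  }

  Yv <- as.numeric(Y)
  f0 <- resid(Yv)
  tol <- 1e-9 * max(1, max(abs(f0)))
  conv <- FALSE
  for (it in 1:25) {
    nrm <- sqrt(mean(f0^2))
    if (nrm < 1e-8) { conv <- TRUE; break }
    # forward-difference Jacobian
    J <- matrix(0, length(f0), length(Yv))
    h <- pmax(1e-6, 1e-7 * abs(Yv))
    for (j in seq_along(Yv)) {
      Yp <- Yv; Yp[j] <- Yp[j] + h[j]
      J[, j] <- (resid(Yp) - f0) / h[j]
    }
    step <- tryCatch(solve(J, -f0), error = function(e)
      -qr.solve(qr(J, LAPACK = TRUE), f0))
    lam <- 1
    repeat {
      Yn <- Yv + lam * step
      fn <- resid(Yn)
      if (sqrt(mean(fn^2)) < nrm * (1 - 1e-4 * lam) || lam < 1e-3) break
      lam <- lam / 2
    }
    Yv <- Yv + lam * step
    f0 <- resid(Yv)
  }
  if (!conv && sqrt(mean(f0^2)) > 1e-5)
    warning("DOA collocation residuals did not fully converge (RMS ",
            signif(sqrt(mean(f0^2)), 3), ")")

  Yfull <- rbind(y0, matrix(Yv, n, ns + 1))
  grid <- seq(spec$t0, spec$tf, length.out = spec$G + 1)
  L <- .lagrange_eval_matrix(pts, grid)
  states_grid <- pmax(L %*% Yfull, 0)

  FLUX <- matrix(0, length(grid), ctx$nrxn,
                 dimnames = list(NULL, spec$network$rxns$id))
  MU <- numeric(length(grid)); Zsum <- 0
  warm <- NULL
  for (i in seq_along(grid)) {
    r <- .flux_solve(ctx, states_grid[i, 1], warm = warm, w = w_fix)
    warm <- r$fluxes
    FLUX[i, ] <- r$fluxes
    MU[i] <- r$mu
    Zsum <- Zsum + r$Z
  }
  Zm <- states_grid[, seq_len(ns), drop = FALSE]
  colnames(Zm) <- names(.species_map)
  .make_trajectory(spec, grid, rep(spec$V0, length(grid)),
                   states_grid[, ns + 1], Zm, MU,
                   rep(w_fix, length(grid)), rep(kd_fix, length(grid)),
                   FLUX,
                   diagnostics = list(newton_iterations = it,
                                      residual_rms = sqrt(mean(f0^2)),
                                      objective_sum = Zsum,
                                      converged = conv))
}

# ---------------------------------------------------------------------------
# methods

#' @export
print.dfba_trajectory <- function(x, ...) {
  s <- x$states
  cat(sprintf("DFBA trajectory (%s): t = %.3g..%.3g h, %d reported times\n",
              toupper(x$approach), min(s$time), max(s$time), nrow(s)))
  cat(sprintf("  biomass %.3g -> %.3g g/L; glycerol %.3g -> %.3g g/L; PDO -> %.3g g/L\n",
              s$X[1], s$X[nrow(s)], s$glycerol[1], s$glycerol[nrow(s)],
              s$pdo[nrow(s)]))
  invisible(x)
}

#' @export
summary.dfba_trajectory <- function(object, ...) {
  m <- trajectory_metrics(object)
  cat(sprintf("DFBA %s simulation, %s culture\n", toupper(object$approach),
              if (is.null(object$spec$feed)) "batch" else "fed-batch"))
  print(m)
  invisible(m)
}

#' @export
as.data.frame.dfba_trajectory <- function(x, ...) x$states

#' @export
plot.dfba_trajectory <- function(x, which = c("states", "fluxes"), ...) {
  which <- match.arg(which)
  s <- x$states
  if (which == "states") {
    oldpar <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(oldpar))
    graphics::matplot(s$time, cbind(s$glycerol, s$pdo, s$acetate,
                                    s$butyrate),
                      type = "l", lty = 1, lwd = 2,
                      col = c("#333333", "#1b7837", "#d95f02", "#7570b3"),
                      xlab = "time (h)", ylab = "concentration (g/L)", ...)
    graphics::legend("topright", c("glycerol", "PDO", "acetate", "butyrate"),
                     col = c("#333333", "#1b7837", "#d95f02", "#7570b3"),
                     lty = 1, lwd = 2, bty = "n")
    graphics::plot(s$time, s$X, type = "l", lwd = 2, col = "#b2182b",
                   xlab = "time (h)", ylab = "biomass (gDW/L)")
  } else {
    sec <- x$fluxes[, grepl("^EX_", colnames(x$fluxes)), drop = FALSE]
    graphics::matplot(s$time, sec, type = "l", xlab = "time (h)",
                      ylab = "exchange flux (mmol/gDW/h)", ...)
  }
  invisible(x)
}
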