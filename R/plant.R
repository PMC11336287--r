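# Modified-A2O plant: flowsheet assembly and dynamic simulation of the
# coupled 7-bioreactor + layered-settler system.
#
# Topology (defaults): influent + returned sludge -> T0 (pre-anoxic) ->
# T1 (anaerobic) -> T2 (anoxic) -> T3 (aerobic) -> T4 (deoxygenation) ->
# T5 (post-anoxic) -> T6 (post-aerobic) -> settler. Internal recycle is
# drawn from the deoxygenation tank outlet back to the anoxic tank (the
# deox tank exists to strip dissolved oxygen from this stream); sludge
# return goes from the settler underflow to T0; wastage is drawn from the
# underflow.

.tank_roles <- c("pre-anoxic", "anaerobic", "anoxic", "aerobic",
                 "deox", "post-anoxic", "post-aerobic")

#' Plant configuration
#'
#' Defaults reproduce the studied full-scale modified-A2O plant: tank
#' volumes (1113, 1825, 5518, 7461, 472, 1433, 945) m^3 (18798 m^3
#' total), an aerobic-tank air supply capacity of 98 m^3 min^-1, internal
#' recirculation ratio 320 % of the influent flow and sludge return ratio
#' 100 %. The wastage ratio and the post-aerobic KLa are not reported for
#' the baseline and default to typical operating values.
#'
#' @param volumes named numeric of 7 tank volumes (m^3), names T0..T6.
#' @param kla named numeric: oxygen transfer coefficients (d^-1) of the
#'   aerated tanks (default `c(T3 = 248, T6 = 120)`).
#' @param Ql internal recirculation ratio (fraction of Qin).
#' @param Qs sludge return ratio (fraction of Qin).
#' @param Qw wastage ratio (fraction of Qin).
#' @param recycle_from,recycle_to,return_to tank names wiring the
#'   internal recycle and the sludge return.
#' @param so_sat dissolved-oxygen saturation (g m^-3).
#' @param temperature operating temperature (degC).
#' @param aeration_cap air supply capacity of the aerobic tank
#'   (m^3 air min^-1; informational).
#' @param settler `settler_config`.
#' @param params `asm2d_params`.
#' @param scheme `fractionation_scheme` for influent conversion.
#' @return object of class `plant_config`.
#' @export
plant_config <- function(volumes = c(T0 = 1113, T1 = 1825, T2 = 5518,
                                     T3 = 7461, T4 = 472, T5 = 1433,
                                     T6 = 945),
                         kla = c(T3 = 248, T6 = 120),
                         Ql = 3.2, Qs = 1.0, Qw = 0.01,
                         recycle_from = "T4", recycle_to = "T2",
                         return_to = "T0",
                         so_sat = 8, temperature = 20,
                         aeration_cap = 98,
                         settler = settler_config(),
                         params = asm2d_params(),
                         scheme = fractionation_scheme()) {
  if (length(volumes) != 7L) stop("exactly 7 tank volumes are required")
  if (is.null(names(volumes))) names(volumes) <- paste0("T", 0:6)
  if (any(volumes <= 0)) stop("tank volumes must be > 0")
  if (any(c(Ql, Qs, Qw) < 0)) stop("flow ratios must be >= 0")
  kla_full <- stats::setNames(numeric(7), names(volumes))
  if (length(kla)) {
    if (!all(names(kla) %in% names(volumes)))
      stop("unknown tank in kla: ", paste(setdiff(names(kla),
                                                  names(volumes)),
                                          collapse = ", "))
    kla_full[names(kla)] <- kla
  }
  if (any(kla_full < 0)) stop("KLa must be >= 0")
  roles <- stats::setNames(.tank_roles, names(volumes))
  aerated <- kla_full > 0
  if (any(aerated & !(roles %in% c("aerobic", "post-aerobic"))))
    stop("only aerobic/post-aerobic tanks may be aerated")
  for (nm in c(recycle_from, recycle_to, return_to))
    if (!nm %in% names(volumes)) stop("unknown tank: ", nm)
  if (match(recycle_to, names(volumes)) >= match(recycle_from, names(volumes)))
    stop("internal recycle must be drawn downstream of its return point")
  structure(list(volumes = volumes, roles = roles, kla = kla_full,
                 Ql = Ql, Qs = Qs, Qw = Qw,
                 recycle_from = recycle_from, recycle_to = recycle_to,
                 return_to = return_to,
                 so_sat = so_sat, temperature = temperature,
                 aeration_cap = aeration_cap,
                 settler = settler, params = params, scheme = scheme),
            class = "plant_config")
}

#' Assemble the plant model
#'
#' Validates the configuration, precomputes the stoichiometric matrix and
#' index maps, and returns the flowsheet object used by
#' [simulate_plant()].
#'
#' @param cfg `plant_config`.
#' @return object of class `plant_model`.
#' @export
build_flowsheet <- function(cfg = plant_config()) {
  pm <- asm2d_stoichiometry(cfg$params)
  comps <- asm2d_components()
  sol <- asm2d_components(soluble_only = TRUE)
  n_layers <- cfg$settler$n_layers
  idx <- list(
    tanks = lapply(1:7, function(i) (i - 1L) * 19L + 1:19),
    settler_X = 7L * 19L + seq_len(n_layers),
    settler_S = 7L * 19L + n_layers +
      seq_len(n_layers * length(sol))
  )
  structure(list(cfg = cfg, pm = pm, comps = comps, sol = sol,
                 n_state = 7L * 19L + n_layers * (1L + length(sol)),
                 idx = idx,
                 i_from = match(cfg$recycle_from, names(cfg$volumes)),
                 i_to = match(cfg$recycle_to, names(cfg$volumes)),
                 i_ret = match(cfg$return_to, names(cfg$volumes))),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  cat("Modified-A2O plant:", length(x$cfg$volumes),
      "bioreactors + 10-layer settler\n")
  cat("  total bioreactor volume:", sum(x$cfg$volumes), "m^3\n")
  cat("  Ql =", x$cfg$Ql, " Qs =", x$cfg$Qs, " Qw =", x$cfg$Qw, "\n")
  invisible(x)
}

#' Node flows of the flowsheet for a given influent flow
#'
#' @param model `plant_model`; `Qin` influent flow (m^3 d^-1).
#' @return list with per-tank throughflow `Q_tank`, recycle `Q_int`,
#'   sludge return `Q_ret`, wastage `Q_was`, settler feed/effluent/
#'   underflow, and the largest node imbalance `balance`.
#' @export
plant_flows <- function(model, Qin) {
  cfg <- model$cfg
  Q_int <- cfg$Ql * Qin
  Q_ret <- cfg$Qs * Qin
  Q_was <- cfg$Qw * Qin
  Q_base <- Qin + Q_ret
  Q_tank <- rep(Q_base, 7)
  Q_tank[model$i_to:model$i_from] <- Q_base + Q_int
  Q_feed <- Q_base                     # settler feed (after recycle draw)
  Q_under <- Q_ret + Q_was
  Q_eff <- Q_feed - Q_under
  if (Q_eff < 0) stop("effluent flow negative: Qs + Qw too large")
  # node balances (all closed by construction; recomputed as a check)
  bal <- c(
    T0 = (Qin + Q_ret) - Q_tank[1],
    recycle_node = (Q_tank[model$i_to - 1L] + Q_int) - Q_tank[model$i_to],
    draw_node = Q_tank[model$i_from] - (Q_int + Q_tank[model$i_from + 1L]),
    settler = Q_feed - (Q_eff + Q_under),
    underflow = Q_under - (Q_ret + Q_was)
  )
  list(Q_in = Qin, Q_int = Q_int, Q_ret = Q_ret, Q_was = Q_was,
       Q_tank = Q_tank, Q_feed = Q_feed, Q_under = Q_under, Q_eff = Q_eff,
       balance = max(abs(bal)))
}

#' Default initial state of the plant
#'
#' Typical mixed-liquor composition in every tank and a thickened solids
#' profile in the settler.
#'
#' @param model `plant_model`.
#' @return numeric state vector for [simulate_plant()].
#' @export
plant_init_state <- function(model) {
  st <- asm2d_state(SO2 = 0.5, SF = 2, SA = 1, SNH4 = 8, SNO3 = 4,
                    SPO4 = 3, SI = 30, SALK = 5, SN2 = 15,
                    XI = 1200, XS = 80, XH = 2200, XPAO = 300, XPP = 90,
                    XPHA = 10, XAUT = 130, XTSS = 3600,
                    XMeOH = 0, XMeP = 0)
  y <- rep(as.numeric(st), 7)
  n_layers <- model$cfg$settler$n_layers
  # mild bottom-heavy solids profile
  Xs <- seq(50, 7000, length.out = n_layers)
  Ss <- matrix(rep(as.numeric(st[model$sol]), each = n_layers),
               n_layers, length(model$sol))
  c(y, Xs, as.numeric(Ss))
}

# split state vector into named pieces
.unpack_state <- function(model, y) {
  tanks <- matrix(y[1:(7 * 19)], nrow = 7, byrow = TRUE,
                  dimnames = list(names(model$cfg$volumes), model$comps))
  X <- y[model$idx$settler_X]
  S <- matrix(y[model$idx$settler_S], model$cfg$settler$n_layers,
              length(model$sol), dimnames = list(NULL, model$sol))
  list(tanks = tanks, X = X, S = S)
}

# particulate indices within the 19-component order
.part_idx <- function() which(!asm2d_soluble_flags())
.sol_idx <- function() which(asm2d_soluble_flags())

#' Plant derivative (reference R implementation)
#'
#' The compiled derivative used by [simulate_plant()] mirrors this
#' function; it is kept as the readable specification of the coupled
#' balance and as the oracle in equivalence tests.
#'
#' @param t time (d); `y` state vector; `model` `plant_model`;
#'   `inf_fun` function(t) returning `list(Q, z)` with the influent flow
#'   and the fractionated 19-component vector.
#' @return derivative vector.
#' @export
plant_derivs_r <- function(t, y, model, inf_fun) {
  cfg <- model$cfg
  y <- pmax(y, 0)
  st <- .unpack_state(model, y)
  inf <- inf_fun(t)
  fl <- plant_flows(model, inf$Q)
  sol_i <- .sol_idx(); part_i <- .part_idx()

  feed_tank <- st$tanks[7, ]
  X_feed <- tss_cod_groups(feed_tank)
  ratio <- function(Xl) if (X_feed > 1e-12) Xl / X_feed else 0
  n_layers <- cfg$settler$n_layers
  # underflow / effluent compositions
  under <- feed_tank
  under[sol_i] <- st$S[n_layers, ]
  under[part_i] <- feed_tank[part_i] * ratio(st$X[n_layers])

  dtanks <- matrix(0, 7, 19)
  for (i in 1:7) {
    if (i == 1) {
      Qin_i <- inf$Q + fl$Q_ret
      cin <- (inf$Q * inf$z + fl$Q_ret * under) / Qin_i
    } else {
      Q_up <- fl$Q_tank[i - 1]
      cin <- st$tanks[i - 1, ]
      Qin_i <- Q_up
      if (i == model$i_to) {
        cin <- (Q_up * cin + fl$Q_int * st$tanks[model$i_from, ]) /
          (Q_up + fl$Q_int)
        Qin_i <- Q_up + fl$Q_int
      }
      if (i == model$i_from + 1L) Qin_i <- fl$Q_tank[i]  # after recycle draw
    }
    dtanks[i, ] <- asm2d_reactor_derivatives(
      st$tanks[i, ], cin, Qin_i, cfg$volumes[i],
      KLa = cfg$kla[i], SO_sat = cfg$so_sat,
      params = cfg$params, temperature = cfg$temperature, pm = model$pm)
  }
  sd <- settler_derivatives(
    list(X = st$X, S = st$S), X_feed,
    stats::setNames(feed_tank[sol_i], model$sol),
    fl$Q_feed, fl$Q_under, fl$Q_eff, cfg$settler)
  c(as.numeric(t(dtanks)), sd$dX, as.numeric(sd$dS))
}

.interp1 <- function(tg, v, t) {
  if (length(tg) == 1L) return(rep(v[1], length(t)))
  stats::approx(tg, v, xout = t, rule = 2)$y
}

# fractionated influent on its native grid + interpolating closure,
# shared by the integrator and the balance checks
.plant_inf_grid <- function(model, influent) {
  cfg <- model$cfg
  zgrid <- t(vapply(seq_len(nrow(influent)), function(i)
    as.numeric(fractionate(influent[i, ], cfg$scheme, cfg$params)),
    numeric(19)))
  tgrid <- influent$time
  qgrid <- influent$flow
  inf_fun <- function(t) {
    list(Q = .interp1(tgrid, qgrid, t),
         z = vapply(1:19, function(j) .interp1(tgrid, zgrid[, j], t),
                    numeric(1)))
  }
  list(tgrid = tgrid, qgrid = qgrid, zgrid = zgrid, inf_fun = inf_fun)
}

#' Conservation-law residuals along a trajectory
#'
#' At every stored time the model derivative is re-evaluated (reference
#' implementation) and two instantaneous balances are formed: (a) a
#' non-reactive soluble tracer over the whole plant, d(stored mass)/dt
#' versus influent load minus effluent + wastage export, and (b) the
#' settler TSS balance, d(blanket inventory)/dt versus feed flux minus
#' underflow + overflow flux. Both residuals are reported relative to
#' the instantaneous inflow flux; for a structurally mass-conserving
#' model they close to numerical round-off at every point of any
#' trajectory.
#'
#' @param traj `plant_trajectory`.
#' @param tracer soluble non-reactive component (default `"SI"`).
#' @return list with `tracer` and `settler_tss`, each the maximum
#'   relative residual over the trajectory, plus the per-time vectors.
#' @export
plant_balance_check <- function(traj, tracer = "SI") {
  model <- traj$model
  cfg <- model$cfg
  if (!tracer %in% model$sol) stop("tracer must be a soluble component")
  ig <- .plant_inf_grid(model, traj$influent)
  ci <- match(tracer, model$comps)
  si <- match(tracer, model$sol)
  n_layers <- cfg$settler$n_layers
  v_layer <- cfg$settler$h * cfg$settler$area
  s_rows <- (si - 1L) * n_layers + seq_len(n_layers)
  nt <- length(traj$times)
  res_tr <- res_tss <- numeric(nt)
  for (i in seq_len(nt)) {
    t <- traj$times[i]
    y <- .traj_state(traj, i)
    dy <- plant_derivs_r(t, y, model, ig$inf_fun)
    inf <- ig$inf_fun(t)
    fl <- plant_flows(model, inf$Q)
    # (a) whole-plant tracer balance
    dM <- sum(vapply(1:7, function(k)
      cfg$volumes[k] * dy[model$idx$tanks[[k]][ci]], numeric(1))) +
      v_layer * sum(dy[model$idx$settler_S[s_rows]])
    S <- matrix(y[model$idx$settler_S], n_layers, length(model$sol))
    in_flux <- inf$Q * inf$z[ci]
    out_flux <- fl$Q_eff * S[1, si] + fl$Q_was * S[n_layers, si]
    res_tr[i] <- abs(dM - in_flux + out_flux) / max(in_flux, 1e-12)
    # (b) settler TSS balance
    X <- y[model$idx$settler_X]
    dX <- dy[model$idx$settler_X]
    feed_tank <- y[model$idx$tanks[[7]]]
    names(feed_tank) <- model$comps
    X_feed <- tss_cod_groups(feed_tank)
    f_in <- fl$Q_feed * X_feed
    f_out <- fl$Q_under * X[n_layers] + fl$Q_eff * X[1]
    res_tss[i] <- abs(v_layer * sum(dX) - f_in + f_out) / max(f_in, 1e-12)
  }
  list(tracer = max(res_tr), settler_tss = max(res_tss),
       tracer_series = res_tr, settler_tss_series = res_tss)
}

# parameter list for the compiled derivative
.plant_cpp_parms <- function(model, tgrid, qgrid, zgrid) {
  cfg <- model$cfg
  s <- cfg$settler
  list(nu = unname(model$pm$nu),
       kin = unname(asm2d_kinetic_values(cfg$params, cfg$temperature)),
       chem = c(unname(cfg$params$chemical),
                as.numeric(isTRUE(cfg$params$chemical_P))),
       volumes = unname(cfg$volumes), kla = unname(cfg$kla),
       so_sat = cfg$so_sat,
       Ql = cfg$Ql, Qs = cfg$Qs, Qw = cfg$Qw,
       i_from = model$i_from, i_to = model$i_to,
       settler = c(s$area, s$h, s$feed_layer, s$v0, s$v0_max,
                   s$r_h, s$r_p, s$f_ns, s$X_t, s$n_layers),
       tgrid = tgrid, qgrid = qgrid, zgrid = zgrid)
}

#' Simulate the plant over a dynamic influent
#'
#' Integrates the coupled reactor + settler system with a stiff-capable
#' solver (`deSolve::lsoda`). Negative excursions are clipped at the
#' derivative level (reported in the trajectory as `n_clip`).
#'
#' @param model `plant_model`.
#' @param influent `influent_series` (or a single record treated as
#'   constant influent).
#' @param init initial state vector (default [plant_init_state()]).
#' @param t_end end time (d); defaults to the influent horizon.
#' @param dt_out output step (d).
#' @param rtol,atol integrator tolerances.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @return object of class `plant_trajectory`: list with `times`,
#'   `tanks` (list of per-tank state matrices), `settler_X`, `settler_S`,
#'   `effluent` (19-component matrix), `composites` (effluent COD/TN/TP/
#'   NH4N/TSS), `flows`, `model`.
#' @export
simulate_plant <- function(model, influent, init = NULL, t_end = NULL,
                           dt_out = 0.05, rtol = 1e-5, atol = 1e-3,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- model$cfg
  if (!is.data.frame(influent))
    influent <- as.data.frame(influent)
  if (!"time" %in% names(influent)) influent$time <- 0
  if (is.null(t_end)) t_end <- max(influent$time)
  if (t_end <= 0) t_end <- max(influent$time, 1)
  if (is.null(init)) init <- plant_init_state(model)
  if (any(init < 0)) stop("initial state must be non-negative")
  # fractionate the influent once on its native grid
  ig <- .plant_inf_grid(model, influent)
  tgrid <- ig$tgrid; qgrid <- ig$qgrid; zgrid <- ig$zgrid
  interp1 <- .interp1
  inf_fun <- ig$inf_fun
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  if (engine == "cpp") {
    parms <- NULL
    plant_ctx_set(.plant_cpp_parms(model, tgrid, qgrid, zgrid))
    func <- function(t, y, p) list(plant_deriv_fast(t, y))
  } else {
    parms <- NULL
    func <- function(t, y, p) list(plant_derivs_r(t, y, model, inf_fun))
  }
  out <- deSolve::ode(y = init, times = times, func = func, parms = parms,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("plant integration failed at t = ",
         signif(out[nrow(out), 1], 6), " d")
  yout <- pmax(unname(out[, -1, drop = FALSE]), 0)
  tt <- out[, 1]
  n_layers <- cfg$settler$n_layers
  tanks <- lapply(1:7, function(i)
    `colnames<-`(yout[, model$idx$tanks[[i]], drop = FALSE], model$comps))
  names(tanks) <- names(cfg$volumes)
  X <- yout[, model$idx$settler_X, drop = FALSE]
  S <- yout[, model$idx$settler_S, drop = FALSE]
  sol_i <- .sol_idx(); part_i <- .part_idx()
  X_feed <- tss_cod_groups(tanks[[7]])
  r_eff <- ifelse(X_feed > 1e-12, X[, 1] / X_feed, 0)
  effluent <- tanks[[7]]
  effluent[, sol_i] <- S[, seq_len(length(model$sol)) * n_layers -
                           n_layers + 1L, drop = FALSE]
  effluent[, part_i] <- tanks[[7]][, part_i, drop = FALSE] * r_eff
  composites <- asm2d_composites(effluent, cfg$params)
  flows <- t(vapply(tt, function(t) {
    fl <- plant_flows(model, interp1(tgrid, qgrid, t))
    c(Q_in = fl$Q_in, Q_int = fl$Q_int, Q_ret = fl$Q_ret,
      Q_was = fl$Q_was, Q_eff = fl$Q_eff)
  }, numeric(5)))
  structure(list(times = tt, tanks = tanks, settler_X = X, settler_S = S,
                 effluent = effluent, composites = composites,
                 flows = as.data.frame(flows), influent = influent,
                 model = model),
            class = "plant_trajectory")
}

#' @export
print.plant_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("plant trajectory:", n, "time points over",
      signif(max(x$times), 4), "d\n")
  cat("  final effluent:",
      paste(sprintf("%s=%.2f", colnames(x$composites),
                    x$composites[n, ]), collapse = "  "), "\n")
  invisible(x)
}

#' Steady state of the plant under constant influent
#'
#' Pseudo-transient continuation: the system is integrated under frozen
#' influent until the state drift falls below `tol` (relative, per day).
#'
#' @param model `plant_model`.
#' @param influent_record single influent record (list with flow, COD,
#'   TN, TP, NH4N, SS).
#' @param tol relative drift tolerance (d^-1).
#' @param chunk integration horizon per check (d); `max_time` cap (d).
#' @param ... passed to [simulate_plant()].
#' @return list with `state` (vector), `tanks` (7 x 19), `settler_X`,
#'   `settler_S`, `residual` (achieved drift), `converged`.
#' @export
steady_state_plant <- function(model, influent_record, tol = 1e-6,
                               chunk = 50, max_time = 800, ...) {
  rec <- as.data.frame(influent_record)
  rec$time <- 0
  y <- plant_init_state(model)
  t_done <- 0
  resid <- Inf
  while (t_done < max_time) {
    traj <- simulate_plant(model, rec, init = y, t_end = chunk,
                           dt_out = chunk / 2, ...)
    n <- length(traj$times)
    y_new <- .traj_state(traj, n)
    dt <- traj$times[n] - traj$times[n - 1]
    resid <- max(abs(y_new - .traj_state(traj, n - 1)) /
                   pmax(abs(y_new), 1)) / dt
    y <- y_new
    t_done <- t_done + chunk
    if (resid < tol) break
  }
  if (resid >= tol)
    warning("steady state not reached: residual drift ", signif(resid, 3),
            " d^-1 after ", t_done, " d")
  st <- .unpack_state(model, y)
  list(state = y, tanks = st$tanks, settler_X = st$X, settler_S = st$S,
       residual = resid, converged = resid < tol)
}

# reassemble the flat state vector from a trajectory row
.traj_state <- function(traj, i) {
  model <- traj$model
  y <- numeric(model$n_state)
  for (k in 1:7) y[model$idx$tanks[[k]]] <- traj$tanks[[k]][i, ]
  y[model$idx$settler_X] <- traj$settler_X[i, ]
  y[model$idx$settler_S] <- traj$settler_S[i, ]
  y
}

#' Check effluent limit compliance
#'
#' @param traj `plant_trajectory` (or a composite matrix with columns
#'   COD/TN/NH4N/TP and an attached `times` attribute).
#' @param limits named vector of effluent limits (g m^-3).
#' @param warmup initial period excluded from the assessment (d).
#' @return list: `violation_fraction` per indicator (fraction of time in
#'   violation), `feasible` (no violation anywhere), `worst_excess`
#'   (max concentration / limit - 1, clipped at 0).
#' @export
effluent_limits_check <- function(traj,
                                  limits = c(COD = 50, TN = 15,
                                             NH4N = 5, TP = 0.5),
                                  warmup = 0) {
  comp <- traj$composites
  keep <- traj$times >= warmup
  comp <- comp[keep, , drop = FALSE]
  tt <- traj$times[keep]
  w <- c(diff(tt), 0)
  w[length(w)] <- w[max(1, length(w) - 1)]
  w <- w / sum(w)
  vf <- vapply(names(limits), function(ind)
    sum(w * (comp[, ind] > limits[[ind]])), numeric(1))
  excess <- vapply(names(limits), function(ind)
    max(0, max(comp[, ind]) / limits[[ind]] - 1), numeric(1))
  list(violation_fraction = vf, feasible = all(vf == 0),
       worst_excess = excess, limits = limits)
}

#' Export a plant trajectory
#'
#' Writes per-tank states to CSV (`<stem>_tank<k>.csv`), the effluent
#' composites to `<stem>_effluent.csv`, and a JSON summary.
#'
#' @param traj `plant_trajectory`; `stem` output path stem.
#' @return invisibly, the files written.
#' @export
export_trajectory <- function(traj, stem) {
  files <- character(0)
  for (k in seq_along(traj$tanks)) {
    f <- paste0(stem, "_tank", k - 1, ".csv")
    utils::write.csv(data.frame(time = traj$times, traj$tanks[[k]],
                                check.names = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- paste0(stem, "_effluent.csv")
  utils::write.csv(data.frame(time = traj$times, traj$composites,
                              check.names = FALSE),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  summ <- list(t_end = max(traj$times),
               mean_effluent = as.list(colMeans(traj$composites)),
               final_effluent = as.list(
                 traj$composites[length(traj$times), ]))
  fj <- paste0(stem, "_summary.json")
  jsonlite::write_json(summ, fj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fj))
}
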