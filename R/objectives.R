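# Optimization objectives: mean quality of effluent (MQE), total cost
# index (TCI = aeration + pumping energy + 5 x sludge production) and
# overall volume (OV), plus the evaluation of a 12-variable operating/
# design decision vector into a minimization triple via plant simulation.

# trapezoidal quadrature on a (possibly non-uniform) grid
.trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Mean quality of effluent
#'
#' Average relative deviation of a simulated effluent series from a
#' reference ("actual") series, `MQE = (1/n) sum (C_act - C_sim)/C_act`
#' over all indicator x time points. Positive values mean the simulated
#' effluent is cleaner than the reference; negative values are possible
#' and meaningful.
#'
#' @param actual,simulated aligned numeric vectors or matrices
#'   (time x indicator) of effluent concentrations.
#' @param on_zero `"skip"` (drop zero-reference points with a warning) or
#'   `"error"`.
#' @return dimensionless scalar.
#' @export
mqe <- function(actual, simulated, on_zero = c("skip", "error")) {
  on_zero <- match.arg(on_zero)
  a <- as.numeric(actual); s <- as.numeric(simulated)
  if (length(a) != length(s))
    stop("actual and simulated series must be aligned")
  zero <- a == 0
  if (any(zero)) {
    if (on_zero == "error") stop("zero reference concentration in MQE")
    warning(sum(zero), " zero-reference point(s) skipped in MQE")
    a <- a[!zero]; s <- s[!zero]
  }
  if (!length(a)) stop("no usable points for MQE")
  mean((a - s) / a)
}

#' Pumping energy
#'
#' `EP = 0.04 / T * integral(Qh + Qw + Qs) dt` (kWh d^-1) with
#' trapezoidal quadrature; `Qh` is the internal recirculation flow, `Qw`
#' the wastage flow and `Qs` the sludge return flow (m^3 d^-1).
#'
#' @param times quadrature grid (d); scalars are accepted for the flows
#'   and recycled along it.
#' @param Qh,Qw,Qs flow series (m^3 d^-1).
#' @return kWh d^-1.
#' @export
pumping_energy <- function(times, Qh, Qw, Qs) {
  n <- length(times)
  if (n < 2) stop("need at least two time points")
  q <- rep_len(Qh, n) + rep_len(Qw, n) + rep_len(Qs, n)
  if (any(q < 0)) stop("flows must be non-negative")
  T_ <- times[n] - times[1]
  0.04 / T_ * .trapz(times, q)
}

#' Aeration energy
#'
#' Implemented exactly in the printed form
#' `EA = 24/(t2 - t1) * integral( Qin(t)^-1 * sum_i [0.3267 KLa_i (T_i/Tref_i)
#' + 0.0007 KLa_i^2 (T_i/Tref_i)] ) dt`, where the sum runs over the
#' configured aerated tanks. The `T_i/Tref` multiplier is applied
#' literally as a dimensionless factor; `Tref` defaults to the tank
#' volumes themselves so the multiplier is 1 at the baseline design.
#'
#' @param times quadrature grid (d).
#' @param Qin influent flow series (m^3 d^-1); must be positive
#'   everywhere.
#' @param kla named or plain vector of KLa values (d^-1), one per aerated
#'   tank (constant in time).
#' @param volumes aerated-tank volumes `T_i` (m^3), aligned with `kla`.
#' @param Tref reference volume(s); scalar or aligned vector, default
#'   `volumes`.
#' @return kWh d^-1 (as-printed formula units).
#' @export
aeration_energy <- function(times, Qin, kla, volumes, Tref = volumes) {
  n <- length(times)
  if (n < 2) stop("need at least two time points")
  if (length(kla) != length(volumes))
    stop("kla and volumes must be aligned")
  if (any(kla < 0)) stop("KLa must be non-negative")
  if (any(Tref <= 0)) stop("Tref must be positive")
  Qin <- rep_len(Qin, n)
  if (any(Qin <= 0)) stop("Qin must be positive on the quadrature grid")
  ratio <- volumes / rep_len(Tref, length(volumes))
  tank_sum <- sum(0.3267 * kla * ratio + 0.0007 * kla^2 * ratio)
  T_ <- times[n] - times[1]
  24 / T_ * .trapz(times, tank_sum / Qin)
}

# particulate COD groups entering the TSS proxy (ASM1-style naming:
# ZI = XI, ZS = XS, ZP = XPP + XPHA, ZBH = XH, ZBA = XPAO + XAUT)
.z_components <- c("XI", "XS", "XPP", "XPHA", "XH", "XPAO", "XAUT")

#' Reactor TSS inventory
#'
#' `TSSr = 0.75 * sum_j V_j * (ZI + ZS + ZP + ZBH + ZBA)_j` in kg. The
#' sum runs over all configured bioreactors by default; a restricted
#' tank subset can be supplied.
#'
#' @param tanks 7 x 19 matrix of tank states (rows named by tank,
#'   columns by component) or a list of named state vectors.
#' @param volumes named tank volumes (m^3).
#' @param tanks_used names of the tanks included (default: all).
#' @return kg.
#' @export
reactor_tss_inventory <- function(tanks, volumes,
                                  tanks_used = names(volumes)) {
  if (is.list(tanks) && !is.matrix(tanks))
    tanks <- do.call(rbind, tanks)
  z <- rowSums(tanks[, .z_components, drop = FALSE])
  sum(volumes[tanks_used] * z[tanks_used]) * 0.75 / 1000
}

#' Sludge production rate
#'
#' `SG = T^-1 * (TSS_final - TSS_first + 0.75 * integral(Z_w * Qw) dt)`
#' in kg SS d^-1, where `Z_w` is the particulate COD group sum of the
#' wasted sludge (g m^-3) and `Qw` the wastage flow (m^3 d^-1).
#'
#' @param tss_first,tss_final reactor TSS inventory at the period start
#'   and end (kg).
#' @param times quadrature grid (d).
#' @param z_wastage particulate COD group sum of the wastage stream
#'   (g m^-3), series or scalar.
#' @param Qw wastage flow series or scalar (m^3 d^-1).
#' @return kg SS d^-1.
#' @export
sludge_production <- function(tss_first, tss_final, times, z_wastage, Qw) {
  n <- length(times)
  if (n < 2) stop("need at least two time points")
  T_ <- times[n] - times[1]
  if (T_ <= 0) stop("period length must be positive")
  wasted <- .trapz(times, rep_len(z_wastage, n) * rep_len(Qw, n)) / 1000
  (tss_final - tss_first + 0.75 * wasted) / T_
}

#' Total cost index
#'
#' `TCI = EA + EP + 5 * SG` (kWh d^-1 equivalent; sludge weighted by 5).
#'
#' @param EA aeration energy (kWh d^-1); `EP` pumping energy (kWh d^-1);
#'   `SG` sludge production (kg SS d^-1).
#' @return scalar.
#' @export
total_cost_index <- function(EA, EP, SG) {
  if (any(c(EA, EP, SG) < 0)) stop("cost components must be non-negative")
  EA + EP + 5 * SG
}

#' Energy and sludge breakdown of a plant trajectory
#'
#' Evaluates the pumping-energy, aeration-energy and sludge-production
#' terms over `[warmup, t_end]` of a simulated trajectory.
#'
#' @param traj `plant_trajectory`.
#' @param warmup initial period excluded (d).
#' @param tss_tanks tank names entering the reactor TSS inventory
#'   (default: all seven).
#' @param Tref reference volume(s) for [aeration_energy()]; default: the
#'   aerated-tank volumes of the trajectory's own model (multiplier 1).
#' @return list `EP`, `EA`, `SG`, `TCI`, `TSS_first`, `TSS_final` of
#'   class `energy_breakdown`.
#' @export
energy_breakdown <- function(traj, warmup = 0, tss_tanks = NULL,
                             Tref = NULL) {
  cfg <- traj$model$cfg
  keep <- traj$times >= warmup
  if (sum(keep) < 2) stop("fewer than two time points after warmup")
  tt <- traj$times[keep]
  fl <- traj$flows[keep, , drop = FALSE]
  EP <- pumping_energy(tt, fl$Q_int, fl$Q_was, fl$Q_ret)
  aer <- names(cfg$kla)[cfg$kla > 0]
  if (is.null(Tref)) Tref <- cfg$volumes[aer]
  EA <- aeration_energy(tt, fl$Q_in, cfg$kla[aer], cfg$volumes[aer], Tref)
  if (is.null(tss_tanks)) tss_tanks <- names(cfg$volumes)
  snap <- function(i) {
    st <- do.call(rbind, lapply(traj$tanks, function(m) m[i, ]))
    reactor_tss_inventory(st, cfg$volumes, tss_tanks)
  }
  i0 <- which(keep)[1]; i1 <- which(keep)[sum(keep)]
  tss0 <- snap(i0); tss1 <- snap(i1)
  # wastage carries the settler underflow composition
  n_layers <- cfg$settler$n_layers
  X_feed <- tss_cod_groups(traj$tanks[[7]][keep, , drop = FALSE])
  r_under <- ifelse(X_feed > 1e-12,
                    traj$settler_X[keep, n_layers] / X_feed, 0)
  z_w <- rowSums(traj$tanks[[7]][keep, .z_components, drop = FALSE]) *
    r_under
  SG <- sludge_production(tss0, tss1, tt, z_w, fl$Q_was)
  structure(list(EP = EP, EA = EA, SG = SG,
                 TCI = total_cost_index(EA, EP, max(0, SG)),
                 TSS_first = tss0, TSS_final = tss1),
            class = "energy_breakdown")
}

#' Decision-vector bounds
#'
#' The 12 operating/design variables: recirculation ratio `Ql`, sludge
#' return ratio `Qs`, wastage ratio `Qw`, the two aeration coefficients
#' `KLa1` (aerobic) and `KLa2` (post-aerobic), and the seven tank volumes
#' `T1..T7`. Default volume bounds span 0.5-1.5 x the baseline design.
#'
#' @param cfg `plant_config` supplying the baseline volumes.
#' @return 2 x 12 matrix with rows `lower`, `upper`.
#' @export
decision_bounds <- function(cfg = plant_config()) {
  v <- unname(cfg$volumes)
  lower <- c(Ql = 0.5, Qs = 0.5, Qw = 0.002, KLa1 = 60, KLa2 = 30,
             setNames(0.5 * v, paste0("T", 1:7)))
  upper <- c(Ql = 5.0, Qs = 2.0, Qw = 0.05, KLa1 = 360, KLa2 = 240,
             setNames(1.5 * v, paste0("T", 1:7)))
  rbind(lower = lower, upper = upper)
}

#' Apply a decision vector to a plant configuration
#'
#' @param x named length-12 vector (see [decision_bounds()]).
#' @param cfg baseline `plant_config`.
#' @return new `plant_config`.
#' @export
decision_plant <- function(x, cfg = plant_config()) {
  nm <- colnames(decision_bounds(cfg))
  if (length(x) != 12) stop("decision vector must have length 12")
  x <- setNames(as.numeric(x), nm)
  vols <- setNames(x[paste0("T", 1:7)], names(cfg$volumes))
  kla <- cfg$kla
  aer <- names(kla)[kla > 0]
  kla[aer[1]] <- x[["KLa1"]]
  if (length(aer) > 1) kla[aer[2]] <- x[["KLa2"]]
  plant_config(volumes = vols, kla = kla[kla > 0],
               Ql = x[["Ql"]], Qs = x[["Qs"]], Qw = x[["Qw"]],
               recycle_from = cfg$recycle_from, recycle_to = cfg$recycle_to,
               return_to = cfg$return_to, so_sat = cfg$so_sat,
               temperature = cfg$temperature,
               aeration_cap = cfg$aeration_cap, settler = cfg$settler,
               params = cfg$params, scheme = cfg$scheme)
}

#' Optimization scenario
#'
#' Bundles the influent series, the baseline (reference) effluent that
#' plays the role of the "actual" series in the MQE, the warmup period
#' and the effluent limits used for feasibility.
#'
#' @param influent `influent_series`.
#' @param base_cfg baseline `plant_config`.
#' @param warmup warmup period excluded from objective quadrature (d).
#' @param limits effluent limits for the feasibility check.
#' @param indicators composite columns entering the MQE.
#' @param ... passed to [simulate_plant()] (tolerances etc.).
#' @return object of class `plant_scenario` (baseline trajectory
#'   included).
#' @export
make_scenario <- function(influent, base_cfg = plant_config(),
                          warmup = 2,
                          limits = c(COD = 50, TN = 15, NH4N = 5, TP = 0.5),
                          indicators = c("COD", "TN", "NH4N", "TP"), ...) {
  model <- build_flowsheet(base_cfg)
  baseline <- simulate_plant(model, influent, ...)
  structure(list(influent = influent, base_cfg = base_cfg,
                 baseline = baseline, warmup = warmup, limits = limits,
                 indicators = indicators, sim_args = list(...)),
            class = "plant_scenario")
}

#' Evaluate a decision vector
#'
#' Builds the plant described by `x`, simulates it over the scenario
#' influent and returns the minimization triple `(-MQE, TCI, OV)` with a
#' feasibility flag from the effluent-limit check (constraint-domination
#' material). A failed simulation yields an infeasible result with
#' worst-case objectives.
#'
#' @param x length-12 decision vector.
#' @param scenario `plant_scenario` from [make_scenario()].
#' @return object of class `objective_triple`: list with `objectives`
#'   (minimization triple), `mqe`, `tci`, `ov`, `feasible`, `violation`,
#'   `breakdown`.
#' @export
evaluate_decision <- function(x, scenario) {
  sc <- scenario
  ov <- sum(x[6:12])
  res <- tryCatch({
    cfg <- decision_plant(x, sc$base_cfg)
    model <- build_flowsheet(cfg)
    traj <- do.call(simulate_plant,
                    c(list(model = model, influent = sc$influent),
                      sc$sim_args))
    keep <- traj$times >= sc$warmup
    m <- mqe(sc$baseline$composites[keep, sc$indicators],
             traj$composites[keep, sc$indicators])
    br <- energy_breakdown(traj, warmup = sc$warmup)
    lim <- effluent_limits_check(traj, sc$limits, warmup = sc$warmup)
    list(mqe = m, tci = br$TCI, feasible = lim$feasible,
         violation = sum(lim$worst_excess), breakdown = br)
  }, error = function(e) {
    warning("decision evaluation failed: ", conditionMessage(e))
    list(mqe = -Inf, tci = Inf, feasible = FALSE, violation = Inf,
         breakdown = NULL)
  })
  structure(list(objectives = c(neg_mqe = -res$mqe, tci = res$tci,
                                ov = ov),
                 mqe = res$mqe, tci = res$tci, ov = ov,
                 feasible = res$feasible, violation = res$violation,
                 breakdown = res$breakdown),
            class = "objective_triple")
}
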