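# One-dimensional ten-layer Takacs secondary settler.
#
# Solids settle with the double-exponential velocity law and move between
# layers by the standard flux-limited balance; soluble components are
# ideally advected (no reaction in the settler). Layers are numbered from
# the top: layer 1 feeds the effluent, layer `n_layers` the underflow.

#' Settler configuration
#'
#' Double-exponential settling parameters default to the widely used
#' benchmark-simulation (BSM1) values; geometry defaults to a 1500 m^2,
#' 4 m deep clarifier. The model uses 10 layers.
#'
#' @param area cross-sectional area (m^2).
#' @param height total settler depth (m).
#' @param n_layers number of layers (the flux balance is written for 10).
#' @param feed_layer index of the feed layer, counted from the top.
#' @param v0 maximum theoretical settling velocity (m d^-1).
#' @param v0_max maximum practical settling velocity (m d^-1).
#' @param r_h hindered-settling parameter (m^3 g^-1).
#' @param r_p flocculant-settling parameter (m^3 g^-1).
#' @param f_ns non-settleable fraction of the feed solids.
#' @param X_t threshold solids concentration for the clarification-zone
#'   flux limitation (g m^-3).
#' @return object of class `settler_config`.
#' @export
settler_config <- function(area = 1500, height = 4, n_layers = 10,
                           feed_layer = 5, v0 = 474, v0_max = 250,
                           r_h = 5.76e-4, r_p = 2.86e-3,
                           f_ns = 2.28e-3, X_t = 3000) {
  if (area <= 0) stop("settler area must be > 0")
  if (n_layers != 10L) stop("the layered flux balance is defined for 10 layers")
  if (feed_layer < 1 || feed_layer > n_layers)
    stop("feed layer out of range")
  structure(list(area = area, height = height, n_layers = as.integer(n_layers),
                 h = height / n_layers, feed_layer = as.integer(feed_layer),
                 v0 = v0, v0_max = v0_max, r_h = r_h, r_p = r_p,
                 f_ns = f_ns, X_t = X_t),
            class = "settler_config")
}

#' Takacs double-exponential settling velocity
#'
#' `v_s = max(0, min(v0_max, v0 (exp(-r_h X*) - exp(-r_p X*))))` with
#' `X* = X - f_ns X_feed` the settleable solids.
#'
#' @param X layer solids concentration (g m^-3), vectorized.
#' @param cfg `settler_config`.
#' @param X_feed feed solids concentration (g m^-3).
#' @return settling velocity (m d^-1), in `[0, v0_max]`.
#' @export
settling_velocity <- function(X, cfg = settler_config(), X_feed = 0) {
  if (any(X < 0)) stop("solids concentration must be >= 0")
  Xs <- X - cfg$f_ns * X_feed
  pmax(0, pmin(cfg$v0_max, cfg$v0 * (exp(-cfg$r_h * Xs) - exp(-cfg$r_p * Xs))))
}

#' Initial settler state
#'
#' @param cfg `settler_config`.
#' @param X uniform initial solids (g m^-3); `S` named vector of initial
#'   soluble concentrations (defaults to 0 for the 9 ASM2d solubles).
#' @return list with `X` (length 10) and `S` (10 x 9 matrix), class
#'   `settler_state`.
#' @export
settler_state <- function(cfg = settler_config(), X = 0, S = NULL) {
  sol <- asm2d_components(soluble_only = TRUE)
  Sm <- matrix(0, cfg$n_layers, length(sol), dimnames = list(NULL, sol))
  if (!is.null(S)) Sm[, names(S)] <- rep(S, each = cfg$n_layers)
  structure(list(X = rep(X, length.out = cfg$n_layers), S = Sm),
            class = "settler_state")
}

# settling flux between consecutive layers with the Takacs limitation:
# below (and at) the feed layer the flux is limited by the receiving
# layer; above the feed it is limited only when the layer below exceeds
# the threshold X_t.
.settler_fluxes <- function(X, cfg, X_feed) {
  n <- cfg$n_layers
  m <- cfg$feed_layer
  vs <- settling_velocity(X, cfg, X_feed)
  J <- vs * X                       # unconstrained flux out of each layer
  Js <- numeric(n - 1)              # flux from layer i to i+1
  for (i in seq_len(n - 1)) {
    if (i < m) {
      Js[i] <- if (X[i + 1] <= cfg$X_t) J[i] else min(J[i], J[i + 1])
    } else {
      Js[i] <- min(J[i], J[i + 1])
    }
  }
  Js
}

#' Settler layer derivatives
#'
#' Flux-limited solids balance plus ideal advection of the soluble
#' components. The feed enters at `cfg$feed_layer`; bulk flow is upward
#' above the feed (to the effluent) and downward below it (to the
#' underflow).
#'
#' @param state `settler_state`.
#' @param X_feed feed solids concentration (g m^-3).
#' @param S_feed named vector of feed soluble concentrations (g m^-3).
#' @param Q_feed,Q_under,Q_eff feed, underflow and effluent flows
#'   (m^3 d^-1); `Q_feed` must equal `Q_under + Q_eff`.
#' @param cfg `settler_config`.
#' @return list with `dX` (length 10) and `dS` (10 x n_sol) derivatives
#'   (g m^-3 d^-1).
#' @export
settler_derivatives <- function(state, X_feed, S_feed, Q_feed, Q_under,
                                Q_eff, cfg = settler_config()) {
  if (any(c(Q_feed, Q_under, Q_eff) < 0)) stop("flows must be >= 0")
  if (abs(Q_feed - (Q_under + Q_eff)) > 1e-8 * max(1, Q_feed))
    stop("settler flow imbalance: Q_feed must equal Q_under + Q_eff")
  n <- cfg$n_layers; m <- cfg$feed_layer; h <- cfg$h; A <- cfg$area
  v_up <- Q_eff / A
  v_dn <- Q_under / A
  X <- state$X
  Js <- .settler_fluxes(X, cfg, X_feed)
  dX <- numeric(n)
  for (i in seq_len(n)) {
    adv <- if (i < m) v_up * ((if (i < n) X[i + 1] else 0) - X[i])
           else if (i == m) Q_feed * X_feed / A - (v_up + v_dn) * X[i]
           else v_dn * (X[i - 1] - X[i])
    setl <- (if (i > 1) Js[i - 1] else 0) - (if (i < n) Js[i] else 0)
    dX[i] <- (adv + setl) / h
  }
  S <- state$S
  Sf <- if (is.null(colnames(S))) S_feed else S_feed[colnames(S)]
  if (length(Sf) != ncol(S) || anyNA(Sf))
    stop("S_feed must supply one concentration per soluble column")
  dS <- matrix(0, n, ncol(S), dimnames = dimnames(S))
  for (i in seq_len(n)) {
    dS[i, ] <- if (i < m) v_up * (S[i + 1, ] - S[i, ]) / h
               else if (i == m) (Q_feed * Sf / A - (v_up + v_dn) * S[i, ]) / h
               else v_dn * (S[i - 1, ] - S[i, ]) / h
  }
  list(dX = dX, dS = dS)
}

#' Solids inventory of the settler (kg)
#'
#' Sum over the 10 layers of layer volume times solids, where the layer
#' solids are 0.75 times the summed particulate COD groups (inert,
#' slowly biodegradable, storage products, heterotrophic and autotrophic
#' biomass). If the state already carries TSS (`X`), the 0.75 factor has
#' been applied upstream.
#'
#' @param state `settler_state` (uses `state$X` in g m^-3 as TSS).
#' @param cfg `settler_config`.
#' @return inventory in kg.
#' @export
settler_tss_inventory <- function(state, cfg = settler_config()) {
  sum(cfg$h * cfg$area * state$X) / 1000
}

#' TSS from particulate COD groups
#'
#' The solids accounting used throughout the cost model: 0.75 times the
#' sum of the particulate COD components mapped to the classical groups
#' (inert ZI = XI, substrate ZS = XS, storage products ZP = XPP + XPHA,
#' heterotrophs ZBH = XH, autotrophs + PAO ZBA = XPAO + XAUT).
#'
#' @param state ASM2d state vector or matrix with named columns.
#' @return TSS (g m^-3).
#' @export
tss_cod_groups <- function(state) {
  comps <- c("XI", "XS", "XPP", "XPHA", "XH", "XPAO", "XAUT")
  if (is.matrix(state)) 0.75 * rowSums(state[, comps, drop = FALSE])
  else 0.75 * sum(state[comps])
}
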