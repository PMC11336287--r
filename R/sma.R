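# Slime mould algorithm (SMA) primitives and the single-objective
# improved variant ISMA (SMA + opposition-based learning + Levy flight).
# All randomness is drawn from an isolated rng_stream so runs are
# bit-reproducible under a fixed seed.

#' Levy-flight configuration
#'
#' @param beta stability index in (0, 2]; `s` fixed step scale.
#' @param mode `"multiplicative"` (position times the Levy draw, the
#'   printed form) or `"additive"` (position plus the Levy step) —
#'   the multiplicative form cannot escape an all-zero position.
#' @return list of class `levy_config`.
#' @export
levy_config <- function(beta = 1.5, s = 0.01,
                        mode = c("multiplicative", "additive")) {
  if (beta <= 0 || beta > 2) stop("beta must lie in (0, 2]")
  if (s < 0) stop("s must be >= 0")
  structure(list(beta = beta, s = s, mode = match.arg(mode)),
            class = "levy_config")
}

#' Mantegna sigma constant
#'
#' `sigma = [Gamma(1+beta) sin(pi beta/2) /
#' (Gamma((1+beta)/2) beta 2^((beta-1)/2))]^(1/beta)`.
#'
#' @param beta stability index.
#' @return scalar; approximately 0.6966 at `beta = 1.5`.
#' @export
levy_sigma <- function(beta = 1.5) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Adaptive SMA weights
#'
#' The elite (better) half of the population receives
#' `1 + r log10((FO - C_i)/(FO - wO) + 1)` and the remaining half
#' `1 - r log10(...)`, with `FO`/`wO` the best/worst objective values
#' and `r ~ U(0,1)` per individual. When all objective values coincide
#' the weight is 1 for everyone (degenerate fallback).
#'
#' @param C objective values (minimization).
#' @param rng `rng_stream`.
#' @param log_base logarithm base (default 10).
#' @return weight vector aligned with `C`.
#' @export
sma_weights <- function(C, rng, log_base = 10) {
  n <- length(C)
  if (!n) stop("empty population")
  FO <- min(C); wO <- max(C)
  if (FO == wO) return(rep(1, n))
  sid <- order(C)
  r <- rng_unif(rng, n)
  term <- r * log((FO - C[sid]) / (FO - wO) + 1, base = log_base)
  W <- numeric(n)
  elite <- seq_len(ceiling(n / 2))
  W[sid[elite]] <- 1 + term[elite]
  W[sid[-elite]] <- 1 - term[-elite]
  W
}

#' SMA position update
#'
#' Per individual: with probability `z` a uniform re-draw in the bounds;
#' otherwise every dimension `j` independently takes the approach move
#' `yb_j + kb (W_i yD_j - yE_j)` when `p_i = tanh|C_i - DO| > r_j`
#' (with `kb ~ U(-a, a)`, `a = arctanh(1 - t/t_max)`, and `yD`, `yE`
#' re-drawn per dimension) and the contraction `kc y_j` with
#' `kc = 1 - t/t_max` otherwise. The per-dimension branching acts as a
#' uniform crossover between the leader and the contracted self.
#' All positions are clamped to the bounds.
#'
#' @param pop N x D position matrix; `C` objective values; `yb` best
#'   position; `DO` best objective value; `W` weights from
#'   [sma_weights()].
#' @param t current iteration (1-based); `t_max` iteration budget.
#' @param lower,upper bounds (length D).
#' @param z re-draw probability (default 0.03).
#' @param rng `rng_stream`.
#' @return new N x D position matrix.
#' @export
sma_move <- function(pop, C, yb, DO, W, t, t_max, lower, upper,
                     z = 0.03, rng) {
  if (t > t_max) stop("iteration t exceeds t_max")
  n <- nrow(pop); D <- ncol(pop)
  a <- atanh(max(0, 1 - t / t_max))
  kc <- 1 - t / t_max
  p <- tanh(abs(C - DO))
  u_z <- rng_unif(rng, n)
  R <- matrix(rng_unif(rng, n * D), n, D)
  KB <- matrix(rng_unif(rng, n * D) * 2 - 1, n, D) * a
  A <- ceiling(rng_unif(rng, n * D) * n)
  B <- ceiling(rng_unif(rng, n * D) * n)
  colix <- rep(seq_len(D), each = n)
  Amat <- matrix(pop[cbind(A, colix)], n, D)
  Bmat <- matrix(pop[cbind(B, colix)], n, D)
  Yb <- matrix(yb, n, D, byrow = TRUE)
  approach <- Yb + KB * (W * Amat - Bmat)
  out <- ifelse(R < p, approach, kc * pop)
  z_rows <- which(u_z < z)
  if (length(z_rows)) {
    redraw <- matrix(rng_unif(rng, length(z_rows) * D),
                     length(z_rows), D)
    out[z_rows, ] <- sweep(sweep(redraw, 2, upper - lower, "*"),
                           2, lower, "+")
  }
  out[] <- pmin(rep(upper, each = n), pmax(rep(lower, each = n), out))
  out
}

#' Opposition-based learning mirror
#'
#' `y'_j = upper_j + lower_j - y_j` per dimension (an involution; the
#' caller keeps the better of the pair).
#'
#' @param y position vector (or matrix of rows).
#' @param upper,lower bounds.
#' @return mirrored position(s).
#' @export
obl_opposite <- function(y, upper, lower) {
  if (is.matrix(y))
    sweep(-y, 2, upper + lower, "+")
  else
    upper + lower - y
}

#' Levy-flight move
#'
#' Per-dimension Mantegna step `s * sigma * u / |v|^(1/beta)` with
#' standard-normal `u`, `v`; applied to `yb` multiplicatively (printed
#' form) or additively, then clamped.
#'
#' @param yb base position; `lower`, `upper` bounds.
#' @param cfg `levy_config`; `rng` `rng_stream`.
#' @return new position.
#' @export
levy_step <- function(yb, lower, upper, cfg = levy_config(), rng) {
  D <- length(yb)
  u <- rng_norm(rng, D); v <- rng_norm(rng, D)
  step <- cfg$s * levy_sigma(cfg$beta) * u / abs(v)^(1 / cfg$beta)
  y <- if (cfg$mode == "multiplicative") yb * step else yb + step
  pmin(upper, pmax(lower, y))
}

#' Logistic chaos sequence
#'
#' `M(t+1) = 4 M(t) (1 - M(t))`; the seed must avoid the fixed/periodic
#' points 0.25, 0.5, 0.75 and 1.
#'
#' @param M0 seed in (0, 1) excluding the forbidden set.
#' @param n sequence length.
#' @return numeric vector in [0, 1].
#' @export
logistic_chaos_sequence <- function(M0, n) {
  if (M0 <= 0 || M0 >= 1 || M0 %in% c(0.25, 0.5, 0.75))
    stop("chaos seed must lie in (0,1) and avoid {0.25, 0.5, 0.75, 1}")
  out <- numeric(n)
  m <- M0
  for (i in seq_len(n)) {
    m <- 4 * m * (1 - m)
    out[i] <- m
  }
  out
}

#' One-dimensional chaos perturbation
#'
#' Replaces dimension `j` of `y` by `lower_j + M (upper_j - lower_j)`;
#' all other coordinates are untouched.
#'
#' @param y position; `j` dimension index; `M` chaos value in [0, 1];
#'   `lower`, `upper` bounds.
#' @return perturbed position.
#' @export
chaos_perturb <- function(y, j, M, lower, upper) {
  if (j < 1 || j > length(y)) stop("invalid dimension")
  if (M < 0 || M > 1) stop("chaos value must lie in [0, 1]")
  y[j] <- lower[j] + M * (upper[j] - lower[j])
  y
}

#' ISMA: improved slime mould algorithm (single-objective)
#'
#' Per individual per iteration one of three branches is drawn: the SMA
#' position update (probability 0.9), the opposition-based mirror
#' (0.05) or a Levy flight from the global best (0.05). Every candidate
#' is kept only if it improves on the individual's current value
#' (greedy elitism), so the best-so-far curve is non-increasing.
#'
#' @param fn objective function of a length-D vector (minimized). `NaN`
#'   values are treated as worst.
#' @param lower,upper bounds (length D).
#' @param N population size (>= 4); `t_max` iterations; `z` re-draw
#'   probability; `levy` a [levy_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class `isma_result`: `best_x`, `best_f`, `history`
#'   (best-so-far per iteration), `pop`, `C`, `evals`, `seed`.
#' @export
isma_minimize <- function(fn, lower, upper, N = 30, t_max = 200,
                          z = 0.03, levy = levy_config(), seed = 1) {
  if (N < 4) stop("population size must be >= 4")
  if (t_max < 1) stop("t_max must be >= 1")
  D <- length(lower)
  if (length(upper) != D) stop("bound length mismatch")
  if (any(upper < lower)) stop("upper < lower")
  rng <- new_rng(seed)
  score <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) {
      warning("non-finite objective treated as worst")
      v <- Inf
    }
    v
  }
  pop <- matrix(rng_unif(rng, N * D), N, D)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  C <- apply(pop, 1, score)
  evals <- N
  best_i <- which.min(C)
  best_x <- pop[best_i, ]; best_f <- C[best_i]
  history <- numeric(t_max)
  for (t in seq_len(t_max)) {
    W <- sma_weights(C, rng)
    moved <- sma_move(pop, C, best_x, best_f, W, t, t_max, lower, upper,
                      z, rng)
    for (i in seq_len(N)) {
      b <- rng_unif(rng)
      cand <- if (b < 0.9) {
        moved[i, ]
      } else if (rng_unif(rng) <= 0.5) {
        obl_opposite(pop[i, ], upper, lower)
      } else {
        levy_step(best_x, lower, upper, levy, rng)
      }
      f_cand <- score(cand)
      evals <- evals + 1
      if (f_cand <= C[i]) {
        pop[i, ] <- cand
        C[i] <- f_cand
        if (f_cand < best_f) { best_f <- f_cand; best_x <- cand }
      }
    }
    history[t] <- best_f
  }
  structure(list(best_x = best_x, best_f = best_f, history = history,
                 pop = pop, C = C, evals = evals, seed = seed),
            class = "isma_result")
}
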