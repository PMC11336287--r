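# Kinetic-parameter calibration: one-at-a-time relative sensitivity,
# high-sensitivity parameter selection, and ARD-minimizing estimation
# with ISMA.

#' Average relative deviation
#'
#' `(1/N) sum |x_i - y_i| / x_i` over aligned observed/simulated
#' values. Matrix input is flattened, so multiple output series can be
#' pooled by column-binding them.
#'
#' @param observed,simulated aligned numeric vectors or matrices.
#' @param on_zero `"skip"` drops samples with `observed == 0` (with a
#'   warning); `"error"` stops.
#' @return scalar ARD (>= 0).
#' @export
ard <- function(observed, simulated, on_zero = c("skip", "error")) {
  on_zero <- match.arg(on_zero)
  x <- as.numeric(observed); y <- as.numeric(simulated)
  if (length(x) != length(y)) stop("observed/simulated length mismatch")
  if (!length(x)) stop("empty series")
  zero <- x == 0
  if (any(zero)) {
    if (on_zero == "error") stop("observed value of 0 in ARD")
    warning(sum(zero), " zero observed value(s) skipped in ARD")
    x <- x[!zero]; y <- y[!zero]
    if (!length(x)) stop("no usable samples after skipping zeros")
  }
  mean(abs(x - y) / x)
}

#' One-at-a-time relative sensitivity analysis
#'
#' For each parameter `j` and output series `i`, the relative
#' sensitivity is the absolute elasticity
#' `S_ij = |((Y1 - Y0)/Y0) / ((P1 - P0)/P0)|` averaged over the
#' samples of the series; the per-parameter total `S^T_j` sums `S_ij`
#' over the outputs. Parameters are perturbed one at a time by
#' `+delta` (one-sided, the default) or by `±delta` with a central
#' difference.
#'
#' @param runner function taking a full named parameter vector and
#'   returning a numeric matrix/data frame of output series (columns
#'   named by output).
#' @param params named numeric baseline parameter vector.
#' @param outputs optional character vector restricting/ordering the
#'   output columns used.
#' @param delta perturbation fraction (> 0, default 0.10).
#' @param method `"one_sided"` (default) or `"central"`.
#' @return list of class `sensitivity_report`: `S` (parameters x
#'   outputs), `S_total`, `ranking` (parameter names, descending
#'   `S_total`, ties by name order), `delta`, `method`, `baseline`.
#' @export
sensitivity <- function(runner, params, outputs = NULL, delta = 0.10,
                        method = c("one_sided", "central")) {
  method <- match.arg(method)
  if (delta <= 0) stop("delta must be > 0")
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop("params must be a fully named vector")
  Y0 <- as.matrix(runner(params))
  if (is.null(colnames(Y0))) colnames(Y0) <- paste0("y", seq_len(ncol(Y0)))
  if (is.null(outputs)) outputs <- colnames(Y0)
  if (!all(outputs %in% colnames(Y0))) stop("unknown output column")
  Y0 <- Y0[, outputs, drop = FALSE]
  S <- matrix(0, length(params), length(outputs),
              dimnames = list(names(params), outputs))
  elasticity <- function(Ynum, denom) {
    # per-sample relative response over relative perturbation,
    # averaged over the usable samples of each series
    vapply(outputs, function(o) {
      y0 <- Y0[, o]
      use <- y0 != 0
      if (!all(use))
        warning(sum(!use), " zero baseline sample(s) skipped for ", o)
      if (!any(use)) return(0)
      mean(abs((Ynum[use, o] / y0[use]) / denom))
    }, numeric(1))
  }
  for (j in seq_along(params)) {
    if (params[j] == 0) {
      warning("parameter ", names(params)[j],
              " has baseline 0; sensitivity set to 0")
      next
    }
    if (method == "one_sided") {
      up <- params; up[j] <- params[j] * (1 + delta)
      Y1 <- as.matrix(runner(up))[, outputs, drop = FALSE]
      S[j, ] <- elasticity(Y1 - Y0, delta)
    } else {
      up <- params; up[j] <- params[j] * (1 + delta)
      dn <- params; dn[j] <- params[j] * (1 - delta)
      Yp <- as.matrix(runner(up))[, outputs, drop = FALSE]
      Ym <- as.matrix(runner(dn))[, outputs, drop = FALSE]
      S[j, ] <- elasticity(Yp - Ym, 2 * delta)
    }
  }
  S_total <- rowSums(S)
  ranking <- names(params)[order(-S_total, names(params))]
  structure(list(S = S, S_total = S_total, ranking = ranking,
                 delta = delta, method = method, baseline = params),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity report (", x$method, ", delta = ", x$delta, "):\n",
      sep = "")
  top <- utils::head(x$ranking, 10)
  for (p in top)
    cat(sprintf("  %-12s S^T = %.4g\n", p, x$S_total[p]))
  invisible(x)
}

#' Select the most sensitive parameters
#'
#' Returns the `k` parameters with the largest total sensitivity
#' `S^T`; ties are broken by parameter name order (deterministic).
#'
#' @param report a [sensitivity()] report.
#' @param k number of parameters (default 8).
#' @return character vector of parameter names, length `k`.
#' @export
select_parameters <- function(report, k = 8) {
  if (!inherits(report, "sensitivity_report")) stop("need a sensitivity_report")
  if (k < 1 || k > length(report$ranking))
    stop("k must lie in [1, ", length(report$ranking), "]")
  report$ranking[seq_len(k)]
}

#' Calibrate model parameters by minimizing the ARD with ISMA
#'
#' The selected parameters are optimized over a box; every other
#' parameter stays at its baseline value. The objective is the mean of
#' the per-output ARDs between the observed and simulated series; a
#' failing simulation scores worst (with a warning).
#'
#' @param runner as in [sensitivity()].
#' @param observed numeric matrix/data frame of observed output series
#'   (columns named like the runner output).
#' @param params named numeric baseline parameter vector (full set).
#' @param select character vector of parameter names to fit (may be
#'   empty: the baseline ARD is returned unchanged).
#' @param lower,upper named bounds for the selected parameters; default
#'   `0.5x`/`2x` the baseline values.
#' @param N,t_max,z,levy ISMA settings (see [isma_minimize()]).
#' @param seed integer seed.
#' @return list of class `calibration_result`: `params` (full fitted
#'   vector), `fitted` (selected subset), `selected`, `bounds`,
#'   `ard` (final), `ard_initial`, `per_output_ard`, `history`,
#'   `evals`, `seed`.
#' @export
calibrate <- function(runner, observed, params, select,
                      lower = NULL, upper = NULL,
                      N = 10, t_max = 30, z = 0.03,
                      levy = levy_config(), seed = 1) {
  observed <- as.matrix(observed)
  if (is.null(colnames(observed))) stop("observed needs column names")
  if (!all(select %in% names(params)))
    stop("selected parameters must be a subset of params")
  outs <- colnames(observed)
  score <- function(theta) {
    full <- params
    full[select] <- theta
    sim <- tryCatch(as.matrix(runner(full)), error = function(e) {
      warning("simulation failed during calibration: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(sim) || !all(outs %in% colnames(sim))) return(Inf)
    mean(vapply(outs, function(o) ard(observed[, o], sim[, o]),
                numeric(1)))
  }
  per_output <- function(full) {
    sim <- as.matrix(runner(full))
    vapply(outs, function(o) ard(observed[, o], sim[, o]), numeric(1))
  }
  ard0 <- score(params[select])
  if (!length(select)) {
    po <- per_output(params)
    return(structure(list(params = params, fitted = numeric(0),
                          selected = character(0), bounds = NULL,
                          ard = ard0, ard_initial = ard0,
                          per_output_ard = po, history = numeric(0),
                          evals = 1L, seed = seed),
                     class = "calibration_result"))
  }
  if (is.null(lower)) lower <- 0.5 * params[select]
  if (is.null(upper)) upper <- 2.0 * params[select]
  lower <- lower[select]; upper <- upper[select]
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must cover every selected parameter")
  fit <- isma_minimize(score, lower, upper, N = N, t_max = t_max,
                       z = z, levy = levy, seed = seed)
  # greedy elitism in ISMA guarantees no regression, but guard anyway
  if (fit$best_f > ard0) {
    fit$best_x <- unname(params[select])
    fit$best_f <- ard0
  }
  full <- params
  full[select] <- fit$best_x
  structure(list(params = full,
                 fitted = stats::setNames(fit$best_x, select),
                 selected = select,
                 bounds = cbind(lower = lower, upper = upper),
                 ard = fit$best_f, ard_initial = ard0,
                 per_output_ard = per_output(full),
                 history = fit$history, evals = fit$evals, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration result:", length(x$selected), "parameter(s), ARD ",
      signif(x$ard_initial, 4), "->", signif(x$ard, 4), "\n")
  invisible(x)
}

#' Single-CSTR ASM2d runner for calibration
#'
#' Builds a model runner (for [sensitivity()] / [calibrate()]) that
#' simulates one continuously stirred ASM2d reactor at constant
#' influent and reports daily effluent composites.
#'
#' @param influent length-19 named influent state (see
#'   [asm2d_state()]).
#' @param volume reactor volume (m3); `q` flow (m3/d); `kla` oxygen
#'   transfer coefficient (1/d).
#' @param days simulated horizon; composites are sampled once per day
#'   (excluding time 0).
#' @param outputs composite columns to report.
#' @param base_params optional named overrides applied to the default
#'   [asm2d_params()] before the runner's own parameter vector.
#' @return function: named parameter vector (kinetic/stoichiometric
#'   overrides, may be empty) -> days x outputs matrix.
#' @export
make_cstr_runner <- function(influent, volume = 1000, q = 2000,
                             kla = 120, days = 5,
                             outputs = c("COD", "TN", "TP", "NH4N"),
                             base_params = NULL) {
  stopifnot(inherits(influent, "asm2d_state"))
  force(volume); force(q); force(kla); force(days); force(outputs)
  function(theta) {
    ov <- base_params
    if (length(theta)) {
      if (is.null(names(theta))) stop("parameter vector must be named")
      ov <- c(ov[setdiff(names(ov), names(theta))], theta)
    }
    m <- asm2d_params(overrides = ov)
    pm <- asm2d_stoichiometry(m)
    deriv <- function(t, y, p) {
      names(y) <- asm2d_components()
      list(asm2d_reactor_derivatives(y, influent, Q_in = q, V = volume,
                                     KLa = kla, params = m, pm = pm))
    }
    y0 <- unname(as.numeric(influent))
    times <- seq(0, days, by = 1)
    sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                          rtol = 1e-6, atol = 1e-8)
    states <- sol[-1, -1, drop = FALSE]
    colnames(states) <- asm2d_components()
    asm2d_composites(states, m)[, outputs, drop = FALSE]
  }
}
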