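# CRFSMA: multi-objective slime mould algorithm with one-dimensional
# logistic-chaos perturbation and reference-point non-dominated sorting
# selection, plus run-record export helpers.

# scalar SMA fitness in multi-objective mode: individuals ordered
# lexicographically by (front rank, niche count of the associated
# reference point), seeded-random tie-break; C(i) = position in that
# order (1 = best)
.mo_fitness <- function(objs, refs, rng, violation = NULL) {
  n <- nrow(objs)
  v <- if (is.null(violation)) numeric(0) else as.numeric(violation)
  ranks <- nds_ranks_cpp(objs, v)
  fn <- .normalize_objs(objs)
  assoc <- max.col(-.perp_dist(fn, refs), ties.method = "first")
  nc <- tabulate(assoc, nbins = nrow(refs))[assoc]
  ord <- order(ranks, nc, rng_unif(rng, n))
  C <- integer(n)
  C[ord] <- seq_len(n)
  list(C = C, ranks = ranks)
}

# evaluate a population matrix; fn may be vectorized (matrix -> matrix)
# and may return list(objectives, violation)
.eval_pop <- function(fn, X, M, vectorized) {
  n <- nrow(X)
  if (vectorized) {
    res <- fn(X)
    if (is.list(res)) {
      objs <- as.matrix(res$objectives)
      viol <- as.numeric(res$violation)
    } else {
      objs <- as.matrix(res)
      viol <- numeric(n)
    }
  } else {
    objs <- matrix(NA_real_, n, M)
    viol <- numeric(n)
    for (i in seq_len(n)) {
      res <- fn(X[i, ])
      if (is.list(res)) {
        objs[i, ] <- res$objectives
        viol[i] <- res$violation
      } else objs[i, ] <- res
    }
  }
  bad <- !is.finite(rowSums(objs)) | !is.finite(viol)
  if (any(bad)) {
    warning(sum(bad), " non-finite evaluation(s) treated as worst")
    worst <- if (all(bad)) rep(1, ncol(objs))
             else apply(objs[!bad, , drop = FALSE], 2,
                        function(cc) max(cc, 0) + 1)
    objs[bad, ] <- rep(worst, each = sum(bad))
    viol[bad] <- max(viol[is.finite(viol)], 0, na.rm = TRUE) + 1
  }
  list(objs = objs, viol = viol)
}

#' CRFSMA multi-objective optimizer
#'
#' Each generation applies the SMA position update driven by a scalar
#' fitness derived from (front rank, niche count); the uniform re-draw
#' branch is replaced by a one-dimensional logistic-chaos perturbation
#' fed by a shared chaotic sequence (toggleable). Parents and offspring
#' are pooled and reduced to `N` by fast non-dominated sorting with
#' reference-point niching. A bounded external archive collects all
#' feasible non-dominated solutions encountered; the returned front is
#' the archive (or the population's first front when disabled).
#'
#' @param fn objective function: length-D vector -> length-M objective
#'   vector, or (with `vectorized = TRUE`) an N x D matrix -> N x M
#'   matrix. It may instead return `list(objectives, violation)` with a
#'   non-negative total constraint violation, in which case
#'   feasibility-first constraint domination is applied.
#' @param lower,upper bounds (length D).
#' @param M number of objectives.
#' @param N population size; default 100 for `M = 2`, else the
#'   reference-point count.
#' @param t_max generations.
#' @param H reference-point divisions; default `N - 1` for `M = 2` and
#'   12 for `M = 3`.
#' @param z chaos/re-draw branch probability.
#' @param chaos `TRUE`: one-dimension logistic perturbation (default);
#'   `FALSE`: plain uniform re-draw.
#' @param use_archive keep an external archive (default); `archive_cap`
#'   its capacity.
#' @param vectorized whether `fn` accepts a population matrix.
#' @param seed integer seed.
#' @return list of class `crfsma_result`: `front` (objectives), `set`
#'   (decision vectors aligned with `front`), `pop`, `pop_objs`,
#'   `archive`, `history` (archive size per generation), `evals`,
#'   `config`.
#' @export
crfsma_optimize <- function(fn, lower, upper, M, N = NULL, t_max = 1000,
                            H = NULL, z = 0.03, chaos = TRUE,
                            use_archive = TRUE, archive_cap = 1000,
                            vectorized = FALSE, seed = 1) {
  if (M < 2) stop("need at least two objectives")
  D <- length(lower)
  if (length(upper) != D || any(upper < lower)) stop("invalid bounds")
  if (is.null(H)) H <- if (M == 2) max(1, (if (is.null(N)) 100 else N) - 1)
                       else 12
  refs <- reference_points(M, H)
  if (is.null(N)) N <- if (M == 2) 100 else nrow(refs)
  if (N < 4) stop("population size must be >= 4")
  rng <- new_rng(seed)
  # chaos state: seeded away from the forbidden fixed points
  m_chaos <- 0.2 + 0.6 * rng_unif(rng)
  while (m_chaos %in% c(0.25, 0.5, 0.75)) m_chaos <- 0.2 + 0.6 * rng_unif(rng)
  next_chaos <- function() {
    m_chaos <<- 4 * m_chaos * (1 - m_chaos)
    m_chaos
  }
  pop <- matrix(rng_unif(rng, N * D), N, D)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  ev <- .eval_pop(fn, pop, M, vectorized)
  objs <- ev$objs; viol <- ev$viol
  evals <- N
  archive <- pareto_archive(cap = archive_cap)
  if (use_archive) {
    ok <- viol == 0
    if (any(ok)) archive <- archive_update(archive,
                                           pop[ok, , drop = FALSE],
                                           objs[ok, , drop = FALSE])
  }
  history <- integer(t_max)
  for (t in seq_len(t_max)) {
    fit <- .mo_fitness(objs, refs, rng, viol)
    C <- fit$C
    W <- sma_weights(C, rng)
    f1 <- which(fit$ranks == 1L)
    a <- atanh(max(0, 1 - t / t_max))
    kc <- 1 - t / t_max
    p <- tanh(abs(C - 1))
    # one batched draw per role keeps the RNG-stream overhead per
    # generation constant
    u_z <- rng_unif(rng, N)
    u_yb <- rng_unif(rng, N)
    yb_idx <- f1[ceiling(u_yb * length(f1))]
    R <- matrix(rng_unif(rng, N * D), N, D)
    KB <- matrix(rng_unif(rng, N * D) * 2 - 1, N, D) * a
    A <- ceiling(rng_unif(rng, N * D) * N)
    B <- ceiling(rng_unif(rng, N * D) * N)
    colix <- rep(seq_len(D), each = N)
    approach <- pop[yb_idx, , drop = FALSE] +
      KB * (W * matrix(pop[cbind(A, colix)], N, D) -
              matrix(pop[cbind(B, colix)], N, D))
    off <- ifelse(R < p, approach, kc * pop)
    z_rows <- u_z < z
    if (any(z_rows)) {
      zi <- which(z_rows)
      off[zi, ] <- pop[zi, , drop = FALSE]
      if (chaos) {
        jdim <- ceiling(rng_unif(rng, length(zi)) * D)
        for (k in seq_along(zi))
          off[zi[k], ] <- chaos_perturb(pop[zi[k], ], jdim[k],
                                        next_chaos(), lower, upper)
      } else {
        redraw <- matrix(rng_unif(rng, length(zi) * D), length(zi), D)
        off[zi, ] <- sweep(sweep(redraw, 2, upper - lower, "*"),
                           2, lower, "+")
      }
    }
    off[] <- pmin(rep(upper, each = N), pmax(rep(lower, each = N), off))
    ev <- .eval_pop(fn, off, M, vectorized)
    evals <- evals + N
    pool_X <- rbind(pop, off)
    pool_objs <- rbind(objs, ev$objs)
    pool_viol <- c(viol, ev$viol)
    sel <- niche_select(pool_objs, refs, N, rng, pool_viol)
    pop <- pool_X[sel$indices, , drop = FALSE]
    objs <- pool_objs[sel$indices, , drop = FALSE]
    viol <- pool_viol[sel$indices]
    if (use_archive) {
      # offspring entering the pool's first front are the only genuinely
      # new non-dominated material
      cand <- which(sel$ranks == 1L & pool_viol == 0 &
                      seq_along(pool_viol) > N)
      if (length(cand))
        archive <- archive_update(archive,
                                  pool_X[cand, , drop = FALSE],
                                  pool_objs[cand, , drop = FALSE])
    }
    history[t] <- if (is.null(archive$objs)) 0L else nrow(archive$objs)
  }
  if (use_archive && !is.null(archive$objs)) {
    if (nrow(archive$objs) > archive_cap) {
      keep <- thin_points_cpp(archive$objs, archive_cap)
      archive$X <- archive$X[keep, , drop = FALSE]
      archive$objs <- archive$objs[keep, , drop = FALSE]
    }
    front <- archive$objs
    set <- archive$X
  } else {
    fp <- fast_nondominated_sort(objs, viol)
    front <- objs[fp$fronts[[1]], , drop = FALSE]
    set <- pop[fp$fronts[[1]], , drop = FALSE]
  }
  structure(list(front = front, set = set, pop = pop, pop_objs = objs,
                 pop_viol = viol, archive = archive, history = history,
                 evals = evals,
                 config = list(N = N, t_max = t_max, H = H, z = z,
                               chaos = chaos, use_archive = use_archive,
                               archive_cap = archive_cap, seed = seed)),
            class = "crfsma_result")
}

#' @export
print.crfsma_result <- function(x, ...) {
  cat("crfsma result:", nrow(x$front), "non-dominated solutions,",
      x$evals, "evaluations (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Export an optimizer run
#'
#' `write_run_record` serializes the configuration, seed and
#' per-generation history to JSON; `write_front_csv` writes the front
#' (decision variables, then objectives) as CSV.
#'
#' @param result `crfsma_result` (or `isma_result` for the JSON record).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_run_record <- function(result, path) {
  rec <- list(
    class = class(result)[1],
    config = result$config %||% list(seed = result$seed),
    evals = result$evals,
    history = result$history,
    front = if (!is.null(result$front)) unname(as.matrix(result$front)),
    best_f = result$best_f,
    package_version = as.character(utils::packageVersion("wwtpopt")))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_run_record
#' @export
write_front_csv <- function(result, path) {
  X <- as.matrix(result$set)
  FF <- as.matrix(result$front)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(FF) <- paste0("f", seq_len(ncol(FF)))
  utils::write.csv(cbind(X, FF), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
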