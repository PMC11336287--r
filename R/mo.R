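# Multi-objective selection machinery: fast non-dominated sorting,
# Das-Dennis reference points, NSGA-III-style normalization /
# association / niching, and a bounded external non-dominated archive.

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts (minimization). With a
#' `violation` vector, feasibility-first constraint domination is used:
#' a feasible solution dominates any infeasible one, and two infeasible
#' solutions are compared by total violation.
#'
#' @param objs N x M objective matrix.
#' @param violation optional length-N non-negative violation totals.
#' @return list of class `front_partition`: `ranks` (1 = first front)
#'   and `fronts` (list of index vectors).
#' @export
fast_nondominated_sort <- function(objs, violation = NULL) {
  objs <- as.matrix(objs)
  if (!nrow(objs)) stop("empty population")
  if (ncol(objs) < 2) stop("need at least two objectives")
  v <- if (is.null(violation)) numeric(0) else as.numeric(violation)
  ranks <- nds_ranks_cpp(objs, v)
  structure(list(ranks = ranks,
                 fronts = split(seq_len(nrow(objs)), ranks)),
            class = "front_partition")
}

#' Das-Dennis reference points
#'
#' Simplex-lattice points with `H` divisions per objective; the count is
#' `choose(H + M - 1, M - 1)` and every point sums to 1.
#'
#' @param M number of objectives (>= 2); `H` divisions (>= 1).
#' @return matrix (count x M).
#' @export
reference_points <- function(M, H) {
  if (M < 2 || H < 1) stop("require M >= 2 and H >= 1")
  sep <- utils::combn(H + M - 1, M - 1)
  counts <- rbind(sep, H + M) - rbind(0, sep) - 1
  t(counts) / H
}

# perpendicular distances of normalized objectives to reference lines
.perp_dist <- function(fn, refs) {
  u <- refs / sqrt(rowSums(refs^2))
  proj <- fn %*% t(u)                       # N x R projections
  sq <- rowSums(fn^2) - proj^2              # recycled column-wise
  sq[sq < 0] <- 0
  sqrt(sq)
}

# NSGA-III objective normalization: ideal point and extreme-point
# intercepts, with a max-range fallback for degenerate geometry
.normalize_objs <- function(objs) {
  M <- ncol(objs)
  ideal <- apply(objs, 2, min)
  ft <- sweep(objs, 2, ideal)
  # extreme point per axis by the achievement scalarizing function
  intercepts <- rep(NA_real_, M)
  ext <- matrix(NA_real_, M, M)
  for (m in seq_len(M)) {
    w <- rep(1e-6, M); w[m] <- 1
    asf <- apply(sweep(ft, 2, w, "/"), 1, max)
    ext[m, ] <- ft[which.min(asf), ]
  }
  ok <- FALSE
  if (abs(det(ext)) > 1e-12) {
    b <- tryCatch(solve(ext, rep(1, M)), error = function(e) NULL)
    if (!is.null(b) && all(is.finite(b)) && all(b > 1e-12)) {
      intercepts <- 1 / b
      ok <- TRUE
    }
  }
  if (!ok) intercepts <- apply(ft, 2, max)  # max-range fallback
  intercepts[intercepts < 1e-12] <- 1
  sweep(ft, 2, intercepts, "/")
}

#' Reference-point environmental selection
#'
#' NSGA-III-style survival: whole fronts are admitted while they fit;
#' the partially admitted last front is filled by ascending niche count
#' over the reference points (normalize, associate, niche), with seeded
#' random tie-breaks.
#'
#' @param objs pool objective matrix (N_pool x M).
#' @param refs reference point set from [reference_points()].
#' @param N number of survivors.
#' @param rng `rng_stream` for tie-breaks.
#' @param violation optional constraint violations (see
#'   [fast_nondominated_sort()]).
#' @return list: `indices` (survivor rows of `objs`), `ranks`, `assoc`
#'   (reference index per pool member), `dist` (perpendicular distance),
#'   `niche_counts` (per reference, over the survivors).
#' @export
niche_select <- function(objs, refs, N, rng, violation = NULL) {
  objs <- as.matrix(objs)
  n <- nrow(objs)
  if (N > n) stop("cannot select more survivors than pool members")
  fp <- fast_nondominated_sort(objs, violation)
  ranks <- fp$ranks
  ord_fronts <- fp$fronts
  keep <- integer(0)
  l <- 0
  for (k in seq_along(ord_fronts)) {
    if (length(keep) + length(ord_fronts[[k]]) > N) { l <- k; break }
    keep <- c(keep, ord_fronts[[k]])
    if (length(keep) == N) break
  }
  fn <- .normalize_objs(objs)
  dmat <- .perp_dist(fn, refs)
  assoc <- max.col(-dmat, ties.method = "first")
  dist <- dmat[cbind(seq_len(n), assoc)]
  nref <- nrow(refs)
  rho <- tabulate(assoc[keep], nbins = nref)
  if (l > 0 && length(keep) < N) {
    last <- ord_fronts[[l]]
    T_ <- N - length(keep)
    members <- split(last, factor(assoc[last], levels = seq_len(nref)))
    u <- rng_unif(rng, 2 * T_)  # pre-drawn tie-break randomness
    for (s in seq_len(T_)) {
      has <- which(lengths(members) > 0)
      jmin <- has[rho[has] == min(rho[has])]
      r_sel <- if (length(jmin) > 1)
        jmin[ceiling(u[2 * s - 1] * length(jmin))] else jmin
      mem <- members[[r_sel]]
      pick <- if (rho[r_sel] == 0) mem[which.min(dist[mem])]
              else if (length(mem) > 1)
                mem[ceiling(u[2 * s] * length(mem))] else mem
      keep <- c(keep, pick)
      members[[r_sel]] <- mem[mem != pick]
      rho[r_sel] <- rho[r_sel] + 1
    }
  }
  list(indices = keep, ranks = ranks, assoc = assoc, dist = dist,
       niche_counts = tabulate(assoc[keep], nbins = nref))
}

#' Bounded non-dominated archive
#'
#' Maintains an external archive of mutually non-dominated solutions,
#' thinned to a capacity bound by removing the most crowded points
#' (per-objective extremes are always retained).
#'
#' @param X decision matrix (rows aligned with `objs`); `objs` objective
#'   matrix; `cap` capacity.
#' @return list of class `pareto_archive` with `X`, `objs`, `cap`.
#' @export
pareto_archive <- function(X = NULL, objs = NULL, cap = 1000) {
  structure(list(X = X, objs = objs, cap = cap), class = "pareto_archive")
}

#' @rdname pareto_archive
#' @param archive existing archive; `newX`, `newobjs` candidate batch.
#' @export
archive_update <- function(archive, newX, newobjs) {
  newX <- as.matrix(newX); newobjs <- as.matrix(newobjs)
  if (is.null(archive$objs)) {
    fp <- nds_ranks_cpp(newobjs, numeric(0))
    keep <- fp == 1L
    archive$X <- newX[keep, , drop = FALSE]
    archive$objs <- newobjs[keep, , drop = FALSE]
  } else {
    upd <- nd_update_cpp(archive$objs, newobjs)
    archive$X <- rbind(archive$X[upd$keepA, , drop = FALSE],
                       newX[upd$keepC, , drop = FALSE])
    archive$objs <- rbind(archive$objs[upd$keepA, , drop = FALSE],
                          newobjs[upd$keepC, , drop = FALSE])
  }
  if (nrow(archive$objs) > archive$cap * 1.5) {
    keep <- thin_points_cpp(archive$objs, archive$cap)
    archive$X <- archive$X[keep, , drop = FALSE]
    archive$objs <- archive$objs[keep, , drop = FALSE]
  }
  archive
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat("pareto archive:", if (is.null(x$objs)) 0 else nrow(x$objs),
      "solutions (cap", x$cap, ")\n")
  invisible(x)
}
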