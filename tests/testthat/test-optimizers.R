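test_that("SMA weights bracket 1 with elite/laggard split", {
  rng <- new_rng(1)
  expect_equal(sma_weights(rep(3, 8), rng), rep(1, 8))
  C <- c(5, 1, 3, 9, 2, 7)
  W <- sma_weights(C, rng)
  # the log10 term lies in [0, log10(2)], so W in [1 - log10 2, 1 + log10 2]
  expect_true(all(W >= 1 - log10(2) - 1e-12))
  expect_true(all(W <= 1 + log10(2) + 1e-12))
  elite <- order(C)[1:3]
  expect_true(all(W[elite] >= 1))
  expect_true(all(W[-elite] <= 1))
  expect_error(sma_weights(numeric(0), rng), "empty")
})

test_that("SMA move collapses to full contraction at the final iteration", {
  rng <- new_rng(2)
  lower <- rep(-10, 4); upper <- rep(10, 4)
  pop <- matrix(runif(20, -5, 5), 5, 4)
  C <- rep(2, 5)                       # p = tanh|C - DO| = 0 everywhere
  W <- rep(1, 5)
  out <- sma_move(pop, C, pop[1, ], DO = 2, W, t = 10, t_max = 10,
                  lower, upper, z = 0, rng = rng)
  expect_true(all(out == 0))           # kc = 1 - t/t_max = 0
  # with p = 1 the approach branch is taken and KB = 0 at t = t_max,
  # so every element equals the leader coordinate
  C2 <- rep(1e9, 5)
  out2 <- sma_move(pop, C2, pop[3, ], DO = 0, W, t = 10, t_max = 10,
                   lower, upper, z = 0, rng = rng)
  expect_true(all(out2 == matrix(pop[3, ], 5, 4, byrow = TRUE)))
  # bounds always respected
  out3 <- sma_move(pop, c(3, 1, 4, 1, 5), pop[2, ], 1, W, t = 1,
                   t_max = 10, lower, upper, z = 0.5, rng = rng)
  expect_true(all(out3 >= -10 & out3 <= 10))
  expect_error(sma_move(pop, C, pop[1, ], 2, W, t = 11, t_max = 10,
                        lower, upper, rng = rng), "exceeds")
})

test_that("opposition-based learning is an involution about the midpoint", {
  lo <- c(0, -2); up <- c(1, 4)
  y <- c(0.3, 1)
  expect_equal(obl_opposite(y, up, lo), c(0.7, 1))
  expect_equal(obl_opposite(obl_opposite(y, up, lo), up, lo), y)
  # the midpoint is the fixed point
  expect_equal(obl_opposite((lo + up) / 2, up, lo), (lo + up) / 2)
  # matrix form mirrors row-wise
  m <- rbind(y, c(1, 4))
  expect_equal(unname(obl_opposite(m, up, lo)), rbind(c(0.7, 1), c(0, -2)))
})

test_that("Mantegna sigma and Levy steps behave as documented", {
  expect_equal(levy_sigma(1.5), 0.6965745, tolerance = 1e-6)
  expect_equal(levy_sigma(2), (gamma(3) * sin(pi) + 0) / 1, tolerance = 1)
  rng <- new_rng(3)
  cfg <- levy_config(mode = "additive", s = 0.01)
  draws <- replicate(2e4,
    levy_step(0, lower = -1e6, upper = 1e6, cfg = cfg, rng = rng))
  # heavy tail: extreme draws dwarf the typical ones
  expect_gt(max(abs(draws)) / stats::median(abs(draws)), 50)
  # multiplicative mode cannot leave the origin
  expect_equal(levy_step(c(0, 0), c(-1, -1), c(1, 1),
                         levy_config(), rng), c(0, 0))
  expect_error(levy_config(beta = 3), "beta")
})

test_that("logistic chaos map iterates and rejects degenerate seeds", {
  expect_equal(logistic_chaos_sequence(0.2, 2), c(0.64, 4 * 0.64 * 0.36),
               tolerance = 1e-15)
  for (bad in c(0, 0.25, 0.5, 0.75, 1))
    expect_error(logistic_chaos_sequence(bad, 5), "seed")
  # ergodicity: a long orbit visits all 100 bins of [0, 1]
  s <- logistic_chaos_sequence(0.2, 2e4)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(length(unique(cut(s, breaks = seq(0, 1, by = 0.01)))), 100)
})

test_that("chaos perturbation rewrites exactly one coordinate", {
  y <- c(1, 2, 3); lo <- rep(0, 3); up <- rep(10, 3)
  expect_equal(chaos_perturb(y, 2, 0.4, lo, up), c(1, 4, 3))
  expect_equal(chaos_perturb(y, 1, 0, lo, up)[1], 0)
  expect_equal(chaos_perturb(y, 3, 1, lo, up)[3], 10)
  expect_identical(chaos_perturb(y, 2, 0.4, lo, up)[c(1, 3)], y[c(1, 3)])
  expect_error(chaos_perturb(y, 4, 0.5, lo, up), "dimension")
  expect_error(chaos_perturb(y, 1, 1.5, lo, up), "chaos value")
})

test_that("ISMA minimizes the sphere with a monotone history", {
  sphere <- function(x) sum(x^2)
  r <- isma_minimize(sphere, rep(-5, 5), rep(5, 5), N = 20, t_max = 150,
                     seed = 4)
  expect_lt(r$best_f, 1e-3)
  expect_true(all(diff(r$history) <= 0))
  expect_equal(r$best_f, sphere(r$best_x))
  r2 <- isma_minimize(sphere, rep(-5, 5), rep(5, 5), N = 20, t_max = 150,
                      seed = 4)
  expect_identical(r$best_x, r2$best_x)
  expect_identical(r$history, r2$history)
  r3 <- isma_minimize(sphere, rep(-5, 5), rep(5, 5), N = 20, t_max = 150,
                      seed = 5)
  expect_false(identical(r$best_x, r3$best_x))
})

test_that("non-dominated sorting matches hand example and brute force", {
  objs <- rbind(c(0, 0), c(1, 0.5), c(0.5, 1), c(2, 2))
  fp <- fast_nondominated_sort(objs)
  expect_equal(fp$ranks, c(1L, 2L, 2L, 3L))
  expect_equal(fp$fronts[[1]], 1L)
  # identical rows form a single first front
  same <- matrix(1, 5, 2)
  expect_equal(fast_nondominated_sort(same)$ranks, rep(1L, 5))
  # feasibility-first: any feasible point outranks every infeasible one
  v <- c(0, 0, 1, 0.5)
  fpv <- fast_nondominated_sort(objs, v)
  expect_lt(max(fpv$ranks[v == 0]), min(fpv$ranks[v > 0]))
  expect_gt(fpv$ranks[3], fpv$ranks[4])  # larger violation ranks worse
  # randomized cross-check against the O(N^2) oracle
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:40, 1); M <- sample(2:4, 1)
    o <- matrix(stats::rnorm(n * M), n, M)
    vv <- ifelse(stats::runif(n) < 0.3, stats::runif(n), 0)
    expect_equal(fast_nondominated_sort(o, vv)$ranks, brute_nds(o, vv))
  }
})

test_that("Das-Dennis reference points form the simplex lattice", {
  rp <- reference_points(2, 4)
  expect_equal(nrow(rp), 5)
  expect_equal(rp[order(rp[, 1]), ],
               cbind(c(0, 0.25, 0.5, 0.75, 1), c(1, 0.75, 0.5, 0.25, 0)),
               ignore_attr = TRUE)
  expect_equal(nrow(reference_points(3, 1)), 3)
  rp3 <- reference_points(3, 12)
  expect_equal(nrow(rp3), choose(12 + 2, 2))   # 91
  expect_true(all(abs(rowSums(rp3) - 1) < 1e-12))
  expect_true(all(rp3 >= 0))
  expect_error(reference_points(1, 4), "M >= 2")
})

test_that("niche selection is elitist and spreads over references", {
  rng <- new_rng(6)
  # F1: three spread points; F2: the same shifted up
  f1 <- rbind(c(0, 1), c(0.5, 0.5), c(1, 0))
  f2 <- f1 + 0.5
  objs <- rbind(f1, f2)
  refs <- reference_points(2, 4)
  sel <- niche_select(objs, refs, 4, rng)
  expect_length(sel$indices, 4)
  expect_true(all(1:3 %in% sel$indices))       # whole first front kept
  expect_equal(sum(sel$indices > 3), 1)
  # when N equals the pool everything survives
  sel2 <- niche_select(objs, refs, 6, rng)
  expect_setequal(sel2$indices, 1:6)
  expect_error(niche_select(objs, refs, 7, rng), "more survivors")
})

test_that("the archive stays mutually non-dominated and keeps extremes", {
  a <- pareto_archive(cap = 50)
  x <- seq(0, 1, length.out = 30)
  a <- archive_update(a, cbind(x), cbind(x, 1 - x))
  expect_equal(nrow(a$objs), 30)
  # dominated batch changes nothing
  a2 <- archive_update(a, cbind(x), cbind(x + 0.1, 1 - x + 0.1))
  expect_equal(a2$objs, a$objs)
  # a dominating point evicts what it dominates
  a3 <- archive_update(a, cbind(-1), cbind(-1, 2))
  expect_true(any(a3$objs[, 1] == -1))
  expect_equal(brute_nds(a3$objs), rep(1L, nrow(a3$objs)))
  # overfilling triggers thinning to the cap, extremes retained
  xx <- seq(0, 1, length.out = 400)
  b <- archive_update(pareto_archive(cap = 50), cbind(xx),
                      cbind(xx, 1 - xx))
  expect_lte(nrow(b$objs), 50)
  expect_true(any(b$objs[, 1] == 0) && any(b$objs[, 1] == 1))
})

test_that("CRFSMA returns a reproducible internally non-dominated front", {
  fn <- function(X) cbind(X[, 1], (1 + X[, 2]) * (1 - X[, 1] / (1 + X[, 2])))
  r <- crfsma_optimize(fn, c(0, 0), c(1, 1), M = 2, N = 12, t_max = 40,
                       H = 11, vectorized = TRUE, seed = 8)
  expect_s3_class(r, "crfsma_result")
  expect_gt(nrow(r$front), 3)
  expect_equal(brute_nds(r$front), rep(1L, nrow(r$front)))
  expect_equal(nrow(r$front), nrow(r$set))
  # front values re-evaluate exactly from the stored decision vectors
  expect_equal(unname(fn(r$set)), unname(r$front), tolerance = 1e-12)
  r2 <- crfsma_optimize(fn, c(0, 0), c(1, 1), M = 2, N = 12, t_max = 40,
                        H = 11, vectorized = TRUE, seed = 8)
  expect_identical(r$front, r2$front)
  expect_identical(r$history, r2$history)
  # degenerate identical objectives collapse to (near) a single point
  fn2 <- function(X) { s <- rowSums(X^2); cbind(s, s) }
  rd <- crfsma_optimize(fn2, c(-1, -1), c(1, 1), M = 2, N = 8, t_max = 60,
                        H = 7, vectorized = TRUE, seed = 9)
  expect_lt(min(rd$front[, 1]), 0.05)
  expect_equal(rd$front[, 1], rd$front[, 2])
})

test_that("run records and fronts serialize", {
  fn <- function(X) cbind(X[, 1], 1 - X[, 1] + X[, 2]^2)
  r <- crfsma_optimize(fn, c(0, -1), c(1, 1), M = 2, N = 8, t_max = 10,
                       H = 7, vectorized = TRUE, seed = 10)
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_run_record(r, fj)
  rec <- jsonlite::fromJSON(fj)
  expect_equal(rec$config$seed, 10)
  expect_equal(rec$evals, r$evals)
  write_front_csv(r, fc)
  df <- utils::read.csv(fc)
  expect_equal(nrow(df), nrow(r$front))
  expect_equal(df$f1, unname(r$front[, 1]), tolerance = 1e-12)
  expect_equal(df$x1, unname(r$set[, 1]), tolerance = 1e-12)
})
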