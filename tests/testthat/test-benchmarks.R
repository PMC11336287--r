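bench_names <- c("ZDT1", "ZDT2", "ZDT3", "UF1", "UF2", "UF3",
                 "DTLZ1", "DTLZ2", "DTLZ3", "DTLZ7")

test_that("problem configurations match the published set", {
  for (nm in bench_names) {
    pb <- benchmark_problem(nm)
    if (startsWith(nm, "DTLZ")) {
      expect_equal(pb$D, 10L); expect_equal(pb$M, 3L)
    } else {
      expect_equal(pb$D, 30L); expect_equal(pb$M, 2L)
    }
    expect_equal(pb$t_max, 1000L)
    expect_equal(pb$lower[1], 0)       # x1 in [0,1] everywhere
    expect_equal(pb$upper[1], 1)
  }
  # standard domains by default
  expect_equal(benchmark_problem("ZDT2")$lower, rep(0, 30))
  expect_equal(benchmark_problem("UF3")$lower, rep(0, 30))
  expect_equal(benchmark_problem("UF1")$lower, c(0, rep(-1, 29)))
  # as-printed toggle widens them
  expect_equal(benchmark_problem("ZDT2", as_printed = TRUE)$lower,
               c(0, rep(-5, 29)))
  expect_equal(benchmark_problem("UF3", as_printed = TRUE)$lower,
               rep(-1, 30))
  expect_error(benchmark_problem("NOPE"))
})

test_that("objective evaluations satisfy known point identities", {
  # ZDT1 endpoints of the front
  expect_equal(unname(evaluate_problem("ZDT1", rep(0, 30))[1, ]),
               c(0, 1))
  expect_equal(unname(evaluate_problem("ZDT1", c(1, rep(0, 29)))[1, ]),
               c(1, 0))
  # a UF1 Pareto-set member maps onto f2 = 1 - sqrt(f1)
  x1 <- 0.3; D <- 30
  x <- c(x1, sin(6 * pi * x1 + (2:D) * pi / D))
  f <- evaluate_problem("UF1", x)[1, ]
  expect_equal(unname(f), c(x1, 1 - sqrt(x1)), tolerance = 1e-12)
  # DTLZ2 with x_m = 0.5 lies on the unit sphere
  f2 <- evaluate_problem("DTLZ2", c(0.3, 0.7, rep(0.5, 8)))[1, ]
  expect_equal(sum(f2^2), 1, tolerance = 1e-12)
  # DTLZ1 with x_m = 0.5 sums to 0.5
  f3 <- evaluate_problem("DTLZ1", c(0.2, 0.6, rep(0.5, 8)))[1, ]
  expect_equal(sum(f3), 0.5, tolerance = 1e-12)
})

test_that("vectorized evaluators agree with independent scalar oracles", {
  set.seed(31)
  for (nm in bench_names) {
    pb <- benchmark_problem(nm)
    X <- matrix(runif(200 * pb$D), 200, pb$D)
    X <- sweep(sweep(X, 2, pb$upper - pb$lower, "*"), 2, pb$lower, "+")
    got <- pb$fn(X)
    want <- t(apply(X, 1, function(x) ref_problem(nm, x)))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("true front samples lie on the analytic fronts", {
  p3 <- true_front_sample("ZDT1", 3)
  expect_equal(unname(p3),
               cbind(c(0, 0.5, 1), 1 - sqrt(c(0, 0.5, 1))),
               tolerance = 1e-12)
  p2 <- true_front_sample("ZDT2", 100)
  expect_equal(p2[, 2], 1 - p2[, 1]^2, ignore_attr = TRUE)
  d1 <- true_front_sample("DTLZ1", 500)
  expect_true(all(abs(rowSums(d1) - 0.5) < 1e-12))
  d2 <- true_front_sample("DTLZ2", 500)
  expect_true(all(abs(rowSums(d2^2) - 1) < 1e-12))
  # samples are internally non-dominated (incl. the disconnected ZDT3)
  for (nm in c("ZDT3", "DTLZ7")) {
    P <- true_front_sample(nm, 150)
    expect_equal(brute_nds(P), rep(1L, nrow(P)))
  }
  z3 <- true_front_sample("ZDT3", 150)
  expect_equal(z3[, 2], 1 - sqrt(z3[, 1]) - z3[, 1] * sin(10 * pi * z3[, 1]),
               ignore_attr = TRUE)
  expect_error(true_front_sample("ZDT1", 1), "two reference")
})

test_that("IGD identities hold", {
  P <- true_front_sample("ZDT1", 50)
  expect_equal(igd(P, P), 0)
  # single obtained point at unit distance from a single reference point
  expect_equal(igd(matrix(c(0, 0), 1), matrix(c(0, 1), 1)), 1)
  expect_equal(igd(rbind(c(0, 0), c(3, 4)), matrix(c(0, 0), 1)),
               (0 + 5) / 2)
  # agreement with the brute oracle on random sets
  set.seed(13)
  A <- matrix(runif(60), 20, 3); B <- matrix(runif(30), 10, 3)
  expect_equal(igd(A, B), brute_igd(A, B), tolerance = 1e-12)
  # enlarging the obtained set can only reduce IGD
  Q1 <- matrix(runif(20), 10, 2); Q2 <- rbind(Q1, matrix(runif(10), 5, 2))
  expect_lte(igd(P, Q2), igd(P, Q1))
  expect_error(igd(P, matrix(1, 1, 3)), "dimension")
})

test_that("benchmark harness reports exact statistics per run", {
  # oracle optimizer that returns the analytic front exactly
  oracle <- function(fn, lower, upper, M, t_max, seed, ...)
    list(front = true_front_sample("ZDT1", 1000))
  r <- run_benchmark(benchmark_problem("ZDT1"), n_runs = 1,
                     base_seed = 5, optimizer = oracle)
  expect_equal(r$avg, 0)
  expect_equal(r$std, 0)
  expect_equal(r$min, r$max)
  expect_equal(r$n_runs, 1)
  expect_equal(r$ref_size, 1000)
  # deterministic dummy with per-seed output: statistics recompute
  dummy <- function(fn, lower, upper, M, t_max, seed, ...)
    list(front = true_front_sample("ZDT1", 1000) + (seed %% 3) * 0.01)
  r3 <- run_benchmark(benchmark_problem("ZDT1"), n_runs = 3,
                      base_seed = 1, optimizer = dummy)
  expect_equal(r3$avg, mean(r3$igd))
  expect_equal(r3$std, sd(r3$igd))
  expect_equal(r3$min, min(r3$igd))
  expect_equal(r3$max, max(r3$igd))
})

test_that("benchmark CSV export has the comparison-table layout", {
  oracle <- function(fn, lower, upper, M, t_max, seed, ...)
    list(front = true_front_sample("ZDT1", 1000))
  r <- run_benchmark(benchmark_problem("ZDT1"), n_runs = 2,
                     base_seed = 1, optimizer = oracle)
  f <- tempfile(fileext = ".csv")
  df <- write_benchmark_csv(list(r), f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 4)
  expect_equal(got$statistic, c("Avg", "StD", "Min", "Max"))
  expect_equal(got$problem, rep("ZDT1", 4))
  expect_equal(got$IGD, c(r$avg, r$std, r$min, r$max))
})
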