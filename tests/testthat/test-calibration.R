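test_that("average relative deviation matches hand arithmetic", {
  expect_equal(ard(c(10, 20), c(10, 20)), 0)
  # |10-8|/10 = 0.2 and |20-26|/20 = 0.3 -> mean 0.25
  expect_equal(ard(c(10, 20), c(8, 26)), 0.25, tolerance = 1e-15)
  # scale invariance
  expect_equal(ard(c(10, 20) * 7, c(8, 26) * 7), 0.25, tolerance = 1e-12)
  expect_warning(v <- ard(c(0, 10), c(1, 8)), "skipped")
  expect_equal(v, 0.2)
  expect_error(ard(c(0, 10), c(1, 8), on_zero = "error"), "0 in ARD")
  expect_error(ard(1:3, 1:2), "mismatch")
})

test_that("sensitivity elasticities reproduce analytic values", {
  # linear model Y = 3 * P: elasticity is exactly 1 for both methods
  runner <- function(p) cbind(Y = 3 * p[["a"]])
  for (m in c("one_sided", "central")) {
    rep_ <- sensitivity(runner, c(a = 2), method = m)
    expect_s3_class(rep_, "sensitivity_report")
    expect_equal(unname(rep_$S["a", "Y"]), 1, tolerance = 1e-9)
    expect_equal(unname(rep_$S_total[["a"]]), 1, tolerance = 1e-9)
  }
  # an ignored parameter scores exactly zero and ranks last
  runner2 <- function(p) cbind(Y = 3 * p[["a"]], Z = p[["a"]]^2)
  rep2 <- sensitivity(runner2, c(a = 2, b = 5))
  expect_equal(unname(rep2$S["b", ]), c(0, 0))
  expect_equal(rep2$ranking, c("a", "b"))
  # power model Y = P^2: one-sided elasticity is ((1.1^2 - 1)) / 0.1
  rep3 <- sensitivity(function(p) cbind(Y = p[["a"]]^2), c(a = 3),
                      delta = 0.10)
  expect_equal(unname(rep3$S["a", "Y"]), 2.1, tolerance = 1e-9)
  # central difference of the same model: ((1.1^2 - 0.9^2)) / 0.2 = 2
  rep3c <- sensitivity(function(p) cbind(Y = p[["a"]]^2), c(a = 3),
                       delta = 0.10, method = "central")
  expect_equal(unname(rep3c$S["a", "Y"]), 2, tolerance = 1e-9)
  # S_total sums the per-output elasticities
  expect_equal(unname(rep2$S_total[["a"]]), sum(abs(rep2$S["a", ])),
               tolerance = 1e-12)
  # multi-sample series average their per-sample elasticities
  rep4 <- sensitivity(function(p) cbind(Y = c(3 * p[["a"]], p[["a"]]^2)),
                      c(a = 3), delta = 0.10)
  expect_equal(unname(rep4$S["a", "Y"]), (1 + 2.1) / 2, tolerance = 1e-9)
  expect_error(sensitivity(runner, c(2)), "named")
  expect_error(sensitivity(runner, c(a = 2), outputs = "nope"),
               "unknown output")
})

test_that("parameter selection follows the total-sensitivity ranking", {
  rep_ <- sensitivity(function(p) cbind(Y = 5 * p[["a"]] + 0.2 * p[["b"]] +
                                          2 * p[["c"]]),
                      c(a = 1, b = 1, c = 1))
  expect_equal(select_parameters(rep_, 1), "a")
  expect_setequal(select_parameters(rep_, 2), c("a", "c"))
  expect_error(select_parameters(rep_, 0), "k")
  expect_error(select_parameters(rep_, 9), "k")
  expect_error(select_parameters(list(), 1), "sensitivity_report")
  # deterministic alphabetical tie-break for equal sensitivities
  rep_t <- sensitivity(function(p) cbind(Y = p[["b"]] + p[["a"]]),
                       c(b = 1, a = 1))
  expect_equal(select_parameters(rep_t, 1), "a")
})

test_that("calibration recovers a parameter of a cheap analytic model", {
  truth <- c(k = 1.7)
  observed <- cbind(Y1 = 3 * truth[["k"]], Y2 = truth[["k"]]^2)
  runner <- function(p) cbind(Y1 = 3 * p[["k"]], Y2 = p[["k"]]^2)
  res <- calibrate(runner, observed, params = c(k = 1.0), select = "k",
                   N = 8, t_max = 150, seed = 3)
  expect_s3_class(res, "calibration_result")
  expect_lt(abs(res$fitted[["k"]] - truth[["k"]]) / truth[["k"]], 0.01)
  expect_lt(res$ard, 1e-3)
  expect_lte(res$ard, res$ard_initial)
  expect_equal(res$params[["k"]], res$fitted[["k"]])
  # empty selection returns the baseline untouched
  res0 <- calibrate(runner, observed, params = c(k = 1.0),
                    select = character(0), seed = 3)
  expect_equal(res0$params[["k"]], 1.0)
  expect_equal(res0$ard, res0$ard_initial)
  # determinism under the seed
  res2 <- calibrate(runner, observed, params = c(k = 1.0), select = "k",
                    N = 8, t_max = 150, seed = 3)
  expect_identical(res$fitted, res2$fitted)
  expect_error(calibrate(runner, observed, params = c(k = 1.0),
                         select = "zz"), "subset")
})

test_that("the CSTR runner exposes effluent composites of the bioreactor", {
  inf <- test_cstr_influent()
  runner <- make_cstr_runner(inf, volume = 1000, q = 8000, kla = 120,
                             days = 2, outputs = c("COD", "TN", "NH4N"))
  y <- runner(c())
  expect_equal(dim(y), c(2L, 3L))
  expect_equal(colnames(y), c("COD", "TN", "NH4N"))
  expect_true(all(is.finite(y)) && all(y >= 0))
  # effluent COD below the influent COD (the reactor degrades substrate)
  cod_in <- asm2d_composites(inf, asm2d_params())[["COD"]]
  expect_lt(y[2, "COD"], cod_in)
  # a slower-growing nitrifier population leaves more ammonium behind
  y_slow <- runner(c(mu_AUT = 0.2))
  y_fast <- runner(c(mu_AUT = 1.5))
  expect_gt(y_slow[2, "NH4N"], y_fast[2, "NH4N"])
  # deterministic: same parameters, same output
  expect_identical(runner(c(mu_H = 5)), runner(c(mu_H = 5)))
})
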