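test_that("default plant geometry matches the documented configuration", {
  cfg <- plant_config()
  expect_equal(unname(cfg$volumes),
               c(1113, 1825, 5518, 7461, 472, 1433, 945))
  expect_equal(sum(cfg$volumes), 18767)
  expect_equal(unname(cfg$kla[c("T3", "T6")]), c(248, 120))
  expect_equal(cfg$Ql, 3.2)
  expect_equal(cfg$Qs, 1.0)
  expect_equal(cfg$Qw, 0.01)
})

test_that("configuration rejects inconsistent wiring", {
  expect_error(plant_config(volumes = c(100, 200)), "7 tank volumes")
  expect_error(plant_config(kla = c(T1 = 50)), "aerated")
  expect_error(plant_config(recycle_from = "T2", recycle_to = "T4"),
               "downstream")
  expect_error(plant_config(kla = c(T9 = 10)), "unknown tank")
  expect_error(plant_config(Ql = -1), ">= 0")
})

test_that("node flow balances close for default and degenerate recycles", {
  for (cfg in list(plant_config(),
                   plant_config(Ql = 0),
                   plant_config(Qs = 0, Qw = 0),
                   plant_config(Ql = 5, Qs = 2, Qw = 0.05))) {
    model <- build_flowsheet(cfg)
    for (Qin in c(1, 2.5e4, 1e5)) {
      fl <- plant_flows(model, Qin)
      expect_lt(fl$balance, 1e-10)
      expect_equal(fl$Q_in + fl$Q_ret, fl$Q_feed + 0 * fl$Q_feed)
      # overall plant balance: in = effluent + wastage
      expect_equal(fl$Q_in, fl$Q_eff + fl$Q_was, tolerance = 1e-12)
    }
  }
  # wastage above the influent flow itself starves the effluent
  expect_error(plant_flows(build_flowsheet(plant_config(Qw = 1.5)), 100),
               "negative")
})

test_that("compiled and reference derivatives agree at random states", {
  model <- build_flowsheet(plant_config())
  inf <- generate_synthetic_influent(days = 2, seed = 7)
  ig <- wwtpopt:::.plant_inf_grid(model, as.data.frame(inf))
  wwtpopt:::plant_ctx_set(
    wwtpopt:::.plant_cpp_parms(model, ig$tgrid, ig$qgrid, ig$zgrid))
  set.seed(5)
  for (rep in 1:5) {
    y <- runif(model$n_state, 0, 100)
    t <- runif(1, 0, 2)
    d_cpp <- wwtpopt:::plant_deriv_fast(t, y)
    d_r <- plant_derivs_r(t, y, model, ig$inf_fun)
    expect_lt(max(abs(d_cpp - d_r)) / max(1, max(abs(d_r))), 1e-10)
  }
})

test_that("short simulation conserves the inert tracer and settler TSS", {
  model <- build_flowsheet(plant_config())
  inf <- generate_synthetic_influent(days = 2, seed = 3)
  traj <- simulate_plant(model, inf, dt_out = 0.25)
  chk <- plant_balance_check(traj)
  expect_lt(chk$tracer, 1e-6)
  expect_lt(chk$settler_tss, 1e-8)
})

test_that("integrator tolerances are self-consistent", {
  model <- build_flowsheet(plant_config())
  inf <- generate_synthetic_influent(days = 2, seed = 12)
  a <- simulate_plant(model, inf, dt_out = 0.5)
  b <- simulate_plant(model, inf, dt_out = 0.5, rtol = 1e-7, atol = 1e-5)
  n <- length(a$times)
  for (ind in c("COD", "TN", "NH4N", "TP")) {
    ca <- a$composites[n, ind]; cb <- b$composites[n, ind]
    expect_lt(abs(ca - cb) / max(abs(cb), 0.1), 1e-3)
  }
})

test_that("effluent SI relaxes toward the influent SI under constant feed", {
  model <- build_flowsheet(plant_config())
  rec <- data.frame(time = 0, flow = 25000, COD = 260, TN = 42, TP = 9,
                    NH4N = 28, SS = 140)
  traj <- simulate_plant(model, rec, t_end = 5, dt_out = 0.5)
  z <- fractionate(as.list(rec[-(1:2)]), model$cfg$scheme,
                   params = model$cfg$params)
  si_in <- unname(z[["SI"]])
  n <- length(traj$times)
  err0 <- abs(traj$effluent[1, "SI"] - si_in)
  errN <- abs(traj$effluent[n, "SI"] - si_in)
  expect_lt(errN, err0)           # monotone approach
  expect_lt(errN / si_in, 0.25)   # substantially relaxed after 5 d
})

test_that("effluent limit check counts violations with exact weights", {
  # synthetic trajectory: 11 evenly spaced samples, COD above limit at
  # exactly one sample; under uniform weights that is 1/11 of the time
  comp <- matrix(0, 11, 4, dimnames = list(NULL, c("COD", "TN", "NH4N",
                                                   "TP")))
  comp[, "COD"] <- 40; comp[4, "COD"] <- 60
  traj <- list(times = seq(0, 1, by = 0.1), composites = comp)
  res <- effluent_limits_check(traj, limits = c(COD = 50, TN = 15,
                                                NH4N = 5, TP = 0.5))
  expect_equal(unname(res$violation_fraction[["COD"]]), 1 / 11,
               tolerance = 1e-12)
  expect_false(res$feasible)
  expect_equal(unname(res$worst_excess[["COD"]]), 60 / 50 - 1,
               tolerance = 1e-12)
  comp2 <- comp; comp2[, "COD"] <- 40
  res2 <- effluent_limits_check(list(times = traj$times,
                                     composites = comp2))
  expect_true(res2$feasible)
  expect_true(all(res2$worst_excess == 0))
})
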