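test_that("MQE matches hand arithmetic and handles zeros", {
  expect_equal(mqe(c(10, 20, 30), c(10, 20, 30)), 0)
  # (10-8)/10 at every point
  expect_equal(mqe(c(10, 10), c(8, 8)), 0.2, tolerance = 1e-15)
  # dirtier-than-reference effluent is negative
  expect_equal(mqe(c(20, 20), c(23, 23)), -0.15, tolerance = 1e-15)
  # mixed: mean of 0.2 and -0.15
  expect_equal(mqe(c(10, 20), c(8, 23)), (0.2 - 0.15) / 2,
               tolerance = 1e-15)
  expect_warning(v <- mqe(c(0, 10), c(5, 8)), "skipped")
  expect_equal(v, 0.2)
  expect_error(mqe(c(0, 10), c(5, 8), on_zero = "error"), "zero")
  expect_error(mqe(1:3, 1:4), "aligned")
})

test_that("pumping energy follows EP = 0.04/T integral(Qh+Qw+Qs)", {
  tt <- seq(0, 1, by = 0.1)
  # constant total flow 1000 m^3/d over one day -> 0.04 * 1000
  expect_equal(pumping_energy(tt, 500, 250, 250), 40, tolerance = 1e-12)
  expect_equal(pumping_energy(tt, 0, 0, 0), 0)
  # linear in the flows
  expect_equal(pumping_energy(tt, 1000, 500, 500),
               2 * pumping_energy(tt, 500, 250, 250), tolerance = 1e-12)
  # period length cancels for constant flows
  expect_equal(pumping_energy(seq(0, 5, by = 0.5), 500, 250, 250), 40,
               tolerance = 1e-12)
  expect_error(pumping_energy(0.5, 1, 1, 1), "two time points")
  expect_error(pumping_energy(tt, -5, 0, 0), "non-negative")
})

test_that("aeration energy reproduces the printed scalar oracle", {
  tt <- seq(0, 2, by = 0.1)
  expect_equal(aeration_energy(tt, 2e4, c(0, 0), c(7461, 945)), 0)
  # single tank, V = Tref: sum term is 0.3267*100 + 0.0007*100^2 = 39.67,
  # and for constant Qin the quadrature is exact:
  # EA = 24/(t2-t1) * (t2-t1) * 39.67/Qin
  expect_equal(aeration_energy(tt, 2e4, 100, 7461),
               24 * 39.67 / 2e4, tolerance = 1e-12)
  # volume multiplier is literal: doubling V at fixed Tref doubles EA
  expect_equal(aeration_energy(tt, 2e4, 100, 2 * 7461, Tref = 7461),
               2 * 24 * 39.67 / 2e4, tolerance = 1e-12)
  # two tanks add
  expect_equal(aeration_energy(tt, 2e4, c(100, 100), c(7461, 945)),
               2 * 24 * 39.67 / 2e4, tolerance = 1e-12)
  expect_error(aeration_energy(tt, c(2e4, 0), 100, 7461), "positive")
  expect_error(aeration_energy(tt, 2e4, c(100, 50), 7461), "aligned")
})

test_that("reactor TSS inventory matches hand arithmetic", {
  vols <- setNames(rep(2000, 7), paste0("T", 0:6))
  tanks <- lapply(1:7, function(i) asm2d_state(XI = 1000))
  names(tanks) <- names(vols)
  # one tank: 0.75 * 2000 m^3 * 1000 g/m^3 / 1000 = 1500 kg
  expect_equal(reactor_tss_inventory(tanks, vols, "T1"), 1500)
  # additive over tanks
  expect_equal(reactor_tss_inventory(tanks, vols),
               7 * reactor_tss_inventory(tanks, vols, "T1"))
  # only the five particulate-COD groups count
  tanks2 <- lapply(1:7, function(i) asm2d_state(SI = 500, XTSS = 900))
  names(tanks2) <- names(vols)
  expect_equal(reactor_tss_inventory(tanks2, vols), 0)
})

test_that("sludge production follows the inventory-difference formula", {
  tt <- seq(0, 1, by = 0.25)
  # nothing wasted, nothing accumulated
  expect_equal(sludge_production(100, 100, tt, 0, 0), 0)
  # hand case: d(inventory) = -50 kg, wasted = 0.75*400*1000/1000 = 300 kg
  expect_equal(sludge_production(100, 50, tt, 400, 1000), 250,
               tolerance = 1e-12)
  # telescoping over sub-periods
  t1 <- seq(0, 1, by = 0.25); t2 <- seq(1, 3, by = 0.25)
  sg1 <- sludge_production(100, 80, t1, 400, 1000)
  sg2 <- sludge_production(80, 90, t2, 400, 1000)
  sg <- sludge_production(100, 90, seq(0, 3, by = 0.25), 400, 1000)
  expect_equal(1 * sg1 + 2 * sg2, 3 * sg, tolerance = 1e-12)
  expect_error(sludge_production(1, 1, c(2, 1), 0, 0), "positive")
})

test_that("TCI combines the components with the sludge weight of five", {
  expect_equal(total_cost_index(0, 0, 0), 0)
  expect_equal(total_cost_index(100, 50, 10), 200)
  expect_equal(total_cost_index(2, 3, 4), 2 + 3 + 5 * 4)
  expect_error(total_cost_index(-1, 0, 0), "non-negative")
})

test_that("decision bounds and plant mapping are consistent", {
  b <- decision_bounds()
  expect_equal(dim(b), c(2L, 12L))
  expect_true(all(b["lower", ] < b["upper", ]))
  expect_equal(colnames(b), c("Ql", "Qs", "Qw", "KLa1", "KLa2",
                              paste0("T", 1:7)))
  # the baseline decision reproduces the baseline configuration
  cfg0 <- plant_config()
  x0 <- c(3.2, 1.0, 0.01, 248, 120, unname(cfg0$volumes))
  cfg <- decision_plant(x0, cfg0)
  expect_equal(cfg$volumes, cfg0$volumes)
  expect_equal(cfg$kla, cfg0$kla)
  expect_equal(cfg$Ql, cfg0$Ql)
  expect_error(decision_plant(1:5), "length 12")
})

test_that("decision evaluation is deterministic with additive OV", {
  inf <- generate_synthetic_influent(days = 2, seed = 21)
  sc <- make_scenario(inf, warmup = 0.5,
                      limits = c(COD = 100, TN = 15, NH4N = 5, TP = 10),
                      dt_out = 0.25, rtol = 1e-4, atol = 1e-2)
  cfg0 <- plant_config()
  x <- c(3.2, 1.0, 0.01, 248, 120, unname(cfg0$volumes))
  r1 <- evaluate_decision(x, sc)
  r2 <- evaluate_decision(x, sc)
  expect_s3_class(r1, "objective_triple")
  expect_identical(r1$objectives, r2$objectives)
  expect_equal(unname(r1$ov), sum(x[6:12]))
  expect_equal(unname(r1$objectives[["ov"]]), sum(x[6:12]))
  expect_equal(r1$objectives[["neg_mqe"]], -r1$mqe)
  # the baseline decision simulated on its own scenario: MQE ~ 0
  expect_lt(abs(r1$mqe), 1e-6)
  expect_equal(r1$tci, r1$breakdown$TCI)
  expect_true(is.finite(r1$tci) && r1$tci > 0)
})
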