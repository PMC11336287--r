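test_that("component set and soluble/particulate partition are fixed", {
  comps <- asm2d_components()
  expect_length(comps, 19)
  fl <- asm2d_soluble_flags()
  expect_equal(sum(fl), 9)
  expect_true(all(c("SO2", "SF", "SA", "SNH4", "SNO3", "SPO4", "SI",
                    "SALK", "SN2") %in% names(fl)[fl]))
  expect_true(all(startsWith(names(fl)[!fl], "X")))
})

test_that("state constructor validates input", {
  st <- asm2d_state(SNH4 = 10, SALK = 5)
  expect_equal(unname(st[["SNH4"]]), 10)
  expect_equal(sum(st), 15)
  expect_error(asm2d_state(BOGUS = 1), "unknown")
  expect_error(asm2d_state(SNH4 = -1), "non-negative")
})

test_that("parameter set has 42 kinetic entries with bracketing ranges", {
  p <- asm2d_params()
  expect_equal(nrow(p$kinetic), 42)
  expect_true(all(p$kinetic$value >= 0))
  expect_true(all(p$kinetic$min <= p$kinetic$value))
  expect_true(all(p$kinetic$max >= p$kinetic$value))
  p2 <- asm2d_params(overrides = c(mu_H = 4))
  expect_equal(p2$kinetic$value[p2$kinetic$name == "mu_H"], 4)
  expect_error(asm2d_params(overrides = c(nope = 1)), "unknown")
})

test_that("stoichiometric continuity closes to 1e-8", {
  resid <- asm2d_continuity(asm2d_stoichiometry(asm2d_params()))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("process rates obey the limiting-substrate trivial cases", {
  p <- asm2d_params()
  st <- asm2d_state(SF = 50, SA = 20, SNH4 = 10, SPO4 = 5, SALK = 5,
                    XH = 1000, XS = 100, XPAO = 200, XPP = 50,
                    XPHA = 20, XAUT = 100)
  # no O2 and no NO3: every aerobic and anoxic growth process is off
  r <- asm2d_process_rates(st, p)
  aer_anx <- grep("aerobic_growth|anoxic_growth", names(r))
  expect_true(all(r[aer_anx] == 0))
  # empty reactor: nothing happens
  r0 <- asm2d_process_rates(asm2d_state(), p)
  expect_true(all(r0 == 0))
  expect_true(all(is.finite(r)) && all(r >= 0))
})

test_that("heterotrophic aerobic growth matches a scalar Monod oracle", {
  p <- asm2d_params()
  k <- wwtpopt:::asm2d_kinetic_values(p)
  st <- asm2d_state(SO2 = 1e4, SF = 1e5, SA = 1e-9, SNH4 = 1e4,
                    SPO4 = 1e4, SALK = 1e4, XH = 1000)
  r <- asm2d_process_rates(st, p)
  oracle <- k[["mu_H"]] *
    (1e4 / (k[["K_O2_H"]] + 1e4)) *
    (1e5 / (k[["K_F"]] + 1e5)) * (1e5 / (1e5 + 1e-9)) *
    (1e4 / (k[["K_NH4_H"]] + 1e4)) * (1e4 / (k[["K_P_H"]] + 1e4)) *
    (1e4 / (k[["K_ALK_H"]] + 1e4)) * 1000
  expect_equal(unname(r[["aerobic_growth_SF"]]), oracle, tolerance = 1e-12)
  expect_equal(unname(r[["aerobic_growth_SF"]]) / 1000, k[["mu_H"]],
               tolerance = 1e-3)
})

test_that("rates are monotone in their own substrate", {
  p <- asm2d_params()
  base <- asm2d_state(SO2 = 2, SF = 5, SA = 3, SNH4 = 10, SPO4 = 5,
                      SALK = 5, XH = 1000)
  r0 <- asm2d_process_rates(base, p)[["aerobic_growth_SF"]]
  up <- base; up["SF"] <- 6
  r1 <- asm2d_process_rates(up, p)[["aerobic_growth_SF"]]
  expect_gte(r1, r0)
})

test_that("reactor derivative trivial and hand-arithmetic cases hold", {
  p <- asm2d_params()
  # no biomass, in = state, no aeration: everything still
  st <- asm2d_state(SI = 30, SALK = 5)
  d <- asm2d_reactor_derivatives(st, st, Q_in = 1000, V = 500, KLa = 0,
                                 params = p)
  expect_true(all(abs(d) < 1e-12))
  # aeration only: dSO2/dt = KLa (SO_sat - SO2) = 100 * (8 - 4)
  st2 <- asm2d_state(SO2 = 4)
  d2 <- asm2d_reactor_derivatives(st2, st2, Q_in = 0, V = 500, KLa = 100,
                                  SO_sat = 8, params = p)
  expect_equal(unname(d2[["SO2"]]), 400)
  expect_error(asm2d_reactor_derivatives(st, st, Q_in = 10, V = 0,
                                         params = p), "volume")
})

test_that("tracer SI has a zero stoichiometric column", {
  pm <- asm2d_stoichiometry(asm2d_params())
  expect_true(all(pm$nu[, "SI"] == 0))
})

test_that("composite variables match hand sums", {
  p <- asm2d_params()
  expect_true(all(asm2d_composites(asm2d_state(), p) == 0))
  one <- asm2d_composites(asm2d_state(SNH4 = 10), p)
  expect_equal(unname(one[["NH4N"]]), 10)
  expect_equal(unname(one[["TN"]]), 10)
  expect_equal(unname(one[["COD"]]), 0)
  cm <- asm2d_composition(p)
  st <- asm2d_state(SF = 50, XS = 100, SNH4 = 5)
  expect_equal(unname(asm2d_composites(st, p)[["TN"]]),
               5 + cm["N", "XS"] * 100 + cm["N", "SF"] * 50)
  expect_equal(unname(asm2d_composites(st, p)[["COD"]]), 150)
})

test_that("a closed batch reactor conserves oxygen-equivalent COD", {
  p <- asm2d_params()
  pm <- asm2d_stoichiometry(p)
  cm <- asm2d_composition(p)
  codw <- cm["COD", ]
  st <- asm2d_state(SO2 = 6, SF = 40, SA = 20, SNH4 = 15, SNO3 = 5,
                    SPO4 = 6, SALK = 5, SI = 25, XI = 400, XS = 150,
                    XH = 1500, XPAO = 250, XPP = 80, XPHA = 15,
                    XAUT = 90, XTSS = 2500)
  deriv <- function(t, y, parms) {
    names(y) <- asm2d_components()
    list(asm2d_reaction(pmax(y, 0), p, pm = pm))
  }
  sol <- deSolve::lsoda(as.numeric(st), seq(0, 1, by = 0.25), deriv,
                        NULL, rtol = 1e-8, atol = 1e-10)
  tot <- sol[, -1] %*% codw
  expect_lt(max(abs(tot - tot[1])) / abs(tot[1]), 1e-6)
})

test_that("parameter serialization round-trips", {
  p <- asm2d_params(overrides = c(mu_H = 5.5, Y_H = 0.6))
  f <- tempfile(fileext = ".txt")
  write_asm2d_params(p, f)
  p2 <- read_asm2d_params(f)
  expect_equal(p2$kinetic$value, p$kinetic$value, tolerance = 1e-12)
  expect_equal(p2$stoich, p$stoich, tolerance = 1e-12)
})
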