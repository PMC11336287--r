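# ASM2d biokinetics: components, parameters, stoichiometry, process rates.
#
# The model is the IWA Activated Sludge Model No. 2d (Henze et al. 1999):
# 19 components (9 soluble, 10 particulate) and 21 processes covering
# hydrolysis, heterotrophic growth/fermentation, biological P removal by
# phosphorus-accumulating organisms (PAO), nitrification, lysis, and
# (default-off) chemical P precipitation.

#' ASM2d component names
#'
#' The 19 state components of ASM2d in canonical order: 9 soluble
#' (`SO2`, `SF`, `SA`, `SNH4`, `SNO3`, `SPO4`, `SI`, `SALK`, `SN2`)
#' followed by 10 particulate (`XI`, `XS`, `XH`, `XPAO`, `XPP`, `XPHA`,
#' `XAUT`, `XTSS`, `XMeOH`, `XMeP`). Concentrations are g m^-3 (SALK:
#' mol HCO3 m^-3).
#'
#' @param soluble_only logical; return only the soluble subset.
#' @return character vector of component names.
#' @export
asm2d_components <- function(soluble_only = FALSE) {
  sol <- c("SO2", "SF", "SA", "SNH4", "SNO3", "SPO4", "SI", "SALK", "SN2")
  part <- c("XI", "XS", "XH", "XPAO", "XPP", "XPHA", "XAUT",
            "XTSS", "XMeOH", "XMeP")
  if (soluble_only) sol else c(sol, part)
}

#' Soluble/particulate flags for the ASM2d components
#'
#' @return named logical vector, TRUE for soluble ("D") components.
#' @export
asm2d_soluble_flags <- function() {
  comps <- asm2d_components()
  stats::setNames(comps %in% asm2d_components(soluble_only = TRUE), comps)
}

#' Construct an ASM2d state vector
#'
#' @param ... named component concentrations (g m^-3); unnamed components
#'   default to 0. Unknown names are an error.
#' @param .values optional named numeric vector used instead of `...`.
#' @return named numeric vector of length 19 with class `asm2d_state`.
#' @export
asm2d_state <- function(..., .values = NULL) {
  comps <- asm2d_components()
  x <- stats::setNames(numeric(length(comps)), comps)
  vals <- if (is.null(.values)) unlist(list(...)) else .values
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals))))
      stop("all state values must be named")
    bad <- setdiff(names(vals), comps)
    if (length(bad))
      stop("unknown ASM2d component(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(vals)) || any(vals < 0))
      stop("ASM2d concentrations must be finite and non-negative")
    x[names(vals)] <- vals
  }
  class(x) <- c("asm2d_state", "numeric")
  x
}

# 21 ASM2d process names, canonical order
asm2d_process_names <- function() {
  c("aerobic_hydrolysis", "anoxic_hydrolysis", "anaerobic_hydrolysis",
    "aerobic_growth_SF", "aerobic_growth_SA",
    "anoxic_growth_SF", "anoxic_growth_SA",
    "fermentation", "lysis_XH",
    "storage_XPHA", "aerobic_storage_XPP", "anoxic_storage_XPP",
    "aerobic_growth_XPAO", "anoxic_growth_XPAO",
    "lysis_XPAO", "lysis_XPP", "lysis_XPHA",
    "aerobic_growth_XAUT", "lysis_XAUT",
    "precipitation_P", "redissolution_P")
}

# default values of the 42 biological kinetic parameters at 20 degC,
# with the 10 degC value used to build the Arrhenius factor where the
# published tables give one (half-saturation constants are temperature
# independent here).
.asm2d_kinetic_table <- function() {
  # name, value at 20C, value at 10C (NA -> no temperature correction)
  tab <- rbind(
    # hydrolysis
    c("K_h",          3.0,  2.0),
    c("eta_NO3_hyd",  0.60, NA),
    c("eta_fe",       0.40, NA),
    c("K_O2_hyd",     0.20, NA),
    c("K_NO3_hyd",    0.50, NA),
    c("K_X",          0.10, 0.10),
    # heterotrophs
    c("mu_H",         6.0,  3.0),
    c("q_fe",         3.0,  1.5),
    c("eta_NO3_H",    0.80, NA),
    c("b_H",          0.40, 0.20),
    c("K_O2_H",       0.20, NA),
    c("K_F",          4.0,  NA),
    c("K_fe",         4.0,  NA),
    c("K_A_H",        4.0,  NA),
    c("K_NO3_H",      0.50, NA),
    c("K_NH4_H",      0.05, NA),
    c("K_P_H",        0.01, NA),
    c("K_ALK_H",      0.10, NA),
    # phosphorus-accumulating organisms
    c("q_PHA",        3.0,  2.0),
    c("q_PP",         1.50, 1.00),
    c("mu_PAO",       1.00, 0.67),
    c("eta_NO3_PAO",  0.60, NA),
    c("b_PAO",        0.20, 0.10),
    c("b_PP",         0.20, 0.10),
    c("b_PHA",        0.20, 0.10),
    c("K_O2_PAO",     0.20, NA),
    c("K_NO3_PAO",    0.50, NA),
    c("K_A_PAO",      4.0,  NA),
    c("K_NH4_PAO",    0.05, NA),
    c("K_PS",         0.20, NA),
    c("K_P_PAO",      0.01, NA),
    c("K_ALK_PAO",    0.10, NA),
    c("K_PP",         0.01, NA),
    c("K_MAX",        0.34, NA),
    c("K_IPP",        0.02, NA),
    c("K_PHA",        0.01, NA),
    # autotrophs (nitrifiers)
    c("mu_AUT",       1.00, 0.35),
    c("b_AUT",        0.15, 0.05),
    c("K_O2_AUT",     0.50, NA),
    c("K_NH4_AUT",    1.00, NA),
    c("K_ALK_AUT",    0.50, NA),
    c("K_P_AUT",      0.01, NA)
  )
  data.frame(name = tab[, 1],
             value = as.numeric(tab[, 2]),
             value10 = as.numeric(tab[, 3]),
             stringsAsFactors = FALSE)
}

.asm2d_kinetic_units <- function() {
  u <- c(
    K_h = "d-1", eta_NO3_hyd = "-", eta_fe = "-", K_O2_hyd = "gO2 m-3",
    K_NO3_hyd = "gN m-3", K_X = "gXS gXH-1",
    mu_H = "d-1", q_fe = "d-1", eta_NO3_H = "-", b_H = "d-1",
    K_O2_H = "gO2 m-3", K_F = "gCOD m-3", K_fe = "gCOD m-3",
    K_A_H = "gCOD m-3", K_NO3_H = "gN m-3", K_NH4_H = "gN m-3",
    K_P_H = "gP m-3", K_ALK_H = "mol m-3",
    q_PHA = "d-1", q_PP = "d-1", mu_PAO = "d-1", eta_NO3_PAO = "-",
    b_PAO = "d-1", b_PP = "d-1", b_PHA = "d-1", K_O2_PAO = "gO2 m-3",
    K_NO3_PAO = "gN m-3", K_A_PAO = "gCOD m-3", K_NH4_PAO = "gN m-3",
    K_PS = "gP m-3", K_P_PAO = "gP m-3", K_ALK_PAO = "mol m-3",
    K_PP = "gXPP gXPAO-1", K_MAX = "gXPP gXPAO-1",
    K_IPP = "gXPP gXPAO-1", K_PHA = "gXPHA gXPAO-1",
    mu_AUT = "d-1", b_AUT = "d-1", K_O2_AUT = "gO2 m-3",
    K_NH4_AUT = "gN m-3", K_ALK_AUT = "mol m-3", K_P_AUT = "gP m-3"
  )
  u
}

#' ASM2d parameter set
#'
#' Builds the full ASM2d parameter set: the 42 biological kinetic
#' parameters (with units, allowed ranges and Arrhenius-type temperature
#' factors referenced to 20 degC), the stoichiometric constants (yields,
#' inert fractions) and the composition fractions (N/P/TSS content per
#' component) used to close the conservation equations. Chemical P
#' precipitation (processes 20-21) is retained in the matrix but switched
#' off by default (`chemical_P = FALSE`), describing a purely biological
#' A2O plant.
#'
#' @param overrides named list/vector of parameter values replacing the
#'   defaults (kinetic or stoichiometric).
#' @param chemical_P logical; enable the precipitation/redissolution rates.
#' @param range_factor kinetic ranges are `default/range_factor` to
#'   `default*range_factor` (used by calibration bounds).
#' @return object of class `asm2d_params`: list with elements `kinetic`
#'   (data.frame name/value/unit/min/max/theta), `stoich` (named vector),
#'   `chemical` (named vector kPRE/kRED), `chemical_P` flag.
#' @export
asm2d_params <- function(overrides = NULL, chemical_P = FALSE,
                         range_factor = 2) {
  kin <- .asm2d_kinetic_table()
  stopifnot(nrow(kin) == 42L)
  units <- .asm2d_kinetic_units()
  kin$unit <- unname(units[kin$name])
  # Arrhenius factor theta with v(T) = v20 * theta^(T - 20)
  kin$theta <- ifelse(is.na(kin$value10) | kin$value10 == kin$value, 1,
                      (kin$value / kin$value10)^(1 / 10))
  kin$value10 <- NULL
  stoich <- c(
    f_SI = 0.0, Y_H = 0.625, f_XI = 0.10,
    Y_PAO = 0.625, Y_PO4 = 0.40, Y_PHA = 0.20, Y_A = 0.24,
    i_N_SI = 0.01, i_N_SF = 0.03, i_N_XI = 0.02, i_N_XS = 0.04,
    i_N_BM = 0.07,
    i_P_SI = 0.00, i_P_SF = 0.01, i_P_XI = 0.01, i_P_XS = 0.01,
    i_P_BM = 0.02,
    i_TSS_XI = 0.75, i_TSS_XS = 0.75, i_TSS_BM = 0.90
  )
  chem <- c(k_PRE = 1.0, k_RED = 0.60, K_ALK_PRE = 0.50)
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    for (nm in names(ov)) {
      if (nm %in% kin$name) kin$value[kin$name == nm] <- ov[[nm]]
      else if (nm %in% names(stoich)) stoich[[nm]] <- ov[[nm]]
      else if (nm %in% names(chem)) chem[[nm]] <- ov[[nm]]
      else stop("unknown ASM2d parameter: ", nm)
    }
  }
  if (any(kin$value < 0)) stop("kinetic parameters must be >= 0")
  kin$min <- kin$value / range_factor
  kin$max <- kin$value * range_factor
  structure(list(kinetic = kin, stoich = stoich, chemical = chem,
                 chemical_P = isTRUE(chemical_P)),
            class = "asm2d_params")
}

#' @export
print.asm2d_params <- function(x, ...) {
  cat("ASM2d parameter set: 42 kinetic parameters,",
      length(x$stoich), "stoichiometric constants;",
      if (x$chemical_P) "chemical P ON" else "chemical P off", "\n")
  invisible(x)
}

# named kinetic lookup (value at given temperature, degC)
asm2d_kinetic_values <- function(params, temperature = 20) {
  k <- params$kinetic
  v <- k$value * k$theta^(temperature - 20)
  stats::setNames(v, k$name)
}

#' Composition matrix of the ASM2d components
#'
#' Conservative-quantity content per component: ThOD/COD, nitrogen,
#' phosphorus, ionic charge and TSS rows used both for the stoichiometric
#' continuity closure and for composite variables. Negative COD entries
#' are oxygen (-1) and the oxygen equivalents of nitrate (-64/14) and
#' dinitrogen (-24/14).
#'
#' @param params `asm2d_params` object supplying composition fractions.
#' @return 5 x 19 numeric matrix, rows `COD`, `N`, `P`, `charge`, `TSS`.
#' @export
asm2d_composition <- function(params = asm2d_params()) {
  s <- params$stoich
  comps <- asm2d_components()
  M <- matrix(0, 5, length(comps),
              dimnames = list(c("COD", "N", "P", "charge", "TSS"), comps))
  M["COD", c("SF", "SA", "SI", "XI", "XS", "XH", "XPAO", "XPHA", "XAUT")] <- 1
  M["COD", "SO2"] <- -1
  M["COD", "SNO3"] <- -64 / 14
  M["COD", "SN2"] <- -24 / 14
  M["N", ] <- c(SO2 = 0, SF = s[["i_N_SF"]], SA = 0, SNH4 = 1, SNO3 = 1,
                SPO4 = 0, SI = s[["i_N_SI"]], SALK = 0, SN2 = 1,
                XI = s[["i_N_XI"]], XS = s[["i_N_XS"]], XH = s[["i_N_BM"]],
                XPAO = s[["i_N_BM"]], XPP = 0, XPHA = 0,
                XAUT = s[["i_N_BM"]], XTSS = 0, XMeOH = 0, XMeP = 0)[comps]
  M["P", ] <- c(SO2 = 0, SF = s[["i_P_SF"]], SA = 0, SNH4 = 0, SNO3 = 0,
                SPO4 = 1, SI = s[["i_P_SI"]], SALK = 0, SN2 = 0,
                XI = s[["i_P_XI"]], XS = s[["i_P_XS"]], XH = s[["i_P_BM"]],
                XPAO = s[["i_P_BM"]], XPP = 1, XPHA = 0,
                XAUT = s[["i_P_BM"]], XTSS = 0, XMeOH = 0,
                XMeP = 1 / 4.87)[comps]
  M["charge", c("SA", "SNH4", "SNO3", "SPO4", "SALK")] <-
    c(-1 / 64, 1 / 14, -1 / 14, -1.5 / 31, -1)
  M["charge", "XPP"] <- -1 / 31
  M["TSS", ] <- c(SO2 = 0, SF = 0, SA = 0, SNH4 = 0, SNO3 = 0, SPO4 = 0,
                  SI = 0, SALK = 0, SN2 = 0,
                  XI = s[["i_TSS_XI"]], XS = s[["i_TSS_XS"]],
                  XH = s[["i_TSS_BM"]], XPAO = s[["i_TSS_BM"]],
                  XPP = 3.23, XPHA = 0.60, XAUT = s[["i_TSS_BM"]],
                  XTSS = -1, XMeOH = 1, XMeP = 1)[comps]
  M
}

#' ASM2d stoichiometric matrix
#'
#' Assembles the 21 x 19 stoichiometric matrix. Primary coefficients
#' (substrate/product yields per the published model) are entered per
#' process; the coefficients of SO2 (from COD/ThOD conservation), SNH4
#' (N), SPO4 (P, where not a primary entry), XTSS (solids) and SALK
#' (charge) are derived from the conservation equations with the
#' composition matrix, which is the construction the published model
#' prescribes.
#'
#' @param params `asm2d_params`.
#' @return list of class `asm2d_process_matrix`: `nu` (21 x 19 matrix),
#'   `composition` (5 x 19), `processes` (names).
#' @export
asm2d_stoichiometry <- function(params = asm2d_params()) {
  s <- params$stoich
  comps <- asm2d_components()
  procs <- asm2d_process_names()
  nu <- matrix(0, length(procs), length(comps),
               dimnames = list(procs, comps))
  fSI <- s[["f_SI"]]; fXI <- s[["f_XI"]]
  YH <- s[["Y_H"]]; YPAO <- s[["Y_PAO"]]
  YPO4 <- s[["Y_PO4"]]; YPHA <- s[["Y_PHA"]]; YA <- s[["Y_A"]]

  set <- function(proc, ...) {
    v <- unlist(list(...))
    nu[proc, names(v)] <<- v
  }
  # hydrolysis (1-3): identical stoichiometry
  for (pr in c("aerobic_hydrolysis", "anoxic_hydrolysis",
               "anaerobic_hydrolysis"))
    set(pr, XS = -1, SF = 1 - fSI, SI = fSI)
  # heterotrophic growth (4-7)
  set("aerobic_growth_SF", SF = -1 / YH, XH = 1)
  set("aerobic_growth_SA", SA = -1 / YH, XH = 1)
  den <- (1 - YH) / (2.86 * YH)
  set("anoxic_growth_SF", SF = -1 / YH, XH = 1, SNO3 = -den, SN2 = den)
  set("anoxic_growth_SA", SA = -1 / YH, XH = 1, SNO3 = -den, SN2 = den)
  set("fermentation", SF = -1, SA = 1)
  set("lysis_XH", XH = -1, XS = 1 - fXI, XI = fXI)
  # PAO (10-17)
  set("storage_XPHA", SA = -1, XPHA = 1, XPP = -YPO4, SPO4 = YPO4)
  set("aerobic_storage_XPP", SPO4 = -1, XPP = 1, XPHA = -YPHA)
  set("anoxic_storage_XPP", SPO4 = -1, XPP = 1, XPHA = -YPHA,
      SNO3 = -YPHA / 2.86, SN2 = YPHA / 2.86)
  set("aerobic_growth_XPAO", XPAO = 1, XPHA = -1 / YPAO)
  dpao <- (1 - YPAO) / (2.86 * YPAO)
  set("anoxic_growth_XPAO", XPAO = 1, XPHA = -1 / YPAO,
      SNO3 = -dpao, SN2 = dpao)
  set("lysis_XPAO", XPAO = -1, XS = 1 - fXI, XI = fXI)
  set("lysis_XPP", XPP = -1, SPO4 = 1)
  set("lysis_XPHA", XPHA = -1, SA = 1)
  # autotrophs (18-19)
  set("aerobic_growth_XAUT", XAUT = 1, SNO3 = 1 / YA)
  set("lysis_XAUT", XAUT = -1, XS = 1 - fXI, XI = fXI)
  # chemical P (20-21); 4.87 g FePO4 formed and 3.45 g Fe(OH)3 consumed
  # per g P precipitated
  set("precipitation_P", SPO4 = -1, XMeOH = -3.45, XMeP = 4.87)
  set("redissolution_P", SPO4 = 1, XMeOH = 3.45, XMeP = -4.87)

  # conservation closure
  cm <- asm2d_composition(params)
  spo4_primary <- c("storage_XPHA", "aerobic_storage_XPP",
                    "anoxic_storage_XPP", "lysis_XPP",
                    "precipitation_P", "redissolution_P")
  close_balance <- function(pr, row, comp) {
    resid <- sum(cm[row, ] * nu[pr, ])
    nu[pr, comp] <<- nu[pr, comp] - resid / cm[row, comp]
  }
  for (pr in procs) {
    # order matters: SNH4/SNO3/SPO4 feed into the charge balance
    close_balance(pr, "COD", "SO2")
    close_balance(pr, "N", "SNH4")
    if (!(pr %in% spo4_primary)) close_balance(pr, "P", "SPO4")
    close_balance(pr, "TSS", "XTSS")
    close_balance(pr, "charge", "SALK")
  }
  structure(list(nu = nu, composition = cm, processes = procs),
            class = "asm2d_process_matrix")
}

#' Check stoichiometric continuity
#'
#' Evaluates the COD, N, P, charge and TSS balances of every process
#' against the composition matrix.
#'
#' @param pm `asm2d_process_matrix` from [asm2d_stoichiometry()].
#' @return 21 x 5 matrix of balance residuals (should be ~0).
#' @export
asm2d_continuity <- function(pm) {
  res <- pm$nu %*% t(pm$composition)
  res
}

#' ASM2d process rates
#'
#' Evaluates the 21 process rate expressions (g m^-3 d^-1 in the units of
#' the rate-defining component) at a given state, parameter set and
#' temperature. All switching functions are Monod terms in [0, 1];
#' ratio terms (XS/XH, XPP/XPAO, XPHA/XPAO) are zero when the biomass
#' denominator is zero. Precipitation/redissolution rates are zero unless
#' `params$chemical_P`.
#'
#' @param state `asm2d_state` (or named non-negative vector of length 19).
#' @param params `asm2d_params`.
#' @param temperature degC (Arrhenius correction, reference 20 degC).
#' @return named numeric vector of 21 non-negative rates.
#' @export
asm2d_process_rates <- function(state, params = asm2d_params(),
                                temperature = 20) {
  comps <- asm2d_components()
  if (length(state) != 19L) stop("state must have 19 components")
  st <- as.numeric(state)
  names(st) <- if (!is.null(names(state))) names(state) else comps
  if (!all(comps %in% names(st))) stop("state must name all 19 components")
  st <- st[comps]
  if (any(!is.finite(st))) stop("state must be finite")
  if (any(st < 0)) stop("negative concentration in state")
  k <- asm2d_kinetic_values(params, temperature)
  mon <- function(S, K) S / (K + S)
  SO2 <- st[["SO2"]]; SF <- st[["SF"]]; SA <- st[["SA"]]
  SNH4 <- st[["SNH4"]]; SNO3 <- st[["SNO3"]]; SPO4 <- st[["SPO4"]]
  SALK <- st[["SALK"]]
  XS <- st[["XS"]]; XH <- st[["XH"]]; XPAO <- st[["XPAO"]]
  XPP <- st[["XPP"]]; XPHA <- st[["XPHA"]]; XAUT <- st[["XAUT"]]

  rXS <- if (XH > 0) XS / XH else 0
  fXSXH <- if (XH > 0) rXS / (k[["K_X"]] + rXS) else 0
  rPP <- if (XPAO > 0) XPP / XPAO else 0
  rPHA <- if (XPAO > 0) XPHA / XPAO else 0
  fPP <- rPP / (k[["K_PP"]] + rPP)
  fPHA <- rPHA / (k[["K_PHA"]] + rPHA)
  fPPmax <- (k[["K_MAX"]] - rPP) / (k[["K_IPP"]] + k[["K_MAX"]] - rPP)
  fPPmax <- max(0, fPPmax)  # storage stops at the maximum PP content

  # anoxic/anaerobic switch = K/(K+S)
  off <- function(S, K) K / (K + S)
  sfsa <- if (SF + SA > 0) SF / (SF + SA) else 0
  nutH <- mon(SNH4, k[["K_NH4_H"]]) * mon(SPO4, k[["K_P_H"]]) *
    mon(SALK, k[["K_ALK_H"]])

  r <- numeric(21)
  names(r) <- asm2d_process_names()
  r["aerobic_hydrolysis"] <- k[["K_h"]] * mon(SO2, k[["K_O2_hyd"]]) *
    fXSXH * XH
  r["anoxic_hydrolysis"] <- k[["K_h"]] * k[["eta_NO3_hyd"]] *
    off(SO2, k[["K_O2_hyd"]]) * mon(SNO3, k[["K_NO3_hyd"]]) * fXSXH * XH
  r["anaerobic_hydrolysis"] <- k[["K_h"]] * k[["eta_fe"]] *
    off(SO2, k[["K_O2_hyd"]]) * off(SNO3, k[["K_NO3_hyd"]]) * fXSXH * XH
  r["aerobic_growth_SF"] <- k[["mu_H"]] * mon(SO2, k[["K_O2_H"]]) *
    mon(SF, k[["K_F"]]) * sfsa * nutH * XH
  r["aerobic_growth_SA"] <- k[["mu_H"]] * mon(SO2, k[["K_O2_H"]]) *
    mon(SA, k[["K_A_H"]]) * (1 - sfsa) * nutH * XH
  r["anoxic_growth_SF"] <- k[["mu_H"]] * k[["eta_NO3_H"]] *
    off(SO2, k[["K_O2_H"]]) * mon(SNO3, k[["K_NO3_H"]]) *
    mon(SF, k[["K_F"]]) * sfsa * nutH * XH
  r["anoxic_growth_SA"] <- k[["mu_H"]] * k[["eta_NO3_H"]] *
    off(SO2, k[["K_O2_H"]]) * mon(SNO3, k[["K_NO3_H"]]) *
    mon(SA, k[["K_A_H"]]) * (1 - sfsa) * nutH * XH
  r["fermentation"] <- k[["q_fe"]] * off(SO2, k[["K_O2_H"]]) *
    off(SNO3, k[["K_NO3_H"]]) * mon(SF, k[["K_fe"]]) *
    mon(SALK, k[["K_ALK_H"]]) * XH
  r["lysis_XH"] <- k[["b_H"]] * XH
  nutP <- mon(SALK, k[["K_ALK_PAO"]])
  r["storage_XPHA"] <- k[["q_PHA"]] * mon(SA, k[["K_A_PAO"]]) * nutP *
    fPP * XPAO
  store_common <- k[["q_PP"]] * mon(SPO4, k[["K_PS"]]) * nutP *
    fPHA * fPPmax * XPAO
  r["aerobic_storage_XPP"] <- store_common * mon(SO2, k[["K_O2_PAO"]])
  r["anoxic_storage_XPP"] <- store_common * k[["eta_NO3_PAO"]] *
    off(SO2, k[["K_O2_PAO"]]) * mon(SNO3, k[["K_NO3_PAO"]])
  grow_common <- k[["mu_PAO"]] * mon(SNH4, k[["K_NH4_PAO"]]) *
    mon(SPO4, k[["K_P_PAO"]]) * nutP * fPHA * XPAO
  r["aerobic_growth_XPAO"] <- grow_common * mon(SO2, k[["K_O2_PAO"]])
  r["anoxic_growth_XPAO"] <- grow_common * k[["eta_NO3_PAO"]] *
    off(SO2, k[["K_O2_PAO"]]) * mon(SNO3, k[["K_NO3_PAO"]])
  r["lysis_XPAO"] <- k[["b_PAO"]] * nutP * XPAO
  r["lysis_XPP"] <- k[["b_PP"]] * nutP * XPP
  r["lysis_XPHA"] <- k[["b_PHA"]] * nutP * XPHA
  r["aerobic_growth_XAUT"] <- k[["mu_AUT"]] * mon(SO2, k[["K_O2_AUT"]]) *
    mon(SNH4, k[["K_NH4_AUT"]]) * mon(SPO4, k[["K_P_AUT"]]) *
    mon(SALK, k[["K_ALK_AUT"]]) * XAUT
  r["lysis_XAUT"] <- k[["b_AUT"]] * XAUT
  if (isTRUE(params$chemical_P)) {
    ch <- params$chemical
    r["precipitation_P"] <- ch[["k_PRE"]] * SPO4 * st[["XMeOH"]]
    r["redissolution_P"] <- ch[["k_RED"]] * st[["XMeP"]] *
      mon(SALK, ch[["K_ALK_PRE"]])
  }
  r
}

#' Reaction term of the ASM2d model
#'
#' `r_C = nu^T %*% rho`: net conversion rate per component.
#'
#' @param state,params,temperature as in [asm2d_process_rates()].
#' @param pm optional precomputed `asm2d_process_matrix`.
#' @return named numeric vector of 19 derivatives (g m^-3 d^-1).
#' @export
asm2d_reaction <- function(state, params = asm2d_params(),
                           temperature = 20, pm = NULL) {
  if (is.null(pm)) pm <- asm2d_stoichiometry(params)
  rho <- asm2d_process_rates(state, params, temperature)
  drop(rho %*% pm$nu)
}

#' CSTR mass balance for one bioreactor
#'
#' dC/dt = Q_in/V (C_in - C) + r(C), plus the aeration term
#' KLa (SO_sat - SO2) on dissolved oxygen only.
#'
#' @param state tank state; `in_state` inflow composition.
#' @param Q_in inflow (m^3 d^-1); `V` volume (m^3); `KLa` d^-1;
#'   `SO_sat` oxygen saturation (g m^-3).
#' @param params,temperature,pm as in [asm2d_reaction()].
#' @return named derivative vector (g m^-3 d^-1).
#' @export
asm2d_reactor_derivatives <- function(state, in_state, Q_in, V,
                                      KLa = 0, SO_sat = 8,
                                      params = asm2d_params(),
                                      temperature = 20, pm = NULL) {
  if (V <= 0) stop("tank volume must be > 0")
  if (Q_in < 0) stop("inflow must be >= 0")
  if (KLa < 0) stop("KLa must be >= 0")
  r <- asm2d_reaction(state, params, temperature, pm)
  d <- Q_in / V * (as.numeric(in_state) - as.numeric(state)) + r
  names(d) <- asm2d_components()
  d["SO2"] <- d["SO2"] + KLa * (SO_sat - state[["SO2"]])
  d
}

#' Composite quality indicators of an ASM2d state
#'
#' COD sums the organic (positive-COD) components; NH4-N is SNH4; TN is
#' inorganic N (SNH4 + SNO3) plus organically bound N via the composition
#' fractions (dissolved N2 gas excluded); TP likewise includes poly-P and
#' mineral P; TSS follows the ASM2d solids accounting of the composition
#' matrix.
#'
#' @param state ASM2d state vector (or matrix with 19 named columns).
#' @param params `asm2d_params` supplying composition fractions.
#' @return named vector (or matrix) with `COD`, `TN`, `TP`, `NH4N`, `TSS`.
#' @export
asm2d_composites <- function(state, params = asm2d_params()) {
  cm <- asm2d_composition(params)
  comps <- asm2d_components()
  m <- if (is.matrix(state)) state[, comps, drop = FALSE]
       else matrix(as.numeric(state[comps]), 1,
                   dimnames = list(NULL, comps))
  codw <- pmax(cm["COD", ], 0)           # measured COD: organics only
  nw <- cm["N", ]; nw["SN2"] <- 0        # TN excludes dissolved N2
  pw <- cm["P", ]
  tssw <- cm["TSS", ]; tssw["XTSS"] <- 0
  out <- cbind(COD = drop(m %*% codw),
               TN = drop(m %*% nw),
               TP = drop(m %*% pw),
               NH4N = m[, "SNH4"],
               TSS = drop(m %*% tssw))
  if (is.matrix(state)) out else out[1, ]
}

#' Write / read an ASM2d parameter set as a flat text table
#'
#' Serialization of the kinetic table (name, value, unit, min, max) plus
#' the stoichiometric constants, as whitespace-delimited key-value text.
#'
#' @param params `asm2d_params`; `path` file path.
#' @return `read_asm2d_params` returns an `asm2d_params`.
#' @export
write_asm2d_params <- function(params, path) {
  kin <- params$kinetic
  lines <- c("# ASM2d parameters: name value unit min max",
             sprintf("%-14s %.6g %-14s %.6g %.6g", kin$name, kin$value,
                     gsub(" ", "_", kin$unit), kin$min, kin$max),
             "# stoichiometric",
             sprintf("%-14s %.6g - NA NA", names(params$stoich),
                     params$stoich))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_asm2d_params
#' @export
read_asm2d_params <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  parts <- strsplit(trimws(raw), "\\s+")
  nm <- vapply(parts, `[[`, "", 1L)
  val <- as.numeric(vapply(parts, `[[`, "", 2L))
  asm2d_params(overrides = stats::setNames(as.list(val), nm))
}
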