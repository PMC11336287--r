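# Influent handling: fractionation of measured indicators (COD, TN, TP,
# NH4-N, SS) into the 19 ASM2d components, synthetic dynamic influent
# generation, and CSV input/output.

.influent_cols <- c("time", "flow", "COD", "TN", "TP", "NH4N", "SS")

#' Influent fractionation scheme
#'
#' Splits measured total COD into the ASM2d organic fractions. The
#' defaults are typical municipal-wastewater characterization values.
#' Ammonium is taken directly from the measured NH4-N; organically bound
#' N and P follow from the composition fractions of the fractionated
#' components; the residual inorganic N (TN - NH4N - organic N) is
#' assigned to nitrate, and residual P to ortho-phosphate, so the
#' measured totals are conserved exactly. Alkalinity is fixed (`SALK`,
#' default 5 mol m^-3); trace components outside the COD/N/P balances
#' (`SO2`, `SN2`, `XMeOH`) receive a small floor value (default
#' 0.02 g m^-3); storage and biomass pools not present in raw sewage
#' (`XPAO`, `XAUT`, `XPP`, `XPHA`, `XMeP`) are zero.
#'
#' @param cod_fractions named vector over a subset of
#'   `SF, SA, SI, XI, XS, XH`, summing to 1.
#' @param SALK fixed influent alkalinity (mol m^-3).
#' @param floor_value concentration assigned to the floor components.
#' @param floor_components components receiving the floor value; must not
#'   carry COD, N or P.
#' @return object of class `fractionation_scheme`.
#' @export
fractionation_scheme <- function(cod_fractions = c(SF = 0.20, SA = 0.10,
                                                   SI = 0.08, XI = 0.12,
                                                   XS = 0.35, XH = 0.15),
                                 SALK = 5, floor_value = 0.02,
                                 floor_components = c("SO2", "SN2", "XMeOH")) {
  allowed <- c("SF", "SA", "SI", "XI", "XS", "XH")
  if (!all(names(cod_fractions) %in% allowed))
    stop("cod_fractions must be named over ", paste(allowed, collapse = ", "))
  if (any(cod_fractions < 0) || any(cod_fractions > 1))
    stop("COD fractions must lie in [0, 1]")
  if (abs(sum(cod_fractions) - 1) > 1e-9)
    stop("COD fractions must sum to 1")
  structure(list(cod_fractions = cod_fractions, SALK = SALK,
                 floor_value = floor_value,
                 floor_components = floor_components),
            class = "fractionation_scheme")
}

#' Fractionate one influent record into an ASM2d state
#'
#' @param rec list/one-row data.frame with `COD`, `TN`, `TP`, `NH4N`, `SS`
#'   (g m^-3).
#' @param scheme `fractionation_scheme`.
#' @param params `asm2d_params` (composition fractions for organic N/P).
#' @return `asm2d_state` whose composite COD, TN, TP, NH4N reproduce the
#'   record (nitrogen residuals clipped at zero are warned about).
#' @export
fractionate <- function(rec, scheme = fractionation_scheme(),
                        params = asm2d_params()) {
  st <- asm2d_state()
  fr <- scheme$cod_fractions
  st[names(fr)] <- fr * rec$COD
  st["SALK"] <- scheme$SALK
  st[scheme$floor_components] <- scheme$floor_value
  cm <- asm2d_composition(params)
  orgN <- sum(cm["N", names(fr)] * st[names(fr)])
  orgP <- sum(cm["P", names(fr)] * st[names(fr)])
  st["SNH4"] <- rec$NH4N
  sno3 <- rec$TN - rec$NH4N - orgN
  if (sno3 < -1e-9)
    warning("organic N exceeds TN - NH4N; clipping SNO3 at 0 ",
            "(TN not conserved)")
  st["SNO3"] <- max(0, sno3)
  spo4 <- rec$TP - orgP
  if (spo4 < -1e-9)
    warning("organic P exceeds TP; clipping SPO4 at 0 (TP not conserved)")
  st["SPO4"] <- max(0, spo4)
  st["XTSS"] <- rec$SS
  st
}

#' Synthetic influent profile
#'
#' Statistical model of a 40-day municipal influent: per-indicator base
#' level, diurnal sinusoid, first-order autocorrelated (AR(1)) noise and
#' Poisson-timed rain events that raise the flow while diluting the
#' pollutant concentrations. Defaults emulate an influent whose COD spans
#' roughly 98-422 g m^-3 and whose TP/NH4-N/TN standard deviations are
#' about 5.8/6.0/1.9 g m^-3 over 40 days.
#'
#' @param flow_base dry-weather flow (m^3 d^-1).
#' @param cod_base,cod_amp,cod_sd COD base level, diurnal amplitude and
#'   AR(1) marginal standard deviation (g m^-3).
#' @param cod_range clipping range for COD (g m^-3).
#' @param tn_base,tn_sd total nitrogen base and noise SD.
#' @param nh4_ratio,nh4_ratio_sd mean and SD of the ratio of NH4-N to the
#'   inorganic-available nitrogen `TN - orgn_frac * COD` (ratio clipped to
#'   [0.05, 0.98] so the series always fractionates with `NH4N < TN` and
#'   a non-negative nitrate residual).
#' @param orgn_frac,orgp_frac organically bound N and P per unit COD;
#'   defaults match the default [fractionation_scheme()] and
#'   [asm2d_params()] composition fractions.
#' @param tp_base,tp_sd total phosphorus base and noise SD; TP is floored
#'   at `orgp_frac * COD + 0.1` so phosphate never clips negative.
#' @param ss_ratio SS as a fraction of COD.
#' @param diurnal_frac relative diurnal amplitude applied to flow and COD
#'   load (nutrient concentrations carry only stochastic variation).
#' @param ar_phi lag-1 autocorrelation of the noise at the output step.
#' @param rain_rate rain events per day (Poisson); `rain_factor` peak
#'   flow multiplier; `rain_dilution` concentration multiplier at peak;
#'   `rain_duration` event e-folding time (d).
#' @return object of class `influent_profile`.
#' @export
influent_profile <- function(flow_base = 30000,
                             cod_base = 255, cod_amp = 40, cod_sd = 55,
                             cod_range = c(98, 422),
                             tn_base = 42, tn_sd = 1.8,
                             nh4_ratio = 0.75, nh4_ratio_sd = 0.17,
                             orgn_frac = 0.0337, orgp_frac = 0.0097,
                             tp_base = 9, tp_sd = 6.3,
                             ss_ratio = 0.55,
                             diurnal_frac = 0.15, ar_phi = 0.7,
                             rain_rate = 0.15, rain_factor = 1.8,
                             rain_dilution = 0.55, rain_duration = 0.4) {
  structure(as.list(environment()), class = "influent_profile")
}

#' Generate a synthetic dynamic influent series
#'
#' Deterministic for a fixed seed. COD is clipped to `profile$cod_range`;
#' the NH4-N/TN ratio construction keeps `NH4N <= TN` everywhere.
#'
#' @param days length of the series (d).
#' @param dt output step (d), default hourly.
#' @param seed integer RNG seed.
#' @param profile `influent_profile`.
#' @return data.frame of class `influent_series` with columns
#'   `time, flow, COD, TN, TP, NH4N, SS`.
#' @export
generate_synthetic_influent <- function(days = 40, dt = 1 / 24, seed = 1,
                                        profile = influent_profile()) {
  if (days <= 0) stop("days must be > 0")
  p <- profile
  n <- floor(days / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  rng <- new_rng(seed)
  ar1 <- function(sd) {
    # AR(1) with marginal SD sd and lag-1 correlation ar_phi
    e <- rng_norm(rng, n) * sd * sqrt(1 - p$ar_phi^2)
    x <- numeric(n)
    x[1] <- rng_norm(rng, 1) * sd
    for (i in 2:n) x[i] <- p$ar_phi * x[i - 1] + e[i]
    x
  }
  diurnal <- sin(2 * pi * (tt - 0.35))   # morning peak
  # rain events: Poisson-timed, exponential decay
  n_rain <- rng_pois(rng, p$rain_rate * days)
  rain <- numeric(n)
  if (n_rain > 0) {
    starts <- sort(rng_unif(rng, n_rain) * days)
    for (s in starts) {
      idx <- tt >= s
      rain[idx] <- pmax(rain[idx], exp(-(tt[idx] - s) / p$rain_duration))
    }
  }
  flow <- p$flow_base * (1 + p$diurnal_frac * diurnal) *
    (1 + (p$rain_factor - 1) * rain)
  dil <- 1 - (1 - p$rain_dilution) * rain
  cod <- (p$cod_base + p$cod_amp * diurnal + ar1(p$cod_sd)) * dil
  cod <- pmin(p$cod_range[2], pmax(p$cod_range[1], cod))
  orgn <- p$orgn_frac * cod
  tn <- pmax(orgn + 0.5, (p$tn_base + ar1(p$tn_sd)) * (0.8 + 0.2 * dil))
  ratio <- pmin(0.98, pmax(0.05, p$nh4_ratio + ar1(p$nh4_ratio_sd)))
  nh4 <- ratio * (tn - orgn)
  orgp <- p$orgp_frac * cod
  tp <- pmax(orgp + 0.1, (p$tp_base + ar1(p$tp_sd)) * dil)
  ss <- p$ss_ratio * cod
  out <- data.frame(time = tt, flow = flow, COD = cod, TN = tn, TP = tp,
                    NH4N = nh4, SS = ss)
  class(out) <- c("influent_series", "data.frame")
  out
}

validate_influent <- function(df) {
  missing <- setdiff(.influent_cols, names(df))
  if (length(missing))
    stop("influent is missing column(s): ", paste(missing, collapse = ", "))
  if (any(diff(df$time) <= 0)) stop("influent time must be strictly increasing")
  for (cc in setdiff(.influent_cols, "time")) {
    bad <- which(df[[cc]] < 0)
    if (length(bad))
      stop("negative ", cc, " in influent row ", bad[1])
  }
  if (any(df$NH4N > df$TN + 1e-9))
    stop("influent NH4N exceeds TN")
  invisible(df)
}

#' Read / write an influent CSV
#'
#' Comma-separated, header `time,flow,COD,TN,TP,NH4N,SS`, `.` decimal.
#' Reading validates the header, monotone time and non-negativity.
#'
#' @param path file path; `df` influent data.frame.
#' @return `read_influent_csv` returns a validated `influent_series`.
#' @export
read_influent_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  validate_influent(df)
  df <- df[, .influent_cols]
  class(df) <- c("influent_series", "data.frame")
  df
}

#' @rdname read_influent_csv
#' @export
write_influent_csv <- function(df, path) {
  validate_influent(df)
  utils::write.csv(df[, .influent_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Interpolating functions over an influent series
#'
#' @param df influent series; constant extrapolation beyond the range.
#' @return named list of functions of time for flow and each indicator.
#' @keywords internal
influent_interpolators <- function(df) {
  lapply(stats::setNames(setdiff(.influent_cols, "time"),
                         setdiff(.influent_cols, "time")),
         function(cc) stats::approxfun(df$time, df[[cc]], rule = 2))
}
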