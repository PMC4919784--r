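#' Fit a slow H/D amide-exchange decay
#'
#' Fits the three-parameter decay I(t) = I_inf + A exp(-k t) to cross-peak
#' intensities (or volumes) recorded after dissolution in D2O. Residues that
#' exchanged fully before the first spectrum are censored as `too_fast` with
#' a lower bound on k derived from the experimental dead time; residues whose
#' decay over the observation window is indistinguishable from noise are
#' censored as `too_slow` with an upper bound on k. Censored results carry
#' bounds only, never point estimates.
#'
#' @param series An `intensity_series` with `x_kind = "exchange_time"`
#'   (seconds, >= 4 points).
#' @param noise_floor Intensity level considered indistinguishable from
#'   noise.
#' @param dead_time Experimental dead time in seconds (default 1800).
#' @param ref_intensity Pre-exchange reference intensity for the dead-time
#'   bound; defaults to the largest observed intensity in the series.
#' @param noise_frac Fractional noise level used for the too-slow test.
#' @return List of class `hx_fit`: `censor` (`"measured"`, `"too_fast"`,
#'   `"too_slow"`), and either `k`, `amplitude`, `plateau` with SDs, or
#'   `k_lower`/`k_upper` bound (s^-1).
#' @export
fit_hx_decay <- function(series, noise_floor = 0, dead_time = 1800,
                         ref_intensity = NULL, noise_frac = 0.02) {
  t <- series$x; y <- series$intensity
  if (length(t) < 4) stop("need >= 4 time points", call. = FALSE)
  if (is.null(ref_intensity)) ref_intensity <- max(y)
  key <- list(residue = series$residue, residue_name = series$residue_name)

  if (all(y <= noise_floor + .Machine$double.eps) ||
      (noise_floor > 0 && y[which.min(t)] <= noise_floor)) {
    # fully exchanged within the dead time: signal was >= ref at t = 0 and
    # is at the floor by the first observation
    k_lower <- log(max(ref_intensity / max(noise_floor, ref_intensity * 1e-3),
                       exp(1))) / dead_time
    return(structure(c(key, list(censor = "too_fast", k_lower = k_lower)),
                     class = "hx_fit"))
  }
  # too-slow censor on the mean early vs late signal (robust to single-point
  # noise): relative decay below 3 sigma of the difference of means
  ord <- order(t)
  nt <- max(2L, length(t) %/% 3)
  y_early <- mean(y[ord][seq_len(nt)])
  y_late <- mean(y[ord][seq(length(t) - nt + 1, length(t))])
  rel_decay <- (y_early - y_late) / y_early
  if (rel_decay < 3 * noise_frac * sqrt(2 / nt)) {
    window <- max(t) - min(t)
    k_upper <- -log(1 - 3 * noise_frac) / window
    return(structure(c(key, list(censor = "too_slow", k_upper = k_upper)),
                     class = "hx_fit"))
  }
  st <- list(iinf = min(y), A = max(y) - min(y),
             k = max(1 / max(t), loglin_start(t, pmax(y - min(y), 1e-12))["rate"]))
  fit <- try(minpack.lm::nlsLM(y ~ iinf + A * exp(-k * t),
                               data = data.frame(t = t, y = y), start = st,
                               lower = c(-Inf, 0, 0),
                               control = minpack.lm::nls.lm.control(maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # near-flat data that escaped the censor threshold
    if (rel_decay < 6 * noise_frac) {
      k_upper <- -log(1 - 3 * noise_frac) / (max(t) - min(t))
      return(structure(c(key, list(censor = "too_slow", k_upper = k_upper)),
                       class = "hx_fit"))
    }
    stop("H/D decay fit failed for residue ", series$residue, call. = FALSE)
  }
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(c(key, list(censor = "measured",
                        k = unname(co["k"]), k_sd = unname(se["k"]),
                        amplitude = unname(co["A"]),
                        amplitude_sd = unname(se["A"]),
                        plateau = unname(co["iinf"]),
                        plateau_sd = unname(se["iinf"]))),
            class = "hx_fit")
}

#' CLEANEX build-up model
#'
#' I(tau_m)/I_0 = k/(R_1A + k - R_1B) * (exp(-R_1B tau_m)
#'                - exp(-(R_1A + k) tau_m)).
#'
#' @param tau_m Mixing times (s).
#' @param k Exchange rate (s^-1).
#' @param r1a_app Apparent amide relaxation rate (s^-1).
#' @param r1b_app Apparent water relaxation rate (s^-1), fixed constant.
#' @return Normalized build-up intensities.
#' @export
cleanex_model <- function(tau_m, k, r1a_app, r1b_app = 0.6) {
  k / (r1a_app + k - r1b_app) *
    (exp(-r1b_app * tau_m) - exp(-(r1a_app + k) * tau_m))
}

#' Fit a CLEANEX hydrogen-exchange build-up curve
#'
#' Fits (k, R_1A,app) of [cleanex_model()] to I(tau_m)/I_0 with the water
#' relaxation rate R_1B,app held at a fixed, previously determined value
#' (default 0.6 s^-1; configuration, never fitted). The initial slope of the
#' model at tau_m = 0 equals k, which provides the starting guess.
#'
#' @param series An `intensity_series` with `x_kind = "mixing_time"`
#'   (seconds).
#' @param i0 Reference intensity at tau_m = 0 (> 0), supplied separately.
#' @param r1b_app Fixed apparent water relaxation rate (s^-1).
#' @return List of class `cleanex_fit`: `k`, `k_sd`, `r1a_app`, `r1a_sd`,
#'   `r1b_app`, `flag` (`"ok"` or `"bound"`).
#' @export
fit_cleanex_buildup <- function(series, i0, r1b_app = 0.6) {
  if (i0 <= 0) stop("reference intensity must be positive", call. = FALSE)
  tau <- series$x; y <- series$intensity / i0
  use <- tau > 0
  slope0 <- if (any(use)) max(y[use] / tau[use]) else 1
  st <- list(k = max(slope0, 0.5), r1a = 2)
  fit <- minpack.lm::nlsLM(
    y ~ cleanex_model(tau, k, r1a, r1b_app),
    data = data.frame(tau = tau, y = y), start = st,
    lower = c(1e-6, 1e-6), upper = c(1e4, 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  at_bound <- co["k"] <= 2e-6 || co["k"] >= 9.9e3
  structure(list(residue = series$residue,
                 residue_name = series$residue_name,
                 k = unname(co["k"]), k_sd = unname(se["k"]),
                 r1a_app = unname(co["r1a"]), r1a_sd = unname(se["r1a"]),
                 r1b_app = r1b_app,
                 flag = if (at_bound) "bound" else "ok"),
            class = "cleanex_fit")
}

load_exchange_factors <- function() {
  path <- system.file("extdata", "intrinsic_exchange_factors.csv",
                      package = "nmrdyn")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Poly-DL-alanine reference rate constants (log10, min^-1 scale) and
# Arrhenius activation energies (kcal/mol), 293 K reference.
INTRINSIC_REF <- list(
  D2O = list(log_ka = 1.62, log_kb = 10.05, log_kw = -1.5, pK = 15.05),
  H2O = list(log_ka = 1.62, log_kb = 10.05, log_kw = -1.5, pK = 14.17),
  ea = c(acid = 14, base = 17, water = 19),
  t_ref = 293.15
)

#' Intrinsic (random-coil) amide exchange rate for one position
#'
#' Predicts the sequence-dependent intrinsic exchange rate of the backbone
#' amide at `position` from the poly-DL-alanine reference rates with the
#' published side-chain correction factors, acid/base/water catalysis terms,
#' pH (or pD) dependence, and Arrhenius temperature correction. In D2O the
#' glass-electrode reading is corrected as pD = pH_read + 0.4 by default.
#'
#' @param sequence Character vector of three-letter codes (or a single
#'   one-letter string).
#' @param position Residue position (>= 2; position 1 and prolines have no
#'   exchangeable backbone amide).
#' @param pH Glass-electrode pH reading.
#' @param temperature_k Temperature in Kelvin.
#' @param medium `"D2O"` (H/D exchange) or `"H2O"` (CLEANEX).
#' @param pd_correction Apply the +0.4 pD correction in D2O.
#' @return Intrinsic rate k_int in s^-1.
#' @export
intrinsic_rate <- function(sequence, position, pH = 7.4,
                           temperature_k = 298.15,
                           medium = c("D2O", "H2O"), pd_correction = TRUE) {
  medium <- match.arg(medium)
  seq3 <- as_seq3(sequence)
  n <- length(seq3)
  if (position < 2 || position > n) {
    stop("position ", position, if (position == 1)
      " is the N-terminal residue: no observable backbone amide" else
      " outside sequence", call. = FALSE)
  }
  if (seq3[position] == "PRO") {
    stop("proline at position ", position, " has no backbone amide",
         call. = FALSE)
  }
  fac <- load_exchange_factors()
  row_of <- function(code) fac[fac$residue == code, ]
  self <- row_of(seq3[position])
  prev <- row_of(seq3[position - 1])
  acid <- self$acid_self + prev$acid_prev
  base <- self$base_self + prev$base_prev
  if (position == 2) {
    nt <- row_of("NT2")
    acid <- acid + nt$acid_prev
    base <- base + nt$base_prev
  }
  if (position == n) {
    ct <- row_of("CT")
    acid <- acid + ct$acid_self
    base <- base + ct$base_self
  }
  ref <- INTRINSIC_REF[[medium]]
  pX <- if (medium == "D2O" && pd_correction) pH + 0.4 else pH
  k_acid <- 10^(ref$log_ka + acid - pX)
  k_base <- 10^(ref$log_kb + base + pX - ref$pK)
  k_water <- 10^(ref$log_kw + base)
  ea <- INTRINSIC_REF$ea
  arr <- function(e) exp(-e / 1.9872e-3 * (1 / temperature_k - 1 / INTRINSIC_REF$t_ref))
  k_min <- k_acid * arr(ea["acid"]) + k_base * arr(ea["base"]) +
    k_water * arr(ea["water"])
  unname(k_min / 60)   # min^-1 -> s^-1
}

as_seq3 <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 3 &&
      !sequence[1] %in% AA3) {
    letters1 <- strsplit(toupper(sequence[1]), "")[[1]]
    code3 <- names(AA1)[match(letters1, AA1)]
    if (anyNA(code3)) stop("unknown one-letter code in sequence", call. = FALSE)
    return(code3)
  }
  toupper(sequence)
}

#' Protection factor and EX2 opening thermodynamics
#'
#' Under the EX2 limit (closing much faster than intrinsic exchange), the
#' observed rate reports the opening equilibrium: P_f = k_int / k_obs,
#' K_op = P_f^-1, Delta-G_op = R T ln(P_f), and the open-state population
#' P_op = K_op / (1 + K_op). Censored observed rates (bounds from
#' [fit_hx_decay()]) propagate to one-sided bounds on all derived
#' quantities.
#'
#' @param k_obs Observed exchange rate (s^-1), or `NULL` if censored.
#' @param k_int Intrinsic rate from [intrinsic_rate()] (s^-1).
#' @param temperature_k Temperature (K).
#' @param censor `"measured"`, `"too_fast"`, `"too_slow"`.
#' @param k_bound Bounding rate for censored inputs (lower bound of k for
#'   `too_fast`, upper bound for `too_slow`).
#' @param source Label recording which experiment k_obs came from.
#' @return List of class `protection_result` with `pf`, `log10_pf`,
#'   `dg_op_kcal`, `k_op`, `p_op` (point values or one-sided bounds with a
#'   `bound_type` field: `"lower"`/`"upper"` refer to the bound on `pf` and
#'   `dg_op_kcal`; the implied bound on `p_op` is in the opposite
#'   direction), plus `ex2_assumed = TRUE`.
#' @export
protection_analysis <- function(k_obs, k_int, temperature_k = 298.15,
                                censor = "measured", k_bound = NULL,
                                source = "HX") {
  R <- 1.9872e-3
  derive <- function(k) {
    pf <- k_int / k
    if (pf <= 0) stop("non-positive protection factor", call. = FALSE)
    k_op <- 1 / pf
    list(pf = pf, log10_pf = log10(pf),
         dg_op_kcal = R * temperature_k * log(pf),
         k_op = k_op, p_op = k_op / (1 + k_op))
  }
  if (censor == "measured") {
    if (is.null(k_obs) || k_obs <= 0) stop("k_obs must be positive", call. = FALSE)
    out <- c(derive(k_obs), list(bound_type = "point"))
  } else if (censor == "too_slow") {
    # k_obs < k_upper  =>  P_f > k_int/k_upper: lower bounds on pf, dG_op
    out <- c(derive(k_bound), list(bound_type = "lower"))
  } else if (censor == "too_fast") {
    # k_obs > k_lower  =>  P_f < k_int/k_lower: upper bounds
    out <- c(derive(k_bound), list(bound_type = "upper"))
  } else stop("unknown censor status: ", censor, call. = FALSE)
  structure(c(out, list(k_int = k_int, censor = censor, source = source,
                        temperature_k = temperature_k, ex2_assumed = TRUE)),
            class = "protection_result")
}
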