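#' Construct a CD melting curve
#'
#' @param temp_c Temperatures in degrees Celsius (strictly increasing).
#' @param signal Ellipticity values.
#' @param unit `"mdeg"` (raw) or `"mre"` (mean-residue ellipticity,
#'   deg cm^2 dmol^-1).
#' @param conc_m Protein concentration (mol/L).
#' @param ligand_m Total ligand concentration (mol/L; 0 for apo).
#' @param mrw Mean residue weight (g/mol).
#' @param path_cm CD cell path length (cm).
#' @param n_residues Number of residues (chain mass = mrw * n_residues).
#' @return List of class `melt_curve` (temperatures stored in Kelvin).
#' @export
melt_curve <- function(temp_c, signal, unit = c("mdeg", "mre"),
                       conc_m, ligand_m = 0, mrw = 110, path_cm = 0.1,
                       n_residues = 210) {
  unit <- match.arg(unit)
  stopifnot(length(temp_c) == length(signal), conc_m > 0,
            all(diff(temp_c) > 0))
  structure(list(temp_k = temp_c + 273.15, signal = signal, unit = unit,
                 conc_m = conc_m, ligand_m = ligand_m, mrw = mrw,
                 path_cm = path_cm, n_residues = n_residues),
            class = "melt_curve")
}

#' Convert raw mdeg ellipticity to mean-residue ellipticity
#'
#' [theta] = mdeg * MRW / (10 * l * c), with c the protein concentration in
#' mg/mL (derived from molarity and the MRW-consistent chain mass), l the
#' path length in cm. The transformation is linear and invertible.
#'
#' @param curve A `melt_curve` with `unit = "mdeg"`.
#' @return The curve with signal in deg cm^2 dmol^-1 and `unit = "mre"`.
#' @export
mdeg_to_mre <- function(curve) {
  if (curve$unit != "mdeg") stop("curve is not in raw mdeg", call. = FALSE)
  if (is.null(curve$mrw) || is.null(curve$path_cm) || is.null(curve$conc_m)) {
    stop("MRW, path length and concentration are required", call. = FALSE)
  }
  chain_mass <- curve$mrw * curve$n_residues          # g/mol
  c_mg_ml <- curve$conc_m * chain_mass                # mg/mL
  curve$signal <- curve$signal * curve$mrw / (10 * curve$path_cm * c_mg_ml)
  curve$unit <- "mre"
  curve
}

#' Gibbs-Helmholtz free energy of unfolding
#'
#' Delta-G_u(T) = dH (1 - T/Tm) + dCp ((T - Tm) - T ln(T/Tm)), which is zero
#' at T = Tm by construction.
#'
#' @param temp_k Temperature(s) of evaluation, Kelvin.
#' @param tm Melting temperature, Kelvin.
#' @param dh_kcal van't Hoff enthalpy of unfolding at `tm`, kcal/mol.
#' @param dcp_kcal Heat-capacity change of unfolding, kcal/(mol K).
#' @return Delta-G_u in kcal/mol.
#' @export
gibbs_free_energy <- function(temp_k, tm, dh_kcal, dcp_kcal = 0) {
  dh_kcal * (1 - temp_k / tm) +
    dcp_kcal * ((temp_k - tm) - temp_k * log(temp_k / tm))
}

two_state_signal <- function(temp_k, tm, dh, dcp, yf0, yf1, yu0, yu1) {
  R <- 1.9872e-3
  dg <- gibbs_free_energy(temp_k, tm, dh, dcp)
  K <- exp(-dg / (R * temp_k))
  yf <- yf0 + yf1 * temp_k
  yu <- yu0 + yu1 * temp_k
  (yf + yu * K) / (1 + K)
}

#' Fit a two-state thermal denaturation curve
#'
#' Signal model y(T) = (y_F(T) + y_U(T) K(T)) / (1 + K(T)) with
#' K(T) = exp(-DeltaG_u(T)/(R T)), linear folded/unfolded baselines and the
#' Gibbs-Helmholtz DeltaG_u. Fits (Tm, dH, 4 baseline parameters); dCp is
#' held fixed (default 0) or at a supplied value.
#'
#' @param curve A `melt_curve`.
#' @param dcp_kcal Fixed heat-capacity change (kcal/(mol K)).
#' @return List of class `two_state_fit`: `tm_k`, `dh_kcal`, SDs, baselines,
#'   `dcp_kcal` (with provenance tag "fixed"), `p_unfolded` function of T(K),
#'   `dg` function of T(K), `curve`.
#' @export
fit_melt_two_state <- function(curve, dcp_kcal = 0) {
  T <- curve$temp_k; y <- curve$signal
  n <- length(T)
  lo <- y[seq_len(max(3, n %/% 10))]
  hi <- y[seq(n - max(3, n %/% 10) + 1, n)]
  # crude midpoint: temperature at half signal change
  ymid <- (mean(lo) + mean(hi)) / 2
  tm0 <- T[which.min(abs(y - ymid))]
  st <- list(tm = tm0, dh = 80,
             yf0 = mean(lo), yf1 = 0, yu0 = mean(hi), yu1 = 0)
  fit <- minpack.lm::nlsLM(
    y ~ two_state_signal(T, tm, dh, dcp_kcal, yf0, yf1, yu0, yu1),
    data = data.frame(T = T, y = y), start = st,
    lower = c(min(T), 1, -Inf, -Inf, -Inf, -Inf),
    upper = c(max(T), 1000, Inf, Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  span <- range(T)
  if (co["tm"] - span[1] < 5 || span[2] - co["tm"] < 5) {
    warning("melt barely spans a baseline; parameters ill-conditioned",
            call. = FALSE)
  }
  tm <- unname(co["tm"]); dh <- unname(co["dh"])
  structure(list(
    tm_k = tm, tm_sd = unname(se["tm"]),
    dh_kcal = dh, dh_sd = unname(se["dh"]),
    dcp_kcal = dcp_kcal, dcp_provenance = "fixed",
    baselines = co[c("yf0", "yf1", "yu0", "yu1")],
    dg = function(temp_k) gibbs_free_energy(temp_k, tm, dh, dcp_kcal),
    p_unfolded = function(temp_k) {
      K <- exp(-gibbs_free_energy(temp_k, tm, dh, dcp_kcal) /
                 (1.9872e-3 * temp_k))
      K / (1 + K)
    },
    ligand_m = curve$ligand_m,
    residual_sd = stats::sd(stats::resid(fit))), class = "two_state_fit")
}

#' Heat-capacity change from the ligand-concentration melt series
#'
#' Under ligand-linked stabilization, plotting the fitted van't Hoff
#' enthalpies against the fitted melting temperatures across ligand
#' concentrations gives a line whose slope is the (temperature-independent)
#' heat-capacity change of unfolding.
#'
#' @param tm_k Melting temperatures (K).
#' @param dh_kcal Corresponding enthalpies (kcal/mol).
#' @return List: `dcp_kcal` (slope, kcal/(mol K)), `dcp_sd`, `intercept`.
#' @export
delta_cp_from_series <- function(tm_k, dh_kcal) {
  if (length(tm_k) < 2) stop("need >= 2 (Tm, dH) points", call. = FALSE)
  if (length(tm_k) == 2) {
    slope <- diff(dh_kcal) / diff(tm_k)
    return(list(dcp_kcal = slope, dcp_sd = NA_real_,
                intercept = dh_kcal[1] - slope * tm_k[1]))
  }
  fit <- stats::lm(dh_kcal ~ tm_k)
  co <- stats::coef(fit)
  # collinear inputs trip lm's perfect-fit warning; the slope is still exact
  se <- suppressWarnings(summary(fit))$coefficients
  sd2 <- if (nrow(se) >= 2 && !is.nan(se[2, 2])) se[2, 2] else 0
  list(dcp_kcal = unname(co[2]), dcp_sd = sd2, intercept = unname(co[1]))
}

#' Ligand-induced stability shift at the apo melting temperature
#'
#' DeltaDeltaG_u,L(T_ref) = DeltaG_u,L(T_ref) - DeltaG_u,apo(T_ref),
#' both evaluated by Gibbs-Helmholtz with a shared heat-capacity change.
#' At T_ref = Tm(apo) the apo term vanishes, so the shift equals the
#' liganded state's DeltaG_u at the apo midpoint.
#'
#' @param apo_fit,holo_fit `two_state_fit` objects.
#' @param dcp_kcal Shared heat-capacity change (kcal/(mol K)).
#' @param t_ref_k Reference temperature; defaults to the apo Tm.
#' @return DeltaDeltaG_u,L in kcal/mol.
#' @export
ddg_at_reference <- function(apo_fit, holo_fit, dcp_kcal = 0,
                             t_ref_k = NULL) {
  if (is.null(t_ref_k)) t_ref_k <- apo_fit$tm_k
  gibbs_free_energy(t_ref_k, holo_fit$tm_k, holo_fit$dh_kcal, dcp_kcal) -
    gibbs_free_energy(t_ref_k, apo_fit$tm_k, apo_fit$dh_kcal, dcp_kcal)
}

#' Free-ligand concentration in the stoichiometric regime
#'
#' Physical root of L^2 + (P_T - L_T + Kd) L - Kd L_T = 0.
#'
#' @param l_tot,p_tot Total ligand and protein concentrations (M).
#' @param kd Dissociation constant (M).
#' @return Free ligand concentration (M).
#' @export
free_ligand <- function(l_tot, p_tot, kd) {
  b <- p_tot - l_tot + kd
  (-b + sqrt(b^2 + 4 * kd * l_tot)) / 2
}

ddg_binding_model <- function(l_tot, p_tot, kd, t_ref_k) {
  R <- 1.9872e-3
  lf <- free_ligand(l_tot, p_tot, kd)
  R * t_ref_k * log(1 + lf / kd)
}

#' Dissociation constant from a thermal-shift DeltaDeltaG series
#'
#' Fits DeltaDeltaG_u,L(T_ref) = R T_ref ln(1 + [L]_free/Kd) over the ligand
#' concentration series, with [L]_free from the stoichiometric-regime
#' binding quadratic (protein and ligand comparable to Kd). One-parameter
#' weighted least squares in log10(Kd); the uncertainty comes from seeded
#' Monte-Carlo resampling of the DeltaDeltaG values.
#'
#' @param l_tot Total ligand concentrations (M).
#' @param ddg DeltaDeltaG_u,L values at `t_ref_k` (kcal/mol).
#' @param p_tot Total protein concentration (M).
#' @param t_ref_k Reference temperature (K), typically the apo Tm.
#' @param ddg_sd Optional uncertainties for inverse-variance weighting.
#' @param config An [nmr_config()] (seed, Monte-Carlo replicates).
#' @return List of class `kd_fit`: `kd`, `kd_sd`, `log10_kd`, `log10_kd_sd`,
#'   `ci95` (Kd), `verdict` (`"binding"` or `"no_binding"`), `fitted` values.
#' @export
fit_kd_thermal_shift <- function(l_tot, ddg, p_tot, t_ref_k,
                                 ddg_sd = NULL, config = nmr_config()) {
  stopifnot(length(l_tot) == length(ddg))
  if (all(ddg <= 0)) {
    return(structure(list(verdict = "no_binding", kd = NA_real_),
                     class = "kd_fit"))
  }
  w <- if (is.null(ddg_sd)) rep(1, length(ddg)) else 1 / ddg_sd^2
  obj <- function(log10kd) {
    kd <- 10^log10kd
    sum(w * (ddg - ddg_binding_model(l_tot, p_tot, kd, t_ref_k))^2)
  }
  opt <- stats::optimize(obj, interval = c(-12, 0))
  log10kd <- opt$minimum
  kd <- 10^log10kd
  # Monte-Carlo uncertainty
  set.seed(config$seed)
  base <- ddg_binding_model(l_tot, p_tot, kd, t_ref_k)
  resid_sd <- if (is.null(ddg_sd)) {
    rep(max(stats::sd(ddg - base), 1e-6), length(ddg))
  } else ddg_sd
  draws <- vapply(seq_len(config$mc_replicates), function(i) {
    d <- base + stats::rnorm(length(ddg), 0, resid_sd)
    stats::optimize(function(l) {
      k <- 10^l
      sum(w * (d - ddg_binding_model(l_tot, p_tot, k, t_ref_k))^2)
    }, interval = c(log10kd - 3, log10kd + 3))$minimum
  }, numeric(1))
  structure(list(
    verdict = "binding",
    kd = kd, log10_kd = log10kd,
    kd_sd = stats::sd(10^draws), log10_kd_sd = stats::sd(draws),
    ci95 = 10^stats::quantile(draws, c(0.025, 0.975), names = FALSE),
    fitted = base, t_ref_k = t_ref_k, p_tot = p_tot,
    seed = config$seed), class = "kd_fit")
}
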