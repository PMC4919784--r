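# Default experimental schedules used by the generators: the R1 and R2
# relaxation delay series, the CPMG field grid with its repeated 480 Hz
# point, and the CLEANEX mixing-time grid.
R1_DELAYS_S <- c(0, 30, 60, 90, 120, 150, 250, 350, 450, 550, 650, 800,
                 1000) / 1000
R2_DELAYS_S <- c(0, 10, 30, 50, 70, 90, 110, 130, 150, 170, 250, 350,
                 490) / 1000
CPMG_GRID_HZ <- c(seq(80, 1000, by = 40), 480)
CLEANEX_TAUS_S <- c(0, 5, 10, 20, 40, 60, 80, 100, 150, 200) / 1000

#' Generate NH bond-vector orientations
#'
#' Modes: area-uniform sampling on the sphere, an explicit list of alpha
#' angles relative to the z axis, or vectors extracted from a structure.
#'
#' @param n Number of vectors (ignored for `fixed_alpha_list`/`from_pdb`).
#' @param mode `"uniform_sphere"`, `"fixed_alpha_list"` or `"from_pdb"`.
#' @param alpha_deg Alpha angles for `fixed_alpha_list`.
#' @param ensemble A `structure_ensemble` for `from_pdb` (unique axis =
#'   z axis of the supplied `axis`).
#' @param axis Unique axis used for alpha computation (default z).
#' @param seed Random seed for the uniform mode.
#' @return Data frame `residue`, `alpha_deg`, `ux`, `uy`, `uz`.
#' @export
gen_orientations <- function(n = 100, mode = c("uniform_sphere",
                                               "fixed_alpha_list",
                                               "from_pdb"),
                             alpha_deg = NULL, ensemble = NULL,
                             axis = c(0, 0, 1), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "uniform_sphere") {
    if (n < 1) stop("n must be >= 1", call. = FALSE)
    set.seed(seed)
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    u <- cbind(r * cos(phi), r * sin(phi), z)
  } else if (mode == "fixed_alpha_list") {
    stopifnot(!is.null(alpha_deg))
    a <- alpha_deg * pi / 180
    u <- cbind(sin(a), 0, cos(a))
    n <- length(alpha_deg)
  } else {
    stopifnot(!is.null(ensemble))
    df <- nh_alpha_angles(ensemble, axis)
    return(df)
  }
  axis <- axis / sqrt(sum(axis^2))
  alpha <- acos(pmin(1, abs(u %*% axis))) * 180 / pi
  data.frame(residue = seq_len(n), alpha_deg = as.numeric(alpha),
             ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

#' Write a toy ideal alpha-helix PDB (synthetic fixture)
#'
#' Builds an ideal poly-alanine-like helix (backbone N, H, CA, C, O) with
#' standard helical geometry (rise 1.5 A, 100 degrees per residue) and
#' writes `n_models` identical (optionally jittered) MODEL blocks. Purely
#' synthetic: for testing geometry code without any downloaded structure.
#'
#' @param path Output PDB path.
#' @param n_res Number of residues.
#' @param n_models Number of models.
#' @param jitter_a Gaussian coordinate jitter (Angstrom) applied to models
#'   after the first.
#' @param seed Seed for the jitter.
#' @return Invisibly, the path.
#' @export
write_toy_helix_pdb <- function(path, n_res = 12, n_models = 1,
                                jitter_a = 0, seed = 1) {
  rise <- 1.5; twist <- 100 * pi / 180; r_helix <- 2.3
  atoms <- list()
  for (i in seq_len(n_res)) {
    th <- (i - 1) * twist
    z <- (i - 1) * rise
    base <- c(r_helix * cos(th), r_helix * sin(th), z)
    # local offsets approximating backbone geometry
    npos <- base
    ca <- base + c(0.8 * cos(th + 0.5), 0.8 * sin(th + 0.5), 0.6)
    cc <- ca + c(0.6 * cos(th + 1.0), 0.6 * sin(th + 1.0), 0.9)
    oo <- cc + c(0.7 * cos(th + 1.4), 0.7 * sin(th + 1.4), -0.3)
    # amide H roughly anti to the helix axis tilt, unit length from N
    hdir <- c(cos(th) * 0.54, sin(th) * 0.54, -0.84)
    hh <- npos + hdir / sqrt(sum(hdir^2))
    atoms[[i]] <- rbind(
      data.frame(res = i, name = "N", x = npos[1], y = npos[2], z = npos[3]),
      data.frame(res = i, name = "H", x = hh[1], y = hh[2], z = hh[3]),
      data.frame(res = i, name = "CA", x = ca[1], y = ca[2], z = ca[3]),
      data.frame(res = i, name = "C", x = cc[1], y = cc[2], z = cc[3]),
      data.frame(res = i, name = "O", x = oo[1], y = oo[2], z = oo[3]))
  }
  at <- do.call(rbind, atoms)
  set.seed(seed)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    jit <- if (m > 1 && jitter_a > 0)
      matrix(stats::rnorm(nrow(at) * 3, 0, jitter_a), ncol = 3) else 0
    xyz <- as.matrix(at[, c("x", "y", "z")]) + jit
    for (i in seq_len(nrow(at))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, sprintf(" %-3s", at$name[i]), at$res[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3],
        substr(at$name[i], 1, 1)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Generate a synthetic 15N relaxation dataset (R1, R2, NOE)
#'
#' Predicts per-residue rates from a diffusion tensor and model-free
#' parameters via [predict_rates()], then emits intensity decay tables on
#' the standard delay schedules with multiplicative Gaussian noise, and a
#' saturated/reference NOE intensity pair table. Ground truth is returned
#' alongside the tables.
#'
#' @param orientations Data frame from [gen_orientations()].
#' @param tensor A [diffusion_tensor()] (ground truth).
#' @param s2 Per-residue order parameters (recycled).
#' @param tau_e,rex Per-residue internal times (s) / exchange terms
#'   (s^-1), recycled.
#' @param noise Fractional Gaussian noise on intensities.
#' @param config An [nmr_config()].
#' @param seed Seed (all randomness in this generator).
#' @param r1_delays,r2_delays Delay grids in seconds.
#' @return List: `r1_series`, `r2_series` (lists of `intensity_series` with
#'   per-point errors), `noe` (data frame residue, i_sat, i_ref, sds),
#'   `truth` (data frame of per-residue generating rates and parameters).
#' @export
gen_relaxation_dataset <- function(orientations, tensor, s2 = 0.85,
                                   tau_e = 0, rex = 0, noise = 0.02,
                                   config = nmr_config(), seed = 1,
                                   r1_delays = R1_DELAYS_S,
                                   r2_delays = R2_DELAYS_S) {
  physics <- spin_physics(config)
  n <- nrow(orientations)
  s2 <- rep_len(s2, n); tau_e <- rep_len(tau_e, n); rex <- rep_len(rex, n)
  rates <- t(vapply(seq_len(n), function(i) {
    predict_rates(orientations$alpha_deg[i], tensor, s2 = s2[i],
                  tau_e = tau_e[i], rex = rex[i], physics = physics)
  }, numeric(3)))
  set.seed(seed)
  i0 <- 1e6
  mk_series <- function(res, rate, delays) {
    ideal <- i0 * exp(-rate * delays)
    obs <- ideal * (1 + stats::rnorm(length(delays), 0, noise))
    intensity_series(res, "ALA", delays, obs,
                     error = if (noise > 0) noise * ideal,
                     x_kind = "relaxation_delay")
  }
  r1_series <- lapply(seq_len(n), function(i)
    mk_series(orientations$residue[i], rates[i, "R1"], r1_delays))
  r2_series <- lapply(seq_len(n), function(i)
    mk_series(orientations$residue[i], rates[i, "R2"], r2_delays))
  i_ref <- i0 * (1 + stats::rnorm(n, 0, noise))
  i_sat <- i0 * rates[, "NOE"] * (1 + stats::rnorm(n, 0, noise))
  noe <- data.frame(residue = orientations$residue,
                    i_sat = i_sat, i_ref = i_ref,
                    sd_sat = noise * i0 * abs(rates[, "NOE"]),
                    sd_ref = noise * i0)
  truth <- data.frame(orientations,
                      R1 = rates[, "R1"], R2 = rates[, "R2"],
                      NOE = rates[, "NOE"], s2 = s2, tau_e = tau_e,
                      rex = rex)
  list(r1_series = r1_series, r2_series = r2_series, noe = noe,
       truth = truth, tensor = tensor, noise = noise, seed = seed)
}

#' Generate synthetic constant-time CPMG dispersion intensity tables
#'
#' Profiles are generated from the Ishima-Torchia model (or, with
#' `oracle = TRUE`, from the numerical Bloch-McConnell propagator), then
#' converted to intensities I = I0 exp(-R2eff T_relax) with multiplicative
#' Gaussian noise. The default field grid includes the duplicated 480 Hz
#' measurement used downstream for error estimation.
#'
#' @param residues Residue numbers.
#' @param p_b,k_ex Shared ground-truth exchange parameters.
#' @param dw_ppm Per-residue shift differences in ppm (recycled).
#' @param r2_0 Per-residue exchange-free rates (recycled).
#' @param t_relax Constant-time delay (s).
#' @param nu_grid CPMG fields (Hz).
#' @param noise Fractional intensity noise.
#' @param oracle Generate from the Bloch-McConnell propagator instead of
#'   the closed-form model.
#' @param config An [nmr_config()].
#' @param seed Seed.
#' @return List: `series` (intensity series, x_kind `cpmg_field`), `i0`,
#'   `truth` (list of per-residue `two_site_exchange`), `t_relax`.
#' @export
gen_dispersion_dataset <- function(residues, p_b, k_ex, dw_ppm, r2_0 = 15,
                                   t_relax = 0.05, nu_grid = CPMG_GRID_HZ,
                                   noise = 0.02, oracle = FALSE,
                                   config = nmr_config(), seed = 1) {
  n <- length(residues)
  dw_ppm <- rep_len(dw_ppm, n); r2_0 <- rep_len(r2_0, n)
  set.seed(seed)
  i0 <- 1e6
  truth <- list(); series <- list()
  for (i in seq_len(n)) {
    pars <- two_site_exchange(p_b, k_ex, dw_convert(dw_ppm[i], config), r2_0[i])
    r2 <- if (oracle) {
      as.numeric(bloch_mcconnell_r2eff(pars, nu_grid, t_relax))
    } else {
      model_r2eff(pars, nu_grid)
    }
    ideal <- i0 * exp(-r2 * t_relax)
    obs <- ideal * (1 + stats::rnorm(length(nu_grid), 0, noise))
    series[[i]] <- intensity_series(residues[i], "ALA", nu_grid, obs,
                                    error = if (noise > 0) noise * ideal,
                                    x_kind = "cpmg_field")
    truth[[i]] <- pars
  }
  list(series = series, i0 = i0, truth = truth, t_relax = t_relax,
       noise = noise, seed = seed)
}

#' Generate synthetic H/D exchange and CLEANEX datasets
#'
#' Observed rates follow k_obs = k_int / P_f per residue. Slow H/D decays
#' are sampled from the dead time out to the observation window; residues
#' whose k_obs empties the signal before the dead time emit noise-floor
#' intensities (exercising the too-fast censor), and residues with
#' log10(P_f) > 8 emit essentially flat curves (too-slow censor). Fast
#' exchangers also get CLEANEX build-up curves on the standard mixing-time
#' grid.
#'
#' @param residues Residue numbers.
#' @param pf Per-residue ground-truth protection factors.
#' @param k_int Per-residue intrinsic rates (s^-1).
#' @param hx_times H/D sampling times (s), starting at the dead time.
#' @param cleanex_taus CLEANEX mixing times (s).
#' @param r1a_app Apparent amide relaxation for the CLEANEX curves.
#' @param r1b_app Apparent water relaxation (fixed).
#' @param noise Fractional noise.
#' @param noise_floor Absolute intensity floor.
#' @param seed Seed.
#' @return List: `hx_series`, `cleanex_series` (fast residues only),
#'   `cleanex_i0`, `truth` (data frame residue, pf, k_int, k_obs).
#' @export
gen_exchange_dataset <- function(residues, pf, k_int,
                                 hx_times = c(1800, 3600, 7200, 14400,
                                              28800, 57600, 115200, 230400,
                                              345600),
                                 cleanex_taus = CLEANEX_TAUS_S,
                                 r1a_app = 2, r1b_app = 0.6,
                                 noise = 0.02, noise_floor = 0.01,
                                 seed = 1) {
  n <- length(residues)
  pf <- rep_len(pf, n); k_int <- rep_len(k_int, n)
  k_obs <- k_int / pf
  set.seed(seed)
  hx_series <- list(); cleanex_series <- list(); clx_res <- c()
  for (i in seq_len(n)) {
    ideal <- exp(-k_obs[i] * hx_times)
    obs <- pmax(ideal * (1 + stats::rnorm(length(hx_times), 0, noise)),
                0)
    obs[ideal < noise_floor] <- noise_floor *
      abs(1 + stats::rnorm(sum(ideal < noise_floor), 0, 0.5))
    hx_series[[i]] <- intensity_series(residues[i], "ALA", hx_times, obs,
                                       x_kind = "exchange_time")
    if (k_obs[i] > 0.5) {   # fast exchanger: visible CLEANEX build-up
      mu <- cleanex_model(cleanex_taus, k_obs[i], r1a_app, r1b_app)
      yo <- mu * (1 + stats::rnorm(length(cleanex_taus), 0, noise))
      cleanex_series[[length(cleanex_series) + 1]] <-
        intensity_series(residues[i], "ALA", cleanex_taus, pmax(yo, 0),
                         x_kind = "mixing_time")
      clx_res <- c(clx_res, residues[i])
    }
  }
  list(hx_series = hx_series, cleanex_series = cleanex_series,
       cleanex_i0 = 1, cleanex_residues = clx_res,
       truth = data.frame(residue = residues, pf = pf, k_int = k_int,
                          k_obs = k_obs),
       seed = seed)
}

#' Generate a ligand-linked thermal-shift melt series
#'
#' Produces an apo melting curve and one curve per ligand concentration.
#' The liganded melting temperature is found by numerically solving
#' DeltaG_u,L(T) = DeltaG_u,apo(T) + R T ln(1 + [L]_free/Kd) = 0, with
#' [L]_free from the stoichiometric binding quadratic; the liganded
#' enthalpy at its midpoint follows from the shared heat-capacity change,
#' dH(Tm) = dH_apo + dCp (Tm - Tm_apo).
#'
#' @param tm_apo_c,dh_apo Apo melting temperature (deg C) and enthalpy
#'   (kcal/mol).
#' @param dcp_kcal Heat-capacity change (kcal/(mol K)).
#' @param kd Ground-truth dissociation constant (M).
#' @param p_tot Protein concentration (M).
#' @param ratios Ligand:protein molar ratios.
#' @param baselines Named list `yf0`, `yf1`, `yu0`, `yu1`.
#' @param temp_c Temperature grid (deg C).
#' @param noise Absolute Gaussian noise as a fraction of the signal span.
#' @param seed Seed.
#' @return List: `curves` (list of `melt_curve`, first apo), `truth`
#'   (data frame ligand_m, tm_c, dh, ddg at apo Tm).
#' @export
gen_melt_dataset <- function(tm_apo_c = 54.0, dh_apo = 106.5,
                             dcp_kcal = 0, kd = 3.08e-6, p_tot = 6e-6,
                             ratios = c(0.5, 1, 2, 5),
                             baselines = list(yf0 = -12, yf1 = 0.01,
                                              yu0 = -2, yu1 = 0.005),
                             temp_c = seq(10, 90, by = 1),
                             noise = 0.01, seed = 1) {
  R <- 1.9872e-3
  tm_apo <- tm_apo_c + 273.15
  set.seed(seed)
  temp_k <- temp_c + 273.15
  span_guess <- abs(baselines$yu0 - baselines$yf0)
  mk_curve <- function(tm, dh, lig) {
    y <- two_state_signal(temp_k, tm, dh, dcp_kcal,
                          baselines$yf0, baselines$yf1,
                          baselines$yu0, baselines$yu1)
    y <- y + stats::rnorm(length(y), 0, noise * span_guess)
    melt_curve(temp_c, y, unit = "mre", conc_m = p_tot, ligand_m = lig)
  }
  curves <- list(mk_curve(tm_apo, dh_apo, 0))
  truth <- data.frame(ligand_m = 0, tm_c = tm_apo_c, dh = dh_apo, ddg = 0)
  for (r in ratios) {
    lt <- r * p_tot
    g <- function(T) {
      lf <- free_ligand(lt, p_tot, kd)
      gibbs_free_energy(T, tm_apo, dh_apo, dcp_kcal) + R * T * log(1 + lf / kd)
    }
    tm_l <- stats::uniroot(g, c(tm_apo - 1e-3, tm_apo + 40))$root
    dh_l <- dh_apo + dcp_kcal * (tm_l - tm_apo)
    curves[[length(curves) + 1]] <- mk_curve(tm_l, dh_l, lt)
    truth <- rbind(truth, data.frame(
      ligand_m = lt, tm_c = tm_l - 273.15, dh = dh_l,
      ddg = R * tm_apo * log(1 + free_ligand(lt, p_tot, kd) / kd)))
  }
  list(curves = curves, truth = truth, kd = kd, p_tot = p_tot,
       dcp_kcal = dcp_kcal, seed = seed)
}
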