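cfg <- nmr_config(seed = 19, mc_replicates = 50)

test_that("R2_eff computation: closed form and replicate error propagation", {
  s <- intensity_series(7, "ALA", c(80, 160, 480, 960),
                        c(1, exp(-1), 0.5, 0.6),
                        error = rep(0.01, 4), x_kind = "cpmg_field")
  pr <- r2eff_profile(s, i0 = 1, t_relax = 0.05)
  expect_equal(pr$r2eff[pr$nu_cpmg == 80], 0)          # I = I0
  expect_equal(pr$r2eff[pr$nu_cpmg == 160], 20.0,      # I/I0 = 1/e, 50 ms
               tolerance = 1e-12)

  # replicate 480 Hz pair differing by 2% sets the error for every point
  i480 <- c(0.80, 0.80 * 1.02)
  s2 <- intensity_series(7, "ALA", c(80, 240, 480, 480, 720, 960),
                         c(0.95, 0.85, i480, 0.78, 0.77),
                         x_kind = "cpmg_field")
  expect_warning(pr2 <- r2eff_profile(s2, i0 = 1, t_relax = 0.05), NA)
  frac <- abs(diff(i480)) / sqrt(2) / mean(i480)
  # hand propagation at the first point: sigma_R2 = sigma_I / (I T)
  expect_equal(pr2$r2eff_sd[pr2$nu_cpmg == 80],
               frac * 0.95 / (0.95 * 0.05), tolerance = 1e-10)

  # I > I0 flagged, I <= 0 dropped with warning
  s3 <- intensity_series(7, "ALA", c(80, 160, 240), c(1.1, -0.1, 0.5),
                         error = rep(0.01, 3), x_kind = "cpmg_field")
  expect_warning(pr3 <- r2eff_profile(s3, i0 = 1, t_relax = 0.05),
                 "non-positive")
  expect_equal(nrow(pr3), 2)
  expect_true(80 %in% attr(pr3, "flagged"))
})

test_that("Ishima-Torchia model: limits, monotonicity, fast-exchange check", {
  nu <- seq(80, 1000, by = 40)
  # no shift difference or no minor state -> flat at R2_0
  p0 <- list(p_a = 0.93, p_b = 0.07, k_ex = 420, delta_omega = 0, r2_0 = 15)
  expect_equal(model_r2eff(p0, nu), rep(15, length(nu)))
  # monotone non-increasing, approaches R2_0 from above
  p <- two_site_exchange(0.07, 420, dw_convert(2, cfg), 15)
  r2 <- model_r2eff(p, nu)
  expect_true(all(diff(r2) <= 1e-12))
  expect_gt(r2[1], 15)
  # fast exchange: low-nu plateau within 5% of p_a p_b dw^2 / k_ex above R2_0
  pf <- two_site_exchange(0.05, 5000, dw_convert(2, cfg), 15)
  plateau <- model_r2eff(pf, 1)[1] - 15
  fast_limit <- pf$p_a * pf$p_b * pf$delta_omega^2 / pf$k_ex
  expect_lt(abs(plateau - fast_limit) / fast_limit, 0.05)
  # derived R_ex is the zero-field dispersion amplitude
  expect_equal(p$r_ex,
               p$p_a * p$p_b * p$delta_omega^2 * p$k_ex /
                 (p$k_ex^2 + p$p_a * p$delta_omega^2), tolerance = 1e-12)
})

test_that("Bloch-McConnell oracle: degenerate limits and model agreement", {
  nu <- seq(80, 1000, by = 40)
  p0 <- list(p_a = 0.93, p_b = 0.07, k_ex = 420, delta_omega = 0, r2_0 = 15)
  expect_equal(as.numeric(bloch_mcconnell_r2eff(p0, nu, 0.05)),
               rep(15, length(nu)), tolerance = 1e-8)
  # the published cluster truth: approximation within 10% of the oracle
  p <- two_site_exchange(0.07, 420, dw_convert(2, cfg), 15)
  bm <- bloch_mcconnell_r2eff(p, nu, 0.05)
  it <- model_r2eff(p, nu)
  expect_lt(max(abs(it - bm) / bm), 0.10)
})

test_that("individual profile fit separates exchange from flat profiles", {
  sim <- gen_dispersion_dataset(1, p_b = 0.1, k_ex = 500, dw_ppm = 2,
                                r2_0 = 15, noise = 0.02, config = cfg,
                                seed = 3)
  pr <- r2eff_profile(sim$series[[1]], sim$i0, sim$t_relax)
  fit <- fit_profile_individual(pr, cfg)
  expect_equal(fit$verdict, "exchange")

  # flat profile: no-exchange verdict
  set.seed(4)
  nu <- nmrdyn:::CPMG_GRID_HZ
  flat <- intensity_series(2, "ALA", nu,
                           1e6 * exp(-15 * 0.05) * (1 + rnorm(length(nu), 0, 0.01)),
                           error = rep(1e6 * exp(-0.75) * 0.01, length(nu)),
                           x_kind = "cpmg_field")
  prf <- r2eff_profile(flat, 1e6, 0.05)
  expect_equal(fit_profile_individual(prf, cfg)$verdict, "no_exchange")

  # too few points errors
  short <- pr[1:4, ]
  attr(short, "residue") <- 1
  expect_error(fit_profile_individual(short, cfg), "6 distinct")
})

test_that("cluster fit recovers shared parameters and beats mismatched sharing", {
  set.seed(7)
  dws <- runif(6, 1, 3)
  sim <- gen_dispersion_dataset(1:6, p_b = 0.07, k_ex = 420,
                                dw_ppm = dws, r2_0 = 15,
                                noise = 0.02, config = cfg, seed = 7)
  profs <- lapply(sim$series, r2eff_profile, i0 = sim$i0,
                  t_relax = sim$t_relax)
  cf <- fit_cluster(profs, cfg, mc_replicates = 30)
  expect_lt(abs(cf$k_ex - 420), 1.96 * cf$k_ex_sd + 0.05 * 420)
  expect_lt(abs(cf$p_b - 0.07), 1.96 * cf$p_b_sd + 0.01)
  expect_equal(nrow(cf$members), 6)
  # per-member shift differences recovered
  expect_lt(max(abs(cf$members$dw_ppm - dws) / dws), 0.2)

  # overlap exclusion honoured
  cf2 <- fit_cluster(profs, cfg, overlap = c(2, 4), mc_replicates = 5)
  expect_setequal(cf2$excluded, c(2, 4))
  expect_equal(nrow(cf2$members), 4)
})

test_that("single-member cluster equals the individual fit", {
  sim <- gen_dispersion_dataset(9, p_b = 0.08, k_ex = 600, dw_ppm = 2.5,
                                r2_0 = 14, noise = 0.01, config = cfg,
                                seed = 11)
  pr <- r2eff_profile(sim$series[[1]], sim$i0, sim$t_relax)
  ind <- fit_profile_individual(pr, cfg)
  cl <- fit_cluster(list(pr), cfg, mc_replicates = 5)
  # same chi^2 surface: shared parameters match the individual optimum
  expect_equal(cl$k_ex, ind$exchange$params$k_ex, tolerance = 0.05)
  expect_equal(cl$p_b, ind$exchange$params$p_b, tolerance = 0.05)
})

test_that("fitting oracle-generated data still recovers k_ex (within 15%)", {
  # guards against approximation-only self-consistency, at the study's
  # beta-sheet cluster conditions
  set.seed(23)
  sim <- gen_dispersion_dataset(1:6, p_b = 0.07, k_ex = 420,
                                dw_ppm = runif(6, 1, 3), r2_0 = 15,
                                noise = 0.02, oracle = TRUE, config = cfg,
                                seed = 23)
  profs <- lapply(sim$series, r2eff_profile, i0 = sim$i0,
                  t_relax = sim$t_relax)
  cf <- fit_cluster(profs, cfg, mc_replicates = 5)
  expect_lt(abs(cf$k_ex - 420) / 420, 0.15)
})
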