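cfg <- nmr_config(seed = 13, mc_replicates = 50)
phys <- spin_physics(cfg)

test_that("spectral density: coefficients, isotropic limits, hand algebra", {
  tn <- diffusion_tensor(10e-9, 1)
  # isotropic rigid: J(0) = 0.4 * tau_m for any alpha
  for (a in c(0, 30, 60, 90)) {
    expect_equal(spectral_density(0, a, tn, s2 = 1), 0.4 * 10e-9,
                 tolerance = 1e-14)
  }
  # A_k sum to 1 across alpha
  for (a in seq(0, 90, by = 5)) {
    expect_equal(sum(nmrdyn:::axial_coeffs(a)), 1, tolerance = 1e-12)
  }
  # S2 = 1 makes J independent of tau_e
  tn2 <- diffusion_tensor(14.5e-9, 1.15)
  expect_equal(spectral_density(1e8, 35, tn2, 1, tau_e = 0),
               spectral_density(1e8, 35, tn2, 1, tau_e = 5e-10),
               tolerance = 1e-15)
  # hand algebra: alpha = 0, D_ratio = 1.15, tau_m_eff = 14.5 ns ->
  # tau_1 = (2 + D_ratio)/3 * tau_m_eff = 15.225 ns, J(0) = 0.4 tau_1
  expect_equal(1 / (6 * tn2$d_perp), 15.225e-9, tolerance = 1e-12)
  expect_equal(spectral_density(0, 0, tn2, 1), 0.4 * 15.225e-9,
               tolerance = 1e-12)
})

test_that("tensor identities hold exactly", {
  tn <- diffusion_tensor(14.5e-9, 1.15)
  expect_lt(abs((2 * tn$d_perp + tn$d_par) / 3 - tn$d_iso) / tn$d_iso, 1e-12)
  expect_lt(abs(1 / (6 * tn$d_iso) - tn$tau_m_eff) / tn$tau_m_eff, 1e-9)
  expect_equal(tn$d_par / tn$d_perp, 1.15, tolerance = 1e-12)
})

test_that("predicted rates: anisotropy spread and isotropic collapse", {
  tn <- diffusion_tensor(14.5e-9, 1.15)
  r_par <- predict_rates(0, tn, s2 = 1, physics = phys)
  r_perp <- predict_rates(90, tn, s2 = 1, physics = phys)
  expect_gt(r_par["R2"], r_perp["R2"])   # parallel NH has the longer local tau_m
  # isotropic: R2 independent of alpha, equal to the closed isotropic form
  ti <- diffusion_tensor(14.5e-9, 1)
  r0 <- predict_rates(0, ti, s2 = 1, physics = phys)
  r77 <- predict_rates(77, ti, s2 = 1, physics = phys)
  expect_equal(r0, r77, tolerance = 1e-10)
  # Rex adds linearly to R2 only
  rx <- predict_rates(0, tn, s2 = 1, rex = 3, physics = phys)
  expect_equal(unname(rx["R2"] - r_par["R2"]), 3, tolerance = 1e-10)
  expect_equal(rx["R1"], r_par["R1"], tolerance = 1e-12)
})

test_that("rigid-subset selection excludes low-NOE and Rex-inflated residues", {
  set.seed(1)
  n <- 30
  tab <- data.frame(residue = 1:n, R1 = rnorm(n, 1.1, 0.02),
                    R2 = rnorm(n, 21, 0.4), R1_sd = 0.02, R2_sd = 0.3,
                    R1_flag = "ok", R2_flag = "ok",
                    noe = rep(0.8, n))
  tab$noe[5] <- 0.3               # flexible residue
  tab$R2[12] <- tab$R2[12] + 8    # exchange-broadened residue
  sel <- select_rigid_subset(tab)
  expect_false(5 %in% sel$kept)
  expect_false(12 %in% sel$kept)
  expect_equal(sel$excluded$reason[sel$excluded$residue == 5], "low NOE")
  expect_equal(sel$excluded$reason[sel$excluded$residue == 12],
               "R2/R1 outlier")
  # uniform rigid set (identical ratios) is fully kept
  tab2 <- tab[-c(5, 12), ]
  tab2$R1 <- 1.1; tab2$R2 <- 21
  sel2 <- select_rigid_subset(tab2)
  expect_setequal(sel2$kept, tab2$residue)
})

test_that("tensor fit equals a brute-force grid minimum on a noiseless toy", {
  ori <- gen_orientations(20, "uniform_sphere", seed = 8)
  tn <- diffusion_tensor(12e-9, 1.2, axis = c(0, 0, 1))
  truth <- t(vapply(ori$alpha_deg, function(a)
    predict_rates(a, tn, s2 = 1, physics = phys), numeric(3)))
  tab <- data.frame(residue = ori$residue, ratio = truth[, 2] / truth[, 1],
                    ratio_sd = 0.01, ux = ori$ux, uy = ori$uy, uz = ori$uz)
  tf <- fit_diffusion_tensor(tab, cfg, mc_replicates = 5)
  # brute-force grid over (tau_m, d_ratio) with the true (z) axis
  grid <- expand.grid(tau = seq(11.5e-9, 12.5e-9, length.out = 21),
                      dr = seq(1.1, 1.3, length.out = 21))
  chis <- vapply(seq_len(nrow(grid)), function(i) {
    tg <- diffusion_tensor(grid$tau[i], grid$dr[i])
    pr <- nmrdyn:::ratio_pred(ori$alpha_deg, tg, phys)
    sum(((tab$ratio - pr) / tab$ratio_sd)^2)
  }, numeric(1))
  best <- grid[which.min(chis), ]
  expect_equal(tf$axial$tau_m_eff, best$tau, tolerance = 0.005)
  expect_equal(tf$axial$d_ratio, best$dr, tolerance = 0.02)
  # optimizer at least as good as the grid
  expect_lte(tf$axial$chisq, min(chis) + 1e-6)
})

test_that("isotropic data reject the axial model", {
  ori <- gen_orientations(40, "uniform_sphere", seed = 5)
  ti <- diffusion_tensor(12e-9, 1)
  truth <- t(vapply(ori$alpha_deg, function(a)
    predict_rates(a, ti, s2 = 1, physics = phys), numeric(3)))
  set.seed(5)
  ratio <- truth[, 2] / truth[, 1] * (1 + rnorm(40, 0, 0.014))
  tab <- data.frame(residue = ori$residue, ratio = ratio,
                    ratio_sd = truth[, 2] / truth[, 1] * 0.014,
                    ux = ori$ux, uy = ori$uy, uz = ori$uz)
  tf <- fit_diffusion_tensor(tab, cfg, mc_replicates = 5)
  expect_equal(tf$f_test$preferred, "isotropic")
  expect_lt(abs(tf$axial$d_ratio - 1), 0.1)
})

test_that("model-free self-consistency: noiseless model-1 data", {
  tn <- diffusion_tensor(14.5e-9, 1.15)
  obs <- predict_rates(40, tn, s2 = 0.85, physics = phys)
  sig <- abs(obs) * c(0.02, 0.02, 0.02)
  fit <- fit_model_free(obs, sig, 40, tn, cfg, mc_replicates = 20)
  expect_equal(fit$model, 1)
  expect_equal(unname(fit$params["s2"]), 0.85, tolerance = 1e-3)
})

test_that("model-free recovers an exchange-bearing residue", {
  tn <- diffusion_tensor(14.5e-9, 1.15)
  truth <- predict_rates(60, tn, s2 = 0.80, tau_e = 50e-12, rex = 3,
                         physics = phys)
  set.seed(99)
  sig <- abs(truth) * 0.02
  obs <- truth + rnorm(3, 0, sig)
  names(obs) <- names(truth)
  fit <- fit_model_free(obs, sig, 60, tn, cfg, mc_replicates = 50)
  expect_true(fit$model %in% c(3, 4))          # a Rex-bearing model
  expect_lt(abs(fit$params["rex"] - 3), 2 * max(fit$sd["rex"], 0.5))
  expect_lt(abs(fit$params["s2"] - 0.80), 0.05)
})

test_that("S2 recovery is nearly unbiased across a synthetic residue set", {
  tn <- diffusion_tensor(14.5e-9, 1.15)
  set.seed(31)
  n <- 30
  alphas <- runif(n, 0, 90)
  s2_true <- runif(n, 0.5, 0.95)
  err <- numeric(n)
  for (i in seq_len(n)) {
    truth <- predict_rates(alphas[i], tn, s2 = s2_true[i], tau_e = 30e-12,
                           physics = phys)
    sig <- abs(truth) * 0.02
    obs <- truth + rnorm(3, 0, sig)
    names(obs) <- names(truth)
    fit <- fit_model_free(obs, sig, alphas[i], tn, cfg, mc_replicates = 2)
    err[i] <- fit$params["s2"] - s2_true[i]
  }
  expect_lt(abs(mean(err)), 0.02)
})
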