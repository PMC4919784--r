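test_that("H/D decay fit recovers noiseless parameters exactly", {
  t <- c(1800, 3600, 7200, 14400, 28800, 86400, 172800)
  y <- 0.1 + 0.9 * exp(-0.001 * t)
  fit <- fit_hx_decay(intensity_series(4, "ALA", t, y,
                                       x_kind = "exchange_time"))
  expect_equal(fit$censor, "measured")
  expect_equal(fit$k, 1e-3, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.9, tolerance = 1e-5)
  expect_equal(fit$plateau, 0.1, tolerance = 1e-5)
  expect_error(fit_hx_decay(intensity_series(1, "ALA", t[1:3], y[1:3],
                                             x_kind = "exchange_time")),
               "4 time points")
})

test_that("censoring yields bounds, never point estimates", {
  t <- c(1800, 3600, 7200, 14400)
  # all intensity at the noise floor from the first spectrum: too fast
  fast <- fit_hx_decay(intensity_series(1, "ALA", t, rep(0.008, 4),
                                        x_kind = "exchange_time"),
                       noise_floor = 0.01, dead_time = 1800,
                       ref_intensity = 1)
  expect_equal(fast$censor, "too_fast")
  expect_null(fast[["k"]])
  expect_gt(fast$k_lower, 0)
  # flat high intensity over 4 days: too slow with an upper bound
  t4 <- c(1800, 86400, 172800, 259200, 345600)
  slow <- fit_hx_decay(intensity_series(2, "ALA", t4, rep(1, 5),
                                        x_kind = "exchange_time"),
                       noise_frac = 0.02)
  expect_equal(slow$censor, "too_slow")
  expect_null(slow[["k"]])
  expect_equal(slow$k_upper, -log(1 - 0.06) / (345600 - 1800),
               tolerance = 1e-12)
  # downstream: with a fast intrinsic rate the censored bound exceeds
  # log10 P_f = 8
  pr <- protection_analysis(NULL, k_int = 100, censor = "too_slow",
                            k_bound = slow$k_upper)
  expect_equal(pr$bound_type, "lower")
  expect_gt(pr$log10_pf, 8)
})

test_that("CLEANEX model and build-up fit behave per the closed form", {
  taus <- nmrdyn:::CLEANEX_TAUS_S
  # tau_m -> 0 limit is 0 for any parameters
  expect_equal(cleanex_model(0, 5, 2, 0.6), 0)
  # with R_1B = 0 the model is a plain rising-exponential difference
  expect_equal(cleanex_model(taus, 3, 2, 0),
               3 / (2 + 3) * (1 - exp(-5 * taus)), tolerance = 1e-12)
  # noiseless recovery at the standard mixing-time grid
  y <- cleanex_model(taus, 5, 2, 0.6)
  fit <- fit_cleanex_buildup(intensity_series(3, "ALA", taus, y,
                                              x_kind = "mixing_time"),
                             i0 = 1)
  expect_equal(fit$k, 5, tolerance = 1e-5)
  expect_equal(fit$r1a_app, 2, tolerance = 1e-4)
  expect_equal(fit$r1b_app, 0.6)      # fixed, not fitted
  expect_error(fit_cleanex_buildup(intensity_series(3, "ALA", taus, y,
                                                    x_kind = "mixing_time"),
                                   i0 = 0), "positive")
})

test_that("CLEANEX Monte-Carlo recovery at 3% noise is within 5% in median", {
  taus <- nmrdyn:::CLEANEX_TAUS_S
  mu <- cleanex_model(taus, 10, 2, 0.6)
  set.seed(17)
  ks <- vapply(1:200, function(i) {
    y <- mu * (1 + rnorm(length(taus), 0, 0.03))
    fit_cleanex_buildup(intensity_series(1, "ALA", taus, y,
                                         x_kind = "mixing_time"), i0 = 1)$k
  }, numeric(1))
  expect_lt(abs(median(ks) - 10) / 10, 0.05)
})

test_that("intrinsic rates: neighbours, catalysis regime, temperature", {
  seq3 <- c("ALA", "ALA", "ALA", "PRO", "GLY")
  expect_error(intrinsic_rate(seq3, 4), "proline")
  expect_error(intrinsic_rate(seq3, 1), "N-terminal")
  # base-catalysed regime: +0.301 pH units doubles the rate
  k1 <- intrinsic_rate(seq3, 3, pH = 7.4)
  k2 <- intrinsic_rate(seq3, 3, pH = 7.701)
  expect_lt(abs(k2 / k1 - 2), 0.02)
  # hand evaluation of the Ala-Ala context at pH 7.4 (pD 7.8), 298.15 K:
  # base term 10^(10.05 + 1.62 + 7.8 - 15.05), water term 10^(-1.5 + 1.62),
  # Arrhenius to 298.15 K, divided by 60 for s^-1
  arr <- function(ea) exp(-ea / 1.9872e-3 * (1 / 298.15 - 1 / 293.15))
  hand <- (10^(10.05 + 1.62 + 7.8 - 15.05) * arr(17) +
             10^(-1.5 + 1.62) * arr(19) +
             10^(1.62 - 1.32 - 7.8) * arr(14)) / 60
  expect_lt(abs(intrinsic_rate(c("ALA", "ALA", "ALA"), 2) - hand) / hand,
            0.05)
  # one-letter input equivalent to three-letter
  expect_equal(intrinsic_rate("AAAG", 3), intrinsic_rate(
    c("ALA", "ALA", "ALA", "GLY"), 3), tolerance = 1e-12)
})

test_that("EX2 protection thermodynamics: identities and monotonicity", {
  pr <- protection_analysis(1e-4, k_int = 1, temperature_k = 298.15)
  expect_equal(pr$pf, 1e4)
  expect_equal(pr$dg_op_kcal, 1.9872e-3 * 298.15 * log(1e4),
               tolerance = 1e-12)
  # internal consistency of K_op / P_op / P_f at machine precision
  expect_equal(pr$k_op, 1 / pr$pf, tolerance = 1e-14)
  expect_equal(pr$p_op, pr$k_op / (1 + pr$k_op), tolerance = 1e-14)
  # no protection: dG = 0, open population one half
  p1 <- protection_analysis(1, k_int = 1)
  expect_equal(p1$dg_op_kcal, 0)
  expect_equal(p1$p_op, 0.5)
  # monotonicity: larger P_f -> larger dG_op -> smaller P_op
  pfs <- 10^seq(0, 8, by = 1)
  res <- lapply(pfs, function(pf) protection_analysis(1 / pf, 1))
  dg <- vapply(res, `[[`, numeric(1), "dg_op_kcal")
  pop <- vapply(res, `[[`, numeric(1), "p_op")
  expect_true(all(diff(dg) > 0))
  expect_true(all(diff(pop) < 0))
  expect_error(protection_analysis(-1, 1), "positive")
})

test_that("exchange generator produces the three observability regimes", {
  sim <- gen_exchange_dataset(1:3, pf = c(1e4, 1e8, 2),
                              k_int = c(1, 1, 10), seed = 6)
  fits <- lapply(sim$hx_series, fit_hx_decay, noise_floor = 0.02,
                 ref_intensity = 1)
  expect_equal(fits[[1]]$censor, "measured")      # visible decay over days
  expect_lt(abs(fits[[1]]$k - 1e-4) / 1e-4, 0.15)
  expect_equal(fits[[2]]$censor, "too_slow")      # logPf 8: flat curve
  expect_equal(fits[[3]]$censor, "too_fast")      # gone before dead time
  # the fast exchanger also produced a CLEANEX build-up
  expect_true(3 %in% sim$cleanex_residues)
  clx <- fit_cleanex_buildup(sim$cleanex_series[[1]], i0 = sim$cleanex_i0)
  expect_lt(abs(clx$k - 5) / 5, 0.25)             # k_obs = 10/2 = 5 /s
})
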