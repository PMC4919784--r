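test_that("inertia frame matches hand-diagonalized 3-point case", {
  xyz <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), list(toy_atom_frame(xyz)))
  ens <- read_pdb_ensemble(path)
  fr <- center_and_inertia(ens, mass_scheme = "unit")
  expect_equal(fr$center, c(2 / 3, 1 / 3, 0), tolerance = 1e-10)
  # hand-diagonalized moments of the planar 3-point set
  expect_equal(fr$moments,
               c(5 / 3 - sqrt(13) / 3, 5 / 3 + sqrt(13) / 3, 10 / 3),
               tolerance = 1e-10)
  # largest-moment axis is the plane normal (z)
  expect_equal(abs(fr$axes[, 3]), c(0, 0, 1), tolerance = 1e-10)
  # orthonormality
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("inertia axes are equivariant under rigid motion", {
  set.seed(3)
  xyz <- matrix(rnorm(30, sd = 4), ncol = 3)
  p1 <- write_toy_pdb(tempfile(fileext = ".pdb"), list(toy_atom_frame(xyz)))
  f1 <- center_and_inertia(read_pdb_ensemble(p1), mass_scheme = "unit")
  # translation leaves axes unchanged
  p2 <- write_toy_pdb(tempfile(fileext = ".pdb"),
                      list(toy_atom_frame(sweep(xyz, 2, c(1, 2, 3), `+`))))
  f2 <- center_and_inertia(read_pdb_ensemble(p2), mass_scheme = "unit")
  expect_equal(f2$center, f1$center + c(1, 2, 3), tolerance = 1e-6)
  expect_equal(abs(diag(crossprod(f1$axes, f2$axes))), rep(1, 3),
               tolerance = 1e-6)
  # rotation rotates the axes with the body
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  p3 <- write_toy_pdb(tempfile(fileext = ".pdb"),
                      list(toy_atom_frame(xyz %*% t(R))))
  f3 <- center_and_inertia(read_pdb_ensemble(p3), mass_scheme = "unit")
  expect_equal(abs(diag(crossprod(R %*% f1$axes, f3$axes))), rep(1, 3),
               tolerance = 1e-6)
})

test_that("alpha angles fold to [0, 90] and flag missing amides", {
  path <- tempfile(fileext = ".pdb")
  write_toy_helix_pdb(path, n_res = 8)
  ens <- read_pdb_ensemble(path)
  a_up <- nh_alpha_angles(ens, c(0, 0, 1))
  a_dn <- nh_alpha_angles(ens, c(0, 0, -1))
  expect_true(all(a_up$alpha_deg >= 0 & a_up$alpha_deg <= 90))
  expect_equal(a_up$alpha_deg, a_dn$alpha_deg, tolerance = 1e-10)
  expect_true(all(abs(a_up$ux^2 + a_up$uy^2 + a_up$uz^2 - 1) < 1e-6))
  # residue 1 is skipped (no observable amide)
  expect_true(1 %in% attr(a_up, "skipped")$residue)

  # explicit geometry: NH along z vs axis z -> 0; x vs z -> 90; -z vs z -> 0
  u <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, -1))
  alpha <- acos(pmin(1, abs(u %*% c(0, 0, 1)))) * 180 / pi
  expect_equal(as.numeric(alpha), c(0, 90, 0))
})

test_that("ensemble RMSD matches the hand Kabsch oracle and invariants", {
  xyz <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  b <- xyz; b[3, 1] <- 3   # one atom displaced 1 A along x
  path <- write_toy_pdb(tempfile(fileext = ".pdb"),
                        list(toy_atom_frame(xyz, name = "CA"),
                             toy_atom_frame(b, name = "CA")))
  ens <- read_pdb_ensemble(path)
  r <- ensemble_rmsd_to_mean(ens, selection = "backbone")
  # closed form: centred difference vector (1/3,1/3,-2/3) -> per-model
  # deviation from the mean is half of it, rmsd = sqrt(1/18)
  expect_equal(r$per_model, rep(sqrt(1 / 18), 2), tolerance = 1e-8)

  # identical models give zero
  p0 <- write_toy_pdb(tempfile(fileext = ".pdb"),
                      list(toy_atom_frame(xyz), toy_atom_frame(xyz)))
  expect_equal(ensemble_rmsd_to_mean(read_pdb_ensemble(p0))$mean, 0,
               tolerance = 1e-10)

  # to-mean RMSD <= max pairwise RMSD on a random ensemble
  set.seed(9)
  base <- matrix(rnorm(24, sd = 3), ncol = 3)
  models <- lapply(1:4, function(i)
    toy_atom_frame(base + matrix(rnorm(24, sd = 0.3), ncol = 3)))
  pr <- write_toy_pdb(tempfile(fileext = ".pdb"), models)
  er <- read_pdb_ensemble(pr)
  tomean <- ensemble_rmsd_to_mean(er)
  pw <- ensemble_rmsd_to_mean(er, pairwise = TRUE)
  expect_lte(max(tomean$per_model), max(pw$per_pair) + 1e-9)

  # invariance to a global rigid motion of the whole ensemble
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  rot_models <- lapply(models, function(m) {
    x <- as.matrix(m[, c("x", "y", "z")]) %*% t(R)
    toy_atom_frame(sweep(x, 2, c(5, -2, 1), `+`))
  })
  er2 <- read_pdb_ensemble(write_toy_pdb(tempfile(fileext = ".pdb"),
                                         rot_models))
  # coordinates are written at 0.001 A precision, so agreement is to ~1e-3
  expect_equal(ensemble_rmsd_to_mean(er2)$per_model, tomean$per_model,
               tolerance = 2e-3)
})

test_that("RMSF recovers closed-form and brute-force fluctuation values", {
  # one atom oscillating +/- d along x, others static, no superposition
  d <- 0.8
  base <- matrix(c(0, 0, 0, 5, 0, 0, 10, 0, 0), ncol = 3, byrow = TRUE)
  models <- lapply(1:6, function(i) {
    m <- base
    m[2, 1] <- m[2, 1] + d * ifelse(i %% 2 == 0, 1, -1)
    toy_atom_frame(m)
  })
  ens <- read_pdb_ensemble(write_toy_pdb(tempfile(fileext = ".pdb"), models))
  rmsf <- ensemble_rmsf(ens)
  expect_equal(rmsf$rmsf, c(0, d, 0), tolerance = 1e-10)

  # random frames: matches direct per-atom SD computation (brute force)
  set.seed(21)
  frames <- lapply(1:20, function(i)
    toy_atom_frame(base + matrix(rnorm(9, sd = 0.2), ncol = 3)))
  e2 <- read_pdb_ensemble(write_toy_pdb(tempfile(fileext = ".pdb"), frames))
  got <- ensemble_rmsf(e2)
  arr <- simplify2array(lapply(seq_len(e2$n_models), function(m)
    matrix(e2$xyz[m, ], ncol = 3, byrow = TRUE)))
  brute <- sqrt(rowMeans(apply(arr, 3, function(f)
    rowSums((f - apply(arr, c(1, 2), mean))^2))))
  expect_equal(got$rmsf, brute, tolerance = 1e-10)

  # static frames give exactly zero, single frame errors
  e0 <- read_pdb_ensemble(write_toy_pdb(tempfile(fileext = ".pdb"),
                                        list(frames[[1]], frames[[1]])))
  expect_equal(ensemble_rmsf(e0)$rmsf, rep(0, 3))
  e1 <- read_pdb_ensemble(write_toy_pdb(tempfile(fileext = ".pdb"),
                                        list(frames[[1]])))
  expect_error(ensemble_rmsf(e1), "frames")
})
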