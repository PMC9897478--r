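test_that("generated assembly is exactly C5 symmetric", {
  toy <- build_toy_channel(small_toy_spec())
  m <- toy$model
  n_per <- n_atoms(m) / 5
  th <- 2 * pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- m$xyz %*% t(R)
  # rotating by 72 degrees maps chain s onto chain s+1 atom-by-atom
  perm <- c((n_per + 1):n_atoms(m), 1:n_per)
  expect_lt(max(abs(rotated - m$xyz[perm, ])), 1e-6)
})

test_that("ground-truth report matches direct recomputation", {
  toy <- build_toy_channel()
  expect_equal(toy$ground_truth$rg,
               radius_of_gyration(toy$model, weighting = "excess_b"),
               tolerance = 1e-9)
  expect_equal(toy$ground_truth$dmax, max(dist(toy$model$xyz)),
               tolerance = 1e-6)
  expect_equal(n_atoms(toy$model), 2540)
  # defaults mirror the real system's scale
  expect_gt(toy$ground_truth$rg, 45); expect_lt(toy$ground_truth$rg, 55)
  expect_gt(toy$ground_truth$dmax, 140); expect_lt(toy$ground_truth$dmax, 175)
})

test_that("builders are bit-reproducible given the same spec and seed", {
  a <- build_toy_channel(small_toy_spec(seed = 9))
  b <- build_toy_channel(small_toy_spec(seed = 9))
  expect_identical(a$model$xyz, b$model$xyz)
  t1 <- lobe_walk_trajectory(a$model, lobe_walk_spec(n_frames = 6, seed = 5))
  t2 <- lobe_walk_trajectory(b$model, lobe_walk_spec(n_frames = 6, seed = 5))
  expect_identical(t1$frames, t2$frames)
  s1 <- simulate_sans(a$model, seed = 77)
  s2 <- simulate_sans(b$model, seed = 77)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("moving lobes outward strictly grows Rg and dmax", {
  # both lobe rings pushed outward together
  specs <- lapply(c(1, 1.2, 1.4), function(f)
    toy_channel_spec(tmd_atoms_per_rod = 4, ecd_atoms = 30, lobe_atoms = 12,
                     ntd1_pos = c(40 * f, 96), ntd2_pos = c(25 * f, 117)))
  gts <- lapply(specs, function(s) build_toy_channel(s)$ground_truth)
  rgs <- vapply(gts, `[[`, 0, "rg")
  dms <- vapply(gts, `[[`, 0, "dmax")
  expect_true(all(diff(rgs) > 0))
  expect_true(all(diff(dms) > 0))
})

test_that("lobe perturbation is exact, local, and symmetry-breaking", {
  toy <- build_toy_channel(small_toy_spec())
  same <- perturb_lobes(toy, list(NTD1_A = c(dr = 0, dz = 0)))
  expect_equal(same$xyz, toy$model$xyz)
  moved <- perturb_lobes(toy, list(NTD1_A = c(dr = 10, dz = -8),
                                   NTD1_C = c(dr = 10, dz = -8)))
  key <- paste(toy$model$atoms$segid, toy$model$atoms$chain, sep = "_")
  untouched <- !(key %in% c("NTD1_A", "NTD1_C"))
  expect_equal(moved$xyz[untouched, ], toy$model$xyz[untouched, ])
  # two of five lobes out-and-down breaks the C5 symmetry
  n_per <- n_atoms(toy$model) / 5
  th <- 2 * pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  perm <- c((n_per + 1):n_atoms(toy$model), 1:n_per)
  expect_gt(max(abs(moved$xyz %*% t(R) - moved$xyz[perm, ])), 1)
  expect_error(perturb_lobes(toy, list(NTD9_A = c(1, 1))), "unknown lobe")
})

test_that("zero step size produces a static trajectory", {
  toy <- build_toy_channel(small_toy_spec())
  traj <- lobe_walk_trajectory(toy, lobe_walk_spec(n_frames = 5,
                                                   sigma_ntd1 = c(0, 0),
                                                   sigma_ntd2 = c(0, 0),
                                                   seed = 2))
  for (f in 2:5) expect_equal(traj$frames[[f]], traj$frames[[1]])
})

test_that("unbounded walk variance matches the OU stationary closed form", {
  toy <- build_toy_channel(toy_channel_spec(tmd_atoms_per_rod = 3,
                                            ecd_atoms = 10, lobe_atoms = 5))
  kappa <- 0.25; sigma <- 1.0
  walk <- lobe_walk_spec(n_frames = 4000, sigma_ntd1 = c(sigma, sigma),
                         sigma_ntd2 = c(sigma, sigma), reversion = kappa,
                         bounds_r = c(-50, 50), bounds_z = c(-50, 50),
                         seed = 11)
  traj <- lobe_walk_trajectory(toy, walk)
  tr <- domain_track(traj, list(NTD1_A = "segid NTD1 and chain A"),
                     fixed_axis = z_axis_frame())
  v_expected <- sigma^2 / (1 - (1 - kappa)^2)   # stationary OU variance
  burn <- tr$frame > 50
  expect_equal(var(tr$z[burn]), v_expected, tolerance = 0.2)
  expect_equal(var(tr$r_xy[burn]), v_expected, tolerance = 0.2)
})

test_that("strong mean reversion keeps end positions near the start", {
  toy <- build_toy_channel(toy_channel_spec(tmd_atoms_per_rod = 3,
                                            ecd_atoms = 10, lobe_atoms = 5))
  ends <- vapply(1:10, function(s) {
    traj <- lobe_walk_trajectory(toy, lobe_walk_spec(
      n_frames = 60, reversion = 0.6, seed = s))
    last <- traj$frames[[60]]
    idx <- select_atoms(toy$model, "segid NTD1 and chain A")
    sqrt(sum((colMeans(last[idx, ]) - colMeans(toy$model$xyz[idx, ]))^2))
  }, 0)
  # reversible excursions: typical end displacement stays near the start,
  # far below the reflecting bounds
  expect_lt(mean(ends), 2.5 * sqrt(2) * 2.5 / sqrt(2 * 0.6))
})

test_that("walk displacements respect the reflecting bounds", {
  toy <- build_toy_channel(small_toy_spec())
  walk <- lobe_walk_spec(n_frames = 200, sigma_ntd1 = c(6, 6),
                         bounds_r = c(-5, 10), bounds_z = c(-8, 4),
                         reversion = 0, seed = 21)
  traj <- lobe_walk_trajectory(toy, walk)
  tr <- domain_track(traj, list(NTD1_B = "segid NTD1 and chain B"),
                     fixed_axis = z_axis_frame())
  dr <- tr$r_xy - tr$r_xy[1]
  dz <- tr$z - tr$z[1]
  expect_true(all(dr >= -5 - 1e-6 & dr <= 10 + 1e-6))
  expect_true(all(dz >= -8 - 1e-6 & dz <= 4 + 1e-6))
})

test_that("simulated SANS reduces to the clean Debye curve at zero noise", {
  toy <- build_toy_channel(small_toy_spec())
  clean <- debye_curve(toy$model)
  sim <- simulate_sans(toy$model, rel_floor = 0, exposure_scale = 1e12,
                       seed = 5)
  expect_equal(sim$intensity, clean$intensity, tolerance = 1e-9)
  expect_equal(sim$metadata$true_intensity, clean$intensity)
})

test_that("standardized residuals of simulated noise look Gaussian", {
  toy <- build_toy_channel(small_toy_spec())
  z <- unlist(lapply(1:20, function(s) {
    sim <- simulate_sans(toy$model, seed = s)
    (sim$intensity - sim$metadata$true_intensity) / sim$sigma
  }))
  expect_equal(mean(z), 0, tolerance = 3 / sqrt(length(z)))
  expect_equal(sd(z), 1, tolerance = 0.05)
  expect_gt(stats::shapiro.test(sample(z, min(length(z), 2000)))$p.value, 1e-3)
})

test_that("refitting the generating model to its noisy curve gives chi2 ~ 1", {
  cal <- chi2_calibration_experiment(
    build_toy_channel(small_toy_spec())$model, n_seeds = 20, seed = 2)
  expect_equal(cal$chi2_mean, 1, tolerance = 0.15)
  expect_equal(cal$scale_mean, 1, tolerance = 0.02)
})
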