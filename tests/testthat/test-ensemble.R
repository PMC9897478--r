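test_that("multi-model PDB and XYZ trajectories round-trip with stride", {
  toy <- build_toy_channel(small_toy_spec())
  frames <- lapply(0:2, function(k) toy$model$xyz + k)
  traj <- trajectory(toy$model, frames)
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, pdb_path)
  back <- load_trajectory(pdb_path)
  expect_equal(n_frames(back), 3)
  expect_equal(back$frames[[2]], traj$frames[[2]], tolerance = 1e-3,
               ignore_attr = TRUE)
  xyz_path <- withr::local_tempfile(fileext = ".xyz")
  many <- trajectory(toy$model, rep(frames, length.out = 101))
  write_xyz_trajectory(many, xyz_path)
  strided <- load_trajectory(xyz_path, topology = toy$model, stride = 10)
  expect_equal(n_frames(strided), 11)
  expect_equal(strided$frames[[1]], many$frames[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
  # atom-count mismatch is rejected with the frame named
  bad <- frames; bad[[2]] <- bad[[2]][-1, ]
  expect_error(trajectory(toy$model, bad), "frame 2")
})

test_that("RMSD series is zero against its own reference and for rigid motion", {
  toy <- build_toy_channel(small_toy_spec())
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  frames <- list(toy$model$xyz,
                 sweep(toy$model$xyz %*% t(R), 2, c(3, 1, -2), `+`),
                 toy$model$xyz + 5)
  traj <- trajectory(toy$model, frames)
  rs <- rmsd_series(traj, fit_selection = "all")
  expect_equal(rs[1], 0, tolerance = 1e-9)
  expect_true(all(rs < 1e-6))   # rigid-body-only motion, fit = measure
})

test_that("scripted lobe translation appears as the constructed RMSD", {
  toy <- build_toy_channel(small_toy_spec())
  moved <- perturb_lobes(toy, list(NTD1_A = c(dr = 8, dz = 0)))
  traj <- trajectory(toy$model, list(toy$model$xyz, moved$xyz))
  rs <- rmsd_series(traj, fit_selection = "not segid NTD1 NTD2",
                    measure_selection = "segid NTD1 and chain A")
  expect_equal(rs[2], 8, tolerance = 0.01)
})

test_that("RMSF converges to sigma*sqrt(3) under isotropic jitter", {
  toy <- build_toy_channel(toy_channel_spec(tmd_atoms_per_rod = 3,
                                            ecd_atoms = 10, lobe_atoms = 5))
  core <- toy$model
  sigma <- 0.5
  set.seed(123)
  frames <- lapply(1:150, function(i)
    core$xyz + matrix(rnorm(length(core$xyz), 0, sigma), ncol = 3))
  traj <- trajectory(core, frames)
  # static trajectory first
  static <- trajectory(core, list(core$xyz, core$xyz, core$xyz))
  expect_true(all(rmsf(static, "all")$rmsf < 1e-9))
  rf <- rmsf(traj, "all", align_selection = "all")
  # alignment on everything absorbs a little variance; stay within 10%
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.1)
  frames2 <- lapply(1:150, function(i)
    core$xyz + matrix(rnorm(length(core$xyz), 0, 2 * sigma), ncol = 3))
  rf2 <- rmsf(trajectory(core, frames2), "all", align_selection = "all")
  expect_equal(mean(rf2$rmsf) / mean(rf$rmsf), 2, tolerance = 0.1)
})

test_that("domain tracking reads scripted displacements back exactly", {
  toy <- build_toy_channel(small_toy_spec())
  moved <- perturb_lobes(toy, list(NTD1_A = c(dr = 10, dz = -8)))
  traj <- trajectory(toy$model, list(toy$model$xyz, moved$xyz))
  ax <- z_axis_frame()
  tr <- domain_track(traj, list(NTD1_A = "segid NTD1 and chain A"),
                     fixed_axis = ax)
  expect_equal(tr$r_xy[2] - tr$r_xy[1], 10, tolerance = 1e-9)
  expect_equal(tr$z[2] - tr$z[1], -8, tolerance = 1e-9)
  # static frames have zero variance in both coordinates
  st_traj <- trajectory(toy$model, list(toy$model$xyz, toy$model$xyz))
  tr0 <- domain_track(st_traj, list(NTD1_A = "segid NTD1 and chain A"),
                      fixed_axis = ax)
  expect_equal(var(tr0$r_xy), 0)
  expect_equal(var(tr0$z), 0)
  # a domain sitting on the axis has r_xy = 0
  onax <- toy$model
  idx <- select_atoms(onax, "segid NTD1 and chain A")
  onax$xyz[idx, 1:2] <- sweep(onax$xyz[idx, 1:2], 2,
                              colMeans(onax$xyz[idx, 1:2, drop = FALSE]))
  tr_ax <- domain_track(trajectory(onax, list(onax$xyz)),
                        list(NTD1_A = "segid NTD1 and chain A"),
                        fixed_axis = ax)
  expect_lt(tr_ax$r_xy[1], 1e-9)
})

test_that("r_xy tracking is invariant under rotations about the axis", {
  toy <- build_toy_channel(small_toy_spec())
  th <- 2 * pi / 7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- set_coords(toy$model, toy$model$xyz %*% t(R))
  ax <- z_axis_frame()
  doms <- list(NTD1_A = "segid NTD1 and chain A",
               NTD2_C = "segid NTD2 and chain C")
  t1 <- domain_track(trajectory(toy$model, list(toy$model$xyz)), doms,
                     fixed_axis = ax)
  t2 <- domain_track(trajectory(rot, list(rot$xyz)), doms, fixed_axis = ax)
  expect_equal(t1$r_xy, t2$r_xy, tolerance = 1e-9)
  expect_equal(t1$z, t2$z, tolerance = 1e-9)
})

test_that("frame ranking finds a planted exact conformer with chi2 ~ 0", {
  toy <- build_toy_channel(small_toy_spec())
  moved <- perturb_lobes(toy, list(NTD1_B = c(dr = 12, dz = -5)))
  clean <- debye_curve(moved, q_grid = default_q_grid(60))
  data <- scattering_curve(clean$q, clean$intensity,
                           sigma = 0.01 * abs(clean$intensity))
  traj <- trajectory(toy$model, list(toy$model$xyz, moved$xyz,
                                     toy$model$xyz + 0))
  rk <- rank_frames_by_sans(traj, data)
  expect_equal(rk$frame[1], 2)
  expect_lt(rk$chi2[1], 1e-9)
  expect_true(all(diff(rk$chi2) >= -1e-12))
  # ordering invariant to common rescaling of the data curve
  data2 <- scattering_curve(data$q, 3.1 * data$intensity, sigma = 3.1 * data$sigma)
  rk2 <- rank_frames_by_sans(traj, data2)
  expect_equal(rk2$frame, rk$frame)
  expect_equal(rk2$chi2, rk$chi2, tolerance = 1e-9)
})

test_that("PCA landscape captures single-direction motion as 100% PC1", {
  toy <- build_toy_channel(small_toy_spec())
  dirvec <- c(1, 0, 0)
  idx <- select_atoms(toy$model, "segid NTD1 and chain A")
  frames <- lapply(seq(-3, 3, by = 1.5), function(a) {
    xyz <- toy$model$xyz
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, a * dirvec, `+`)
    xyz
  })
  # align on the static core so the moving lobe is the only variance source
  ls <- pca_landscape(trajectory(toy$model, frames),
                      selection = "all")
  expect_gt(ls$eigenvalues[1] / sum(ls$eigenvalues), 0.999)
  # eigenvalue sum equals total coordinate variance
  expect_equal(sum(ls$eigenvalues),
               sum(apply(do.call(rbind, lapply(seq_along(frames), function(f)
                 ls$projections[f, ])), 2, var)),
               tolerance = 1e-6)
})

test_that("projection reproduces stored projections and ignores rigid moves", {
  toy <- build_toy_channel(small_toy_spec())
  traj <- lobe_walk_trajectory(toy, lobe_walk_spec(n_frames = 8, seed = 3))
  ls <- pca_landscape(traj, selection = "all")
  p5 <- project_onto_landscape(ls, frame_structure(traj, 5))
  expect_equal(unlist(p5[1, seq_len(ncol(ls$basis))]),
               ls$projections[5, ], tolerance = 1e-8, ignore_attr = TRUE)
  # rigid pre-transformation of the input does not move the projection
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  st <- frame_structure(traj, 5)
  st_moved <- set_coords(st, sweep(st$xyz %*% t(R), 2, c(10, -4, 2), `+`))
  p5r <- project_onto_landscape(ls, st_moved)
  expect_equal(unlist(p5r[1, ]), unlist(p5[1, ]), tolerance = 1e-6)
  # the mean conformation projects to the origin
  mean_st <- set_coords(subset_structure(toy$model, ls$ref_idx),
                        matrix(ls$mean, ncol = 3, byrow = TRUE))
  ls_all <- pca_landscape(traj, selection = "all")
  pm <- project_onto_landscape(ls_all, mean_st)
  expect_lt(max(abs(unlist(pm[1, 1:2]))), 1e-6)
})

test_that("two synthetic clusters separate along PC1", {
  res <- two_cluster_landscape_experiment(n_frames_per = 12, seed = 4)
  expect_true(res$separable)
  expect_gt(res$gap, 1)
  # bimodality: the two cluster means are far apart relative to spread
  m1 <- mean(res$pc1[res$cluster == 1]); m2 <- mean(res$pc1[res$cluster == 2])
  s <- sd(res$pc1)
  expect_gt(abs(m1 - m2), s)
})
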