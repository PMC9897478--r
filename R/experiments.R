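#' Planted-conformer recovery experiment
#'
#' The desk-scale analogue of identifying an asymmetric lobe arrangement
#' from solution scattering: a toy channel with two of five NTD1 lobes
#' translated out-and-down generates a noisy SANS curve; the curve is then
#' ranked against a trajectory of decoy conformers (bounded lobe random
#' walks) plus the planted conformer itself. A repeat succeeds when the
#' top-ranked frame has every lobe center of mass within `tol` of the
#' planted conformer's.
#'
#' @param n_repeats number of independently seeded repeats (default 20)
#' @param n_decoys decoy conformers per repeat (default 49, i.e. 50 frames
#'   in total with the planted one)
#' @param displacement `c(dr, dz)` of the planted lobes, A (default
#'   out-and-down `c(10, -8)`)
#' @param lobes which lobes are displaced (default NTD1 of chains A and C)
#' @param tol lobe-COM tolerance for a qualifying frame, A (default 2)
#' @param seed base seed; repeat `k` uses seeds derived from it
#' @param spec a [toy_channel_spec()]
#' @return List: `success_rate` (fraction of repeats recovering the planted
#'   conformer), `n_repeats`, `details` (per-repeat data.frame with top
#'   frame, its chi2, the planted frame's rank and chi2).
#' @export
planted_recovery_experiment <- function(n_repeats = 20, n_decoys = 49,
                                        displacement = c(dr = 10, dz = -8),
                                        lobes = c("NTD1_A", "NTD1_C"),
                                        tol = 2, seed = 1,
                                        spec = toy_channel_spec()) {
  toy <- build_toy_channel(spec)
  disp <- setNames(rep(list(displacement), length(lobes)), lobes)
  planted <- perturb_lobes(toy, disp)
  key <- paste(toy$model$atoms$segid, toy$model$atoms$chain, sep = "_")
  lobe_labels <- .lobe_labels(toy$model)
  lobe_idx <- lapply(lobe_labels, function(nm) which(key == nm))
  planted_com <- lapply(lobe_idx, function(idx) colMeans(planted$xyz[idx, , drop = FALSE]))
  rows <- vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    dat <- simulate_sans(planted, seed = seed * 1000 + k)
    traj <- lobe_walk_trajectory(toy, lobe_walk_spec(n_frames = n_decoys,
                                                     seed = seed * 2000 + k))
    traj <- trajectory(traj$topology, c(traj$frames, list(planted$xyz)))
    n_fr <- n_frames(traj)
    rk <- rank_frames_by_sans(traj, dat)
    qualifies <- vapply(seq_len(n_fr), function(f) {
      d <- vapply(seq_along(lobe_idx), function(l)
        sqrt(sum((colMeans(traj$frames[[f]][lobe_idx[[l]], , drop = FALSE]) -
                    planted_com[[l]])^2)), 0)
      max(d) <= tol
    }, TRUE)
    rows[[k]] <- data.frame(
      repeat_id = k, top_frame = rk$frame[1], top_chi2 = rk$chi2[1],
      top_qualifies = qualifies[rk$frame[1]],
      planted_rank = which(rk$frame == n_fr),
      planted_chi2 = rk$chi2[rk$frame == n_fr])
  }
  details <- do.call(rbind, rows)
  list(success_rate = mean(details$top_qualifies), n_repeats = n_repeats,
       details = details)
}

#' Two-cluster landscape separation experiment
#'
#' Generates two toy-channel trajectories — one fluctuating around the
#' compact conformation, one around an extended conformation with all NTD1
#' lobes translated outward — builds a joint PCA landscape, and measures
#' how the two clusters separate along PC1: the silhouette-like gap between
#' clusters and whether a single threshold classifies every frame.
#'
#' @param n_frames_per frames per trajectory (default 25)
#' @param extension `c(dr, dz)` applied to every NTD1 lobe for the extended
#'   cluster (default `c(14, -6)`)
#' @param walk_sigma per-frame step SD for the within-cluster jitter
#' @param seed RNG seed
#' @param spec a [toy_channel_spec()]
#' @return List: `landscape`, `pc1` (projections), `cluster` (1/2 labels),
#'   `separable` (logical: clusters split by a PC1 threshold), `gap`
#'   (distance between cluster hulls on PC1, in units of the pooled
#'   within-cluster SD), `pc1_variance_fraction`.
#' @export
two_cluster_landscape_experiment <- function(n_frames_per = 25,
                                             extension = c(dr = 14, dz = -6),
                                             walk_sigma = c(1.2, 1.2),
                                             seed = 1,
                                             spec = toy_channel_spec()) {
  toy <- build_toy_channel(spec)
  ntd1 <- grep("^NTD1", .lobe_labels(toy$model), value = TRUE)
  extended <- perturb_lobes(toy, setNames(rep(list(extension), length(ntd1)), ntd1))
  mk_walk <- function(s) lobe_walk_spec(n_frames = n_frames_per,
                                        sigma_ntd1 = walk_sigma,
                                        sigma_ntd2 = walk_sigma,
                                        reversion = 0.3, seed = s)
  traj_compact <- lobe_walk_trajectory(toy, mk_walk(seed * 10 + 1))
  traj_extended <- lobe_walk_trajectory(extended, mk_walk(seed * 10 + 2))
  ls <- pca_landscape(list(traj_compact, traj_extended), selection = "all")
  pc1 <- ls$projections[, 1]
  cl <- ls$source
  r1 <- range(pc1[cl == 1]); r2 <- range(pc1[cl == 2])
  separable <- (r1[2] < r2[1]) || (r2[2] < r1[1])
  pooled_sd <- sqrt(mean(c(var(pc1[cl == 1]), var(pc1[cl == 2]))))
  gap <- if (r1[2] < r2[1]) (r2[1] - r1[2]) / pooled_sd
         else if (r2[2] < r1[1]) (r1[1] - r2[2]) / pooled_sd
         else -min(abs(r1[2] - r2[1]), abs(r2[2] - r1[1])) / pooled_sd
  list(landscape = ls, pc1 = pc1, cluster = cl, separable = separable,
       gap = gap,
       pc1_variance_fraction = ls$eigenvalues[1] / sum(ls$eigenvalues))
}

#' Noise-model calibration experiment
#'
#' Fits the generating model back to its own simulated noisy curves over
#' many seeds; with a correctly reported sigma column the reduced
#' chi-square should average 1.
#'
#' @param structure structure to simulate (default: the toy channel)
#' @param n_seeds number of simulated measurements (default 20)
#' @param seed base seed
#' @param ... passed to [simulate_sans()]
#' @return List: `chi2_mean`, `chi2` (per seed), `scale_mean`,
#'   `background_mean`.
#' @export
chi2_calibration_experiment <- function(structure = NULL, n_seeds = 20,
                                        seed = 1, ...) {
  if (is.null(structure)) structure <- build_toy_channel()$model
  model <- debye_curve(structure)
  chi2 <- scl <- bkg <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sim <- simulate_sans(structure, seed = seed * 3000 + k, ...)
    ft <- fit_scale_background(model, sim)
    chi2[k] <- ft$chi2_reduced; scl[k] <- ft$scale; bkg[k] <- ft$background
  }
  list(chi2_mean = mean(chi2), chi2 = chi2,
       scale_mean = mean(scl), background_mean = mean(bkg))
}
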