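# run code under a local, seeded RNG and restore the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Toy channel specification
#'
#' Parameters of the synthetic C-n-symmetric pseudo-atomic channel: a
#' transmembrane bundle of helix-like rods, an annular extracellular blob,
#' and two peripheral lobes per subunit (NTD1-like and NTD2-like) that the
#' trajectory generator can move as rigid bodies. Defaults mirror the scale
#' of a pentameric channel with peripheral N-terminal domains: about 2,500
#' pseudo-atoms, radius of gyration near 50 A, maximum dimension near 160 A.
#'
#' @param n_subunits number of subunits (default 5)
#' @param tmd_rods rods per subunit (default 4)
#' @param tmd_atoms_per_rod pseudo-atoms per rod (default 17)
#' @param tmd_rise axial spacing within a rod, A (default 2)
#' @param tmd_z_bottom lowest TMD z, A (default -25)
#' @param tmd_radii radial distance of each rod from the axis, A
#' @param ecd_atoms pseudo-atoms per subunit in the ECD blob (default 240)
#' @param ecd_r_range,ecd_z_range radial / axial extent of the ECD annulus, A
#' @param lobe_atoms pseudo-atoms per lobe (default 100)
#' @param lobe_radius lobe cluster radius, A (default 9)
#' @param ntd1_pos,ntd2_pos c(r_xy, z) of the two lobe centers, A
#' @param lobe_azimuth_offset azimuthal offset of the lobes within the
#'   subunit wedge, degrees
#' @param weight per-pseudo-atom scattering weight, fm (default 1)
#' @param mode `"uniform"` (explicit per-atom weight column) or `"alanine"`
#'   (pseudo-atoms carry alanine-like atom records so the contrast model
#'   applies)
#' @param seed RNG seed for the blob/lobe point clouds
#' @return A list of class `toy_channel_spec`.
#' @export
toy_channel_spec <- function(n_subunits = 5, tmd_rods = 4,
                             tmd_atoms_per_rod = 17, tmd_rise = 2,
                             tmd_z_bottom = -28,
                             tmd_radii = c(8, 13, 13, 17),
                             ecd_atoms = 240, ecd_r_range = c(10, 30),
                             ecd_z_range = c(14, 70),
                             lobe_atoms = 100, lobe_radius = 9,
                             ntd1_pos = c(40, 96), ntd2_pos = c(25, 117),
                             lobe_azimuth_offset = c(-12, 12),
                             weight = 1, mode = c("uniform", "alanine"),
                             seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_subunits > 0, tmd_rods > 0, tmd_atoms_per_rod > 0,
            ecd_atoms > 0, lobe_atoms > 0, length(tmd_radii) == tmd_rods)
  structure(as.list(environment()), class = "toy_channel_spec")
}

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# one subunit's pseudo-atoms in the wedge around azimuth 0
.toy_subunit <- function(spec) {
  xyz <- NULL; segid <- character()
  # TMD rods: vertical lines at fixed radius, azimuth spread across the wedge
  rod_az <- seq(-25, 25, length.out = spec$tmd_rods)
  for (r in seq_len(spec$tmd_rods)) {
    z <- spec$tmd_z_bottom + (seq_len(spec$tmd_atoms_per_rod) - 1) * spec$tmd_rise
    th <- rod_az[r] * pi / 180
    xyz <- rbind(xyz, cbind(spec$tmd_radii[r] * cos(th),
                            spec$tmd_radii[r] * sin(th), z))
    segid <- c(segid, rep("TMD", length(z)))
  }
  # ECD annular wedge blob
  u <- matrix(runif(3 * spec$ecd_atoms), ncol = 3)
  rr <- sqrt(u[, 1] * (spec$ecd_r_range[2]^2 - spec$ecd_r_range[1]^2) +
               spec$ecd_r_range[1]^2)      # uniform in the annulus area
  th <- (u[, 2] - 0.5) * (2 * pi / spec$n_subunits)
  zz <- spec$ecd_z_range[1] + u[, 3] * diff(spec$ecd_z_range)
  xyz <- rbind(xyz, cbind(rr * cos(th), rr * sin(th), zz))
  segid <- c(segid, rep("ECD", spec$ecd_atoms))
  # two peripheral lobes: uniform balls
  lobes <- list(NTD1 = spec$ntd1_pos, NTD2 = spec$ntd2_pos)
  for (li in seq_along(lobes)) {
    ctr_r <- lobes[[li]][1]; ctr_z <- lobes[[li]][2]
    th0 <- spec$lobe_azimuth_offset[li] * pi / 180
    ctr <- c(ctr_r * cos(th0), ctr_r * sin(th0), ctr_z)
    pts <- matrix(rnorm(3 * spec$lobe_atoms * 4), ncol = 3)
    pts <- pts * (runif(nrow(pts))^(1 / 3) * spec$lobe_radius /
                    sqrt(rowSums(pts^2)))
    pts <- pts[seq_len(spec$lobe_atoms), , drop = FALSE]
    xyz <- rbind(xyz, sweep(pts, 2, ctr, `+`))
    segid <- c(segid, rep(names(lobes)[li], spec$lobe_atoms))
  }
  list(xyz = xyz, segid = segid)
}

#' Build a synthetic C-n toy channel
#'
#' Generates the pseudo-atomic assembly described by a [toy_channel_spec()]:
#' one seeded subunit template replicated by exact n-fold rotation about z,
#' so the result is exactly C-n symmetric. Chains are labelled A, B, ... and
#' atoms carry a `segid` of TMD / ECD / NTD1 / NTD2.
#'
#' @param spec a [toy_channel_spec()]
#' @return List of class `toy_channel`: `model` (a [structure_model()]),
#'   and `ground_truth` with `rg` (weighted, from the generated coordinates),
#'   `dmax`, `com`, and per-lobe centers of mass (`lobe_com`, cylindrical
#'   `r_xy`/`z` per chain).
#' @export
build_toy_channel <- function(spec = toy_channel_spec()) {
  sub <- .with_seed(spec$seed, .toy_subunit(spec))
  n_per <- nrow(sub$xyz)
  chains <- LETTERS[seq_len(spec$n_subunits)]
  xyz <- NULL
  for (s in seq_len(spec$n_subunits))
    xyz <- rbind(xyz, sub$xyz %*% t(.rot_z((s - 1) * 360 / spec$n_subunits)))
  n <- n_per * spec$n_subunits
  if (spec$mode == "alanine") {
    # five consecutive pseudo-atoms form one alanine-like residue
    pat_name <- c("N", "CA", "C", "O", "CB")
    pat_elem <- c("N", "C", "C", "O", "C")
    k <- (seq_len(n_per) - 1) %% 5 + 1
    atoms1 <- data.frame(name = pat_name[k], element = pat_elem[k],
                         resname = "ALA",
                         resno = (seq_len(n_per) - 1) %/% 5 + 1)
  } else {
    atoms1 <- data.frame(name = "C", element = "C", resname = "TOY",
                         resno = seq_len(n_per))
  }
  atoms <- atoms1[rep(seq_len(n_per), spec$n_subunits), , drop = FALSE]
  atoms$serial <- seq_len(n)
  atoms$chain <- rep(chains, each = n_per)
  atoms$altloc <- ""; atoms$occupancy <- 1; atoms$is_hetero <- FALSE
  atoms$segid <- rep(sub$segid, spec$n_subunits)
  if (spec$mode == "uniform") atoms$b <- spec$weight
  model <- structure_model(atoms, xyz, title = sprintf("toy C%d channel", spec$n_subunits))
  gt_rg <- radius_of_gyration(model, weighting = if (spec$mode == "uniform")
    "excess_b" else "mass", contrast = NULL)
  h <- .pair_hist_weighted(model$xyz, rep(1, n), 1.0)
  lobe_com <- list()
  for (seg in c("NTD1", "NTD2")) for (ch in chains) {
    idx <- which(atoms$segid == seg & atoms$chain == ch)
    com <- colMeans(xyz[idx, , drop = FALSE])
    lobe_com[[paste(seg, ch, sep = "_")]] <-
      c(x = com[1], y = com[2], z = com[3],
        r_xy = sqrt(com[1]^2 + com[2]^2))
  }
  structure(list(model = model, spec = spec,
                 ground_truth = list(rg = gt_rg, dmax = h$dmax,
                                     com = colMeans(xyz),
                                     lobe_com = lobe_com)),
            class = "toy_channel")
}

#' @export
print.toy_channel <- function(x, ...) {
  cat(sprintf("<toy_channel> %d atoms, Rg = %.1f A, dmax = %.1f A\n",
              n_atoms(x$model), x$ground_truth$rg, x$ground_truth$dmax))
  invisible(x)
}

.lobe_labels <- function(model) {
  a <- model$atoms
  unique(paste(a$segid, a$chain, sep = "_")[a$segid %in% c("NTD1", "NTD2")])
}

#' Rigidly displace named lobes
#'
#' Translates each named lobe cluster (e.g. `"NTD1_A"`) radially outward
#' from the z axis by `dr` and axially by `dz` ("out-and-down" moves use
#' `dz < 0`); the core is untouched.
#'
#' @param model a toy-channel `structure_model` (or the `toy_channel` list)
#' @param displacements named list; each element `c(dr = ..., dz = ...)`
#' @return The displaced `structure_model`.
#' @export
perturb_lobes <- function(model, displacements) {
  if (inherits(model, "toy_channel")) model <- model$model
  labels <- .lobe_labels(model)
  key <- paste(model$atoms$segid, model$atoms$chain, sep = "_")
  xyz <- model$xyz
  for (nm in names(displacements)) {
    if (!nm %in% labels) stop("unknown lobe label '", nm, "'")
    idx <- which(key == nm)
    d <- displacements[[nm]]
    dr <- if ("dr" %in% names(d)) d[["dr"]] else d[1]
    dz <- if ("dz" %in% names(d)) d[["dz"]] else d[2]
    ctr <- colMeans(xyz[idx, , drop = FALSE])
    u <- c(ctr[1], ctr[2], 0)
    u <- u / sqrt(sum(u^2))
    shift <- dr * u + c(0, 0, dz)
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, `+`)
  }
  set_coords(model, xyz)
}

#' Lobe random-walk specification
#'
#' Bounded, mean-reverting (Ornstein-Uhlenbeck-like) per-frame steps of each
#' lobe center in cylindrical coordinates, emulating reversible rigid-body
#' excursions of peripheral domains: NTD1-like lobes move in both `r_xy`
#' and `z`, NTD2-like lobes mainly along `z`.
#'
#' @param n_frames number of frames
#' @param sigma_ntd1,sigma_ntd2 per-frame step SD `c(r, z)` in A
#' @param reversion mean-reversion strength kappa in `[0, 1]` per frame
#' @param bounds_r,bounds_z reflecting bounds on the displacement from the
#'   start position, A
#' @param seed RNG seed
#' @return List of class `lobe_walk_spec`.
#' @export
lobe_walk_spec <- function(n_frames = 50, sigma_ntd1 = c(2.5, 2.5),
                           sigma_ntd2 = c(0.8, 2.0), reversion = 0.08,
                           bounds_r = c(-8, 25), bounds_z = c(-20, 12),
                           seed = 1) {
  stopifnot(n_frames >= 1, reversion >= 0, reversion <= 1,
            bounds_r[1] <= 0, bounds_r[2] >= 0,
            bounds_z[1] <= 0, bounds_z[2] >= 0)
  structure(as.list(environment()), class = "lobe_walk_spec")
}

.reflect <- function(x, lo, hi) {
  # reflect into [lo, hi]
  for (k in 1:10) {
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
    if (all(x >= lo & x <= hi)) break
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a lobe-motion trajectory
#'
#' The core (TMD+ECD) is static; each lobe's displacement from its starting
#' position follows a reflected mean-reverting random walk in (radial,
#' axial) coordinates:
#' \eqn{s_{t+1} = s_t - \kappa s_t + \sigma \epsilon_t}, reflected at the
#' bounds. With no bounds the stationary SD is
#' \eqn{\sigma / \sqrt{1 - (1-\kappa)^2}}.
#'
#' @param model a toy-channel `structure_model` (or `toy_channel` list)
#' @param walk a [lobe_walk_spec()]
#' @return A [trajectory()]; frame 1 is the input conformation.
#' @export
lobe_walk_trajectory <- function(model, walk = lobe_walk_spec()) {
  if (inherits(model, "toy_channel")) model <- model$model
  labels <- .lobe_labels(model)
  key <- paste(model$atoms$segid, model$atoms$chain, sep = "_")
  idx_of <- lapply(labels, function(nm) which(key == nm))
  names(idx_of) <- labels
  sig <- lapply(labels, function(nm)
    if (startsWith(nm, "NTD1")) walk$sigma_ntd1 else walk$sigma_ntd2)
  names(sig) <- labels
  .with_seed(walk$seed, {
    state <- matrix(0, length(labels), 2,
                    dimnames = list(labels, c("dr", "dz")))
    frames <- vector("list", walk$n_frames)
    frames[[1]] <- model$xyz
    for (f in seq_len(walk$n_frames)[-1]) {
      xyz <- model$xyz
      for (nm in labels) {
        s <- sig[[nm]]
        state[nm, ] <- state[nm, ] - walk$reversion * state[nm, ] +
          s * rnorm(2)
        state[nm, "dr"] <- .reflect(state[nm, "dr"], walk$bounds_r[1], walk$bounds_r[2])
        state[nm, "dz"] <- .reflect(state[nm, "dz"], walk$bounds_z[1], walk$bounds_z[2])
        idx <- idx_of[[nm]]
        ctr <- colMeans(model$xyz[idx, , drop = FALSE])
        u <- c(ctr[1], ctr[2], 0); u <- u / sqrt(sum(u^2))
        shift <- state[nm, "dr"] * u + c(0, 0, state[nm, "dz"])
        xyz[idx, ] <- sweep(model$xyz[idx, , drop = FALSE], 2, shift, `+`)
      }
      frames[[f]] <- xyz
    }
    trajectory(model, frames)
  })
}

#' Simulate a noisy SANS measurement of a structure
#'
#' Debye prediction plus Gaussian counting noise. The per-point sigma is
#' \eqn{\sigma_k = f \, I_k + \sqrt{I_k I_0} / E} (a relative floor `f` plus
#' a counting-statistics term scaled by the exposure `E`), and the sigma
#' column of the returned curve reports the generating values.
#'
#' @param structure a `structure_model`
#' @param contrast a [contrast_model()] or `NULL` (explicit weights)
#' @param q_grid Q grid, A^-1
#' @param rel_floor relative noise floor (default 0.01)
#' @param exposure_scale counting-statistics scale (default 500; larger =
#'   quieter high-Q tail)
#' @param bin_width Debye histogram bin width
#' @param seed RNG seed
#' @return A [scattering_curve()] with `metadata$true_intensity` holding the
#'   noiseless curve.
#' @export
simulate_sans <- function(structure, contrast = NULL, q_grid = default_q_grid(),
                          rel_floor = 0.01, exposure_scale = 500,
                          bin_width = 0.5, seed = 1) {
  stopifnot(rel_floor >= 0, exposure_scale > 0)
  clean <- debye_curve(structure, contrast, q_grid = q_grid, bin_width = bin_width)
  i0 <- clean$intensity[1]
  sg <- rel_floor * abs(clean$intensity) +
    sqrt(pmax(clean$intensity * i0, 0)) / exposure_scale
  sg <- pmax(sg, 1e-12 * max(abs(clean$intensity)))
  noisy <- .with_seed(seed, clean$intensity + rnorm(length(sg), 0, sg))
  scattering_curve(q_grid, noisy, sigma = sg,
                   metadata = list(kind = "simulated_sans", seed = seed,
                                   true_intensity = clean$intensity))
}
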