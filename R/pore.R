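# Bondi van der Waals radii (A); heavy-atom structures, no united-atom fattening
.vdw_radius <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, "NA" = 2.27, CL = 1.75, K = 2.75, CA = 2.31,
                 MG = 1.73, ZN = 1.39, FE = 2.00, SE = 1.90)

.vdw_of <- function(element, radii_table = .vdw_radius) {
  r <- unname(radii_table[element])
  r[is.na(r)] <- 1.70
  r
}

#' Channel axis determination
#'
#' Either the principal inertia axis of a (C-alpha) selection, or the line
#' through the centers of mass of two selections (e.g. TMD and ECD). The
#' axis is oriented so the `orient_selection` (extracellular side) lies at
#' positive z; the returned frame places its origin at the structure's
#' selection centroid.
#'
#' @param structure a `structure_model`
#' @param method `"inertia"` or `"selection-com-line"`
#' @param selection atoms defining the axis (default `"calpha"`; falls back
#'   to `"all"` when the structure has no CA atoms)
#' @param from_selection,to_selection the two COM selections for
#'   `"selection-com-line"`; axis points from the first toward the second
#' @param orient_selection selection that should have positive mean z
#'   (optional for `"inertia"`)
#' @return List of class `axis_frame`: `origin`, `axis` (unit vector).
#' @export
channel_axis <- function(structure, method = c("inertia", "selection-com-line"),
                         selection = "calpha", from_selection = NULL,
                         to_selection = NULL, orient_selection = NULL) {
  method <- match.arg(method)
  if (method == "selection-com-line") {
    if (is.null(from_selection) || is.null(to_selection))
      stop("selection-com-line needs from_selection and to_selection")
    a <- center_of_mass(structure, select_atoms(structure, from_selection))
    b <- center_of_mass(structure, select_atoms(structure, to_selection))
    v <- b - a
    if (sqrt(sum(v^2)) < 1e-9) stop("coincident selection centers; axis undefined")
    return(structure(list(origin = a, axis = v / sqrt(sum(v^2))),
                     class = "axis_frame"))
  }
  idx <- select_atoms(structure, selection)
  if (!length(idx)) idx <- select_atoms(structure, "all")
  xyz <- structure$xyz[idx, , drop = FALSE]
  ctr <- colMeans(xyz)
  cv <- stats::cov(xyz)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] < 1.2 * eg$values[2])
    stop("near-spherical inertia tensor: axis ambiguous, use method = 'selection-com-line'")
  ax <- eg$vectors[, 1]
  if (!is.null(orient_selection)) {
    oc <- center_of_mass(structure, select_atoms(structure, orient_selection))
    if (sum((oc - ctr) * ax) < 0) ax <- -ax
  } else if (ax[3] < 0 || (ax[3] == 0 && (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)))) {
    ax <- -ax  # deterministic sign in the absence of an orienting selection
  }
  structure(list(origin = ctr, axis = ax), class = "axis_frame")
}

# orthonormal basis (e1, e2, axis)
.axis_basis <- function(frame) {
  ax <- frame$axis
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  cbind(e1, e2, ax)
}

#' Coordinates in an axis frame
#'
#' @param xyz `n x 3` matrix
#' @param frame an `axis_frame`
#' @return `n x 3` matrix whose third column is the position along the axis
#'   and first two columns span the orthogonal plane.
#' @export
to_axis_frame <- function(xyz, frame) {
  sweep(as.matrix(xyz), 2, frame$origin) %*% .axis_basis(frame)
}

#' Pore radius profile along the channel axis
#'
#' HOLE/CHAP-style profile: at each z-slice the probe radius is the largest
#' clearance `min_i(|c - x_i| - vdw_i)` over probe centers `c` in the slice
#' plane within `max_offaxis` of the axis, found by a multi-start local
#' search (fixed RNG seed, deterministic). Radii are clipped at
#' `bulk_cutoff`; slices with no nearby atoms report the cutoff and are
#' flagged.
#'
#' @param structure a `structure_model`
#' @param axis an `axis_frame` from [channel_axis()]
#' @param z_range length-2 vector along the axis (origin at the frame
#'   origin, or at the anchor if `anchor_selection` is given)
#' @param step slice spacing, Angstrom (default 0.5)
#' @param max_offaxis maximum probe-center displacement from the axis
#'   (default 6)
#' @param bulk_cutoff radius at which the pore is considered open bulk
#'   (default 12)
#' @param atom_subset `"heavy"` or `"backbone"`
#' @param anchor_selection selection whose mean axial position defines
#'   z = 0, e.g. the 9' gate residues (`"resno 554 and name CA"`); default
#'   `NULL` keeps the frame origin
#' @param radii_table named per-element vdW radii (Bondi by default)
#' @param n_starts probe-center starts per slice (default 8)
#' @param seed RNG seed for the multi-start jitter (default 1)
#' @return List of class `pore_profile`: `z`, `radius`, `center_path`
#'   (n x 3, original coordinates), `flagged` (no-atom slices),
#'   `atom_subset`.
#' @export
pore_profile <- function(structure, axis, z_range = NULL, step = 0.5,
                         max_offaxis = 6, bulk_cutoff = 12,
                         atom_subset = c("heavy", "backbone"),
                         anchor_selection = NULL, radii_table = .vdw_radius,
                         n_starts = 8, seed = 1) {
  atom_subset <- match.arg(atom_subset)
  stopifnot(step > 0)
  idx <- select_atoms(structure, if (atom_subset == "heavy") "heavy"
                      else "backbone or hetero")
  local <- to_axis_frame(structure$xyz[idx, , drop = FALSE], axis)
  vdw <- .vdw_of(structure$atoms$element[idx], radii_table)
  z_shift <- 0
  if (!is.null(anchor_selection)) {
    anchor_idx <- select_atoms(structure, anchor_selection)
    if (!length(anchor_idx)) stop("empty anchor selection")
    z_shift <- mean(to_axis_frame(structure$xyz[anchor_idx, , drop = FALSE], axis)[, 3])
  }
  if (is.null(z_range)) z_range <- range(local[, 3]) - z_shift
  zs <- seq(z_range[1], z_range[2], by = step)
  basis <- .axis_basis(axis)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  radius <- numeric(length(zs))
  centers <- matrix(0, length(zs), 3)
  flagged <- logical(length(zs))
  reach <- bulk_cutoff + max(vdw) + max_offaxis
  for (k in seq_along(zs)) {
    z0 <- zs[k] + z_shift
    near <- abs(local[, 3] - z0) <= reach
    if (!any(near)) {
      radius[k] <- bulk_cutoff; flagged[k] <- TRUE
      centers[k, ] <- axis$origin + z0 * axis$axis
      next
    }
    atoms_k <- local[near, , drop = FALSE]
    vdw_k <- vdw[near]
    clearance <- function(xy) {
      if (sqrt(sum(xy^2)) > max_offaxis) return(-1e6)
      .min_clearance(matrix(c(xy[1], xy[2], z0), 1, 3), atoms_k, vdw_k)[1]
    }
    starts <- rbind(c(0, 0),
                    matrix(runif(2 * (n_starts - 1), -max_offaxis / 2, max_offaxis / 2),
                           ncol = 2))
    best <- -Inf; best_xy <- c(0, 0)
    for (s in seq_len(nrow(starts))) {
      opt <- stats::optim(starts[s, ], function(xy) -clearance(xy),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-8, maxit = 300))
      if (-opt$value > best) { best <- -opt$value; best_xy <- opt$par }
    }
    radius[k] <- min(max(best, 0), bulk_cutoff)
    if (best >= bulk_cutoff) flagged[k] <- TRUE
    centers[k, ] <- axis$origin + drop(basis %*% c(best_xy[1], best_xy[2], z0))
  }
  structure(list(z = zs, radius = radius, center_path = centers,
                 flagged = flagged, atom_subset = atom_subset,
                 step = step, max_offaxis = max_offaxis,
                 bulk_cutoff = bulk_cutoff),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> z in [%.1f, %.1f] A, min radius %.2f A at z = %.1f\n",
              min(x$z), max(x$z), min(x$radius), x$z[which.min(x$radius)]))
  invisible(x)
}

#' Elementwise statistics over a set of pore profiles
#'
#' @param profiles list of `pore_profile`s on a common z grid
#' @return data.frame with `z`, `mean`, `sd`, `min`, `max` per slice.
#' @export
profile_statistics <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  z <- profiles[[1]]$z
  for (p in profiles)
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9)
      stop("profiles are not on a common z grid")
  R <- do.call(rbind, lapply(profiles, `[[`, "radius"))
  # population SD: the shaded band of an ensemble of profiles
  pop_sd <- apply(R, 2, function(x) sqrt(mean((x - mean(x))^2)))
  data.frame(z = z, mean = colMeans(R), sd = pop_sd,
             min = apply(R, 2, min), max = apply(R, 2, max))
}

#' Export a pore profile as TSV
#' @param profile a `pore_profile`
#' @param path output file
#' @export
write_pore_profile <- function(profile, path) {
  df <- data.frame(z = profile$z, radius = profile$radius,
                   x = profile$center_path[, 1], y = profile$center_path[, 2])
  write.table(format(df, digits = 6), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
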