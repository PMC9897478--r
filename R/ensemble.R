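#' Coordinate trajectory
#'
#' A topology [structure_model()] plus an ordered list of coordinate frames
#' (each `n_atoms x 3`, Angstrom) and per-frame times.
#'
#' @param topology a `structure_model`
#' @param frames list of `n x 3` matrices
#' @param times numeric vector of frame times (ns), nondecreasing; default
#'   `0, 1, 2, ...`
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = seq_along(frames) - 1) {
  stopifnot(inherits(topology, "structure_model"), length(frames) >= 1,
            length(times) == length(frames))
  for (f in seq_along(frames)) {
    frames[[f]] <- as.matrix(frames[[f]])
    if (nrow(frames[[f]]) != n_atoms(topology))
      stop("frame ", f, " has ", nrow(frames[[f]]), " atoms; topology has ",
           n_atoms(topology))
  }
  if (is.unsorted(times)) stop("frame times must be nondecreasing")
  structure(list(topology = topology, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n",
              length(x$frames), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames
#' @param traj a `trajectory`
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame as a structure
#' @param traj a `trajectory`
#' @param i frame index
#' @export
frame_structure <- function(traj, i) set_coords(traj$topology, traj$frames[[i]])

#' Load a trajectory from file
#'
#' Supported frame sources: a multi-model PDB (MODEL/ENDMDL records), or an
#' XYZ frame series (repeated `n / comment / n atom lines` blocks). Atom
#' metadata comes from `topology` when given, else from the PDB itself (XYZ
#' input requires a topology or synthesizes carbon pseudo-atoms).
#'
#' @param frames_path multi-model PDB or `.xyz` file
#' @param topology optional `structure_model` supplying atom records
#' @param stride keep every `stride`-th frame (default 1)
#' @param dt time per frame, ns (default 1)
#' @return A [trajectory()].
#' @export
load_trajectory <- function(frames_path, topology = NULL, stride = 1, dt = 1) {
  if (grepl("\\.xyz$", frames_path, ignore.case = TRUE)) {
    traj <- .read_xyz_trajectory(frames_path, topology)
  } else {
    traj <- read_structure(frames_path, multi = TRUE)
    if (!inherits(traj, "trajectory"))
      traj <- trajectory(traj, list(traj$xyz))
    if (!is.null(topology)) {
      if (n_atoms(topology) != n_atoms(traj$topology))
        stop("topology has ", n_atoms(topology), " atoms; frames have ",
             n_atoms(traj$topology))
      traj$topology <- topology
    }
  }
  keep <- seq(1, n_frames(traj), by = stride)
  trajectory(traj$topology, traj$frames[keep], times = (keep - 1) * dt)
}

.read_xyz_trajectory <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); pos <- 1L; fidx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    fidx <- fidx + 1L
    if (is.na(n)) stop("bad atom count at frame ", fidx, " (line ", pos, ")")
    block <- lines[(pos + 2):(pos + 1 + n)]
    xyz <- t(vapply(strsplit(trimws(block), "\\s+"), function(f)
      as.numeric(f[2:4]), numeric(3)))
    frames[[fidx]] <- xyz
    pos <- pos + 2L + n
  }
  n_at <- nrow(frames[[1]])
  if (is.null(topology)) {
    atoms <- data.frame(serial = seq_len(n_at), name = "C", element = "C",
                        resname = "UNK", resno = seq_len(n_at), chain = "A",
                        altloc = "", occupancy = 1, is_hetero = FALSE)
    topology <- structure_model(atoms, frames[[1]], source_path = path)
  }
  trajectory(topology, frames)
}

#' Write a trajectory as an XYZ frame series
#' @param traj a `trajectory`
#' @param path output file
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- traj$topology$atoms$element
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n_atoms(traj$topology)), sprintf("frame %d", f)), con)
    xyz <- traj$frames[[f]]
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Per-frame RMSD after superposition
#'
#' Each frame is superposed on the reference over `fit_selection` (the
#' paper-style "align on the ECD+TMD core"), then the RMSD is measured over
#' `measure_selection`.
#'
#' @param traj a `trajectory`
#' @param fit_selection selection string used for the superposition
#' @param measure_selection selection string the RMSD is computed over
#'   (default: same as `fit_selection`)
#' @param reference a `structure_model` (default: frame 1)
#' @return Numeric vector, Angstrom, one value per frame.
#' @export
rmsd_series <- function(traj, fit_selection = "calpha",
                        measure_selection = fit_selection, reference = NULL) {
  if (is.null(reference)) reference <- frame_structure(traj, 1)
  fit_idx <- select_atoms(traj$topology, fit_selection)
  meas_idx <- select_atoms(traj$topology, measure_selection)
  if (!length(fit_idx) || !length(meas_idx)) stop("empty selection")
  ref_xyz <- reference$xyz
  vapply(traj$frames, function(xyz) {
    sp <- superpose(xyz, ref_xyz, fit_idx, fit_idx)
    moved <- apply_transform(xyz[meas_idx, , drop = FALSE], sp)
    sqrt(mean(rowSums((moved - ref_xyz[meas_idx, , drop = FALSE])^2)))
  }, 0)
}

#' Root-mean-square fluctuation
#'
#' Per-frame alignment on `align_selection`, fluctuation of each selected
#' atom about its time mean, averaged (RMS) per residue.
#'
#' @param traj a `trajectory`
#' @param selection atoms to report on
#' @param align_selection alignment selection (default: the same)
#' @return data.frame with `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = "calpha", align_selection = selection) {
  sel <- select_atoms(traj$topology, selection)
  ali <- select_atoms(traj$topology, align_selection)
  if (!length(sel) || !length(ali)) stop("empty selection")
  if (n_frames(traj) < 2) {
    warning("single-frame trajectory: RMSF is zero")
    a <- traj$topology$atoms[sel, ]
    agg <- unique(a[, c("chain", "resno")])
    agg$rmsf <- 0
    return(agg)
  }
  ref <- traj$frames[[1]]
  aligned <- lapply(traj$frames, function(xyz)
    apply_transform(xyz, superpose(xyz, ref, ali, ali))[sel, , drop = FALSE])
  arr <- simplify2array(aligned)           # n_sel x 3 x n_frames
  mean_xyz <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(m) rowSums((m - mean_xyz)^2))
  atom_rmsf2 <- rowMeans(dev2)
  a <- traj$topology$atoms[sel, ]
  key <- paste(a$chain, a$resno)
  agg <- rowsum(atom_rmsf2, key)
  agg <- agg / as.vector(table(key)[rownames(agg)])
  out <- unique(data.frame(chain = a$chain, resno = a$resno, key = key))
  out$rmsf <- sqrt(agg[out$key, 1])
  out$key <- NULL
  rownames(out) <- NULL
  out
}

#' Track domain centers of mass in cylindrical coordinates
#'
#' Per frame and per labeled domain, the center of mass expressed as
#' distance from the pore axis (`r_xy`) and axial position (`z`). The axis
#' is recomputed per frame from `core_selection` by default (set
#' `fixed_axis` to reuse one frame's axis).
#'
#' @param traj a `trajectory`
#' @param domains named list of selection strings, one per domain copy
#'   (e.g. `list(NTD1_A = "segid NTD1 and chain A", ...)`)
#' @param core_selection selection defining the axis per frame
#' @param fixed_axis an `axis_frame` to use for all frames, or `NULL`
#' @param orient_selection passed to [channel_axis()]
#' @return data.frame with `frame`, `time`, `domain`, `r_xy`, `z`.
#' @export
domain_track <- function(traj, domains, core_selection = "not segid NTD1 NTD2",
                         fixed_axis = NULL, orient_selection = NULL) {
  stopifnot(length(domains) >= 1, !is.null(names(domains)))
  dom_idx <- lapply(domains, function(s) {
    idx <- select_atoms(traj$topology, s)
    if (!length(idx)) stop("empty domain selection '", s, "'")
    idx
  })
  masses <- .mass_of(traj$topology$atoms$element)
  out <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    st <- frame_structure(traj, f)
    ax <- if (is.null(fixed_axis))
      channel_axis(st, "inertia", selection = core_selection,
                   orient_selection = orient_selection) else fixed_axis
    rows <- lapply(names(dom_idx), function(nm) {
      idx <- dom_idx[[nm]]
      com <- drop(crossprod(st$xyz[idx, , drop = FALSE], masses[idx])) / sum(masses[idx])
      loc <- drop(to_axis_frame(matrix(com, 1, 3), ax))
      data.frame(frame = f, time = traj$times[f], domain = nm,
                 r_xy = sqrt(loc[1]^2 + loc[2]^2), z = loc[3])
    })
    out[[f]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Rank trajectory frames by goodness of fit to a SANS curve
#'
#' Predicts a Debye curve for every sampled frame and fits it (free scale
#' and background) to the data; frames are returned sorted by ascending
#' reduced chi-square. Ties within 0.01 keep input order.
#'
#' @param traj a `trajectory`
#' @param data experimental [scattering_curve()] with uncertainties
#' @param contrast a [contrast_model()] or `NULL` (explicit weights)
#' @param stride evaluate every `stride`-th frame
#' @param bin_width Debye histogram bin width, Angstrom
#' @return data.frame with `frame`, `chi2`, `scale`, `background`, sorted by
#'   `chi2`.
#' @export
rank_frames_by_sans <- function(traj, data, contrast = NULL, stride = 1,
                                bin_width = 0.5) {
  if (is.null(data$sigma)) stop("data curve must carry uncertainties")
  frames <- seq(1, n_frames(traj), by = stride)
  q_grid <- data$q
  rows <- lapply(frames, function(f) {
    mod <- debye_curve(frame_structure(traj, f), contrast, q_grid = q_grid,
                       bin_width = bin_width)
    ft <- fit_scale_background(mod, data)
    data.frame(frame = f, chi2 = ft$chi2_reduced, scale = ft$scale,
               background = ft$background)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(round(tab$chi2 / 0.01), seq_len(nrow(tab))), ]
  rownames(tab) <- NULL
  tab
}
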