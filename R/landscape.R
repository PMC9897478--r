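#' PCA conformational landscape
#'
#' Cartesian-coordinate principal component analysis over trajectory frames:
#' frames are superposed on a reference over a common selection, the
#' flattened `3n`-coordinate covariance is eigendecomposed, and per-frame
#' projections are stored. Projections of snapshots onto the first two
#' components give the conformational landscape used to separate e.g.
#' closed- and open-like clusters.
#'
#' @param trajs a `trajectory` or list of trajectories sharing the selection
#' @param selection selection string (evaluated on each topology; sizes must
#'   agree), default C-alpha
#' @param reference `structure_model` used for alignment; default frame 1 of
#'   the first trajectory
#' @param weights optional per-atom weights (e.g. masses); default unweighted
#' @return Object of class `landscape`: `mean` (flattened mean conformation),
#'   `basis` (3n x n_pc orthonormal), `eigenvalues` (variance, A^2),
#'   `projections` (frames x n_pc), `source` (trajectory id per frame),
#'   `selection`, `reference`, `ref_idx`.
#' @export
pca_landscape <- function(trajs, selection = "calpha", reference = NULL,
                          weights = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  if (is.null(reference)) reference <- frame_structure(trajs[[1]], 1)
  ref_idx <- select_atoms(reference, selection)
  n_sel <- length(ref_idx)
  if (!n_sel) stop("empty selection on the reference")
  rows <- list(); src <- integer()
  for (t in seq_along(trajs)) {
    idx <- select_atoms(trajs[[t]]$topology, selection)
    if (length(idx) != n_sel)
      stop("selection size differs between trajectory ", t, " and reference")
    for (f in seq_len(n_frames(trajs[[t]]))) {
      xyz <- trajs[[t]]$frames[[f]]
      sp <- superpose(xyz, reference$xyz, idx, ref_idx)
      rows[[length(rows) + 1]] <- as.vector(t(apply_transform(xyz[idx, , drop = FALSE], sp)))
      src <- c(src, t)
    }
  }
  X <- do.call(rbind, rows)
  if (nrow(X) < 2) stop("need at least 2 frames for a landscape")
  if (!is.null(weights)) {
    stopifnot(length(weights) == n_sel)
    X <- sweep(X, 2, rep(sqrt(weights), each = 3), `*`)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc / sqrt(nrow(X) - 1))
  keep <- seq_len(min(dim(Xc)))
  structure(list(mean = mu, basis = sv$v[, keep, drop = FALSE],
                 eigenvalues = sv$d[keep]^2,
                 projections = Xc %*% sv$v[, keep, drop = FALSE],
                 source = src, selection = selection,
                 reference = reference, ref_idx = ref_idx, weights = weights),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<landscape> %d frames, PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
              nrow(x$projections), 100 * ev[1] / sum(ev),
              100 * ev[2] / sum(ev)))
  invisible(x)
}

#' Project structures or frames onto a landscape
#'
#' Inputs are superposed on the landscape's reference over its selection,
#' centered on the stored mean, and projected onto the stored basis.
#'
#' @param landscape a [pca_landscape()] result
#' @param x a `structure_model`, a `trajectory`, or a list of either
#' @param annotation optional vector (e.g. per-frame chi-square) attached as
#'   a column
#' @return data.frame with `pc1`, `pc2`, ... and optionally `annotation`.
#' @export
project_onto_landscape <- function(landscape, x, annotation = NULL) {
  structures <- if (inherits(x, "structure_model")) list(x)
    else if (inherits(x, "trajectory"))
      lapply(seq_len(n_frames(x)), function(f) frame_structure(x, f))
    else x
  ref <- landscape$reference
  proj <- t(vapply(structures, function(st) {
    idx <- select_atoms(st, landscape$selection)
    if (length(idx) != length(landscape$ref_idx))
      stop("selection size mismatch with the landscape (",
           length(idx), " vs ", length(landscape$ref_idx), " atoms)")
    sp <- superpose(st$xyz, ref$xyz, idx, landscape$ref_idx)
    v <- as.vector(t(apply_transform(st$xyz[idx, , drop = FALSE], sp)))
    if (!is.null(landscape$weights))
      v <- v * rep(sqrt(landscape$weights), each = 3)
    drop(crossprod(landscape$basis, v - landscape$mean))
  }, numeric(ncol(landscape$basis))))
  out <- as.data.frame(proj)
  names(out) <- paste0("pc", seq_len(ncol(out)))
  if (!is.null(annotation)) {
    stopifnot(length(annotation) == nrow(out))
    out$annotation <- annotation
  }
  out
}
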