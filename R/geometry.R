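# standard atomic masses (u); D listed for completeness
.atomic_mass <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098,
                  CA = 40.078, MG = 24.305, ZN = 65.38, FE = 55.845, SE = 78.971)

.mass_of <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  m <- .atomic_mass[key]
  m[is.na(m)] <- 12.011  # unknown elements weighted as carbon
  unname(m)
}

.geom_weights <- function(structure, idx, weighting, contrast = NULL) {
  a <- structure$atoms[idx, , drop = FALSE]
  w <- switch(weighting,
    uniform = rep(1, length(idx)),
    mass = .mass_of(a$element),
    excess_b = {
      db <- atom_weights(structure, contrast)
      db[idx]
    })
  if (all(w == 0)) stop("all-zero weights in selection")
  w
}

#' Weighted center of mass
#'
#' @param structure a `structure_model`
#' @param idx atom indices (default: all atoms)
#' @param weighting `"mass"`, `"uniform"`, or `"excess_b"` (excess neutron
#'   scattering length under `contrast`)
#' @param contrast a [contrast_model()], needed for `weighting = "excess_b"`
#'   unless the structure carries explicit per-atom weights.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(structure, idx = seq_len(n_atoms(structure)),
                           weighting = c("mass", "uniform", "excess_b"),
                           contrast = NULL) {
  weighting <- match.arg(weighting)
  if (!length(idx)) stop("empty selection")
  w <- .geom_weights(structure, idx, weighting, contrast)
  drop(crossprod(structure$xyz[idx, , drop = FALSE], w)) / sum(w)
}

#' Weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum w_i |r_i - \bar r|^2 / \sum w_i}}, the quantity a
#' Guinier analysis of the corresponding scattering curve estimates when the
#' weights are excess scattering lengths.
#'
#' @inheritParams center_of_mass
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(structure, idx = seq_len(n_atoms(structure)),
                               weighting = c("mass", "uniform", "excess_b"),
                               contrast = NULL) {
  weighting <- match.arg(weighting)
  if (length(idx) < 2) {
    warning("radius of gyration of a single atom is 0")
    return(0)
  }
  w <- .geom_weights(structure, idx, weighting, contrast)
  xyz <- structure$xyz[idx, , drop = FALSE]
  ctr <- drop(crossprod(xyz, w)) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `R \%*\% mobile + t` and `reference` over paired selections.
#'
#' @param mobile,reference `structure_model`s or bare `n x 3` matrices
#' @param idx_mobile,idx_reference equal-length index vectors giving the 1:1
#'   atom correspondence (default: all atoms of each).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom over the fitted selection), of class
#'   `superposition_result`.
#' @export
superpose <- function(mobile, reference,
                      idx_mobile = NULL, idx_reference = idx_mobile) {
  X <- if (inherits(mobile, "structure_model")) mobile$xyz else as.matrix(mobile)
  Y <- if (inherits(reference, "structure_model")) reference$xyz else as.matrix(reference)
  if (is.null(idx_mobile)) { idx_mobile <- seq_len(nrow(X)); idx_reference <- seq_len(nrow(Y)) }
  if (length(idx_mobile) != length(idx_reference))
    stop("selection size mismatch: ", length(idx_mobile), " vs ", length(idx_reference))
  if (length(idx_mobile) < 3) stop("need at least 3 paired atoms")
  x <- X[idx_mobile, , drop = FALSE]
  y <- Y[idx_reference, , drop = FALSE]
  xc <- colMeans(x); yc <- colMeans(y)
  s <- svd(crossprod(sweep(x, 2, xc), sweep(y, 2, yc)))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- yc - drop(R %*% xc)
  fitted <- sweep(x %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition_result")
}

#' Apply a rigid transform to coordinates
#' @param xyz `n x 3` matrix or `structure_model`
#' @param fit a `superposition_result` (or list with `rotation`, `translation`)
#' @return Object of the same type, transformed.
#' @export
apply_transform <- function(xyz, fit) {
  if (inherits(xyz, "structure_model"))
    return(set_coords(xyz, apply_transform(xyz$xyz, fit)))
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Minimum cross-pair distance between two selections
#'
#' Used for e.g. carboxylate-to-ion coordination distances.
#'
#' @param structure a `structure_model`
#' @param idx_a,idx_b nonempty index vectors
#' @return Minimum Euclidean distance (Angstrom) over all pairs (a, b).
#' @export
pairwise_min_distance <- function(structure, idx_a, idx_b) {
  if (!length(idx_a) || !length(idx_b)) stop("empty selection")
  if (length(intersect(idx_a, idx_b)))
    warning("selections share atoms; minimum distance is 0")
  A <- structure$xyz[idx_a, , drop = FALSE]
  B <- structure$xyz[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}
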