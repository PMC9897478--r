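#' Pair distance distribution container
#'
#' @param r ascending distance grid, Angstrom
#' @param p contrast-weighted pair density on `r`
#' @param dmax support limit, Angstrom
#' @param normalization `"absolute"` (integral reproduces I(0) minus the
#'   atomic self-term) or `"area-one"`
#' @param self_b2 atomic self-term \eqn{\sum \Delta b_i^2} carried alongside
#'   absolute-mode distributions so the forward transform is exact
#' @return Object of class `pair_distribution`.
#' @export
pair_distribution <- function(r, p, dmax = max(r),
                              normalization = c("absolute", "area-one"),
                              self_b2 = 0, rbar = NULL, rvar = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(length(r) == length(p), !is.unsorted(r))
  structure(list(r = r, p = p, dmax = dmax, normalization = normalization,
                 self_b2 = self_b2, rbar = rbar, rvar = rvar),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> %d bins, dmax = %.1f A (%s)\n",
              length(x$r), x$dmax, x$normalization))
  invisible(x)
}

#' Renormalize a pair distribution to unit area
#' @param pd a `pair_distribution`
#' @export
normalize_area_one <- function(pd) {
  area <- sum(pd$p) * mean(diff(pd$r))
  if (area == 0) stop("cannot normalize an all-zero distribution")
  pair_distribution(pd$r, pd$p / area, pd$dmax, "area-one")
}

#' Pair distance distribution of an atomic model
#'
#' Histogram of all interatomic distances weighted by
#' \eqn{\Delta b_i \Delta b_j} (cross pairs, both orderings); the same
#' machinery that accelerates the Debye sum.
#'
#' @param structure a `structure_model`
#' @param contrast a [contrast_model()] or `NULL` (explicit weights)
#' @param dr bin width, Angstrom
#' @return An absolute-mode [pair_distribution()]: `p[k] * dr` is the summed
#'   pair weight in bin `k`, so `sum(p) * dr + self_b2 = I(0)`.
#' @export
model_pddf <- function(structure, contrast = NULL, dr = 1) {
  stopifnot(dr > 0)
  w <- atom_weights(structure, contrast)
  h <- .pair_hist_weighted(structure$xyz, w, dr)
  r <- (seq_along(h$hist) - 0.5) * dr
  # bin centers define the display grid; the per-bin weighted mean distance
  # and variance are kept so the forward transform shares the Debye kernel
  pair_distribution(r, h$hist / dr, dmax = h$dmax,
                    normalization = "absolute", self_b2 = sum(w^2),
                    rbar = h$rbar, rvar = h$rvar)
}

#' Forward transform of a pair distribution
#'
#' \eqn{I(Q) = \sum_k p(r_k) \, \mathrm{sinc}(Q r_k) \, \Delta r + \sum_i \Delta b_i^2}
#' (self-term included for absolute-mode distributions).
#'
#' @param pd a `pair_distribution`
#' @param q_grid Q values, A^-1
#' @return A [scattering_curve()].
#' @export
pddf_to_curve <- function(pd, q_grid = default_q_grid()) {
  dr <- mean(diff(pd$r))
  r_eval <- if (!is.null(pd$rbar)) pd$rbar else pd$r
  x <- outer(q_grid, r_eval)
  ivals <- drop(.sinc(x) %*% pd$p) * dr + pd$self_b2
  if (!is.null(pd$rvar))
    ivals <- ivals + 0.5 * drop(.sinc_dd(x) %*% (pd$p * pd$rvar)) * dr * q_grid^2
  scattering_curve(q_grid, ivals, sigma = pmax(abs(ivals), 1e-12) * 1e-3,
                   metadata = list(kind = "pddf_forward"))
}

#' Radius of gyration from pair-distribution moments
#'
#' \eqn{R_g^2 = \int p(r) r^2 dr \, / \, 2\int p(r) dr}.
#' @param pd a `pair_distribution`
#' @export
pddf_rg <- function(pd) {
  sqrt(sum(pd$p * pd$r^2) / (2 * sum(pd$p)))
}

#' Indirect Fourier transform of a scattering curve
#'
#' Recovers a nonnegative `p(r)` on `[0, dmax]` from `I(Q)` by regularized
#' least squares: minimize
#' \eqn{\chi^2 + \alpha \sum_k (\Delta^2 p)_k^2} subject to `p >= 0` with
#' both endpoint bins pinned to zero. The smoothness weight is chosen
#' automatically at the corner of the log-log trade-off curve between
#' chi-square and roughness unless given. Nonnegativity is enforced by an
#' active-set (Lawson-Hanson) solve of the regularized normal equations.
#'
#' @param curve a [scattering_curve()] with uncertainties
#' @param dmax assumed maximum particle dimension, Angstrom
#' @param n_bins number of r bins (default 100)
#' @param alpha smoothness weight, or `"auto"`
#' @param fit_background also fit a flat background term (default FALSE)
#' @return List with `pd` (a [pair_distribution()]), `fit` (a `fit_result`
#'   comparing the regularized forward curve to the data), and `alpha`.
#' @export
ift <- function(curve, dmax, n_bins = 100, alpha = "auto",
                fit_background = FALSE) {
  stopifnot(dmax > 0)
  if (is.null(curve$sigma)) stop("IFT requires uncertainties on the curve")
  if (dmax < pi / max(curve$q))
    warning("dmax below the information limit of the measured Q range")
  if (2 * pi / min(curve$q) < dmax)
    warning("q_min too high to constrain distances out to dmax")
  r <- seq(0, dmax, length.out = n_bins + 2)[-c(1, n_bins + 2)]  # interior bins
  dr <- r[2] - r[1]
  A <- .sinc(outer(curve$q, r)) * dr
  y <- curve$intensity
  w <- 1 / curve$sigma^2
  # second-difference penalty matrix on the full (0, p, 0)-padded grid
  D <- diff(diag(n_bins + 2), differences = 2)[, -c(1, n_bins + 2), drop = FALSE]
  Aw <- A * sqrt(w)
  yw <- y * sqrt(w)
  AtA <- crossprod(Aw); Aty <- drop(crossprod(Aw, yw))
  DtD <- crossprod(D)
  ridge <- mean(diag(AtA)) * 1e-12  # numerical floor keeping M positive definite
  solve_for <- function(alpha) {
    M <- AtA + alpha * DtD + diag(ridge, n_bins)
    tryCatch(.nnls_quad(M, Aty),
             error = function(e) stop("singular IFT system: ", conditionMessage(e)))
  }
  chi2_of <- function(p) sum((drop(A %*% p) - y)^2 * w) / max(1, length(y) - 2)
  if (identical(alpha, "auto")) {
    # scale-aware grid; the corner of the chi2-vs-smoothness trade-off is
    # located as the largest alpha whose chi2 stays within 10% + 0.05 of the
    # grid minimum (the point where the flat branch starts to bend upward)
    alpha_grid <- mean(diag(AtA)) / mean(diag(DtD)) * 10^seq(-6, 4, length.out = 25)
    sols <- lapply(alpha_grid, solve_for)
    chi2s <- vapply(sols, chi2_of, 0)
    ok <- chi2s <= min(chi2s) * 1.1 + 0.05
    best <- max(which(ok))
    alpha <- alpha_grid[best]
    p <- sols[[best]]
  } else {
    p <- solve_for(alpha)
  }
  model_curve <- scattering_curve(curve$q, drop(A %*% p))
  fit <- fit_scale_background(model_curve, curve, background = fit_background)
  pd <- pair_distribution(r, p, dmax = dmax, normalization = "absolute")
  list(pd = pd, fit = fit, alpha = alpha)
}

# Lawson-Hanson active-set solve of min 0.5 p'Mp - b'p  s.t. p >= 0
# (M symmetric positive definite). Exact constrained optimum; robust on the
# near-singular low-alpha systems where first-order methods crawl.
.nnls_quad <- function(M, b, max_iter = 10 * length(b)) {
  n <- length(b)
  P <- logical(n)
  p <- numeric(n)
  g <- b                       # -gradient at p = 0
  tol <- 1e-10 * max(abs(b), 1)
  for (iter in seq_len(max_iter)) {
    cand <- which(!P & g > tol)
    if (!length(cand)) break
    P[cand[which.max(g[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- drop(solve(M[P, P, drop = FALSE], b[P]))
      if (all(s[P] > 0)) break
      neg <- P & s <= 0
      ratio <- p[neg] / (p[neg] - s[neg])
      a <- min(ratio)
      p <- p + a * (s - p)
      P[P & p <= tol] <- FALSE
      p[!P] <- 0
    }
    p <- s
    g <- b - drop(M %*% p)
  }
  p
}

#' Compare two pair distributions
#'
#' Both are interpolated onto a common grid and normalized to unit area;
#' reports the L1 distance and each distribution's long-distance tail
#' fraction (area beyond `tail_threshold`).
#'
#' @param a,b `pair_distribution` objects
#' @param tail_threshold distance beyond which area counts as tail
#'   (default 100 Angstrom)
#' @return List: `l1`, `tail_fraction_a`, `tail_fraction_b`,
#'   `tail_threshold`.
#' @export
compare_pddf <- function(a, b, tail_threshold = 100) {
  rmax <- max(a$dmax, b$dmax)
  grid <- seq(0, rmax, length.out = 512)
  fa <- stats::approx(a$r, a$p, xout = grid, yleft = 0, yright = 0, rule = 2)$y
  fb <- stats::approx(b$r, b$p, xout = grid, yleft = 0, yright = 0, rule = 2)$y
  fa[grid > a$dmax] <- 0; fb[grid > b$dmax] <- 0
  dg <- grid[2] - grid[1]
  fa <- fa / (sum(fa) * dg); fb <- fb / (sum(fb) * dg)
  list(l1 = sum(abs(fa - fb)) * dg,
       tail_fraction_a = sum(fa[grid > tail_threshold]) * dg,
       tail_fraction_b = sum(fb[grid > tail_threshold]) * dg,
       tail_threshold = tail_threshold)
}

#' Export a pair distribution as GNOM-style text
#' @param pd a `pair_distribution`
#' @param path output file
#' @param error optional per-bin error column
#' @export
write_pddf <- function(pd, path, error = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# r[A]  p(r)  error", sprintf("# dmax = %.2f", pd$dmax)), con)
  e <- if (is.null(error)) rep(0, length(pd$r)) else error
  writeLines(sprintf("%12.4f %14.6e %14.6e", pd$r, pd$p, e), con)
  invisible(path)
}
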