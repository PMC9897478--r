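#' Guinier analysis
#'
#' Weighted linear fit of \eqn{\ln I} against \eqn{Q^2} over the largest
#' low-Q window satisfying \eqn{Q_{max} R_g \le} `qrg_limit`, iterated to
#' self-consistency (the window depends on the fitted `Rg`). Returns
#' \eqn{R_g = \sqrt{-3 \cdot slope}} and \eqn{I(0) = e^{intercept}} with
#' propagated standard errors.
#'
#' @param curve a [scattering_curve()]; uncertainties are used as weights
#'   when present.
#' @param qrg_limit upper limit on `q_max * Rg` (default 1.3, the usual
#'   globular-particle bound)
#' @param q_min lower Q cutoff (default: first point of the curve)
#' @param min_points minimum number of points in the fit window
#' @return A list of class `guinier_result`: `rg`, `rg_se`, `i0`, `i0_se`,
#'   `fit_range`, `n_points`, `qrg_max_used`.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.3, q_min = NULL, min_points = 5) {
  q <- curve$q; I <- curve$intensity
  keep <- I > 0 & (if (is.null(q_min)) TRUE else q >= q_min)
  q <- q[keep]; I <- I[keep]
  s <- if (is.null(curve$sigma)) NULL else curve$sigma[keep]
  if (length(q) < min_points) stop("too few positive low-Q points for Guinier analysis")
  q_hi <- max(q)
  rg_prev <- Inf
  for (iter in 1:50) {
    win <- q <= q_hi
    if (sum(win) < min_points) {
      win <- seq_along(q) <= min_points
      q_hi <- q[min_points]
    }
    x <- q[win]^2; y <- log(I[win])
    wts <- if (is.null(s)) rep(1, sum(win)) else (I[win] / s[win])^2  # var of log I
    fit <- stats::lm(y ~ x, weights = wts)
    slope <- coef(fit)[["x"]]
    if (slope >= 0) stop("no Guinier regime: nonnegative slope of ln I vs Q^2")
    rg <- sqrt(-3 * slope)
    if (is.finite(rg_prev) && abs(rg - rg_prev) <= 1e-3 * rg) break
    if (iter == 50) stop("Guinier window iteration did not converge in 50 rounds")
    rg_prev <- rg
    q_hi <- qrg_limit / rg
    if (q_hi < q[min_points]) q_hi <- q[min_points]
  }
  se <- sqrt(diag(stats::vcov(fit)))
  i0 <- exp(coef(fit)[["(Intercept)"]])
  structure(list(rg = rg,
                 rg_se = if (is.finite(se[["x"]])) 3 * se[["x"]] / (2 * rg) else NA_real_,
                 i0 = i0, i0_se = i0 * se[["(Intercept)"]],
                 fit_range = c(min(q[win]), max(q[win])),
                 n_points = sum(win), qrg_max_used = max(q[win]) * rg),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.2f +/- %.2f A, I(0) = %.4g +/- %.2g (%d pts, qRg <= %.2f)\n",
              x$rg, x$rg_se, x$i0, x$i0_se, x$n_points, x$qrg_max_used))
  invisible(x)
}
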