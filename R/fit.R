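#' Fit a model curve to experimental data (scale + constant background)
#'
#' Analytic weighted least squares for the two linear parameters of
#' \eqn{I_{exp}(Q) \approx c \, I_{mod}(Q) + k}, minimizing
#' \eqn{\sum_k [(c I_{mod} + k - I_{exp})/\sigma]^2}. The model is linearly
#' interpolated onto the data's Q grid; points outside the model range are
#' dropped. The reported goodness of fit is the reduced chi-square with
#' `N - 2` degrees of freedom.
#'
#' @param model predicted [scattering_curve()] (its `sigma` is ignored)
#' @param data experimental [scattering_curve()] with uncertainties
#' @param background if `FALSE`, fit the scale only (`k = 0`)
#' @return List of class `fit_result`: `scale`, `background`, `chi2_reduced`,
#'   `residuals` (error-weighted, on the fitted grid), `q` (fitted grid),
#'   `n_points`.
#' @export
fit_scale_background <- function(model, data, background = TRUE) {
  if (is.null(data$sigma)) stop("data curve must carry uncertainties")
  inside <- data$q >= min(model$q) & data$q <= max(model$q)
  if (sum(inside) < 3) stop("fewer than 3 overlapping points between model and data")
  q <- data$q[inside]
  y <- data$intensity[inside]
  s <- data$sigma[inside]
  m <- stats::approx(model$q, model$intensity, xout = q)$y
  w <- 1 / s^2
  if (background) {
    # normal equations for (scale, background)
    A <- rbind(c(sum(w * m^2), sum(w * m)),
               c(sum(w * m),   sum(w)))
    b <- c(sum(w * m * y), sum(w * y))
    sol <- solve(A, b)
    scale <- sol[1]; bkg <- sol[2]
    dof <- length(q) - 2
  } else {
    scale <- sum(w * m * y) / sum(w * m^2)
    bkg <- 0
    dof <- length(q) - 1
  }
  resid <- (scale * m + bkg - y) / s
  structure(list(scale = scale, background = bkg,
                 chi2_reduced = sum(resid^2) / dof,
                 residuals = resid, q = q, n_points = length(q)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: scale = %.4g, background = %.4g, reduced chi2 = %.3f (%d pts)\n",
              x$scale, x$background, x$chi2_reduced, x$n_points))
  invisible(x)
}
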