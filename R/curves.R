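#' 1D scattering curve
#'
#' Reduced small-angle scattering data: momentum transfer
#' \eqn{Q = (4\pi/\lambda)\sin\theta} (A^-1, strictly increasing),
#' intensities, and 1-sigma uncertainties. Real-space distances relate to Q
#' by \eqn{d = 2\pi/Q}.
#'
#' @param q ascending numeric vector, A^-1
#' @param intensity intensities (arbitrary or absolute cm^-1 units)
#' @param sigma 1-sigma uncertainties (positive), or `NULL`
#' @param metadata free-form list (condition label, concentration mg/mL, ...)
#' @return Object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, metadata = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  stopifnot(length(q) == length(intensity))
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    stopifnot(length(sigma) == length(q))
    if (any(sigma <= 0)) stop("sigma must be positive where present")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 metadata = metadata), class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, Q in [%.4g, %.4g] A^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no uncertainties" else ""))
  invisible(x)
}

#' Read a 3-column ASCII scattering curve
#'
#' Accepts the common reduced-data layout: `Q I sigma` columns, `#` comment
#' lines, optional header junk lines (skipped with a message-free heuristic:
#' only rows whose first field parses as a number are used).
#'
#' @param path input file
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  keep <- vapply(fields, function(f)
    length(f) >= 2 && !is.na(suppressWarnings(as.numeric(f[1]))) &&
      !is.na(suppressWarnings(as.numeric(f[2]))), TRUE)
  fields <- fields[keep]
  if (!length(fields)) stop("no data rows in ", path)
  q <- vapply(fields, function(f) as.numeric(f[1]), 0)
  i <- vapply(fields, function(f) as.numeric(f[2]), 0)
  s <- vapply(fields, function(f)
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA_real_, 0)
  ord <- order(q)
  q <- q[ord]; i <- i[ord]; s <- s[ord]
  dup <- duplicated(q)
  scattering_curve(q[!dup], i[!dup],
                   sigma = if (all(is.na(s)) || any(s[!dup] <= 0, na.rm = TRUE)) NULL else s[!dup],
                   metadata = list(source = path))
}

#' Write a scattering curve as 3-column ASCII
#' @param curve a `scattering_curve`
#' @param path output file
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Q[1/A]  I(Q)  sigma", con)
  s <- if (is.null(curve$sigma)) rep(0, length(curve$q)) else curve$sigma
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$intensity, s), con)
  invisible(path)
}

#' Merge low-Q and high-Q curves at a switch point
#'
#' Takes the first (long-detector-distance) curve for `Q <= lowq_limit` and
#' the second curve above it, e.g. merging 8 m data up to 0.09 A^-1 with
#' 2.8 m data beyond.
#'
#' @param lowq_curve curve providing `Q <= lowq_limit`
#' @param lowq_limit switch point, A^-1
#' @param highq_curve curve providing `Q > lowq_limit`
#' @return Merged [scattering_curve()] with strictly increasing Q.
#' @export
merge_curves <- function(lowq_curve, lowq_limit, highq_curve) {
  keep_lo <- lowq_curve$q <= lowq_limit
  keep_hi <- highq_curve$q > lowq_limit
  q <- c(lowq_curve$q[keep_lo], highq_curve$q[keep_hi])
  i <- c(lowq_curve$intensity[keep_lo], highq_curve$intensity[keep_hi])
  s <- if (!is.null(lowq_curve$sigma) && !is.null(highq_curve$sigma))
    c(lowq_curve$sigma[keep_lo], highq_curve$sigma[keep_hi]) else NULL
  if (!length(q)) stop("merge produced an empty curve")
  if (is.unsorted(q, strictly = TRUE)) stop("merged q grid is not strictly increasing")
  scattering_curve(q, i, s, metadata = c(lowq_curve$metadata,
                                         list(merged_at = lowq_limit)))
}

#' Subtract a constant background
#'
#' Final background adjustment of a reduced curve: subtract a known
#' constant, or estimate it as the mean intensity of the top-Q decile
#' (`constant = "auto"`).
#'
#' @param curve a `scattering_curve`
#' @param constant numeric constant, or `"auto"`
#' @return Adjusted curve; `sigma` is unchanged. The constant used is stored
#'   in `metadata$background_subtracted`.
#' @export
subtract_constant <- function(curve, constant = "auto") {
  if (identical(constant, "auto")) {
    tail_idx <- curve$q >= stats::quantile(curve$q, 0.9)
    constant <- mean(curve$intensity[tail_idx])
  }
  stopifnot(is.finite(constant))
  scattering_curve(curve$q, curve$intensity - constant, curve$sigma,
                   metadata = c(curve$metadata,
                                list(background_subtracted = constant)))
}
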