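#' Smoothing parameters for B-spline fitting
#'
#' @param tau knot-placement tolerance in absorbance units (AU). Two
#'   consecutive data points are treated as redundant when their absorbance
#'   values differ by at most `tau`; each maximal run of redundant points
#'   contributes a single candidate knot at its midpoint. `tau = 0` (the
#'   default) keeps one candidate knot per interior data point, so on a
#'   common wavenumber axis every spectrum receives the same knot vector and
#'   the whole smooth-differentiate-unmix pipeline is exactly linear in the
#'   data.
#' @param dof target effective degrees of freedom (the number of spline
#'   coefficients). Interior knots are thinned uniformly until the
#'   coefficient count is at most `min(dof, n_points)`. Use `Inf` (default)
#'   for no cap beyond what the data can support, or `"auto"` to pick the
#'   smallest dof whose residual RMS does not exceed the noise level.
#' @param noise_sd per-point noise standard deviation (AU) used by
#'   `dof = "auto"`; `NULL` (default) estimates it with [estimate_noise()].
#' @param edge_exclude_spans number of knot spans adjacent to each boundary
#'   whose second-derivative values are flagged as edge-affected and
#'   excluded from unmixing (default 3).
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(tau = 0, dof = Inf, noise_sd = NULL,
                             edge_exclude_spans = 3L) {
  tau <- as.numeric(tau)[1L]
  if (!is.finite(tau) || tau < 0) stop("tau must be finite and >= 0")
  if (identical(dof, "auto")) {
    dof <- "auto"
  } else {
    dof <- as.numeric(dof)[1L]
    if (is.na(dof) || dof < 4) stop("dof must be >= 4 (or \"auto\")")
  }
  if (!is.null(noise_sd)) {
    noise_sd <- as.numeric(noise_sd)[1L]
    if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  }
  edge_exclude_spans <- as.integer(edge_exclude_spans)[1L]
  if (is.na(edge_exclude_spans) || edge_exclude_spans < 0)
    stop("edge_exclude_spans must be a non-negative integer")
  structure(list(tau = tau, dof = dof, noise_sd = noise_sd,
                 edge_exclude_spans = edge_exclude_spans),
            class = "smoothing_params")
}

#' Tolerance-driven knot placement
#'
#' Scans the spectrum for maximal runs of consecutive points whose
#' successive absorbance differences are all within `params$tau`; each run
#' collapses to one candidate knot at its midpoint (lower-index midpoint for
#' even-length runs). The runs containing the first and last data point are
#' carried by the clamped boundary knots, which are repeated
#' `degree + 1 = 4` times; a constant spectrum therefore collapses to a
#' boundary-only knot vector.
#'
#' @param s a `nir_spectrum`.
#' @param params a [smoothing_params()] object.
#' @return The full clamped knot vector (boundary knots repeated 4 times,
#'   interior candidate knots a subset of `s$axis`).
#' @export
place_knots <- function(s, params = smoothing_params()) {
  stopifnot(inherits(s, "nir_spectrum"), inherits(params, "smoothing_params"))
  x <- s$axis; y <- s$absorbance; n <- length(x)
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct wavenumbers to fit a cubic spline")
  # run boundaries: a new run starts wherever |dy| > tau
  brk <- c(TRUE, abs(diff(y)) > params$tau)
  run_id <- cumsum(brk)
  mids <- vapply(split(seq_len(n), run_id), function(ix)
    ix[(length(ix) + 1L) %/% 2L], integer(1L))
  # the runs containing the first and last data point are carried by the
  # clamped boundary knots; every other run contributes its midpoint
  nr <- length(mids)
  mids[1L] <- 1L
  mids[nr] <- n
  interior <- x[mids]
  interior <- interior[interior > x[1L] & interior < x[n]]
  c(rep(x[1L], 4L), interior, rep(x[n], 4L))
}

#' Robust per-point noise estimate
#'
#' Estimates the standard deviation of additive, independent instrument
#' noise from the second differences of the absorbance trace, which
#' annihilate constant and linear trends and strongly attenuate any smooth
#' signal. For iid Gaussian noise the second difference has variance
#' `6 sigma^2`, so `sigma = mad(diff(y, 2)) / sqrt(6)` with the usual
#' Gaussian-consistent MAD scaling.
#'
#' @param s a `nir_spectrum` with at least 5 points.
#' @return Estimated noise standard deviation (AU), `>= 0`.
#' @export
estimate_noise <- function(s) {
  stopifnot(inherits(s, "nir_spectrum"))
  if (length(s$axis) < 5L) stop("need at least 5 points to estimate noise")
  d2 <- diff(s$absorbance, differences = 2L)
  stats::mad(d2, center = 0) / sqrt(6)
}

# interior-knot thinning: keep `target` of `k` interior knots, evenly spaced
# by index (deterministic, depends only on k and target)
thin_interior <- function(interior, target) {
  k <- length(interior)
  if (target <= 0L) return(numeric(0L))
  if (k <= target) return(interior)
  interior[unique(round(seq(1L, k, length.out = target)))]
}

#' Fit a least-squares cubic B-spline
#'
#' Solves for the control points minimising the sum of squared residuals to
#' the data over the clamped cubic B-spline basis on the given knot vector.
#' Interior knots are thinned uniformly until the coefficient count (the
#' effective degrees of freedom) is at most `min(params$dof, n_points)`;
#' with `dof = "auto"` the smallest coefficient count whose residual RMS is
#' at or below the noise level is retained.
#'
#' @param s a `nir_spectrum`.
#' @param knots full clamped knot vector, e.g. from [place_knots()];
#'   `NULL` calls `place_knots(s, params)`.
#' @param params a [smoothing_params()] object.
#' @return An object of class `spline_model`: list with `degree` (3),
#'   `knots`, `coefficients`, `domain`, and the fit diagnostics
#'   `residual_rms` and `dof`.
#' @seealso [second_derivative()], [predict.spline_model()]
#' @export
fit_spline <- function(s, knots = NULL, params = smoothing_params()) {
  stopifnot(inherits(s, "nir_spectrum"), inherits(params, "smoothing_params"))
  if (is.null(knots)) knots <- place_knots(s, params)
  x <- s$axis; y <- s$absorbance; n <- length(x)
  lo <- knots[1L]; hi <- knots[length(knots)]
  interior <- knots[knots > lo & knots < hi]
  # a cubic spline supports at most n data points; shed excess candidate
  # knots from the ends (the not-a-knot construction), which keeps the
  # interpolation design nonsingular by the Schoenberg-Whitney condition
  excess <- length(interior) - (n - 4L)
  if (excess > 0L)
    interior <- interior[(1L + ceiling(excess / 2)):(length(interior) - floor(excess / 2))]

  fit_with <- function(interior) {
    kn <- c(rep(lo, 4L), interior, rep(hi, 4L))
    X <- splines::splineDesign(kn, x, ord = 4L)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient spline design (", ncol(X), " coefficients for ",
           n, " points); increase tau or lower dof")
    cf <- qr.coef(qrX, y)
    res <- y - drop(X %*% cf)
    structure(list(degree = 3L, knots = kn, coefficients = unname(cf),
                   domain = c(lo, hi),
                   residual_rms = sqrt(mean(res^2)), dof = ncol(X)),
              class = "spline_model")
  }

  if (identical(params$dof, "auto")) {
    noise <- if (is.null(params$noise_sd)) estimate_noise(s) else params$noise_sd
    # ladder of candidate dofs, coarse to fine; keep the smallest adequate
    cand <- unique(pmin(n, ceiling(4 * 1.5^(0:24))))
    for (d in cand) {
      m <- fit_with(thin_interior(interior, d - 4L))
      if (m$residual_rms <= noise) return(m)
    }
    return(m)
  }

  target <- max(4L, min(floor(params$dof), n))
  fit_with(thin_interior(interior, target - 4L))
}

#' Evaluate a spline model
#'
#' @param object a `spline_model`.
#' @param x wavenumbers at which to evaluate; must lie inside the model
#'   domain.
#' @param ... unused.
#' @return Numeric vector of spline values.
#' @export
predict.spline_model <- function(object, x, ...) {
  x <- as.numeric(x)
  if (any(x < object$domain[1L] | x > object$domain[2L]))
    stop("evaluation outside spline domain [", object$domain[1L], ", ",
         object$domain[2L], "]")
  B <- splines::splineDesign(object$knots, x, ord = object$degree + 1L)
  drop(B %*% object$coefficients)
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf("<spline_model> degree %d, %d coefficients on [%.0f, %.0f], residual RMS %.3g\n",
              x$degree, length(x$coefficients), x$domain[1L], x$domain[2L],
              x$residual_rms))
  invisible(x)
}

# one analytic differentiation step via the B-spline derivative recurrence:
# coefficients become degree * (c[i+1] - c[i]) / (t[i+p+1] - t[i+1]),
# the first and last knot are dropped, degree decreases by one
deriv_spline_once <- function(m) {
  p <- m$degree
  t <- m$knots
  cf <- m$coefficients
  nc <- length(cf)
  span <- t[(1L + p + 1L):(nc - 1L + p + 1L)] - t[2L:nc]
  newc <- ifelse(span > 0, p * diff(cf) / span, 0)
  structure(list(degree = p - 1L, knots = t[2L:(length(t) - 1L)],
                 coefficients = newc, domain = m$domain,
                 residual_rms = NA_real_, dof = length(newc)),
            class = "spline_model")
}

#' Analytic second derivative of a fitted cubic spline
#'
#' Applies the standard B-spline derivative recurrence twice: each step
#' replaces the coefficients by scaled first differences over the knot
#' spans and drops one knot from each end, lowering the degree from 3 to 1.
#' The result is the exact second derivative of the fitted spline with
#' respect to wavenumber, evaluable anywhere on the original domain --
#' no finite differencing is involved.
#'
#' @param m a degree-3 `spline_model` from [fit_spline()].
#' @return A degree-1 `spline_model` representing `d2A/dnu2`.
#' @export
second_derivative <- function(m) {
  stopifnot(inherits(m, "spline_model"))
  if (m$degree != 3L)
    stop("second_derivative expects a cubic (degree 3) spline model")
  deriv_spline_once(deriv_spline_once(m))
}

#' Flag grid points unaffected by spline boundary artefacts
#'
#' Clamped boundary knots make the second derivative unreliable near the
#' ends of the fitted range. Points within `spans` knot spans (breakpoints
#' of the derivative spline) of either boundary are flagged for exclusion
#' from the unmixing solve.
#'
#' @param m a `spline_model` (typically the second-derivative model).
#' @param x wavenumbers to classify.
#' @param spans number of boundary knot spans to exclude on each side.
#' @return Logical vector, `TRUE` where `x` is safely interior.
#' @export
interior_mask <- function(m, x, spans = 3L) {
  stopifnot(inherits(m, "spline_model"))
  u <- unique(m$knots[m$knots >= m$domain[1L] & m$knots <= m$domain[2L]])
  spans <- as.integer(spans)
  if (spans <= 0L) return(rep(TRUE, length(x)))
  if (length(u) < 2L * spans + 2L)
    stop("too few knot spans (", length(u) - 1L, ") to exclude ", spans,
         " on each side")
  x >= u[1L + spans] & x <= u[length(u) - spans]
}
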