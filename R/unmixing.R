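#' @keywords internal
# restrict a spectrum to the grid span, retaining one covering point on each
# side when the axis does not land exactly on the grid endpoints, so that the
# fitted spline domain contains the whole grid
restrict_covering <- function(s, grid) {
  ax <- s$axis
  if (min(ax) > grid$lo || max(ax) < grid$hi)
    stop("spectrum '", s$sample_id, "' (", min(ax), "-", max(ax),
         " cm-1) does not span grid [", grid$lo, ", ", grid$hi, "]")
  lo_i <- max(which(ax <= grid$lo))
  hi_i <- min(which(ax >= grid$hi))
  if (hi_i - lo_i + 1L < 4L) stop("too few points across the grid span")
  nir_spectrum(ax[lo_i:hi_i], s$absorbance[lo_i:hi_i],
               sample_id = s$sample_id, group = s$group)
}

# ordinary least squares through QR, with diagnostics
solve_cls <- function(E, b, names = colnames(E)) {
  qrE <- qr(E)
  if (qrE$rank < ncol(E)) {
    cc <- suppressWarnings(stats::cor(E))
    cc[!upper.tri(cc)] <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
    stop("rank-deficient component matrix: columns '", names[worst[1L]],
         "' and '", names[worst[2L]], "' are collinear")
  }
  cf <- qr.coef(qrE, b)
  r <- b - drop(E %*% cf)
  sv <- svd(E, nu = 0L, nv = 0L)$d
  list(coef = unname(cf), residual_norm = sqrt(sum(r * r)),
       condition_number = sv[1L] / sv[length(sv)])
}

# exact non-negative least squares for the 3-column system by exhaustive
# active-set enumeration: solve the unconstrained LS on every subset of
# components, keep the feasible solution with the smallest residual
nnls3 <- function(E, b) {
  best <- list(coef = rep(0, 3L), rss = sum(b * b))
  for (sz in 1:3) for (S in utils::combn(3L, sz, simplify = FALSE)) {
    cf <- tryCatch(qr.coef(qr(E[, S, drop = FALSE]), b),
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf) || any(cf < 0)) next
    full <- rep(0, 3L)
    full[S] <- cf
    rss <- sum((b - drop(E %*% full))^2)
    if (rss < best$rss) best <- list(coef = full, rss = rss)
  }
  best
}

new_feature_vector <- function(coef, residual_norm, condition_number,
                               sample_id = NA_character_, group = NA_character_) {
  structure(list(c_w = coef[1L], c_c = coef[2L], c_p = coef[3L],
                 residual_norm = residual_norm,
                 condition_number = condition_number,
                 sample_id = sample_id, group = group),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector>%s c_w = %.4f, c_c = %.4f, c_p = %.4f (residual %.3g, cond %.3g)\n",
              if (is.na(x$sample_id)) "" else paste0(" '", x$sample_id, "':"),
              x$c_w, x$c_c, x$c_p, x$residual_norm, x$condition_number))
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  data.frame(sample_id = x$sample_id, group = x$group,
             c_w = x$c_w, c_c = x$c_c, c_p = x$c_p,
             residual_norm = x$residual_norm,
             condition_number = x$condition_number,
             stringsAsFactors = FALSE)
}

#' Build a second-derivative component library
#'
#' Each pure-constituent spectrum (water, collagen, proteoglycan) is
#' spline-smoothed, differentiated twice analytically, and evaluated on the
#' analysis grid; the three second-derivative absorptivity traces form the
#' columns of the design matrix of the Beer-Lambert mixture model. Grid
#' rows within the configured number of boundary knot spans of any
#' component fit are flagged as edge-affected and dropped from the solve.
#'
#' @param components list of exactly 3 `nir_spectrum` objects, in the order
#'   water, collagen, proteoglycan; each must span the grid.
#' @param grid a [spectral_grid()].
#' @param params a [smoothing_params()] object applied to each component.
#' @param names component labels (defaults to water/collagen/proteoglycan).
#' @return An object of class `component_library`: list with `names`,
#'   `grid`, `wavenumbers` (kept grid points), `d2` (kept rows x 3),
#'   `d2_full` and `keep` (full-grid matrix and row mask), and
#'   `condition_number`. A warning is issued when the condition number
#'   exceeds 1e8.
#' @export
build_library <- function(components, grid = spectral_grid(),
                          params = smoothing_params(),
                          names = c("water", "collagen", "proteoglycan")) {
  if (!is.list(components) || length(components) != 3L ||
      !all(vapply(components, inherits, logical(1L), "nir_spectrum")))
    stop("`components` must be a list of exactly 3 nir_spectrum objects")
  wn <- grid_points(grid)
  keep <- rep(TRUE, length(wn))
  d2_full <- matrix(NA_real_, length(wn), 3L,
                    dimnames = list(NULL, names))
  for (j in 1:3) {
    sr <- restrict_covering(components[[j]], grid)
    m2 <- second_derivative(fit_spline(sr, params = params))
    d2_full[, j] <- predict(m2, wn)
    keep <- keep & interior_mask(m2, wn, params$edge_exclude_spans)
  }
  if (sum(keep) < 3L) stop("fewer than 3 interior grid rows remain")
  E <- d2_full[keep, , drop = FALSE]
  sv <- svd(E, nu = 0L, nv = 0L)$d
  cond <- sv[1L] / sv[length(sv)]
  if (!is.finite(cond) || cond > 1e8)
    warning("component library is badly conditioned (condition number ",
            format(cond, digits = 3), "); concentrations will be unstable")
  structure(list(names = names, grid = grid, wavenumbers = wn[keep],
                 d2 = E, d2_full = d2_full, keep = keep,
                 condition_number = cond),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %s on %d/%d grid rows, condition number %.3g\n",
              paste(x$names, collapse = "/"), nrow(x$d2), x$grid$n_points,
              x$condition_number))
  invisible(x)
}

#' Solve the second-derivative Beer-Lambert system
#'
#' Computes the least-squares concentration estimate `c` minimising
#' `||E'' c - d2A||` over the library rows, through QR factorisation of the
#' component matrix. Concentrations are relative (pure-component spectra
#' stand in for absorptivities) and carry the unknown path length as a
#' common scale factor; no sign constraint is applied.
#'
#' @param d2A second-derivative absorbance evaluated on the library's kept
#'   grid rows (`lib$wavenumbers`).
#' @param lib a [build_library()] object.
#' @param rows optional logical or integer subset of the library rows
#'   (e.g. a spectral window); default uses all kept rows.
#' @param nonneg constrain concentrations to be non-negative (exact
#'   active-set NNLS). Off by default: negative estimates are evidence of
#'   model misfit and are reported rather than hidden.
#' @return A `feature_vector` with fields `c_w`, `c_c`, `c_p`,
#'   `residual_norm`, `condition_number`.
#' @export
solve_concentrations <- function(d2A, lib, rows = NULL, nonneg = FALSE) {
  stopifnot(inherits(lib, "component_library"))
  E <- lib$d2
  if (length(d2A) != nrow(E))
    stop("d2A has ", length(d2A), " values but the library has ", nrow(E),
         " rows")
  if (!is.null(rows)) {
    E <- E[rows, , drop = FALSE]
    d2A <- d2A[rows]
  }
  if (nrow(E) < 3L) stop("need at least 3 rows to solve for 3 components")
  sol <- solve_cls(E, d2A, names = lib$names)
  if (nonneg && any(sol$coef < 0)) {
    nn <- nnls3(E, d2A)
    sol$coef <- nn$coef
    sol$residual_norm <- sqrt(nn$rss)
  }
  new_feature_vector(sol$coef, sol$residual_norm, sol$condition_number)
}

# shared second-derivative evaluation for one spectrum against a library:
# returns d2 values on the full grid plus the spectrum's own interior mask
sample_d2_on_grid <- function(s, lib, params) {
  sr <- restrict_covering(s, lib$grid)
  m2 <- second_derivative(fit_spline(sr, params = params))
  wn <- grid_points(lib$grid)
  list(d2 = predict(m2, wn),
       mask = interior_mask(m2, wn, params$edge_exclude_spans))
}

#' Unmix one spectrum into constituent concentrations
#'
#' Full preprocessing pipeline: restrict to the analysis grid, fit the
#' cubic smoothing spline, take the analytic second derivative, evaluate on
#' the grid, drop edge-affected rows, and solve the second-derivative
#' Beer-Lambert system against the component library. The second-derivative
#' step makes the result invariant to constant and linear baseline offsets;
#' scaling the spectrum (an unknown optical path length) scales the
#' solution by the same factor.
#'
#' @param s a `nir_spectrum` spanning `lib$grid`.
#' @param lib a [build_library()] object.
#' @param params a [smoothing_params()] object.
#' @param nonneg constrain concentrations to be non-negative (see
#'   [solve_concentrations()]).
#' @return A `feature_vector` carrying the sample's id and group.
#' @examples
#' comps <- make_components(grid = spectral_grid(n_points = 300))
#' lib <- build_library(comps, spectral_grid(n_points = 300))
#' mix <- make_mixture(comps, concentrations = c(0.3, 0.5, 0.4))
#' unmix(mix$spectrum, lib)
#' @export
unmix <- function(s, lib, params = smoothing_params(), nonneg = FALSE) {
  stopifnot(inherits(s, "nir_spectrum"), inherits(lib, "component_library"))
  ev <- sample_d2_on_grid(s, lib, params)
  rows <- ev$mask & lib$keep
  if (sum(rows) < 3L) stop("fewer than 3 usable grid rows after edge exclusion")
  E <- lib$d2_full[rows, , drop = FALSE]
  sol <- solve_cls(E, ev$d2[rows], names = lib$names)
  if (nonneg && any(sol$coef < 0)) {
    nn <- nnls3(E, ev$d2[rows])
    sol$coef <- nn$coef
    sol$residual_norm <- sqrt(nn$rss)
  }
  new_feature_vector(sol$coef, sol$residual_norm, sol$condition_number,
                     sample_id = s$sample_id, group = s$group)
}

#' Unmix a batch of spectra
#'
#' Equivalent to calling [unmix()] on each spectrum, but when all spectra
#' share one wavenumber axis and `params$tau == 0` (so the knot vector
#' depends only on the axis) the spline design and library factorisations
#' are computed once and reused, which is much faster for simulation
#' studies.
#'
#' @param spectra list of `nir_spectrum` objects.
#' @inheritParams unmix
#' @return A data.frame with one row per spectrum: `sample_id`, `group`,
#'   `c_w`, `c_c`, `c_p`, `residual_norm`, `condition_number`.
#' @export
unmix_spectra <- function(spectra, lib, params = smoothing_params()) {
  stopifnot(is.list(spectra),
            all(vapply(spectra, inherits, logical(1L), "nir_spectrum")))
  ax <- spectra[[1L]]$axis
  shared <- params$tau == 0 && !identical(params$dof, "auto") &&
    all(vapply(spectra, function(s)
      length(s$axis) == length(ax) && all(s$axis == ax), logical(1L)))
  if (!shared) {
    return(do.call(rbind, lapply(spectra, function(s)
      as.data.frame(unmix(s, lib, params)))))
  }

  sr1 <- restrict_covering(spectra[[1L]], lib$grid)
  sub <- match(sr1$axis, ax)
  m1 <- fit_spline(sr1, params = params)
  X <- splines::splineDesign(m1$knots, sr1$axis, ord = 4L)
  qrX <- qr(X)
  Y <- vapply(spectra, function(s) s$absorbance[sub],
              numeric(length(sub)))
  C <- qr.coef(qrX, Y)                         # coefficients, one column each

  # differentiate all coefficient columns at once (same knots for all)
  d1 <- function(C, t, p) {
    nc <- nrow(C)
    span <- t[(p + 2L):(nc + p)] - t[2L:nc]
    D <- diff(C) * (p / span)
    D[span <= 0, ] <- 0
    D
  }
  C1 <- d1(C, m1$knots, 3L)
  t1 <- m1$knots[2L:(length(m1$knots) - 1L)]
  C2 <- d1(C1, t1, 2L)
  t2 <- t1[2L:(length(t1) - 1L)]

  wn <- grid_points(lib$grid)
  m2_proto <- structure(list(degree = 1L, knots = t2, coefficients = C2[, 1L],
                             domain = m1$domain), class = "spline_model")
  mask <- interior_mask(m2_proto, wn, params$edge_exclude_spans) & lib$keep
  B2 <- splines::splineDesign(t2, wn[mask], ord = 2L)
  D2 <- B2 %*% C2                              # kept-rows x n_spectra

  E <- lib$d2_full[mask, , drop = FALSE]
  qrE <- qr(E)
  if (qrE$rank < ncol(E)) stop("rank-deficient component matrix")
  cf <- qr.coef(qrE, D2)                       # 3 x n_spectra
  R <- D2 - E %*% cf
  sv <- svd(E, nu = 0L, nv = 0L)$d
  cond <- sv[1L] / sv[length(sv)]

  data.frame(
    sample_id = vapply(spectra, `[[`, character(1L), "sample_id"),
    group = vapply(spectra, `[[`, character(1L), "group"),
    c_w = cf[1L, ], c_c = cf[2L, ], c_p = cf[3L, ],
    residual_norm = sqrt(colSums(R * R)),
    condition_number = cond,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Concentration stability across spectral windows
#'
#' Re-solves the unmixing system restricted to each wavenumber window and
#' summarises how much the recovered concentrations move: a solution that
#' depends only weakly on which part of the spectrum is used indicates a
#' stable, well-posed fit.
#'
#' @param s a `nir_spectrum`.
#' @param lib a [build_library()] object.
#' @param params a [smoothing_params()] object.
#' @param windows list of `c(lo, hi)` wavenumber intervals (cm^-1); each
#'   must contain at least 50 grid points.
#' @return A list with `features` (data.frame, one row per window with
#'   `window_lo`/`window_hi`), and `dispersion`: per-component sd of the
#'   estimates across windows divided by the mean absolute estimate.
#' @export
window_stability <- function(s, lib, params = smoothing_params(), windows) {
  stopifnot(is.list(windows), length(windows) >= 1L)
  ev <- sample_d2_on_grid(s, lib, params)
  base_rows <- ev$mask & lib$keep
  d2A_kept <- ev$d2[lib$keep]
  mask_kept <- ev$mask[lib$keep]
  res <- lapply(windows, function(w) {
    if (length(w) != 2L || w[1L] >= w[2L]) stop("windows must be c(lo, hi)")
    in_w <- lib$wavenumbers >= w[1L] & lib$wavenumbers <= w[2L]
    if (sum(in_w) < 50L)
      stop("window [", w[1L], ", ", w[2L], "] contains only ", sum(in_w),
           " grid points (need >= 50)")
    rows <- in_w & mask_kept
    if (sum(rows) < 3L)
      stop("window [", w[1L], ", ", w[2L], "] has fewer than 3 usable rows")
    fv <- solve_concentrations(d2A_kept, lib, rows = rows)
    cbind(data.frame(window_lo = w[1L], window_hi = w[2L]),
          as.data.frame(fv)[c("c_w", "c_c", "c_p", "residual_norm")])
  })
  feats <- do.call(rbind, res)
  M <- as.matrix(feats[, c("c_w", "c_c", "c_p")])
  disp <- apply(M, 2L, function(v)
    if (length(v) > 1L) stats::sd(v) / mean(abs(v)) else 0)
  list(features = feats, dispersion = disp)
}
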