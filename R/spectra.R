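#' Construct an NIR absorbance spectrum
#'
#' A spectrum is a single absorbance trace on a strictly increasing
#' wavenumber axis (cm^-1), with a sample identifier and an optional group
#' label. This is the basic container passed through smoothing,
#' differentiation and unmixing.
#'
#' @param axis numeric vector of wavenumbers in cm^-1. Must be finite; if
#'   unsorted it is re-sorted (with a warning) together with `absorbance`.
#'   Duplicated wavenumbers are an error.
#' @param absorbance numeric vector of absorbance values (AU), same length
#'   as `axis`.
#' @param sample_id character scalar identifying the sample.
#' @param group optional group label, e.g. `"normal"` or `"degraded"`;
#'   `NA` when unknown.
#' @return An object of class `nir_spectrum`: a list with elements `axis`,
#'   `absorbance`, `sample_id`, `group`.
#' @examples
#' s <- nir_spectrum(c(4000, 4008, 4016, 4024), c(0.10, 0.12, 0.11, 0.13), "s1")
#' s
#' @export
nir_spectrum <- function(axis, absorbance, sample_id = "sample", group = NA_character_) {
  axis <- as.numeric(axis)
  absorbance <- as.numeric(absorbance)
  if (length(axis) != length(absorbance))
    stop("`axis` and `absorbance` must have the same length (got ",
         length(axis), " and ", length(absorbance), ")")
  if (length(axis) < 4L)
    stop("a spectrum needs at least 4 points, got ", length(axis))
  if (!all(is.finite(axis)) || !all(is.finite(absorbance)))
    stop("spectrum '", sample_id, "' contains non-finite values")
  if (anyDuplicated(axis)) {
    dup <- axis[duplicated(axis)][1L]
    stop("spectrum '", sample_id, "' has duplicated wavenumber ", format(dup))
  }
  if (is.unsorted(axis)) {
    warning("wavenumber axis of '", sample_id, "' not increasing; re-sorting")
    o <- order(axis)
    axis <- axis[o]
    absorbance <- absorbance[o]
  }
  structure(
    list(axis = axis, absorbance = absorbance,
         sample_id = as.character(sample_id)[1L],
         group = as.character(group)[1L]),
    class = "nir_spectrum"
  )
}

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum> '%s'%s: %d points, %.0f-%.0f cm-1, A in [%.4g, %.4g]\n",
              x$sample_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$axis), min(x$axis), max(x$axis),
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' @export
length.nir_spectrum <- function(x) length(x$axis)

#' Define a uniform spectral analysis grid
#'
#' The default mirrors the standard working region for fibre-optic NIR
#' measurements of soft tissue: 4000 to 10000 cm^-1 sampled at 779 points.
#'
#' @param lo,hi grid endpoints in cm^-1, `lo < hi`.
#' @param n_points number of uniformly spaced points, endpoints inclusive
#'   (at least 4).
#' @return An object of class `spectral_grid` with fields `lo`, `hi`,
#'   `n_points`.
#' @examples
#' g <- spectral_grid()
#' head(grid_points(g))
#' @export
spectral_grid <- function(lo = 4000, hi = 10000, n_points = 779) {
  lo <- as.numeric(lo)[1L]; hi <- as.numeric(hi)[1L]
  n_points <- as.integer(n_points)[1L]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("need finite lo < hi, got [", lo, ", ", hi, "]")
  if (is.na(n_points) || n_points < 4L)
    stop("n_points must be at least 4")
  structure(list(lo = lo, hi = hi, n_points = n_points),
            class = "spectral_grid")
}

#' @rdname spectral_grid
#' @param grid a `spectral_grid`.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  seq(grid$lo, grid$hi, length.out = grid$n_points)
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %.0f-%.0f cm-1, %d points (spacing %.3f)\n",
              x$lo, x$hi, x$n_points, (x$hi - x$lo) / (x$n_points - 1L)))
  invisible(x)
}

#' Read absorbance spectra from CSV
#'
#' Two dialects are supported. `csv_long` has columns `wavenumber` and
#' `absorbance`, plus an optional `sample_id` column carrying several
#' spectra in one file (and an optional `group` column). `csv_wide` has the
#' wavenumber axis in the first column and one absorbance column per sample,
#' with sample ids taken from the column headers.
#'
#' Axes given in nanometres are converted to wavenumber via
#' `nu = 1e7 / lambda_nm` and re-sorted.
#'
#' @param path path to a CSV file.
#' @param dialect `"csv_long"` or `"csv_wide"`.
#' @param unit `"wavenumber"` (cm^-1, default) or `"nm"`.
#' @return A list of `nir_spectrum` objects.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, dialect = c("csv_long", "csv_wide"),
                         unit = c("wavenumber", "nm")) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  to_wn <- function(x) if (unit == "nm") 1e7 / x else x

  if (dialect == "csv_long") {
    need <- c("wavenumber", "absorbance")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
    for (col in need) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop("non-numeric or non-finite '", col, "' at data row ", bad[1L],
             " of ", path, " (value '", df[[col]][bad[1L]], "')")
      df[[col]] <- v
    }
    ids <- if ("sample_id" %in% names(df)) as.character(df$sample_id)
           else rep(sub("\\.[^.]*$", "", basename(path)), nrow(df))
    groups <- if ("group" %in% names(df)) as.character(df$group)
              else rep(NA_character_, nrow(df))
    out <- lapply(unique(ids), function(id) {
      sel <- ids == id
      nir_spectrum(to_wn(df$wavenumber[sel]), df$absorbance[sel],
                   sample_id = id, group = groups[sel][1L])
    })
    return(out)
  }

  # csv_wide
  if (ncol(df) < 2L)
    stop("wide CSV ", path, " needs a wavenumber column plus >= 1 sample column")
  ax <- suppressWarnings(as.numeric(df[[1L]]))
  bad <- which(!is.finite(ax))
  if (length(bad))
    stop("non-numeric wavenumber at data row ", bad[1L], " of ", path)
  ax <- to_wn(ax)
  lapply(names(df)[-1L], function(id) {
    v <- suppressWarnings(as.numeric(df[[id]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric absorbance for sample '", id, "' at data row ",
           bad[1L], " of ", path)
    nir_spectrum(ax, v, sample_id = id)
  })
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]. Long output carries `sample_id`,
#' `wavenumber`, `absorbance` (and `group` when any spectrum has one); wide
#' output requires all spectra to share an identical axis.
#'
#' @param spectra a `nir_spectrum` or list of them.
#' @param path output file path.
#' @param dialect `"csv_long"` or `"csv_wide"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, dialect = c("csv_long", "csv_wide")) {
  dialect <- match.arg(dialect)
  if (inherits(spectra, "nir_spectrum")) spectra <- list(spectra)
  stopifnot(all(vapply(spectra, inherits, logical(1L), "nir_spectrum")))
  if (dialect == "csv_long") {
    df <- do.call(rbind, lapply(spectra, function(s)
      data.frame(sample_id = s$sample_id, wavenumber = s$axis,
                 absorbance = s$absorbance, group = s$group)))
    if (all(is.na(df$group))) df$group <- NULL
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    ax <- spectra[[1L]]$axis
    same <- vapply(spectra, function(s)
      length(s$axis) == length(ax) && all(s$axis == ax), logical(1L))
    if (!all(same))
      stop("csv_wide requires all spectra on an identical axis")
    df <- data.frame(wavenumber = ax)
    for (s in spectra) df[[s$sample_id]] <- s$absorbance
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Restrict a spectrum to the span of an analysis grid
#'
#' Drops points outside `[grid$lo, grid$hi]`; no interpolation is performed,
#' so the operation is idempotent.
#'
#' @param s a `nir_spectrum`.
#' @param grid a `spectral_grid`.
#' @return The restricted `nir_spectrum`.
#' @export
restrict_range <- function(s, grid) {
  stopifnot(inherits(s, "nir_spectrum"), inherits(grid, "spectral_grid"))
  keep <- s$axis >= grid$lo & s$axis <= grid$hi
  if (!any(keep))
    stop("spectrum '", s$sample_id, "' (", min(s$axis), "-", max(s$axis),
         " cm-1) does not overlap grid [", grid$lo, ", ", grid$hi, "]")
  if (all(keep)) return(s)
  nir_spectrum(s$axis[keep], s$absorbance[keep],
               sample_id = s$sample_id, group = s$group)
}

#' Resample a spectrum onto a uniform grid
#'
#' With a fitted [spline_model] the grid values are spline evaluations;
#' without one, piecewise-linear interpolation is used. Extrapolation beyond
#' the spectrum's span is refused: component and tissue spectra recorded on
#' different instruments must be brought onto a common grid by
#' interpolation only.
#'
#' @param s a `nir_spectrum`.
#' @param grid target `spectral_grid`; must lie inside the span of `s`.
#' @param model optional `spline_model` fitted to `s` (see [fit_spline()]).
#' @return A `nir_spectrum` whose axis is exactly `grid_points(grid)`.
#' @export
resample <- function(s, grid, model = NULL) {
  stopifnot(inherits(s, "nir_spectrum"), inherits(grid, "spectral_grid"))
  x <- grid_points(grid)
  if (grid$lo < min(s$axis) || grid$hi > max(s$axis))
    stop("grid [", grid$lo, ", ", grid$hi, "] extends beyond spectrum '",
         s$sample_id, "' span [", min(s$axis), ", ", max(s$axis),
         "]; extrapolation refused")
  y <- if (is.null(model)) {
    stats::approx(s$axis, s$absorbance, xout = x, method = "linear")$y
  } else {
    stopifnot(inherits(model, "spline_model"))
    predict(model, x)
  }
  nir_spectrum(x, y, sample_id = s$sample_id, group = s$group)
}
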