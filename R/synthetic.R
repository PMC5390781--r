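#' Component band specification
#'
#' A pure-constituent spectrum is modelled as a sum of Gaussian absorption
#' bands, each `amplitude * exp(-(nu - center)^2 / (2 width^2))`. Gaussian
#' shapes are adequate for exercising the smoothing/derivative/unmixing
#' mathematics and are simple to differentiate in closed form for
#' cross-checks; they are illustrative, not spectroscopically calibrated.
#'
#' @param name component label.
#' @param centers band centres (cm^-1), inside (4000, 10000).
#' @param widths Gaussian standard deviations (cm^-1), `> 0`.
#' @param amplitudes band amplitudes (AU).
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, centers, widths, amplitudes) {
  centers <- as.numeric(centers); widths <- as.numeric(widths)
  amplitudes <- as.numeric(amplitudes)
  k <- length(centers)
  if (k < 2L) stop("a component needs at least 2 bands")
  if (length(widths) != k || length(amplitudes) != k)
    stop("centers, widths, amplitudes must have equal length")
  if (any(widths <= 0)) stop("band widths must be > 0")
  if (any(centers <= 4000 | centers >= 10000))
    stop("band centres must lie inside (4000, 10000) cm^-1")
  structure(list(name = name,
                 bands = data.frame(center = centers, width = widths,
                                    amplitude = amplitudes)),
            class = "component_spec")
}

#' Default water / collagen / proteoglycan component specifications
#'
#' Water dominates around 5200 and 6900 cm^-1 (the strong O-H combination
#' and first-overtone regions), while the organic matrix components
#' populate the 4000-4900 cm^-1 combination region with broad overlapping
#' bands, giving the characteristic non-independent peaks of tissue NIR
#' spectra while keeping the three second-derivative signatures
#' identifiable.
#'
#' @return Named list of three [component_spec()] objects.
#' @export
default_component_specs <- function() {
  list(
    water = component_spec("water",
      centers = c(4300, 5200, 6900, 8600),
      widths = c(250, 90, 140, 240),
      amplitudes = c(0.45, 1.00, 0.80, 0.22)),
    collagen = component_spec("collagen",
      centers = c(4280, 4610, 5780, 6530, 8270),
      widths = c(70, 95, 170, 210, 260),
      amplitudes = c(0.75, 0.60, 0.38, 0.28, 0.12)),
    proteoglycan = component_spec("proteoglycan",
      centers = c(4390, 4880, 6080, 7120, 8420),
      widths = c(65, 100, 185, 230, 300),
      amplitudes = c(0.70, 0.52, 0.33, 0.20, 0.10))
  )
}

#' Render a pure-component spectrum from its band specification
#'
#' Deterministic: the absorbance is the sum of the Gaussian bands
#' evaluated at the grid points, with no noise or baseline.
#'
#' @param spec a [component_spec()].
#' @param grid a [spectral_grid()].
#' @return A `nir_spectrum` named after the component.
#' @export
make_component <- function(spec, grid = spectral_grid()) {
  stopifnot(inherits(spec, "component_spec"), inherits(grid, "spectral_grid"))
  nu <- grid_points(grid)
  y <- rep(0, length(nu))
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    y <- y + b$amplitude * exp(-(nu - b$center)^2 / (2 * b$width^2))
  }
  nir_spectrum(nu, y, sample_id = spec$name)
}

#' Render the default three-component set
#'
#' @param specs list of three [component_spec()]s (water, collagen,
#'   proteoglycan order); defaults to [default_component_specs()].
#' @param grid a [spectral_grid()].
#' @return List of three `nir_spectrum` objects.
#' @export
make_components <- function(specs = default_component_specs(),
                            grid = spectral_grid()) {
  lapply(specs, make_component, grid = grid)
}

#' Synthesise a mixture spectrum under the Beer-Lambert forward model
#'
#' Absorbance is `l * (c_w e_w + c_c e_c + c_p e_p)` plus an additive
#' baseline `offset + slope * nu` and iid Gaussian instrument noise. The
#' baseline emulates the systematic offsets seen between raw tissue
#' measurements; the second-derivative pipeline is designed to remove it.
#'
#' @param components list of 3 component `nir_spectrum`s on a common grid
#'   (water, collagen, proteoglycan order).
#' @param concentrations numeric `c(c_w, c_c, c_p)`.
#' @param path_length optical path length `l` (mm-equivalent scale
#'   factor), `> 0`.
#' @param baseline numeric `c(offset_AU, slope_AU_per_cm1)`.
#' @param noise_sd iid Gaussian noise standard deviation (AU), `>= 0`.
#' @param seed integer seed for the noise draw (`NULL` leaves the RNG
#'   state alone); identical seeds give bit-identical spectra.
#' @param sample_id,group metadata for the returned spectrum.
#' @return List with `spectrum` (a `nir_spectrum`) and `truth` (one-row
#'   data.frame recording the generating parameters).
#' @export
make_mixture <- function(components, concentrations, path_length = 1,
                         baseline = c(0, 0), noise_sd = 0, seed = NULL,
                         sample_id = "mixture", group = NA_character_) {
  stopifnot(length(components) == 3L,
            all(vapply(components, inherits, logical(1L), "nir_spectrum")))
  ax <- components[[1L]]$axis
  for (s in components[-1L])
    if (length(s$axis) != length(ax) || !all(s$axis == ax))
      stop("component spectra must share one wavenumber axis")
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != 3L) stop("need 3 concentrations")
  if (!is.finite(path_length) || path_length <= 0)
    stop("path_length must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  y <- path_length * (concentrations[1L] * components[[1L]]$absorbance +
                      concentrations[2L] * components[[2L]]$absorbance +
                      concentrations[3L] * components[[3L]]$absorbance) +
       baseline[1L] + baseline[2L] * ax
  if (noise_sd > 0) y <- y + stats::rnorm(length(ax), 0, noise_sd)
  list(
    spectrum = nir_spectrum(ax, y, sample_id = sample_id, group = group),
    truth = data.frame(sample_id = sample_id, group = group,
                       c_w = concentrations[1L], c_c = concentrations[2L],
                       c_p = concentrations[3L], path_length = path_length,
                       baseline_offset = baseline[1L],
                       baseline_slope = baseline[2L], noise_sd = noise_sd,
                       stringsAsFactors = FALSE)
  )
}

#' Feature-cluster specification for one tissue group
#'
#' @param label group label.
#' @param mean 3-vector of mean `(c_w, c_c, c_p)`.
#' @param sd 3-vector of per-component standard deviations (diagonal
#'   covariance), all `> 0`.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, mean, sd) {
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != 3L || length(sd) != 3L) stop("mean and sd must be 3-vectors")
  if (any(sd <= 0)) stop("sd must be > 0 componentwise")
  structure(list(label = as.character(label), mean = mean, sd = sd),
            class = "group_spec")
}

#' Reference cluster parameters for normal and degraded cartilage
#'
#' Built-in feature-space cluster centres and spreads representative of
#' normal versus enzymatically degraded bovine articular cartilage:
#' degradation depletes proteoglycan and collagen and raises the water
#' signal. These drive the default two-cluster simulations.
#'
#' @return Named list of two [group_spec()]s, `normal` and `degraded`.
#' @export
default_group_specs <- function() {
  list(
    normal = group_spec("normal",
      mean = c(0.1418, 0.5949, 0.5571),
      sd = c(0.0169, 0.0446, 0.0517)),
    degraded = group_spec("degraded",
      mean = c(0.4052, 0.2486, 0.2237),
      sd = c(0.0346, 0.0316, 0.0237))
  )
}

#' Draw a two-cluster feature dataset
#'
#' Samples iid feature vectors from each group's independent (diagonal
#' covariance) Gaussian.
#'
#' @param groups list of [group_spec()]s; defaults to
#'   [default_group_specs()].
#' @param n_per_group samples per group, `>= 4`.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return Feature data.frame with `sample_id`, `group`, `c_w`, `c_c`,
#'   `c_p`.
#' @export
make_feature_dataset <- function(groups = default_group_specs(),
                                 n_per_group = 145L, seed = NULL) {
  stopifnot(all(vapply(groups, inherits, logical(1L), "group_spec")))
  n_per_group <- as.integer(n_per_group)[1L]
  if (is.na(n_per_group) || n_per_group < 4L) stop("n_per_group must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(groups, function(g) {
    M <- vapply(1:3, function(j)
      stats::rnorm(n_per_group, g$mean[j], g$sd[j]), numeric(n_per_group))
    data.frame(sample_id = paste0(g$label, "_", seq_len(n_per_group)),
               group = g$label, c_w = M[, 1L], c_c = M[, 2L], c_p = M[, 3L],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Theoretical between-cluster Mahalanobis separation
#'
#' Closed-form squared Mahalanobis distance between two diagonal-Gaussian
#' group specifications, using the pooled (average) covariance.
#'
#' @param g1,g2 [group_spec()] objects.
#' @return Squared Mahalanobis distance (dimensionless).
#' @export
group_separation <- function(g1, g2) {
  stopifnot(inherits(g1, "group_spec"), inherits(g2, "group_spec"))
  pooled_var <- (g1$sd^2 + g2$sd^2) / 2
  sum((g1$mean - g2$mean)^2 / pooled_var)
}

#' Simulate a full two-group spectral study
#'
#' Emulates a paired normal/degraded tissue experiment end to end: per
#' sample, concentrations are drawn from the group's feature cluster and
#' rendered into an absorbance spectrum through the Beer-Lambert forward
#' model, with a group-dependent baseline offset (mimicking systematic
#' offsets between measurement sessions) and instrument noise.
#'
#' @param n_per_group samples per group, `>= 4`.
#' @param seed integer seed.
#' @param groups list of [group_spec()]s for the concentration clusters.
#' @param component_specs list of three [component_spec()]s.
#' @param grid a [spectral_grid()].
#' @param baseline_offsets named numeric, baseline offset (AU) per group.
#' @param baseline_slope common baseline slope (AU per cm^-1).
#' @param noise_sd instrument noise sd (AU).
#' @return List with `spectra` (list of `nir_spectrum`), `truth`
#'   (data.frame of generating parameters per sample), `components`
#'   (rendered component spectra) and `grid`.
#' @export
make_study <- function(n_per_group = 100L, seed = NULL,
                       groups = default_group_specs(),
                       component_specs = default_component_specs(),
                       grid = spectral_grid(),
                       baseline_offsets = c(normal = 0.05, degraded = 0.15),
                       baseline_slope = 1e-5, noise_sd = 0.002) {
  n_per_group <- as.integer(n_per_group)[1L]
  if (is.na(n_per_group) || n_per_group < 4L) stop("n_per_group must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  comps <- make_components(component_specs, grid)
  feats <- make_feature_dataset(groups, n_per_group, seed = NULL)
  spectra <- vector("list", nrow(feats))
  truth <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    g <- feats$group[i]
    off <- if (g %in% names(baseline_offsets)) baseline_offsets[[g]] else 0
    mx <- make_mixture(comps,
                       concentrations = c(feats$c_w[i], feats$c_c[i], feats$c_p[i]),
                       baseline = c(off, baseline_slope),
                       noise_sd = noise_sd, seed = NULL,
                       sample_id = feats$sample_id[i], group = g)
    spectra[[i]] <- mx$spectrum
    truth[[i]] <- mx$truth
  }
  list(spectra = spectra, truth = do.call(rbind, truth),
       components = comps, grid = grid)
}
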