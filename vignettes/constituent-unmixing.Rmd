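---
title: "Constituent-based unmixing of NIR tissue spectra: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constituent-based unmixing of NIR tissue spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmix)
```

## The model

`nirmix` treats a tissue NIR absorbance spectrum as a Beer–Lambert
mixture of three constituents. On the analysis grid ν₁ … ν_k,

A(νᵢ) = c_w·l·ε_w(νᵢ) + c_c·l·ε_c(νᵢ) + c_p·l·ε_p(νᵢ),

where ε_w, ε_c, ε_p are the absorptivities of water, collagen and
proteoglycan (chondroitin sulphate serves as the proteoglycan standard),
c the corresponding concentrations and l the optical path length.
Differentiating twice in wavenumber preserves this linear relation while
annihilating any additive offset and linear tilt — the dominant
systematic differences between measurement sessions. The k×3
second-derivative system is overdetermined and solved for
(c_w·l, c_c·l, c_p·l) by QR least squares.

Three modelling assumptions matter:

* **Relative scale.** Measured pure-component spectra stand in for molar
  absorptivities, so recovered concentrations are relative to the pure
  standards, not absolute. All downstream analyses (clustering,
  classification) are scale-consistent, so this costs nothing for
  discrimination.
* **Path length.** l is unknown in arthroscopic use and fixed at 1.
  Since l multiplies the right-hand side of a linear system, it simply
  scales the solution vector. Mahalanobis distance is invariant under
  any common invertible linear map of the features, so classification is
  provably unaffected by a *common* scaling, and empirically (the
  Monte-Carlo experiment below) robust to *per-sample* scalings of
  realistic spread.
* **Additive nuisances only.** The second derivative removes
  polynomial-degree-≤1 baselines exactly; multiplicative scatter effects
  are not modelled (no MSC/SNV), matching the intended use on
  probe-contact absorbance measurements.

## Spline smoothing and analytic differentiation

The trace is fitted with a clamped cubic B-spline, A(ν) = Σ cᵢ B₍ᵢ,₃₎(ν),
by linear least squares on the spline design matrix. Knots are placed
data-adaptively: consecutive points whose absorbance difference is at
most τ are redundant, and each maximal redundant run collapses to one
candidate knot at its midpoint (lower-index midpoint for even runs; the
runs containing the endpoints are carried by the boundary knots). The
second derivative is obtained by applying the B-spline derivative
recurrence twice — coefficients become scaled first differences over knot
spans, degree drops 3 → 1 — so it is the *exact* derivative of the
fitted spline, testable against finite differences of the spline's own
evaluations.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 0 | AU | knot-thinning tolerance; 0 keeps a knot at every interior point |
| `dof` | `Inf` | — | cap on spline coefficients; `"auto"` matches residual RMS to the noise level |
| `noise_sd` | estimated | AU | robust estimate from second differences, `mad(diff(y, 2))/sqrt(6)` |
| `edge_exclude_spans` | 3 | knot spans | boundary rows dropped before the solve |
| grid | 4000–10000, 779 pts | cm⁻¹ | analysis grid |

`tau = 0` deserves explanation, since it disables knot thinning. With a
knot at every interior data point the knot vector depends only on the
wavenumber axis, not on the measured values. Every spectrum on a common
grid then shares one spline basis, making the entire
smooth → differentiate → solve pipeline a fixed linear operator on the
data. Consequences, each verified in the test suite: noiseless mixtures
are recovered to better than 1e−6 relative; unmixing is exactly linear
and scale-equivariant (to 1e−10); affine baselines perturb
concentrations by far less than 1%. Thinning (τ > 0 or a `dof` cap)
buys noise suppression at the price of exactness and is the right choice
for visibly noisy single spectra; for the CLS solve itself, noise is
already averaged down by the ~770-row least-squares projection, so the
default favours exactness. `dof = "auto"` picks the smallest coefficient
count whose residual RMS falls at or below the estimated noise.

Two smaller conventions: differentiation is taken with respect to
wavenumber (cm⁻¹) for samples and components alike — only consistency
matters, as differentiation is linear either way; and when more candidate
knots exist than the data can support, the surplus is shed from the ends
(the not-a-knot construction), which keeps the design nonsingular by the
Schoenberg–Whitney interlacing condition.

### Edge handling

Clamped boundaries make the second derivative unreliable within a few
knot spans of each end, so rows within `edge_exclude_spans` (default 3)
spans of either boundary — flagged on both the component fits and the
sample fit — are excluded from the solve. On the 779-point grid this
drops 8 of 779 rows.

## Classification

Groups are modelled by their sample mean μ and covariance S (denominator
n−1), and a sample x is assigned to the group minimising
D² = (x−μ)ᵀS⁻¹(x−μ), computed via the Cholesky factor of S (a triangular
solve; S is never inverted explicitly). Design choices:

* **Positive class = degraded** (disease detection polarity): a false
  positive is a normal sample called degraded. Percentages use the grand
  total of classified samples.
* **Evaluation protocol.** `classify()` scores against fixed models
  (resubstitution); `classify_loo()` refits the sample's own group
  without it before scoring. Both are exposed because resubstitution is
  optimistically biased; the CLI defaults to leave-one-out.
* **Ties** (possible only in degenerate geometry) go to the normal group
  with a warning.
* **Ridge** on S is available (`ridge` argument) but defaults to 0; a
  singular covariance is reported as an error naming the deficient
  direction rather than silently regularised.

A caveat the package cannot remove: tissue studies of this design take
multiple measurement points per joint, so points are pseudo-replicated.
They are classified independently here, as is conventional, but the
error rates should not be read as subject-level generalisation estimates.

## Path-length robustness experiment

`run_robustness()` repeats, `n_repeats = 100` times: draw an independent
path length per sample from N(μ = 1.66 mm, σ = 0.25 mm) truncated below
at 0.1 mm (a safety bound — non-positive draws are vanishingly rare);
scale each feature vector; subsample 2/3 of each cluster without
replacement; refit both group models on the subsample; classify the
subsample; record the confusion counts. Counts are summarised by
mode/min/max (for multimodal count vectors all modes are kept and the
smallest is reported), and cluster centres are summarised both across
all scaled samples and across per-repeat means, since "spread of the
cluster centre" admits either reading. Two switches generalise the
protocol: `subsample_fraction` and `n_repeats` are independent knobs
(the repeat count and the 2/3 subsample are distinct concepts even
though both default from the same study description), and
`fixed_models = TRUE` classifies against models fit once on the full
unscaled data, for the reading in which cluster models are not refit per
repeat. With σ = 0 and full sampling every repeat reproduces the
baseline confusion exactly — the affine-invariance argument made
operational, and a property test in the suite.

## The synthetic generator

No raw spectra are deposited, so the generator is a first-class module
that emulates the study conditions:

* **Component spectra** are sums of Gaussian bands. Water dominates near
  5200 and 6900 cm⁻¹ with a weak 8600 cm⁻¹ band and a broad low-end
  shoulder; collagen and proteoglycan populate the 4000–4900 cm⁻¹
  combination region with broad secondary bands further up. The layout
  is qualitatively realistic (overlapping, non-independent peaks;
  pairwise second-derivative correlations below 0.95 so the design stays
  identifiable) but is *illustrative, not spectroscopically calibrated*.
  Gaussian band shapes (rather than Lorentzian/Voigt) were chosen
  because they exercise the same mathematics with simple closed forms.
* **Mixtures** follow the forward model exactly: l·Σcⱼεⱼ plus an
  additive baseline (offset + slope·ν) and iid Gaussian noise.
  Group-dependent baseline offsets (defaults 0.05 / 0.15 AU) mimic the
  systematic offsets seen between measurement sessions of normal and
  treated samples.
* **Feature clusters** use the published normal
  (0.1418, 0.5949, 0.5571 ± 0.0169, 0.0446, 0.0517) and degraded
  (0.4052, 0.2486, 0.2237 ± 0.0346, 0.0316, 0.0237) means and standard
  deviations with diagonal covariance — only per-component spreads are
  published, so independence is the minimal assumption; full covariances
  are accepted where available. These parameters imply a between-cluster
  Mahalanobis separation of ~15.6σ, which is why simulated
  classification is essentially error-free.
* **Noise level** defaults to 0.002 AU, a realistic figure for
  FT-NIR absorbance averaged over ~100 scans; path-length μ, σ mirror
  the reported cartilage thickness distribution.

What passing tests on these simulations do **not** show: performance
under multiplicative scatter, instrument line-shape differences,
wavelength-calibration drift between spectrometers, or constituent
spectra measured in a different physical state than they occur in
tissue. Those effects are absent from the generator by design; the
simulations validate the algebra and the implementation, not the
spectroscopy.

## Numerical choices and degenerate inputs

* All least-squares solves go through QR; the normal-equations
  pseudoinverse appears only as an independent oracle in the tests.
* The library build warns when the component matrix condition number
  exceeds 1e8; an exactly collinear pair is an error naming the columns.
* Duplicate wavenumbers within one spectrum are an error (the knot rule
  needs distinct abscissae); an unsorted axis is re-sorted with a
  warning; nm axes are converted to cm⁻¹ on read.
* Resampling refuses extrapolation; spectra must span the grid they are
  solved on.
* Spectral-window stability (`window_stability()`) requires ≥ 50 grid
  points per window; windows where a component has no appreciable
  absorption give ill-conditioned sub-solves, which the per-window
  condition number exposes.
* Reported problem sizes: unit tests run mostly on a 300-point grid
  (same code paths, smaller basis); the end-to-end guarantees are
  checked on the full 779-point grid with 100–200 random draws per
  property, and the classification surrogate uses 145 samples per group.

## Known limitations

Relative concentrations only; two groups only (no multi-class or
probabilistic output); no non-negativity constraint by default (negative
estimates are evidence of model misfit and are reported, not clipped;
an exact active-set NNLS is available via `nonneg = TRUE`);
no spectral-range optimisation beyond the fixed-window stability check;
no scatter or radiative-transfer modelling.
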