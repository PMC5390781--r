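test_that("knot placement collapses redundant runs per the tolerance rule", {
  ax <- seq(4000, 4080, by = 10)
  # constant spectrum: one run spanning everything -> boundary-only knots
  const <- nir_spectrum(ax, rep(0.5, 9), "const")
  k <- place_knots(const, smoothing_params(tau = 0.1))
  expect_equal(k, c(rep(4000, 4), rep(4080, 4)))

  # tau = 0 with all-distinct values: one candidate per interior point
  dist <- nir_spectrum(ax, seq(0, 0.8, by = 0.1), "dist")
  k0 <- place_knots(dist, smoothing_params(tau = 0))
  expect_equal(k0[k0 > 4000 & k0 < 4080], ax[2:8])

  # staircase plateaus, checked against a brute-force run enumeration
  stair <- nir_spectrum(ax, c(0, 0, 0, 1, 1, 1, 2, 2, 2), "stair")
  tau <- 0.5
  runs <- enumerate_runs(stair$absorbance, tau)
  expect_length(runs, 3L)   # one run per plateau
  ks <- place_knots(stair, smoothing_params(tau = tau))
  interior <- ks[ks > 4000 & ks < 4080]
  # first and last plateau are carried by the boundary knots; the middle
  # plateau contributes its midpoint
  mid_run <- runs[[2L]]
  expect_equal(interior, ax[(mid_run[1L] + mid_run[2L] + 1L) %/% 2L])
})

test_that("noise estimation is exact on trends and calibrated on iid noise", {
  ax <- seq(4000, 6000, length.out = 50)
  expect_equal(estimate_noise(nir_spectrum(ax, 0.3 + 2e-4 * ax, "line")), 0)
  expect_equal(estimate_noise(nir_spectrum(ax, rep(1, 50), "const")), 0)

  set.seed(11)
  ax779 <- grid_points(spectral_grid())
  truth <- 0.01
  est <- replicate(5, {
    y <- sin(ax779 / 700) + rnorm(779, 0, truth)
    estimate_noise(nir_spectrum(ax779, y, "noisy"))
  })
  expect_true(all(abs(est - truth) / truth < 0.3))
})

test_that("spline fitting reproduces cubics exactly and respects dof", {
  ax <- seq(0, 1, length.out = 60) * 6000 + 4000
  u <- (ax - 4000) / 6000
  cubic <- nir_spectrum(ax, u^3 - 2 * u, "cubic")
  m <- fit_spline(cubic)
  expect_lt(max(abs(predict(m, ax) - cubic$absorbance)), 1e-8 * max(abs(cubic$absorbance)))

  smooth <- nir_spectrum(ax, sin(u * 6) + 0.5, "smooth")
  ms <- fit_spline(smooth)
  expect_lt(max(abs(predict(ms, ax) - smooth$absorbance)), 1e-6)

  # residual decreases with dof on a noisy sine
  set.seed(4)
  ax2 <- grid_points(spectral_grid(4000, 10000, 400))
  noisy <- nir_spectrum(ax2, sin(ax2 / 400) + rnorm(400, 0, 0.05), "noisy")
  m20 <- fit_spline(noisy, params = smoothing_params(dof = 20))
  m200 <- fit_spline(noisy, params = smoothing_params(dof = 200))
  expect_equal(m20$dof, 20)
  expect_equal(m200$dof, 200)
  expect_lt(m200$residual_rms, m20$residual_rms)
})

test_that("auto dof picks the smallest fit whose residual matches the noise", {
  set.seed(9)
  ax <- grid_points(spectral_grid(4000, 10000, 400))
  y <- sin(ax / 600) + rnorm(400, 0, 0.01)
  m <- fit_spline(nir_spectrum(ax, y, "auto"),
                  params = smoothing_params(dof = "auto"))
  expect_lte(m$residual_rms, 0.012)
  expect_lt(m$dof, 400)
})

test_that("analytic second derivative matches closed forms", {
  ax <- seq(4000, 10000, length.out = 120)
  u <- (ax - 4000) / 1000

  line <- fit_spline(nir_spectrum(ax, 0.2 + 3e-4 * ax, "line"))
  d2l <- second_derivative(line)
  expect_equal(d2l$degree, 1L)
  expect_lt(max(abs(predict(d2l, ax))), 1e-10)

  quad <- fit_spline(nir_spectrum(ax, u^2, "quad"))
  d2q <- second_derivative(quad)
  # d2(u^2)/dnu^2 = 2 / 1000^2
  expect_lt(max(abs(predict(d2q, ax) - 2e-6)), 1e-10)
})

test_that("second derivative agrees with a finite-difference oracle on the spline itself", {
  set.seed(21)
  ax <- grid_points(spectral_grid(4000, 10000, 300))
  h <- diff(ax)[1L] / 10
  for (rep in 1:5) {
    y <- rowSums(vapply(1:4, function(j)
      runif(1, 0.1, 1) * sin(ax / runif(1, 300, 900) + runif(1, 0, 6)),
      numeric(length(ax))))
    m <- fit_spline(nir_spectrum(ax, y, "r"))
    d2 <- second_derivative(m)
    # evaluate at knot-span midpoints, clear of breakpoints
    xs <- ax[-length(ax)] + diff(ax) / 2
    xs <- xs[xs - h > 4000 & xs + h < 10000]
    fd <- (predict(m, xs - h) - 2 * predict(m, xs) + predict(m, xs + h)) / h^2
    an <- predict(d2, xs)
    expect_lt(max(abs(an - fd)), 1e-6 * max(abs(an)))
  }
})

test_that("second derivative also matches the splineDesign derivative basis", {
  set.seed(3)
  ax <- seq(4000, 8000, length.out = 150)
  y <- sin(ax / 350) + 0.3 * cos(ax / 800)
  m <- fit_spline(nir_spectrum(ax, y, "x"))
  d2 <- second_derivative(m)
  xs <- seq(4050, 7950, length.out = 500)
  ref <- drop(splines::splineDesign(m$knots, xs, ord = 4L, derivs = 2L) %*%
                m$coefficients)
  expect_lt(max(abs(predict(d2, xs) - ref)), 1e-9 * max(1, max(abs(ref))))
})

test_that("differentiation is linear and annihilates affine baselines", {
  ax <- grid_points(spectral_grid(4000, 10000, 200))
  f <- sin(ax / 500)
  g <- cos(ax / 700)
  sp <- smoothing_params()
  kn <- place_knots(nir_spectrum(ax, f, "f"), sp)  # tau = 0: same for all

  d2 <- function(y) second_derivative(
    fit_spline(nir_spectrum(ax, y, "y"), knots = kn, params = sp))
  a <- 2.5; b <- -1.3
  lhs <- predict(d2(a * f + b * g), ax)
  rhs <- a * predict(d2(f), ax) + b * predict(d2(g), ax)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # adding an affine-in-wavenumber term leaves the second derivative alone
  base <- predict(d2(f), ax)
  shifted <- predict(d2(f + 0.7 + 2e-4 * ax), ax)
  expect_lt(max(abs(shifted - base)), 1e-8)
})

test_that("degree bookkeeping survives double differentiation", {
  ax <- seq(4000, 9000, length.out = 80)
  m <- fit_spline(nir_spectrum(ax, sin(ax / 400), "m"))
  expect_equal(length(m$knots), length(m$coefficients) + 3L + 1L)
  d2 <- second_derivative(m)
  expect_equal(d2$degree, 1L)
  expect_equal(length(d2$knots), length(d2$coefficients) + 1L + 1L)
  expect_error(second_derivative(d2), "degree 3")
})

test_that("interior_mask excludes the configured boundary spans", {
  ax <- grid_points(spectral_grid(4000, 10000, 100))
  d2 <- second_derivative(fit_spline(nir_spectrum(ax, sin(ax / 500), "m")))
  keep <- interior_mask(d2, ax, spans = 3L)
  expect_false(any(keep[1:3]))
  expect_false(any(keep[98:100]))
  expect_true(all(keep[5:95]))
  expect_true(all(interior_mask(d2, ax, spans = 0L)))
})
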