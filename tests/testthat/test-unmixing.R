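test_that("library construction reports conditioning honestly", {
  expect_s3_class(fix_lib, "component_library")
  expect_lt(fix_lib$condition_number, 1e3)
  expect_gte(nrow(fix_lib$d2), 3L)

  # supplying the same component twice must trigger the collinearity warning
  expect_warning(
    build_library(list(fix_comps[[1L]], fix_comps[[1L]], fix_comps[[3L]]),
                  fix_grid),
    "badly conditioned")

  # rebuilt library is bit-identical (generators are deterministic)
  lib2 <- build_library(make_components(grid = fix_grid), fix_grid)
  expect_identical(lib2$d2, fix_lib$d2)
  expect_identical(lib2$condition_number, fix_lib$condition_number)
})

test_that("solve_concentrations handles pure, zero, and mixed inputs", {
  fv_w <- solve_concentrations(fix_lib$d2[, 1L], fix_lib)
  expect_lt(max(abs(fv_vec(fv_w) - c(1, 0, 0))), 1e-10)

  fv_0 <- solve_concentrations(rep(0, nrow(fix_lib$d2)), fix_lib)
  expect_equal(fv_vec(fv_0), c(0, 0, 0))
  expect_equal(fv_0$residual_norm, 0)

  truth <- c(0.2, 0.5, 0.3)
  b <- drop(fix_lib$d2 %*% truth)
  fv <- solve_concentrations(b, fix_lib)
  expect_lt(max(abs(fv_vec(fv) - truth)), 1e-8)
  # independent normal-equations pseudoinverse oracle
  expect_lt(max(abs(fv_vec(fv) - normal_equations_oracle(fix_lib$d2, b))), 1e-8)
  # residual orthogonal to the component columns
  r <- b - drop(fix_lib$d2 %*% fv_vec(fv))
  expect_lt(max(abs(crossprod(fix_lib$d2, r))), 1e-8 * sqrt(sum(b^2)))
})

test_that("unmix recovers generator ground truth and ignores baselines", {
  mix <- make_mixture(fix_comps, c(0.3, 0.5, 0.4))
  fv <- unmix(mix$spectrum, fix_lib)
  expect_lt(max(abs(fv_vec(fv) - c(0.3, 0.5, 0.4)) / c(0.3, 0.5, 0.4)), 1e-6)

  withb <- make_mixture(fix_comps, c(0.3, 0.5, 0.4), baseline = c(0.5, 0))
  fvb <- unmix(withb$spectrum, fix_lib)
  expect_lt(max(abs(fv_vec(fvb) - fv_vec(fv)) / abs(fv_vec(fv))), 0.01)

  slope <- make_mixture(fix_comps, c(0.3, 0.5, 0.4), baseline = c(0.2, 5e-5))
  fvs <- unmix(slope$spectrum, fix_lib)
  expect_lt(max(abs(fv_vec(fvs) - fv_vec(fv)) / abs(fv_vec(fv))), 0.01)
})

test_that("unmixing is scale-equivariant and linear", {
  mix <- make_mixture(fix_comps, c(0.3, 0.5, 0.4))
  fv1 <- fv_vec(unmix(mix$spectrum, fix_lib))
  for (l in c(0.5, 1.66, 3.0)) {
    scaled <- mix$spectrum
    scaled$absorbance <- scaled$absorbance * l
    fvl <- fv_vec(unmix(scaled, fix_lib))
    expect_lt(max(abs(fvl - l * fv1)), 1e-10 * max(1, l))
  }

  m1 <- make_mixture(fix_comps, c(0.6, 0.1, 0.2))$spectrum
  m2 <- make_mixture(fix_comps, c(0.1, 0.4, 0.7))$spectrum
  a <- 0.8; b <- 1.7
  comb <- m1
  comb$absorbance <- a * m1$absorbance + b * m2$absorbance
  lhs <- fv_vec(unmix(comb, fix_lib))
  rhs <- a * fv_vec(unmix(m1, fix_lib)) + b * fv_vec(unmix(m2, fix_lib))
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("exact recovery holds over random concentration draws", {
  set.seed(101)
  for (i in 1:25) {
    truth <- runif(3, 0.05, 1)
    mix <- make_mixture(fix_comps, truth)
    fv <- fv_vec(unmix(mix$spectrum, fix_lib))
    expect_lt(max(abs(fv - truth) / truth), 1e-6)
    # QR path vs normal-equations oracle on the same rows
    ev <- nirmix:::sample_d2_on_grid(mix$spectrum, fix_lib, smoothing_params())
    rows <- ev$mask & fix_lib$keep
    ne <- normal_equations_oracle(fix_lib$d2_full[rows, ], ev$d2[rows])
    expect_lt(max(abs(fv - ne) / pmax(abs(ne), 1e-12)), 1e-8)
  }
})

test_that("batch unmixing matches the per-spectrum path", {
  set.seed(55)
  spectra <- lapply(1:6, function(i) {
    make_mixture(fix_comps, runif(3, 0.1, 0.8), baseline = c(runif(1, 0, 0.2), 0),
                 noise_sd = 0.003, seed = 100 + i,
                 sample_id = paste0("s", i))$spectrum
  })
  batch <- unmix_spectra(spectra, fix_lib)
  single <- do.call(rbind, lapply(spectra, function(s)
    as.data.frame(unmix(s, fix_lib))))
  expect_equal(batch$c_w, single$c_w, tolerance = 1e-10)
  expect_equal(batch$c_c, single$c_c, tolerance = 1e-10)
  expect_equal(batch$c_p, single$c_p, tolerance = 1e-10)
  expect_equal(batch$residual_norm, single$residual_norm, tolerance = 1e-8)
})

test_that("the non-negativity option clips only infeasible solutions, optimally", {
  # unconstrained solution already non-negative: nonneg is a no-op
  b <- drop(fix_lib$d2 %*% c(0.2, 0.5, 0.3))
  expect_equal(fv_vec(solve_concentrations(b, fix_lib, nonneg = TRUE)),
               fv_vec(solve_concentrations(b, fix_lib)))

  # a target with a genuinely negative component: NNLS zeroes it and
  # refits the rest; the result must beat simple clipping of the LS fit
  b2 <- drop(fix_lib$d2 %*% c(0.4, -0.15, 0.3))
  free <- fv_vec(solve_concentrations(b2, fix_lib))
  expect_lt(free[2L], 0)
  nn <- solve_concentrations(b2, fix_lib, nonneg = TRUE)
  expect_true(all(fv_vec(nn) >= 0))
  clipped <- pmax(free, 0)
  rss_clip <- sum((b2 - drop(fix_lib$d2 %*% clipped))^2)
  expect_lte(nn$residual_norm^2, rss_clip + 1e-12)
})

test_that("concentration error grows with instrument noise", {
  set.seed(77)
  sds <- c(0, 0.002, 0.005, 0.01)
  err <- vapply(seq_along(sds), function(k) {
    mean(vapply(1:30, function(i) {
      truth <- runif(3, 0.1, 0.8)
      mix <- make_mixture(fix_comps, truth, noise_sd = sds[k])
      mean(abs(fv_vec(unmix(mix$spectrum, fix_lib)) - truth))
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(err) >= 0))
  expect_equal(err[1L], 0, tolerance = 1e-8)
})

test_that("window stability: one window equals the full solve, noiseless windows agree", {
  mix <- make_mixture(fix_comps, c(0.3, 0.5, 0.4))
  full <- unmix(mix$spectrum, fix_lib)
  ws1 <- window_stability(mix$spectrum, fix_lib,
                          windows = list(c(4000, 10000)))
  expect_lt(max(abs(as.numeric(ws1$features[1L, c("c_w", "c_c", "c_p")]) -
                      fv_vec(full))), 1e-10)

  wins <- list(c(4100, 5550), c(5550, 7000), c(7000, 8450), c(8450, 9900))
  ws <- window_stability(mix$spectrum, fix_lib, windows = wins)
  M <- as.matrix(ws$features[, c("c_w", "c_c", "c_p")])
  expect_lt(max(abs(sweep(M, 2L, c(0.3, 0.5, 0.4))) / 0.3), 1e-6)
  expect_lt(max(ws$dispersion), 1e-6)

  noisy <- make_mixture(fix_comps, c(0.3, 0.5, 0.4), noise_sd = 0.005,
                        seed = 8)$spectrum
  wsn <- window_stability(noisy, fix_lib, windows = wins)
  expect_true(all(is.finite(wsn$dispersion)))
  expect_gt(max(wsn$dispersion), max(ws$dispersion))

  expect_error(window_stability(mix$spectrum, fix_lib,
                                windows = list(c(4000, 4100))),
               "grid points")
})
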