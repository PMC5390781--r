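# shared fixtures, built once per test run; a 300-point grid keeps unit
# tests fast while exercising the same code paths as the full-resolution
# 779-point analysis grid used in the acceptance checks

fix_grid <- spectral_grid(4000, 10000, 300)
fix_comps <- make_components(grid = fix_grid)
fix_lib <- build_library(fix_comps, fix_grid)

full_grid <- spectral_grid()

# independent normal-equations pseudoinverse oracle for the CLS solve:
# c = (E'E)^{-1} E' b, deliberately not using QR
normal_equations_oracle <- function(E, b) {
  drop(solve(crossprod(E), crossprod(E, b)))
}

# brute-force run enumeration for the tau knot rule: returns the index
# ranges of maximal runs of consecutive points with |dy| <= tau
enumerate_runs <- function(y, tau) {
  runs <- list(c(1L, 1L))
  for (i in seq_along(y)[-1L]) {
    if (abs(y[i] - y[i - 1L]) <= tau) {
      runs[[length(runs)]][2L] <- i
    } else {
      runs[[length(runs) + 1L]] <- c(i, i)
    }
  }
  runs
}

fv_vec <- function(fv) c(fv$c_w, fv$c_c, fv$c_p)
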