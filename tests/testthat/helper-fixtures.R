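# Shared fixtures for the suite. Everything is generated in code; the only
# expensive object (the form-factor interpolation table for the standard
# 200-point q grid) is built lazily once and shared across test files.

.fixture_env <- new.env(parent = emptyenv())

# the standard simulation grid: 200 log-spaced points over 0.05-1 nm^-1
std_q_grid <- function(n = 200L) {
  exp(seq(log(0.05), log(1), length.out = n))
}

# ground truth used throughout for the untreated-like condition:
# cross-section 2r = 12 nm, stacking d = 24 nm
untreated_truth <- function() {
  saxs_params(
    A = 1, r = 6, sigma_r = 0.25, L = 1000, d = 24, nu = 1,
    B = 1e-5, n_exp = 1, C = 2e-6
  )
}

treated_truth <- function() {
  saxs_params(
    A = 1, r = 4, sigma_r = 0.25, L = 1000, d = 20, nu = 1,
    B = 1e-5, n_exp = 1, C = 2e-6
  )
}

shared_ff_table <- function(q = std_q_grid()) {
  key <- paste0("ff_", length(q), "_", signif(min(q), 8), "_",
                signif(max(q), 8))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- form_factor_table(q, L = 1000)
  }
  .fixture_env[[key]]
}

# independent slow oracle for the orientation average: plain trapezoidal
# quadrature over the orientation angle with n nodes (scalar r, vector q)
brute_cylinder_ff <- function(q, r, L, n = 10000L) {
  stopifnot(length(r) == 1L)
  vapply(q, function(qi) {
    a <- seq(1e-9, pi / 2, length.out = n)
    f <- fibrilscape:::sinc(qi * L / 2 * cos(a))^2 *
      fibrilscape:::bessel_cs(qi * r * sin(a))^2 * sin(a)
    sum((f[-1] + f[-n]) / 2 * diff(a))
  }, numeric(1))
}

# same oracle for one q and a whole radius grid at once (matrix form)
brute_cylinder_ff_grid <- function(q, r_vec, L, n = 6000L) {
  stopifnot(length(q) == 1L)
  a <- seq(1e-9, pi / 2, length.out = n)
  ax <- fibrilscape:::sinc(q * L / 2 * cos(a))^2 * sin(a)
  cs2 <- fibrilscape:::bessel_cs(outer(sin(a) * q, r_vec))^2
  f <- cs2 * ax
  da <- a[2] - a[1]
  colSums((f[-1, , drop = FALSE] + f[-n, , drop = FALSE]) / 2) * da
}
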