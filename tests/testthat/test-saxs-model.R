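# Forward scattering model: form factor, polydispersity, structure factor,
# composed intensity, and the derived analyses.

test_that("cylinder form factor is normalised and matches a brute-force quadrature", {
  expect_equal(cylinder_form_factor(1e-6, r = 4, L = 1000), 1,
    tolerance = 1e-4
  )
  # fine-grid trapezoid oracle, several regimes of (q r, q L)
  cases <- expand.grid(q = c(0.02, 0.1, 0.5, 1.5), r = c(2, 4, 8))
  for (i in seq_len(nrow(cases))) {
    q <- cases$q[i]
    r <- cases$r[i]
    expect_equal(
      cylinder_form_factor(q, r, 1000),
      brute_cylinder_ff(q, r, 1000),
      tolerance = 1e-4
    )
  }
  # bounded in (0, 1]
  p <- cylinder_form_factor(std_q_grid(50), r = 5, L = 1000)
  expect_true(all(p > 0 & p <= 1))
})

test_that("thin-rod regime precondition is enforced", {
  expect_error(cylinder_form_factor(0.1, r = 10, L = 100), "L >= 20")
  expect_error(cylinder_form_factor(-0.1, r = 4, L = 1000), "positive")
})

test_that("long rods scatter as q^-1 in the rod window", {
  q <- exp(seq(log(0.02), log(0.1), length.out = 40))
  prof <- saxs_profile(q, cylinder_form_factor(q, r = 4, L = 1000))
  fit <- powerlaw_slope(prof, 0.02, 0.1)
  expect_equal(fit$alpha, 1, tolerance = 0.15)
})

test_that("rod scaling alpha = 1 holds across aspect ratios (property)", {
  for (case in list(c(r = 3, L = 600), c(r = 5, L = 1000),
                    c(r = 8, L = 2000))) {
    q_lo <- 3 * 2 * pi / case["L"]
    q_hi <- 1 / (2 * case["r"])
    q <- exp(seq(log(q_lo), log(q_hi), length.out = 30))
    prof <- saxs_profile(q, cylinder_form_factor(q, case["r"], case["L"]))
    expect_equal(powerlaw_slope(prof, q_lo, q_hi)$alpha, 1,
      tolerance = 0.15
    )
  }
})

test_that("log-normal weights normalise, centre on the median, and collapse to a delta", {
  g <- exp(seq(log(2), log(18), length.out = 41))
  w <- lognormal_weights(6, 0.25, g)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # weighted median of the discretised distribution within one grid step
  med <- g[which(cumsum(w) >= 0.5)[1]]
  step <- g[2] / g[1]
  expect_true(med / step <= 6 && med * step >= 6)
  # sigma -> 0: all mass on the point nearest the median
  w0 <- lognormal_weights(6, 1e-6, g)
  expect_equal(max(w0), 1)
  expect_equal(g[which.max(w0)], g[which.min(abs(log(g) - log(6)))])
  # grid that truncates the distribution is refused
  expect_error(lognormal_weights(6, 0.5, g), "cover")
})

test_that("PRISM structure factor has the right limits and peak calibration", {
  q <- seq(0.01, 3, by = 0.002)
  expect_equal(prism_structure_factor(q, 24, 0), rep(1, length(q)))
  expect_error(prism_structure_factor(q, 24, -0.5), "attractive")
  # high-q limit
  expect_lt(abs(prism_structure_factor(200 / 24, 24, 1) - 1), 0.01)
  # low-q suppression for repulsive nu
  expect_lt(prism_structure_factor(0.01, 24, 1), 1)
  # calibration: first maximum at 2*pi/d within 2% across the working range
  for (nu in c(0.5, 1, 3)) {
    for (d in c(10, 24, 40)) {
      qd <- seq(0.5 * 2 * pi / d, 1.8 * 2 * pi / d, length.out = 4000)
      s <- prism_structure_factor(qd, d, nu)
      expect_equal(2 * pi / qd[which.max(s)], d, tolerance = 0.02)
    }
  }
})

test_that("model intensity reduces to its parts and refines stably", {
  q <- std_q_grid(60)
  # bare form factor
  pars <- saxs_params(A = 2, r = 5, sigma_r = 0, d = 24, nu = 0,
                      B = 0, n_exp = 1, C = 0)
  expect_equal(model_intensity(q, pars),
    2 * cylinder_form_factor(q, 5, 1000),
    tolerance = 1e-3
  )
  # background only
  pars_bkg <- saxs_params(A = 0, r = 5, sigma_r = 0.2, d = 24, nu = 1,
                          B = 3e-4, n_exp = 1.5, C = 1e-5)
  expect_identical(model_intensity(q, pars_bkg), 3e-4 / q^1.5 + 1e-5)
  # 41-point polydispersity grid vs a 2001-point refinement
  tr <- untreated_truth()
  expect_equal(model_intensity(q, tr, n_r = 41L),
    model_intensity(q, tr, n_r = 2001L),
    tolerance = 5e-3
  )
  expect_true(all(model_intensity(q, tr) > 0))
})

test_that("model intensity agrees with a high-resolution quadrature oracle", {
  # independent path: trapezoid orientation average on a fine grid plus a
  # dense polydispersity sum, on q spanning 0.05-2 nm^-1
  q <- exp(seq(log(0.05), log(2), length.out = 12))
  tr <- untreated_truth()
  r_grid <- exp(seq(log(tr$r) - 4 * tr$sigma_r, log(tr$r) + 4 * tr$sigma_r,
    length.out = 401
  ))
  w <- lognormal_weights(tr$r, tr$sigma_r, r_grid)
  oracle <- vapply(q, function(qi) {
    pf <- sum(brute_cylinder_ff_grid(qi, r_grid, tr$L) * w)
    tr$A * pf * prism_structure_factor(qi, tr$d, tr$nu) +
      tr$B / qi^tr$n_exp + tr$C
  }, numeric(1))
  expect_equal(model_intensity(q, tr), oracle, tolerance = 5e-3)
})

test_that("polydisperse cross-section term decays with a Porod-like exponent", {
  q <- exp(seq(log(0.5), log(3), length.out = 120))
  pars <- saxs_params(A = 1, r = 6, sigma_r = 0.25, d = 24, nu = 0,
                      B = 0, n_exp = 1, C = 0)
  prof <- saxs_profile(q, model_intensity(q, pars))
  alpha <- powerlaw_slope(prof, 1, 3)$alpha
  expect_gte(alpha, 3)
  expect_lte(alpha, 4.3)
})

test_that("power-law slope recovers exact exponents", {
  q <- exp(seq(log(0.02), log(0.2), length.out = 30))
  expect_equal(powerlaw_slope(saxs_profile(q, q^-1), 0.02, 0.2)$alpha, 1,
    tolerance = 1e-9
  )
  expect_equal(powerlaw_slope(saxs_profile(q, q^-4), 0.02, 0.2)$alpha, 4,
    tolerance = 1e-9
  )
  expect_error(powerlaw_slope(saxs_profile(q, q^-1), 0.02, 0.022), ">= 5")
})

test_that("correlation peak is found on structure factors and read as 2*pi/q_max", {
  qs <- seq(0.08, 1, by = 0.002)
  for (d in c(20, 24)) {
    pk <- find_correlation_peak(
      saxs_profile(qs, prism_structure_factor(qs, d, 1)), c(0.12, 0.45)
    )
    expect_true(pk$found)
    expect_equal(pk$d_eff, d, tolerance = 0.02)
    expect_identical(pk$d_eff, 2 * pi / pk$q_max)
  }
  # arithmetic convention: a peak at 0.25 nm^-1 means 25.13 nm
  expect_equal(q_to_d(0.25), 25.13, tolerance = 1e-3)
})

test_that("monotone profiles report no peak; bundled profiles report one", {
  q <- std_q_grid()
  none <- saxs_params(A = 1, r = 6, sigma_r = 0.25, d = 24, nu = 0,
                      B = 1e-5, n_exp = 1, C = 2e-6)
  pk0 <- find_correlation_peak(saxs_profile(q, model_intensity(q, none)))
  expect_false(pk0$found)
  pk1 <- find_correlation_peak(
    saxs_profile(q, model_intensity(q, untreated_truth()))
  )
  expect_true(pk1$found)
  expect_equal(pk1$d_eff, 24, tolerance = 0.15)
  # robust under 2% noise: no false peak without interaction, a peak with
  set.seed(301)
  I0 <- model_intensity(q, none) * (1 + 0.02 * rnorm(length(q)))
  expect_false(find_correlation_peak(saxs_profile(q, I0))$found)
  set.seed(302)
  I1 <- model_intensity(q, untreated_truth()) *
    (1 + 0.02 * rnorm(length(q)))
  expect_true(find_correlation_peak(saxs_profile(q, I1))$found)
})

test_that("modified Guinier analysis recovers homogeneous cylinder radii", {
  q <- exp(seq(log(0.05), log(0.5), length.out = 80))
  for (r in c(4, 6)) {
    prof <- saxs_profile(q, cylinder_form_factor(q, r, 1000))
    g <- cross_section_guinier(prof, c(0.1, 0.5))
    expect_equal(g$implied_radius, r, tolerance = 0.05)
    expect_equal(g$R_c, r / sqrt(2), tolerance = 0.05)
    expect_lte(max(g$q_range) * g$R_c, 1.3 + 1e-9)
  }
  # a flat profile has no cross-sectional decay
  flat <- cross_section_guinier(saxs_profile(q, rep(1, length(q))))
  expect_true(flat$warning)
  expect_true(is.na(flat$R_c))
})

test_that("profile text round trip preserves data and handles Angstrom units", {
  q <- std_q_grid(40)
  prof <- gen_saxs_curve(untreated_truth(), q,
    noise_spec("multiplicative-gaussian", 0.02, seed = 5),
    label = "roundtrip"
  )
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(prof, path)
  back <- read_saxs_profile(path, label = "roundtrip")
  expect_equal(back$q, prof$q)
  expect_equal(back$intensity, prof$intensity)
  expect_equal(back$sigma, prof$sigma)
  # Angstrom^-1 input is converted by x10
  ang <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q[A^-1] I", "0.01 10", "0.02 5"), ang)
  expect_equal(read_saxs_profile(ang, angstrom = TRUE)$q, c(0.1, 0.2))
})

test_that("profile constructor rejects malformed input", {
  expect_error(saxs_profile(c(0.1, 0.1), c(1, 1)), "increasing")
  expect_error(saxs_profile(c(-0.1, 0.2), c(1, 1)), "positive")
  expect_error(saxs_profile(c(0.1, 0.2), 1), "length")
})
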