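# 1D spectrum window integration, normalisation and noise propagation.

test_that("window integration matches closed-form Gaussian areas", {
  sd <- 0.5
  amp <- 1 / (sd * sqrt(2 * pi)) # unit-area line
  spec <- gen_nmr_spectrum(list(nmr_peak(56, sd, amp)),
    seq(40, 75, by = 0.01)
  )
  # a window spanning > 6 sd captures essentially everything
  area <- integrate_window(spec, c(58.99, 51.79))
  expect_gte(area, 0.99)
  expect_equal(area, 1, tolerance = 1e-3)
  # closed form amplitude * sd * sqrt(2*pi) within 0.1%
  spec2 <- gen_nmr_spectrum(list(nmr_peak(56, 0.8, 2.5)),
    seq(40, 75, by = 0.01)
  )
  expect_equal(integrate_window(spec2, c(62, 50)),
    2.5 * 0.8 * sqrt(2 * pi),
    tolerance = 1e-3
  )
})

test_that("integration is linear, additive over adjacent windows, and zero on silence", {
  grid <- seq(40, 75, by = 0.013) # deliberately irregular-ish step
  silent <- gen_nmr_spectrum(list(), grid)
  expect_identical(integrate_window(silent, c(60, 50)), 0)
  spec <- gen_nmr_spectrum(
    list(nmr_peak(56, 0.8, 2), nmr_peak(53, 1.2, 1, shape = "lorentzian")),
    grid
  )
  whole <- integrate_window(spec, c(60, 48))
  halves <- integrate_window(spec, c(60, 54.13)) +
    integrate_window(spec, c(54.13, 48))
  expect_equal(halves, whole, tolerance = 1e-12)
})

test_that("integrals are invariant to the stored axis direction", {
  grid <- seq(40, 75, by = 0.02)
  up <- gen_nmr_spectrum(list(nmr_peak(56, 0.8, 2)), grid) # ascending input
  # the same (ppm, intensity) pairs handed over in descending-axis order
  down <- nmr_spectrum(up$ppm, up$intensity)
  w <- window_scheme("batch2")$QCa
  expect_equal(integrate_window(up, w), integrate_window(down, w))
})

test_that("built-in batch schemes carry the published window bounds", {
  b1 <- window_scheme("batch1")
  expect_equal(
    unlist(lapply(b1, function(w) c(w$ppm_hi, w$ppm_lo))),
    c(PCa1 = 68.31, PCa2 = 60.68, QCa1 = 60.68, QCa2 = 53.40,
      PCd1 = 53.40, PCd2 = 47.78)
  )
  b2 <- window_scheme("batch2")
  expect_equal(
    unlist(lapply(b2, function(w) c(w$ppm_hi, w$ppm_lo))),
    c(PCa1 = 66.70, PCa2 = 58.99, QCa1 = 58.99, QCa2 = 51.79,
      PCd1 = 51.79, PCd2 = 46.01)
  )
  # contiguous, non-overlapping
  expect_identical(b1$PCa$ppm_lo, b1$QCa$ppm_hi)
  expect_identical(b1$QCa$ppm_lo, b1$PCd$ppm_hi)
})

test_that("windows outside the spectral range are refused", {
  spec <- gen_nmr_spectrum(list(nmr_peak(56, 0.5, 1)), seq(50, 60, 0.01))
  expect_error(integrate_window(spec, c(70, 65)), "outside")
})

test_that("Q/P area ratios reflect generated amplitudes and ignore overall scale", {
  grid <- seq(40, 80, by = 0.01)
  # glutamine line twice the proline lines, equal widths
  peaks <- list(
    nmr_peak(62, 0.5, 1), # in PCa window (batch2: 66.70-58.99)
    nmr_peak(56, 0.5, 2), # in QCa window (58.99-51.79)
    nmr_peak(48.5, 0.5, 1) # in PCd window (51.79-46.01)
  )
  spec <- gen_nmr_spectrum(peaks, grid)
  qp <- qp_ratios(spec, window_scheme("batch2"))
  expect_equal(qp$q_to_pca, 2, tolerance = 1e-3)
  expect_equal(qp$q_to_pcd, 2, tolerance = 1e-3)
  # QCa-max normalisation: the QCa window's normalised area is area / height
  expect_equal(qp$qca_max, 2, tolerance = 1e-6)
  # doubling the spectrum changes no normalised quantity
  spec2 <- nmr_spectrum(spec$ppm, spec$intensity * 2)
  qp2 <- qp_ratios(spec2, window_scheme("batch2"))
  expect_equal(qp2$normalized, qp$normalized)
  expect_equal(qp2$q_to_pca, qp$q_to_pca)
})

test_that("raising proline amplitudes strictly lowers the Q/P ratio", {
  grid <- seq(40, 80, by = 0.02)
  ratios <- vapply(c(0.5, 1, 1.5, 2), function(amp_p) {
    spec <- gen_nmr_spectrum(list(
      nmr_peak(62, 0.5, amp_p), nmr_peak(56, 0.5, 2),
      nmr_peak(48.5, 0.5, amp_p)
    ), grid)
    qp_ratios(spec, window_scheme("batch2"))$q_to_pca
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("an empty QCa window cannot be used for normalisation", {
  spec <- gen_nmr_spectrum(list(), seq(40, 80, 0.02))
  expect_error(qp_ratios(spec, window_scheme("batch1")), "noise floor")
})

test_that("noise errors estimate the injected noise and scale as sqrt(n)", {
  grid <- seq(30, 80, by = 0.01)
  clean <- gen_nmr_spectrum(list(nmr_peak(56, 0.5, 2)), grid)
  err0 <- noise_error(clean, c(35, 45), window_scheme("batch2"))
  expect_lt(max(err0), 1e-9)
  sigma0 <- 0.05
  noisy <- gen_nmr_spectrum(list(nmr_peak(56, 0.5, 2)), grid,
    noise_spec("additive-gaussian", sigma0, seed = 12)
  )
  err <- noise_error(noisy, c(33, 43), window_scheme("batch2"))
  expect_equal(attr(err, "noise_sd"), sigma0, tolerance = 0.15)
  # area error = sd * step * sqrt(n): windows' errors scale as sqrt(width)
  n1 <- sum(grid >= 58.99 & grid <= 66.70)
  n2 <- sum(grid >= 51.79 & grid <= 58.99)
  expect_equal(err[["PCa"]] / err[["QCa"]], sqrt(n1 / n2),
    tolerance = 1e-6
  )
  # region overlapping a window is refused
  expect_error(noise_error(noisy, c(50, 55), window_scheme("batch2")),
    "overlaps"
  )
})

test_that("spectrum text IO round-trips", {
  spec <- gen_nmr_spectrum(list(nmr_peak(56, 0.8, 2)), seq(40, 75, 0.05),
    noise_spec("additive-gaussian", 0.01, seed = 3),
    label = "batch1 control"
  )
  path <- withr::local_tempfile(fileext = ".dat")
  write_nmr_spectrum(spec, path)
  back <- read_nmr_spectrum(path, label = "batch1 control")
  expect_equal(back$ppm, spec$ppm)
  expect_equal(back$intensity, spec$intensity)
})
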