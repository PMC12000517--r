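# Seeded synthetic-data generators. Each generator is a pure function of
# its parameters and seed, producing inputs with the statistical structure
# the corresponding analysis stage assumes, so the whole pipeline can be
# exercised end to end without instrument data.

#' Noise specification for synthetic data
#'
#' @param kind `"none"`, `"multiplicative-gaussian"` (level is a relative
#'   fraction: `x * (1 + level * N(0,1))`) or `"additive-gaussian"` (level
#'   is an absolute a.u. amount).
#' @param level Noise level (>= 0): a fraction for multiplicative noise, an
#'   absolute amount for additive.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `noise_spec` list.
#' @export
#' @examples
#' noise_spec("multiplicative-gaussian", 0.02, seed = 1)
noise_spec <- function(kind = c("none", "multiplicative-gaussian",
                                "additive-gaussian"),
                       level = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(level) || level < 0) stop("noise level must be >= 0")
  structure(
    list(kind = kind, level = level, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

# apply a noise_spec to a clean vector; returns list(values, sigma)
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  switch(noise$kind,
    none = list(values = x, sigma = rep(0, length(x))),
    `multiplicative-gaussian` = {
      eps <- with_seed(noise$seed, stats::rnorm(length(x)))
      list(values = x * (1 + noise$level * eps), sigma = noise$level * x)
    },
    `additive-gaussian` = {
      eps <- with_seed(noise$seed, stats::rnorm(length(x)))
      list(
        values = x + noise$level * eps,
        sigma = rep(noise$level, length(x))
      )
    }
  )
}

#' Simulate a SAXS profile from the bundled-fibril model
#'
#' Forward-simulates the full scattering model on a q grid and perturbs it
#' with the requested noise; the per-point noise level is stored in the
#' profile's sigma column. The default noise for simulated SAXS curves in
#' this package is 2% multiplicative Gaussian.
#'
#' @param params A [saxs_params] ground truth.
#' @param q_grid Strictly positive, strictly increasing q values, nm^-1.
#' @param noise A [noise_spec] (default: none).
#' @param label Curve label.
#' @return A [saxs_profile] with sigma column.
#' @export
#' @examples
#' q <- exp(seq(log(0.05), log(1), length.out = 200))
#' gen_saxs_curve(saxs_params(r = 6, d = 24), q,
#'   noise_spec("multiplicative-gaussian", 0.02, seed = 7))
gen_saxs_curve <- function(params, q_grid, noise = noise_spec("none"),
                           label = "") {
  if (any(!is.finite(q_grid)) || any(q_grid <= 0))
    stop("q_grid must be finite and strictly positive")
  if (any(diff(q_grid) <= 0)) stop("q_grid must be strictly increasing")
  clean <- model_intensity(q_grid, params)
  nz <- apply_noise(clean, noise)
  saxs_profile(q_grid, nz$values, sigma = nz$sigma, label = label)
}

#' Simulate TEM fibril-width measurements
#'
#' Draws widths from a normal distribution truncated below at 0.5 nm (a
#' physical floor: nothing narrower is resolvable or plausible as a fibril),
#' emulating per-condition width histograms.
#'
#' @param mean_nm Mean width, nm (> 0).
#' @param sd_nm Width SD, nm (>= 0; 0 gives identical measurements).
#' @param n Number of measurements (>= 1).
#' @param seed Integer seed.
#' @param condition Condition label for the sample.
#' @return A [width_sample].
#' @export
#' @examples
#' gen_tem_widths(10, 1.5, 100, seed = 1, condition = "no curcumin")
gen_tem_widths <- function(mean_nm, sd_nm, n, seed = 1L, condition = "") {
  if (!is.finite(mean_nm) || mean_nm <= 0) stop("mean_nm must be > 0")
  if (!is.finite(sd_nm) || sd_nm < 0) stop("sd_nm must be >= 0")
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1")
  floor_nm <- 0.5
  w <- with_seed(seed, {
    if (sd_nm == 0) {
      rep(mean_nm, n)
    } else {
      out <- numeric(0)
      while (length(out) < n) {
        draw <- stats::rnorm(2L * (n - length(out)), mean_nm, sd_nm)
        out <- c(out, draw[draw >= floor_nm])
      }
      out[seq_len(n)]
    }
  })
  width_sample(w, condition = condition)
}

#' Generator parameters for sigmoidal aggregation curves
#'
#' A logistic time course `baseline + (plateau - baseline) /
#' (1 + exp(-rate * (t - t_mid)))` with `t_mid = lag_h + 2/rate`, so that
#' the tangent at the steepest point intersects the baseline exactly at
#' `lag_h` — the generator's lag is by construction the tangent-intercept
#' lag that [lag_time()] extracts. Lag and steepness are independent knobs,
#' matching how inhibitors can lengthen the lag phase and change the growth
#' steepness separately.
#'
#' @param lag_h Lag time in hours (>= 0).
#' @param rate Logistic growth rate, 1/h (> 0).
#' @param plateau Plateau signal, a.u. (> baseline).
#' @param baseline Baseline signal, a.u. (>= 0).
#' @param sampling_interval_h Sampling interval in hours (default 0.25,
#'   i.e. a reading every 15 minutes).
#' @return A `tht_gen_params` list.
#' @export
tht_gen_params <- function(lag_h = 5, rate = 2, plateau = 1, baseline = 0,
                           sampling_interval_h = 0.25) {
  if (!is.finite(lag_h) || lag_h < 0) stop("lag_h must be >= 0")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (!is.finite(baseline) || baseline < 0) stop("baseline must be >= 0")
  if (!is.finite(plateau) || plateau <= baseline)
    stop("plateau must be > baseline")
  if (!is.finite(sampling_interval_h) || sampling_interval_h <= 0)
    stop("sampling_interval_h must be > 0")
  structure(
    list(
      lag_h = lag_h, rate = rate, plateau = plateau, baseline = baseline,
      sampling_interval_h = sampling_interval_h
    ),
    class = "tht_gen_params"
  )
}

#' Simulate a fluorescence aggregation time course
#'
#' @param gp A [tht_gen_params] parameter set.
#' @param duration_h Total duration in hours; must exceed `gp$lag_h`.
#' @param noise A [noise_spec].
#' @param replicate_id,condition Labels for the curve.
#' @return A [tht_curve].
#' @export
#' @examples
#' gp <- tht_gen_params(lag_h = 5, rate = 2, plateau = 1)
#' lag_time(gen_tht_curve(gp, 24))$lag_h # ~ 5 h
gen_tht_curve <- function(gp, duration_h, noise = noise_spec("none"),
                          replicate_id = "", condition = "") {
  stopifnot(inherits(gp, "tht_gen_params"))
  if (!is.finite(duration_h) || duration_h <= gp$lag_h)
    stop("duration_h must exceed the lag time")
  tt <- seq(0, duration_h, by = gp$sampling_interval_h)
  t_mid <- gp$lag_h + 2 / gp$rate
  clean <- gp$baseline + (gp$plateau - gp$baseline) /
    (1 + exp(-gp$rate * (tt - t_mid)))
  nz <- apply_noise(clean, noise)
  tht_curve(tt, nz$values, replicate_id = replicate_id,
            condition = condition)
}

#' Analytic peak specification for synthetic 1D spectra
#'
#' @param center_ppm Peak centre, ppm.
#' @param width_ppm Width parameter, ppm (> 0): the Gaussian SD, or the
#'   Lorentzian half-width at half-maximum.
#' @param amplitude Peak height, a.u. (>= 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return An `nmr_peak_spec` list.
#' @export
nmr_peak <- function(center_ppm, width_ppm, amplitude = 1,
                     shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.finite(width_ppm) || width_ppm <= 0) stop("width_ppm must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  structure(
    list(center_ppm = center_ppm, width_ppm = width_ppm,
         amplitude = amplitude, shape = shape),
    class = "nmr_peak_spec"
  )
}

#' Simulate a 1D spectrum as a sum of analytic peaks
#'
#' Emulates a 1D cross-polarisation spectrum: a sum of Gaussian and/or
#' Lorentzian lines at given chemical shifts (e.g. glutamine and proline
#' carbon positions) plus optional baseline noise.
#'
#' @param peaks List of [nmr_peak()] specifications (may be empty).
#' @param ppm_grid Monotone ppm axis.
#' @param noise A [noise_spec] (additive noise emulates baseline noise).
#' @param label Spectrum label.
#' @return An [nmr_spectrum()].
#' @export
#' @examples
#' s <- gen_nmr_spectrum(
#'   list(nmr_peak(56, 0.8, 2), nmr_peak(62, 0.8, 1)),
#'   seq(40, 75, by = 0.02)
#' )
gen_nmr_spectrum <- function(peaks, ppm_grid, noise = noise_spec("none"),
                             label = "") {
  if (length(ppm_grid) < 2 ||
    !(all(diff(ppm_grid) > 0) || all(diff(ppm_grid) < 0)))
    stop("ppm_grid must be strictly monotone")
  clean <- rep(0, length(ppm_grid))
  for (pk in peaks) {
    stopifnot(inherits(pk, "nmr_peak_spec"))
    dx <- ppm_grid - pk$center_ppm
    clean <- clean + switch(pk$shape,
      gaussian = pk$amplitude * exp(-dx^2 / (2 * pk$width_ppm^2)),
      lorentzian = pk$amplitude * pk$width_ppm^2 /
        (dx^2 + pk$width_ppm^2)
    )
  }
  nz <- apply_noise(clean, noise)
  nmr_spectrum(ppm_grid, nz$values, label = label)
}
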