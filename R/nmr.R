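# 1D solid-state NMR window integration: PCa / QCa / PCd peak areas,
# QCa-maximum normalisation, Q/P ratios and noise-based error bars. The
# glutamine (fibril core) vs proline (proline-rich flanking domain, PRD)
# signal ratio in cross-polarisation spectra reports on flanking-domain
# rigidity.

#' Construct a 1D NMR spectrum
#'
#' @param ppm Chemical-shift axis (monotone, either direction; stored
#'   internally in decreasing-ppm order, the conventional display order).
#' @param intensity Intensities (a.u.), same length.
#' @param label Sample / batch label.
#' @return An `nmr_spectrum_1d`: data frame with columns `ppm`, `intensity`
#'   (decreasing ppm) and a `label` attribute.
#' @export
nmr_spectrum <- function(ppm, intensity, label = "") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) < 2) stop("need at least 2 points")
  if (length(intensity) != length(ppm))
    stop("ppm and intensity must have equal length")
  d <- diff(ppm)
  if (all(d > 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone")
  }
  structure(
    data.frame(ppm = ppm, intensity = intensity),
    label = as.character(label)[1],
    class = c("nmr_spectrum_1d", "data.frame")
  )
}

#' @export
print.nmr_spectrum_1d <- function(x, ...) {
  cat(sprintf(
    "<nmr_spectrum_1d> %s%d points, %.2f to %.2f ppm\n",
    if (nzchar(attr(x, "label"))) paste0("'", attr(x, "label"), "': ") else "",
    nrow(x), x$ppm[1], x$ppm[nrow(x)]
  ))
  invisible(x)
}

#' Named ppm integration window
#'
#' @param name Window name, one of `"PCa"`, `"QCa"`, `"PCd"` (proline and
#'   glutamine alpha-carbons, proline delta-carbon).
#' @param ppm_hi,ppm_lo Window edges in ppm, `ppm_hi > ppm_lo`.
#' @return An `integration_window` list.
#' @export
integration_window <- function(name, ppm_hi, ppm_lo) {
  if (ppm_hi <= ppm_lo) stop("ppm_hi must be > ppm_lo")
  structure(
    list(name = as.character(name), ppm_hi = ppm_hi, ppm_lo = ppm_lo),
    class = "integration_window"
  )
}

#' Built-in integration schemes for the two fibril batches
#'
#' The per-batch ppm windows used for the PCa / QCa / PCd area analysis of
#' the 13C cross-polarisation spectra. The two batches were referenced
#' slightly differently, hence two schemes:
#' batch 1 — PCa 68.31-60.68, QCa 60.68-53.40, PCd 53.40-47.78 ppm;
#' batch 2 — PCa 66.70-58.99, QCa 58.99-51.79, PCd 51.79-46.01 ppm.
#' Windows within a scheme are contiguous and non-overlapping.
#'
#' @param batch `"batch1"` or `"batch2"`.
#' @return A named list of three [integration_window] objects.
#' @export
#' @examples
#' window_scheme("batch1")$QCa
window_scheme <- function(batch = c("batch1", "batch2")) {
  batch <- match.arg(batch)
  edges <- switch(batch,
    batch1 = c(68.31, 60.68, 53.40, 47.78),
    batch2 = c(66.70, 58.99, 51.79, 46.01)
  )
  list(
    PCa = integration_window("PCa", edges[1], edges[2]),
    QCa = integration_window("QCa", edges[2], edges[3]),
    PCd = integration_window("PCd", edges[3], edges[4])
  )
}

#' Trapezoidal area of a spectrum over a ppm window
#'
#' Integrates intensity over `[ppm_lo, ppm_hi]` by the trapezoidal rule on
#' the native grid, with the window edges included by linear interpolation
#' (so splitting a window into adjacent halves is exactly additive).
#'
#' @param spec An [nmr_spectrum()] object.
#' @param w An [integration_window()] (or length-2 numeric `c(hi, lo)`).
#' @return Area in a.u. * ppm.
#' @export
integrate_window <- function(spec, w) {
  stopifnot(inherits(spec, "nmr_spectrum_1d"))
  if (is.numeric(w) && length(w) == 2) {
    w <- integration_window("window", max(w), min(w))
  }
  stopifnot(inherits(w, "integration_window"))
  pa <- rev(spec$ppm) # ascending
  ia <- rev(spec$intensity)
  if (w$ppm_lo < pa[1] || w$ppm_hi > pa[length(pa)]) {
    stop(sprintf(
      "window [%g, %g] outside spectral range [%g, %g] ppm",
      w$ppm_lo, w$ppm_hi, pa[1], pa[length(pa)]
    ))
  }
  inside <- pa > w$ppm_lo & pa < w$ppm_hi
  edge <- stats::approx(pa, ia, xout = c(w$ppm_lo, w$ppm_hi))$y
  x <- c(w$ppm_lo, pa[inside], w$ppm_hi)
  y <- c(edge[1], ia[inside], edge[2])
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Window areas, QCa-max normalisation and Q/P ratios
#'
#' Integrates the three named windows, normalises every area by the maximum
#' intensity found inside the QCa window (the glutamine alpha-carbon peak,
#' by far the strongest signal in a rigid polyQ core), and reports the
#' glutamine-to-proline area ratios `QCa:PCa` and `QCa:PCd`. A falling Q/P
#' ratio means relatively more proline signal in the cross-polarisation
#' spectrum — the signature of a PRD that is more rigid than usual.
#'
#' @param spec An [nmr_spectrum()] object.
#' @param scheme A named list of [integration_window()]s covering `PCa`,
#'   `QCa`, `PCd` (see [window_scheme()]).
#' @param noise_floor Intensity level below which the QCa maximum is
#'   considered absent (default 0): an error, since normalisation would be
#'   meaningless.
#' @return A `qp_ratios` list: `areas`, `normalized` (areas / QCa max
#'   intensity), `qca_max`, `q_to_pca`, `q_to_pcd`.
#' @export
qp_ratios <- function(spec, scheme = window_scheme("batch1"),
                      noise_floor = 0) {
  need <- c("PCa", "QCa", "PCd")
  if (!all(need %in% names(scheme)))
    stop("scheme must contain windows named PCa, QCa, PCd")
  areas <- vapply(scheme[need], function(w) integrate_window(spec, w),
    numeric(1)
  )
  wq <- scheme$QCa
  in_q <- spec$ppm <= wq$ppm_hi & spec$ppm >= wq$ppm_lo
  qca_max <- max(spec$intensity[in_q])
  if (qca_max <= noise_floor)
    stop("QCa maximum is at or below the noise floor; cannot normalise")
  structure(
    list(
      areas = areas,
      normalized = areas / qca_max,
      qca_max = qca_max,
      q_to_pca = unname(areas["QCa"] / areas["PCa"]),
      q_to_pcd = unname(areas["QCa"] / areas["PCd"])
    ),
    class = "qp_ratios"
  )
}

#' @export
print.qp_ratios <- function(x, ...) {
  cat("<qp_ratios> window areas (a.u.*ppm):\n")
  print(round(x$areas, 4))
  cat(sprintf(
    "  QCa max = %.4g; Q/P area ratios: QCa:PCa = %.3g, QCa:PCd = %.3g\n",
    x$qca_max, x$q_to_pca, x$q_to_pcd
  ))
  invisible(x)
}

#' Noise-based error estimate for window areas
#'
#' Estimates the spectral noise standard deviation from a signal-free ppm
#' region and propagates it to each integration window as
#' `sd * ppm_step * sqrt(n_points_in_window)` — the standard error of a
#' discrete sum of n independent noise samples.
#'
#' @param spec An [nmr_spectrum()] object.
#' @param signal_free_region Length-2 ppm range containing no peaks.
#' @param scheme Windows to propagate to (see [window_scheme()]); the
#'   signal-free region must not overlap any of them.
#' @return Named numeric vector of area uncertainties (a.u. * ppm), with
#'   attribute `noise_sd`.
#' @export
noise_error <- function(spec, signal_free_region,
                        scheme = window_scheme("batch1")) {
  stopifnot(inherits(spec, "nmr_spectrum_1d"),
            length(signal_free_region) == 2)
  lo <- min(signal_free_region)
  hi <- max(signal_free_region)
  for (w in scheme) {
    if (lo < w$ppm_hi && hi > w$ppm_lo) {
      stop(sprintf(
        "signal-free region [%g, %g] overlaps window %s [%g, %g]",
        lo, hi, w$name, w$ppm_lo, w$ppm_hi
      ))
    }
  }
  in_region <- spec$ppm >= lo & spec$ppm <= hi
  if (sum(in_region) < 10)
    stop("signal-free region contains fewer than 10 points")
  sd0 <- stats::sd(spec$intensity[in_region])
  step <- stats::median(abs(diff(spec$ppm)))
  out <- vapply(scheme, function(w) {
    n_in <- sum(spec$ppm >= w$ppm_lo & spec$ppm <= w$ppm_hi)
    sd0 * step * sqrt(n_in)
  }, numeric(1))
  attr(out, "noise_sd") <- sd0
  out
}

#' Read / write 1D spectra as two-column text
#'
#' Plain text with two whitespace-separated columns (ppm, intensity) and
#' `#` comment lines.
#'
#' @param path File path.
#' @param label Spectrum label; defaults to the file name.
#' @return `read_nmr_spectrum()` returns an [nmr_spectrum()];
#'   `write_nmr_spectrum()` returns `path` invisibly.
#' @export
read_nmr_spectrum <- function(path, label = basename(path)) {
  tab <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(tab) < 2) stop("expected two columns: ppm, intensity")
  nmr_spectrum(tab[[1]], tab[[2]], label = label)
}

#' @rdname read_nmr_spectrum
#' @param spec An [nmr_spectrum()] to write.
#' @export
write_nmr_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum_1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nmr_spectrum_1d label=%s", attr(spec, "label")), con)
  writeLines("# ppm intensity[a.u.]", con)
  utils::write.table(as.data.frame(spec), con,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
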