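#' Construct a 1D SAXS profile
#'
#' A `saxs_profile` holds a measured or simulated one-dimensional scattering
#' curve: the modulus of the scattering vector `q` (in reciprocal nanometres),
#' the scattered intensity `I(q)` in arbitrary units, and optionally a
#' per-point uncertainty.
#'
#' @param q Numeric vector of scattering-vector moduli in nm^-1; must be
#'   strictly positive and strictly increasing.
#' @param intensity Numeric vector of intensities (a.u.), same length as `q`.
#' @param sigma Optional numeric vector of per-point uncertainties (a.u.),
#'   strictly positive where present.
#' @param label Character label for the curve (sample / condition).
#'
#' @return An object of class `saxs_profile`: a data frame with columns
#'   `q`, `intensity` and (if supplied) `sigma`, plus a `label` attribute.
#' @export
#' @examples
#' p <- saxs_profile(q = c(0.1, 0.2, 0.4), intensity = c(10, 3, 1))
#' p
saxs_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) == 0) stop("empty q grid")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and strictly positive (nm^-1)")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (length(intensity) != length(q))
    stop("q and intensity must have equal length")
  df <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma must match q in length")
    if (any(is.finite(sigma) & sigma < 0)) stop("sigma must be non-negative")
    df$sigma <- sigma
  }
  structure(df,
    label = as.character(label)[1],
    class = c("saxs_profile", "data.frame")
  )
}

#' @export
print.saxs_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "<saxs_profile> %s%d points, q in [%.4g, %.4g] nm^-1%s\n",
    if (nzchar(lab)) paste0("'", lab, "': ") else "",
    nrow(x), min(x$q), max(x$q),
    if ("sigma" %in% names(x)) ", with uncertainties" else ""
  ))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read / write SAXS profiles as plain text
#'
#' The on-disk dialect is whitespace-separated columns `q I [sigma]` with
#' `#`-prefixed comment/header lines, `q` in nm^-1. `read_saxs_profile()` can
#' convert a file recorded in inverse Angstroms with `angstrom = TRUE`
#' (multiplies q by 10).
#'
#' @param path File path.
#' @param angstrom If `TRUE`, interpret the q column as Angstrom^-1 and
#'   convert to nm^-1.
#' @param label Curve label; defaults to the file name.
#' @return `read_saxs_profile()` returns a [saxs_profile];
#'   `write_saxs_profile()` returns `path` invisibly.
#' @export
read_saxs_profile <- function(path, angstrom = FALSE, label = basename(path)) {
  tab <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(tab) < 2) stop("expected at least two columns: q, intensity")
  q <- tab[[1]]
  if (angstrom) q <- q * 10
  saxs_profile(
    q = q, intensity = tab[[2]],
    sigma = if (ncol(tab) >= 3) tab[[3]] else NULL,
    label = label
  )
}

#' @rdname read_saxs_profile
#' @param profile A [saxs_profile] to write.
#' @export
write_saxs_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# saxs_profile label=%s", attr(profile, "label")), con)
  writeLines(paste0(
    "# q[nm^-1] I[a.u.]",
    if ("sigma" %in% names(profile)) " sigma[a.u.]" else ""
  ), con)
  utils::write.table(as.data.frame(profile), con,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Real-space length scale probed at a scattering vector
#'
#' Converts between a scattering-vector modulus and the corresponding
#' real-space correlation length via the Bragg-like relation `d = 2*pi/q`;
#' used both for the inter-fibrillar distance read off a correlation peak
#' and for the maximum length scale probed at the minimum accessible `q`.
#'
#' @param q Scattering vector modulus, nm^-1 (vectorised).
#' @return Length scale in nm.
#' @export
#' @examples
#' q_to_d(0.25) # ~25.1 nm inter-fibril distance
#' q_to_d(0.05) # ~125.7 nm: largest length scale probed at q_min = 0.05
q_to_d <- function(q) {
  stopifnot(all(q > 0))
  2 * pi / q
}

#' @rdname q_to_d
#' @param d Length scale in nm.
#' @export
d_to_q <- function(d) {
  stopifnot(all(d > 0))
  2 * pi / d
}
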