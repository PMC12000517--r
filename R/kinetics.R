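# ThT / curcumin fluorescence kinetics: control subtraction, maximum
# normalisation, and lag-phase / growth metrics. The two fluorophores gain
# fluorescence analogously on fibril formation and are treated as one
# signal channel.

#' Construct a fluorescence time course
#'
#' @param time_h Time points in hours, strictly increasing, >= 10 points.
#' @param signal Fluorescence signal (a.u.), same length.
#' @param replicate_id Replicate / well identifier.
#' @param condition Condition label (e.g. curcumin concentration).
#' @return A `tht_curve`: data frame with columns `time_h`, `signal` and
#'   attributes `replicate_id`, `condition`, `normalized`.
#' @export
tht_curve <- function(time_h, signal, replicate_id = "", condition = "") {
  time_h <- as.numeric(time_h)
  signal <- as.numeric(signal)
  if (length(time_h) < 10) stop("need at least 10 time points")
  if (any(diff(time_h) <= 0)) stop("time_h must be strictly increasing")
  if (length(signal) != length(time_h))
    stop("time_h and signal must have equal length")
  structure(
    data.frame(time_h = time_h, signal = signal),
    replicate_id = as.character(replicate_id)[1],
    condition = as.character(condition)[1],
    normalized = FALSE,
    class = c("tht_curve", "data.frame")
  )
}

#' @export
print.tht_curve <- function(x, ...) {
  cat(sprintf(
    "<tht_curve> %s%s%d points over %.2g h%s\n",
    if (nzchar(attr(x, "condition"))) paste0(attr(x, "condition"), ", ") else "",
    if (nzchar(attr(x, "replicate_id"))) paste0(attr(x, "replicate_id"), ": ") else "",
    nrow(x), max(x$time_h) - min(x$time_h),
    if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""
  ))
  invisible(x)
}

#' Control-subtract and normalise a fluorescence curve
#'
#' Subtracts the buffer-plus-dye control signal from the raw curve
#' (interpolating the control onto the raw time grid when the grids differ
#' by more than one sampling interval), clips negative values at zero, and
#' scales so the maximum observed signal is 1.
#'
#' @param raw A [tht_curve] of the aggregating sample.
#' @param control A [tht_curve] of the dye-only control.
#' @return A normalised [tht_curve] (max exactly 1).
#' @export
tht_preprocess <- function(raw, control) {
  stopifnot(inherits(raw, "tht_curve"), inherits(control, "tht_curve"))
  dt <- stats::median(diff(raw$time_h))
  ctrl <- if (nrow(control) == nrow(raw) &&
    max(abs(control$time_h - raw$time_h)) <= dt) {
    control$signal
  } else {
    stats::approx(control$time_h, control$signal,
      xout = raw$time_h, rule = 2
    )$y
  }
  s <- pmax(raw$signal - ctrl, 0)
  m <- max(s)
  if (m <= 0) stop("no signal above control after subtraction")
  out <- tht_curve(raw$time_h, s / m,
    replicate_id = attr(raw, "replicate_id"),
    condition = attr(raw, "condition")
  )
  attr(out, "normalized") <- TRUE
  out
}

#' Average replicate curves
#'
#' Point-wise mean of replicate time courses on a common grid (the first
#' curve's grid; others are interpolated onto it if needed).
#'
#' @param curves List of [tht_curve] objects.
#' @param condition Condition label for the averaged curve.
#' @return A [tht_curve] holding the mean signal.
#' @export
average_replicates <- function(curves, condition = NULL) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, logical(1),
    what = "tht_curve"
  )))
  tt <- curves[[1]]$time_h
  sig <- vapply(curves, function(cv) {
    if (nrow(cv) == length(tt) && max(abs(cv$time_h - tt)) < 1e-9) {
      cv$signal
    } else {
      stats::approx(cv$time_h, cv$signal, xout = tt, rule = 2)$y
    }
  }, numeric(length(tt)))
  tht_curve(tt, rowMeans(sig),
    replicate_id = "mean",
    condition = condition %||% attr(curves[[1]], "condition")
  )
}

#' Lag time and growth metrics of a sigmoidal aggregation curve
#'
#' Extracts the standard amyloid-kinetics descriptors from a preprocessed
#' (control-subtracted, max-normalised) curve:
#' \itemize{
#'   \item `max_slope` — the steepest 5-point sliding linear-fit slope
#'     (a.u./h), i.e. the growth-phase steepness;
#'   \item `lag_h` — where the tangent at the steepest point intersects the
#'     pre-transition baseline (the tangent-intercept definition, standard
#'     in amyloid kinetics and robust to the plateau level);
#'   \item `t50_h` — the first crossing of 0.5 on the normalised scale
#'     (linearly interpolated);
#'   \item `plateau` — the median of the last five points.
#' }
#' A curve that never rises above 0.5 reports `transition = FALSE` with
#' `NA` metrics rather than an error.
#'
#' @param curve A [tht_curve], ideally from [tht_preprocess()].
#' @return A `kinetics_summary` list: `lag_h`, `t50_h`, `max_slope`,
#'   `plateau`, `transition`, `replicate_id`, `condition`.
#' @export
lag_time <- function(curve) {
  stopifnot(inherits(curve, "tht_curve"))
  tt <- curve$time_h
  y <- curve$signal
  n <- length(tt)
  # 5-point sliding OLS slope
  ctr <- 3:(n - 2)
  slopes <- vapply(ctr, function(i) {
    ii <- (i - 2):(i + 2)
    unname(stats::coef(stats::lm(y[ii] ~ tt[ii]))[2])
  }, numeric(1))
  k_max <- which.max(slopes)
  i_max <- ctr[k_max]
  m <- slopes[k_max]
  plateau <- stats::median(utils::tail(y, 5))
  baseline <- if (i_max - 3L >= 3L) {
    stats::median(y[seq_len(i_max - 3L)])
  } else {
    min(y)
  }
  # on the normalised scale a curve that never reaches 0.5 has no
  # detectable growth transition
  half <- 0.5
  no_transition <- !is.finite(m) || m <= 0 || max(y) < half
  if (no_transition) {
    return(structure(
      list(
        lag_h = NA_real_, t50_h = NA_real_, max_slope = NA_real_,
        plateau = plateau, transition = FALSE,
        replicate_id = attr(curve, "replicate_id"),
        condition = attr(curve, "condition")
      ),
      class = "kinetics_summary"
    ))
  }
  # tangent through the observed point at the steepest-window centre
  lag <- max(tt[i_max] - (y[i_max] - baseline) / m, 0)
  above <- which(y >= half)
  first <- above[1]
  t50 <- if (first == 1L) {
    tt[1]
  } else {
    tt[first - 1] + (half - y[first - 1]) /
      (y[first] - y[first - 1]) * (tt[first] - tt[first - 1])
  }
  structure(
    list(
      lag_h = lag, t50_h = t50, max_slope = m, plateau = plateau,
      transition = TRUE,
      replicate_id = attr(curve, "replicate_id"),
      condition = attr(curve, "condition")
    ),
    class = "kinetics_summary"
  )
}

#' @export
print.kinetics_summary <- function(x, ...) {
  if (x$transition) {
    cat(sprintf(
      "<kinetics_summary> lag = %.2f h, t50 = %.2f h, max slope = %.3g /h, plateau = %.3g\n",
      x$lag_h, x$t50_h, x$max_slope, x$plateau
    ))
  } else {
    cat("<kinetics_summary> no transition detected\n")
  }
  invisible(x)
}

#' Read / write fluorescence time courses as CSV
#'
#' Long-format CSV with columns `time_h`, `well`, `condition`, `signal`;
#' one row per well per time point.
#'
#' @param path CSV file path.
#' @return `read_tht_csv()` returns a named list of [tht_curve] objects,
#'   one per well; `write_tht_csv()` returns `path` invisibly.
#' @export
read_tht_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "well", "condition", "signal")
  if (!all(need %in% names(tab))) {
    stop(
      "kinetics CSV must have columns: ", paste(need, collapse = ", ")
    )
  }
  wells <- split(tab, tab$well)
  out <- lapply(wells, function(wt) {
    wt <- wt[order(wt$time_h), ]
    tht_curve(wt$time_h, wt$signal,
      replicate_id = wt$well[1], condition = wt$condition[1]
    )
  })
  out
}

#' @rdname read_tht_csv
#' @param curves Named list of [tht_curve] objects.
#' @export
write_tht_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(
      time_h = cv$time_h, well = attr(cv, "replicate_id"),
      condition = attr(cv, "condition"), signal = cv$signal
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
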