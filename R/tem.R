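# TEM fibril-width morphometrics: per-condition summaries, histograms and
# pairwise comparisons of width-measurement sets. Widths are measured
# transverse to the fibril axis and reflect the polyQ core (the negative
# stain penetrates the flexible flanking segments).

#' Construct a fibril-width sample
#'
#' @param widths Width measurements in nm, all > 0.
#' @param condition Condition label (e.g. `"no curcumin"`,
#'   `"20 uM curcumin"`).
#' @param fibril_id Optional identifier of the fibril each measurement came
#'   from (typically three measurements per fibril); enables per-fibril
#'   averaging via [collapse_fibrils()].
#' @return A `width_sample`: data frame with columns `width_nm` and
#'   optionally `fibril_id`, plus a `condition` attribute.
#' @export
width_sample <- function(widths, condition = "", fibril_id = NULL) {
  widths <- as.numeric(widths)
  if (length(widths) < 1) stop("need at least one measurement")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("all widths must be finite and positive (nm)")
  df <- data.frame(width_nm = widths)
  if (!is.null(fibril_id)) {
    if (length(fibril_id) != length(widths))
      stop("fibril_id must match widths in length")
    df$fibril_id <- as.character(fibril_id)
  }
  structure(df,
    condition = as.character(condition)[1],
    class = c("width_sample", "data.frame")
  )
}

#' @export
print.width_sample <- function(x, ...) {
  cat(sprintf(
    "<width_sample> %s: n = %d, mean = %.2f nm, sd = %.2f nm\n",
    attr(x, "condition"), nrow(x), mean(x$width_nm), stats::sd(x$width_nm)
  ))
  invisible(x)
}

#' Collapse a width sample to per-fibril means
#'
#' When several measurements were taken along each fibril, statistics can
#' be computed either on the pooled measurements or on per-fibril averages;
#' this returns the per-fibril-average version of a sample.
#'
#' @param s A [width_sample] with a `fibril_id` column.
#' @return A [width_sample] of per-fibril mean widths.
#' @export
collapse_fibrils <- function(s) {
  stopifnot(inherits(s, "width_sample"))
  if (is.null(s$fibril_id))
    stop("sample has no fibril_id column")
  m <- tapply(s$width_nm, s$fibril_id, mean)
  width_sample(as.numeric(m), condition = attr(s, "condition"))
}

#' Summary statistics and histogram of a width sample
#'
#' Mean, SD, median, SEM and histogram counts on fixed half-open bins
#' `[lo, hi)` anchored at 0 nm, so no width is double-counted and
#' histograms from different conditions share a grid.
#'
#' @param s A [width_sample] with at least 3 measurements.
#' @param bin_width Histogram bin width in nm (default 1).
#' @param reference_nm Optional reference width (nm) carried through to the
#'   output — conventionally the mean width of the untreated condition,
#'   drawn as a dashed line on histograms.
#' @return A `width_stats` list: `condition`, `n`, `mean`, `sd`, `sem`,
#'   `median`, `bin_width`, `breaks`, `counts`, `reference_nm`.
#' @export
width_stats <- function(s, bin_width = 1, reference_nm = NULL) {
  stopifnot(inherits(s, "width_sample"))
  if (nrow(s) < 3) stop("need at least 3 measurements for statistics")
  if (bin_width <= 0) stop("bin_width must be > 0")
  w <- s$width_nm
  breaks <- seq(0, (floor(max(w) / bin_width) + 1) * bin_width,
    by = bin_width
  )
  counts <- vapply(
    seq_len(length(breaks) - 1L),
    function(i) sum(w >= breaks[i] & w < breaks[i + 1L]),
    integer(1)
  )
  structure(
    list(
      condition = attr(s, "condition"), n = length(w),
      mean = mean(w), sd = stats::sd(w),
      sem = stats::sd(w) / sqrt(length(w)), median = stats::median(w),
      bin_width = bin_width, breaks = breaks, counts = counts,
      reference_nm = reference_nm
    ),
    class = "width_stats"
  )
}

#' @export
print.width_stats <- function(x, ...) {
  cat(sprintf(
    "<width_stats> %s: n = %d, mean = %.2f +/- %.2f (SEM) nm, sd = %.2f, median = %.2f\n",
    x$condition, x$n, x$mean, x$sem, x$sd, x$median
  ))
  if (!is.null(x$reference_nm))
    cat(sprintf("  reference line at %.2f nm\n", x$reference_nm))
  invisible(x)
}

#' Compare fibril widths between two conditions
#'
#' Difference of means `a - b` with a seeded bootstrap confidence interval,
#' Cohen's d effect size, and a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' p-value. The rank test is used because measured width distributions are
#' typically skewed and non-normal.
#'
#' @param a,b [width_sample] objects (n >= 3 each).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed Seed for the bootstrap (deterministic given the seed).
#' @param conf Confidence level (default 0.95).
#' @param ... Unused.
#' @return A `width_comparison` list: `condition_a`, `condition_b`,
#'   `mean_diff`, `ci` (length 2), `effect_size` (Cohen's d), `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_conditions.width_sample <- function(a, b, n_boot = 1000L, seed = 1L,
                                            conf = 0.95, ...) {
  stopifnot(inherits(b, "width_sample"), nrow(a) >= 3, nrow(b) >= 3)
  wa <- a$width_nm
  wb <- b$width_nm
  diff_mean <- mean(wa) - mean(wb)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    mean(sample(wa, replace = TRUE)) - mean(sample(wb, replace = TRUE))
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  pooled_sd <- sqrt((
    (length(wa) - 1) * stats::var(wa) + (length(wb) - 1) * stats::var(wb)
  ) / (length(wa) + length(wb) - 2))
  d <- if (pooled_sd > 0) diff_mean / pooled_sd else 0
  p <- stats::wilcox.test(wa, wb, exact = FALSE)$p.value
  structure(
    list(
      condition_a = attr(a, "condition"), condition_b = attr(b, "condition"),
      mean_diff = diff_mean, ci = ci, effect_size = d, p_value = p,
      n_a = length(wa), n_b = length(wb)
    ),
    class = "width_comparison"
  )
}

#' @export
print.width_comparison <- function(x, ...) {
  cat(sprintf(
    "<width_comparison> %s vs %s: mean diff = %.2f nm [%.2f, %.2f], d = %.2f, Mann-Whitney p = %.3g\n",
    x$condition_a, x$condition_b, x$mean_diff, x$ci[1], x$ci[2],
    x$effect_size, x$p_value
  ))
  invisible(x)
}

#' Read / write width measurements as CSV
#'
#' CSV with columns `condition`, `width_nm` and optionally `fibril_id`, one
#' row per measurement.
#'
#' @param path CSV file path.
#' @return `read_widths_csv()` returns a named list of [width_sample]
#'   objects, one per condition; `write_widths_csv()` returns `path`
#'   invisibly.
#' @export
read_widths_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("condition", "width_nm") %in% names(tab)))
    stop("widths CSV must have columns: condition, width_nm")
  lapply(split(tab, tab$condition), function(ct) {
    width_sample(ct$width_nm,
      condition = ct$condition[1],
      fibril_id = ct[["fibril_id"]]
    )
  })
}

#' @rdname read_widths_csv
#' @param samples Named list of [width_sample] objects.
#' @export
write_widths_csv <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    out <- data.frame(
      condition = attr(s, "condition"), width_nm = s$width_nm
    )
    if (!is.null(s$fibril_id)) out$fibril_id <- s$fibril_id
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
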