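# Forward scattering model for a concentrated ensemble of long rod-like
# fibrils: orientation-averaged cylinder form factor, log-normal
# cross-section polydispersity, PRISM-style structure factor for the
# inter-fibrillar correlation, and a power-law + flat background:
#
#   I(q) = A * [ sum_r P(q, r, L) N(r) dr ] * S(q, d, nu) + B/q^n + C

#' Model parameters for the bundled-fibril scattering model
#'
#' Bundles the full parameter set of the fibril scattering model: overall
#' scale, median cross-section radius and log-normal polydispersity width,
#' (fixed) rod length, average inter-fibrillar distance and interaction
#' strength of the structure factor, and the background terms.
#'
#' @param A Overall scale (a.u., > 0); absorbs number density and contrast.
#' @param r Median cross-section radius in nm (> 0).
#' @param sigma_r Log-normal width of the cross-section radius distribution
#'   (dimensionless, >= 0; 0 means monodisperse).
#' @param L Rod length in nm; far outside the probed range, so it is held
#'   fixed (default 1000) and never fitted. Must satisfy `L >= 20 * r`.
#' @param d Average inter-fibrillar (stacking) distance in nm (> 0).
#' @param nu Dimensionless interaction parameter of the structure factor
#'   (>= 0; 0 switches inter-fibril correlation off).
#' @param B Power-law background scale (>= 0).
#' @param n_exp Background power-law exponent (>= 0).
#' @param C Flat background (>= 0).
#'
#' @return An object of class `saxs_params` (a validated named list).
#' @export
#' @examples
#' saxs_params(A = 1, r = 6, sigma_r = 0.25, d = 24, nu = 1)
saxs_params <- function(A = 1, r = 5, sigma_r = 0.25, L = 1000,
                        d = 24, nu = 1, B = 0, n_exp = 1, C = 0) {
  p <- list(
    A = A, r = r, sigma_r = sigma_r, L = L, d = d, nu = nu,
    B = B, n_exp = n_exp, C = C
  )
  validate_saxs_params(p)
  structure(p, class = "saxs_params")
}

validate_saxs_params <- function(p) {
  with(p, {
    if (!is.finite(A) || A < 0) stop("A must be >= 0")
    if (!is.finite(r) || r <= 0) stop("r must be > 0 (nm)")
    if (!is.finite(sigma_r) || sigma_r < 0) stop("sigma_r must be >= 0")
    if (!is.finite(d) || d <= 0) stop("d must be > 0 (nm)")
    if (!is.finite(nu) || nu < 0) stop("nu must be >= 0")
    if (!is.finite(B) || B < 0) stop("B must be >= 0")
    if (!is.finite(n_exp) || n_exp < 0) stop("n_exp must be >= 0")
    if (!is.finite(C) || C < 0) stop("C must be >= 0")
    if (L < 20 * r) {
      stop(sprintf(
        "thin-rod regime violated: need L >= 20*r, got L = %g, r = %g", L, r
      ))
    }
  })
  invisible(p)
}

#' @export
print.saxs_params <- function(x, ...) {
  cat("<saxs_params>\n")
  cat(sprintf(
    "  A = %.4g, r = %.4g nm (sigma_r = %.3g), L = %g nm (fixed)\n",
    x$A, x$r, x$sigma_r, x$L
  ))
  cat(sprintf("  d = %.4g nm, nu = %.4g\n", x$d, x$nu))
  cat(sprintf("  background B/q^n + C: B = %.4g, n = %.3g, C = %.4g\n",
              x$B, x$n_exp, x$C))
  invisible(x)
}

# Panel breakpoints on t = cos(orientation angle) in [0, 1] for the
# orientation average. The sinc(u t) factor has zeros at t = k*pi/u; aligning
# panel edges to them makes fixed-order Gauss-Legendre essentially exact.
# Extra uniform breaks resolve the (slower) Bessel variation.
orientation_breaks <- function(u, v_max) {
  br <- seq(0, 1, length.out = max(9L, ceiling(v_max / pi) + 9L))
  if (u > pi) {
    k <- seq_len(floor(u / pi))
    br <- c(br, k * pi / u)
  }
  sort(unique(pmin(pmax(br, 0), 1)))
}

# Orientation-averaged squared cylinder amplitude for one q and a vector of
# radii at once (the inner loop of the polydisperse model). Normalised so
# the q -> 0 limit is exactly 1.
cyl_ff_row <- function(q, r_vec, L, order = 8L) {
  u <- q * L / 2
  v <- q * r_vec
  nd <- panel_nodes(orientation_breaks(u, max(v)), order = order)
  ax <- sinc(u * nd$t)^2 * nd$w          # axial factor * quadrature weights
  s <- sqrt(pmax(0, 1 - nd$t^2))
  # cross-section amplitude^2 at every (node, radius) pair
  cs2 <- bessel_cs(outer(s * q, r_vec))^2
  as.vector(crossprod(cs2, ax))
}

#' Orientation-averaged form factor of a long cylinder
#'
#' The squared scattering amplitude of a rigid cylinder of radius `r` and
#' length `L`, averaged over orientations (sin-weighted over the angle
#' between the rod axis and the scattering vector), normalised so that
#' `P(q -> 0) = 1`. Computed by panelised Gauss-Legendre quadrature with
#' panel edges aligned to the axial `sinc` oscillations, giving relative
#' accuracy well below 1e-6 even for `L/r` in the thousands.
#'
#' In the rod regime (`2*pi/L << q << 1/r`) the result scales as `q^-1`,
#' the signature power law of long linear aggregates.
#'
#' @param q Scattering vector moduli, nm^-1 (vectorised; all > 0).
#' @param r Cylinder cross-section radius, nm (> 0).
#' @param L Cylinder length, nm; must satisfy `L >= 20 * r`.
#' @return Dimensionless intensities in (0, 1], one per `q`.
#' @export
#' @examples
#' cylinder_form_factor(1e-6, r = 4, L = 1000) # -> 1
#' cylinder_form_factor(c(0.05, 0.1, 0.5), r = 4, L = 1000)
cylinder_form_factor <- function(q, r, L = 1000) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive and finite")
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  if (L < 20 * r) {
    stop(sprintf(
      "thin-rod regime violated: need L >= 20*r, got L = %g, r = %g", L, r
    ))
  }
  vapply(q, function(qi) cyl_ff_row(qi, r, L), numeric(1))
}

#' Discretised log-normal polydispersity weights
#'
#' Normalised quadrature weights of a log-normal size distribution with
#' median `r_median` and log-space width `sigma_r`, evaluated on a given
#' radius grid (density times trapezoidal grid weights, renormalised to sum
#' to one). The grid must cover at least +/- 4 sigma in log space so that no
#' appreciable probability mass is truncated.
#'
#' @param r_median Median radius, nm (> 0).
#' @param sigma_r Log-normal width (>= 0). Values below 1e-4 are treated as
#'   monodisperse: all weight on the grid point nearest `r_median`.
#' @param r_grid Strictly increasing positive radius grid, nm.
#' @return Numeric weights summing to 1, one per grid point.
#' @export
#' @examples
#' g <- exp(seq(log(2), log(18), length.out = 41))
#' w <- lognormal_weights(6, 0.25, g)
#' sum(w) # 1
lognormal_weights <- function(r_median, sigma_r, r_grid) {
  if (!is.finite(r_median) || r_median <= 0) stop("r_median must be > 0")
  if (!is.finite(sigma_r) || sigma_r < 0) stop("sigma_r must be >= 0")
  if (any(r_grid <= 0) || any(diff(r_grid) <= 0))
    stop("r_grid must be positive and strictly increasing")
  if (sigma_r < 1e-4) {
    if (min(r_grid) > r_median || max(r_grid) < r_median)
      stop("r_grid does not cover r_median")
    w <- numeric(length(r_grid))
    w[which.min(abs(log(r_grid) - log(r_median)))] <- 1
    return(w)
  }
  lo_need <- r_median * exp(-4 * sigma_r) * (1 + 1e-9)
  hi_need <- r_median * exp(4 * sigma_r) * (1 - 1e-9)
  if (min(r_grid) > lo_need || max(r_grid) < hi_need) {
    stop(sprintf(
      "r_grid [%g, %g] must cover +/- 4 log-sd of the distribution [%g, %g]",
      min(r_grid), max(r_grid), lo_need, hi_need
    ))
  }
  dens <- stats::dlnorm(r_grid, meanlog = log(r_median), sdlog = sigma_r)
  n <- length(r_grid)
  dr <- numeric(n)
  dr[1] <- (r_grid[2] - r_grid[1]) / 2
  dr[n] <- (r_grid[n] - r_grid[n - 1]) / 2
  if (n > 2) dr[2:(n - 1)] <- (r_grid[3:n] - r_grid[1:(n - 2)]) / 2
  w <- dens * dr
  w / sum(w)
}

# First minimum of sin(x)/x: the nonzero root of x*cos(x) = sin(x).
PRISM_X1 <- 4.493409457909064

#' PRISM-style structure factor for laterally correlated fibrils
#'
#' Inter-fibrillar interference term `S(q) = 1 / (1 + nu * Omega(q * d'))`
#' with the damped oscillatory correlation kernel `Omega(x) = sin(x)/x` and
#' the effective distance `d' = (x1 / (2*pi)) * d`, where `x1 ~= 4.4934` is
#' the location of the kernel's first minimum. This calibration places the
#' first maximum of `S` at `q_max = 2*pi/d`, so the distance parameter `d`
#' obeys the usual Bragg-like reading `d = 2*pi/q_max` of a correlation
#' peak.
#'
#' Limits: `S -> 1` as `q -> Inf` (correlations decay), `S = 1/(1 + nu) < 1`
#' at `q -> 0` for `nu > 0` (repulsive suppression of long-wavelength
#' fluctuations), and `S === 1` when `nu = 0`.
#'
#' @param q Scattering vector moduli, nm^-1 (vectorised; > 0).
#' @param d Average inter-fibrillar distance, nm (> 0).
#' @param nu Interaction parameter (>= 0); negative values (attraction) are
#'   not modelled and raise an error.
#' @return Dimensionless structure-factor values.
#' @export
#' @examples
#' q <- seq(0.05, 1, by = 0.005)
#' s <- prism_structure_factor(q, d = 24, nu = 1)
#' q[which.max(s)] # ~ 2*pi/24 ~ 0.26 nm^-1
prism_structure_factor <- function(q, d, nu) {
  if (any(q <= 0)) stop("q must be positive")
  if (!is.finite(d) || d <= 0) stop("d must be > 0")
  if (!is.finite(nu)) stop("nu must be finite")
  if (nu < 0) stop("nu must be >= 0 (attractive regime not modelled)")
  d_eff <- d * PRISM_X1 / (2 * pi)
  1 / (1 + nu * sinc(q * d_eff))
}

#' Model intensity of the bundled-fibril scattering model
#'
#' Evaluates
#' `I(q) = A * [sum_r P(q, r, L) N(r) dr] * S(q, d, nu) + B/q^n + C`:
#' the orientation-averaged long-cylinder form factor, averaged over a
#' log-normal cross-section radius distribution (41-point log-spaced grid
#' spanning +/- 4 log-sd), multiplied by the PRISM-style structure factor,
#' plus a power-law and flat background.
#'
#' @param q Strictly positive, strictly increasing q grid, nm^-1.
#' @param params A [saxs_params] object (or coercible named list).
#' @param n_r Number of radius-grid points for the polydispersity average
#'   (default 41).
#' @param ff_table Optional precomputed form-factor interpolation table from
#'   [form_factor_table()]; used by the fitting engine to avoid recomputing
#'   the orientation quadrature at every iteration. `NULL` (default) uses
#'   exact quadrature.
#' @return Numeric intensities, strictly positive, one per `q`.
#' @export
#' @examples
#' q <- exp(seq(log(0.05), log(1), length.out = 100))
#' I <- model_intensity(q, saxs_params(r = 6, sigma_r = 0.25, d = 24, nu = 1))
model_intensity <- function(q, params, n_r = 41L, ff_table = NULL) {
  if (!inherits(params, "saxs_params")) params <- do.call(saxs_params, params)
  validate_saxs_params(params)
  if (any(q <= 0)) stop("q must be positive")
  p <- params
  bkg <- if (p$B > 0) p$B / q^p$n_exp else numeric(length(q))
  bkg <- bkg + p$C
  if (p$A == 0) return(bkg)
  if (p$sigma_r < 1e-4) {
    r_grid <- p$r
    w <- 1
  } else {
    r_grid <- exp(seq(log(p$r) - 4 * p$sigma_r, log(p$r) + 4 * p$sigma_r,
      length.out = n_r
    ))
    w <- lognormal_weights(p$r, p$sigma_r, r_grid)
  }
  if (is.null(ff_table)) {
    pf <- vapply(
      seq_along(q),
      function(i) sum(cyl_ff_row(q[i], r_grid, p$L) * w),
      numeric(1)
    )
  } else {
    pf <- as.vector(ff_lookup(ff_table, r_grid) %*% w)
  }
  s <- prism_structure_factor(q, p$d, p$nu)
  pmax(p$A * pf * s + bkg, .Machine$double.xmin)
}

#' Precompute a form-factor interpolation table
#'
#' Tabulates the orientation-averaged cylinder form factor on the given q
#' grid over a dense log-spaced radius grid, for fast repeated evaluation of
#' the polydisperse model during fitting (log-log linear interpolation in
#' radius; relative interpolation error well below the fit's noise level).
#'
#' @param q The q grid the table will serve, nm^-1.
#' @param L Fixed rod length, nm.
#' @param r_range Radius range (nm) the table must cover, e.g. the fit
#'   bounds widened by the polydispersity tails.
#' @param step Log-space grid step (default 0.02).
#' @return An opaque table object for [model_intensity()]'s `ff_table`.
#' @export
form_factor_table <- function(q, L = 1000, r_range = c(0.1, 150),
                              step = 0.02) {
  lr <- seq(log(r_range[1]), log(r_range[2]),
    length.out = max(50L, ceiling(diff(log(r_range)) / step))
  )
  r_nodes <- exp(lr)
  tab <- matrix(0, nrow = length(q), ncol = length(r_nodes))
  for (i in seq_along(q)) tab[i, ] <- cyl_ff_row(q[i], r_nodes, L)
  list(q = q, L = L, log_r = lr, log_p = log(tab))
}

# Interpolate the tabulated form factor at arbitrary radii: 4-point
# Lagrange cubic in (log r, log P) on the uniform log grid. Returns a
# (length(q) x length(r_vec)) matrix.
ff_lookup <- function(ff_table, r_vec) {
  lr <- log(r_vec)
  grid <- ff_table$log_r
  ng <- length(grid)
  if (min(lr) < grid[1] || max(lr) > grid[ng])
    stop("radius outside the precomputed form-factor table range")
  idx <- findInterval(lr, grid, rightmost.closed = TRUE)
  i0 <- pmin(pmax(idx - 1L, 1L), ng - 3L) # stencil start, clamped
  h <- grid[2] - grid[1]
  u <- (lr - grid[i0]) / h # in [0, 3] across the 4-point stencil
  w0 <- -(u - 1) * (u - 2) * (u - 3) / 6
  w1 <- u * (u - 2) * (u - 3) / 2
  w2 <- -u * (u - 1) * (u - 3) / 2
  w3 <- u * (u - 1) * (u - 2) / 6
  lp <- ff_table$log_p
  out <- sweep(lp[, i0, drop = FALSE], 2, w0, `*`) +
    sweep(lp[, i0 + 1L, drop = FALSE], 2, w1, `*`) +
    sweep(lp[, i0 + 2L, drop = FALSE], 2, w2, `*`) +
    sweep(lp[, i0 + 3L, drop = FALSE], 2, w3, `*`)
  exp(out)
}

#' Power-law exponent of a scattering curve
#'
#' Ordinary least squares of `log I` against `log q` inside a q window; the
#' negated slope is the power-law exponent `alpha` of `I ~ q^-alpha`. For
#' long rod-like fibrils the low-q regime gives `alpha = 1`; compact
#' interfaces at high q give Porod-like exponents of 3-4.
#'
#' @param profile A [saxs_profile].
#' @param q_lo,q_hi Window bounds, nm^-1 (`q_lo < q_hi`); at least 5 points
#'   of the profile must fall inside.
#' @return A `powerlaw_fit` list: `alpha`, `q_lo`, `q_hi`, `r_squared`,
#'   `n_points`.
#' @export
#' @examples
#' q <- exp(seq(log(0.02), log(0.1), length.out = 30))
#' p <- saxs_profile(q, q^-1)
#' powerlaw_slope(p, 0.02, 0.1)$alpha # 1
powerlaw_slope <- function(profile, q_lo, q_hi) {
  stopifnot(inherits(profile, "saxs_profile"), q_lo < q_hi)
  sel <- profile$q >= q_lo & profile$q <= q_hi & profile$intensity > 0
  if (sum(sel) < 5) {
    stop(sprintf(
      "power-law window [%g, %g] contains %d points; need >= 5",
      q_lo, q_hi, sum(sel)
    ))
  }
  fit <- stats::lm(log(intensity) ~ log(q), data = profile[sel, ])
  ly <- log(profile$intensity[sel])
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(
      alpha = -unname(stats::coef(fit)[2]),
      q_lo = q_lo, q_hi = q_hi,
      r_squared = r2,
      n_points = sum(sel)
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.3f (I ~ q^-alpha), q in [%g, %g] nm^-1, R^2 = %.4f, n = %d\n",
    x$alpha, x$q_lo, x$q_hi, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Locate the inter-fibrillar correlation peak
#'
#' Finds the broad correlation maximum that lateral fibril bundling imprints
#' on a scattering curve, and converts its position to an average
#' inter-fibrillar distance `d_eff = 2*pi/q_max`. Because the raw curve is
#' monotonically decreasing, the peak is a shoulder: the profile is first
#' detrended by dividing out the local power-law trend fitted over the
#' window, then the maximum of the detrended curve is located (with
#' three-point quadratic refinement in log-log space).
#'
#' @details
#' Detection works on the lowess-smoothed log-log curve: a peak is an
#' interior local maximum whose *side-valley prominence* — its height above
#' the higher of the two flanking minima inside the window, as a relative
#' intensity fraction — exceeds `min_prominence`. This deliberately ignores
#' overall curvature of the decay, so a smooth non-interacting (`nu = 0`)
#' curve reports "no peak" rather than mistaking its concavity for one.
#' The apex of a detected peak is refined by a local quadratic fit in
#' log-log space to the raw curve, which is unbiased by any smooth local
#' power-law trend underneath the peak.
#'
#' @param profile A [saxs_profile] — either a full intensity curve or a pure
#'   structure-factor trace.
#' @param q_window Length-2 window (nm^-1) to search within; must lie inside
#'   the data range. Default `c(0.12, 0.4)`, the intermediate-q region where
#'   bundling correlations appear for these fibrils.
#' @param min_prominence Minimum side-valley prominence as a relative
#'   fraction (default 0.02); below it the result reports no peak rather
#'   than erroring.
#' @param span Lowess smoothing span used for detection (default 0.35 of
#'   the window points); detection only — the reported `q_max` comes from
#'   the raw curve.
#' @return A `correlation_peak` list: `found`, `q_max` (nm^-1), `d_eff`
#'   (nm), `prominence`.
#' @export
find_correlation_peak <- function(profile, q_window = c(0.12, 0.4),
                                  min_prominence = 0.02, span = 0.35) {
  stopifnot(inherits(profile, "saxs_profile"), length(q_window) == 2)
  if (q_window[1] < min(profile$q) || q_window[2] > max(profile$q))
    stop("q_window must lie within the data range")
  # Detection uses up to half a decade of data below the window as the
  # pre-shoulder baseline trend; the reported peak stays inside q_window.
  q_det <- max(min(profile$q), q_window[1] / 2)
  sel <- profile$q >= q_det & profile$q <= q_window[2] &
    profile$intensity > 0
  q <- profile$q[sel]
  I <- profile$intensity[sel]
  n <- length(q)
  in_win <- q >= q_window[1]
  if (sum(in_win) < 5) stop("fewer than 5 points in q_window")
  s <- stats::lowess(log(q), log(I), f = span)$y
  no_peak <- function(p) structure(
    list(found = FALSE, q_max = NA_real_, d_eff = NA_real_, prominence = p),
    class = "correlation_peak"
  )
  quad_apex <- function(lxv, yv, fallback) {
    qf <- stats::lm(yv ~ lxv + I(lxv^2))
    a <- stats::coef(qf)[3]
    apex <- exp(-stats::coef(qf)[2] / (2 * a))
    if (is.finite(a) && a < 0 && apex >= exp(min(lxv)) &&
        apex <= exp(max(lxv))) unname(apex) else fallback
  }
  lx <- log(q)
  cand <- which(diff(sign(diff(s))) == -2) + 1L
  cand <- cand[in_win[cand]]
  if (length(cand) > 0) {
    # a genuine local maximum of the curve itself
    side_prom <- vapply(cand, function(j) {
      min(s[j] - min(s[1:j]), s[j] - min(s[j:n]))
    }, numeric(1))
    j <- cand[which.max(side_prom)]
    prominence <- expm1(max(side_prom))
    if (prominence < min_prominence) return(no_peak(prominence))
    rng <- max(1L, j - 4L):min(n, j + 4L)
    q_max <- quad_apex(lx[rng], log(I[rng]), q[j])
  } else {
    # Shoulder case: the raw curve is monotone, but bundling still bends it.
    # Signature: the smoothed log-log slope rises by more than 0.1 from its
    # running minimum to an interior local maximum (a pure decay has a
    # monotonically falling slope, so it never rises). The peak position is
    # then read off the curve detrended by its window-wide power-law trend.
    g <- diff(s) / diff(lx)
    gc <- which(diff(sign(diff(g))) == -2) + 1L
    gc <- gc[in_win[gc]]
    gc <- gc[vapply(gc, function(jg) g[jg] - min(g[1:jg]) > 0.1, logical(1))]
    if (length(gc) == 0) return(no_peak(0))
    r <- stats::residuals(stats::lm(s ~ lx))
    r_masked <- replace(r, !in_win, -Inf)
    j <- which.max(r_masked)
    prominence <- expm1(min(r[j] - min(r[1:j]), r[j] - min(r[j:n])))
    if (j == 1L || j == n || prominence < min_prominence)
      return(no_peak(prominence))
    rng <- max(1L, j - 4L):min(n, j + 4L)
    q_max <- quad_apex(lx[rng], r[rng], q[j])
  }
  structure(
    list(found = TRUE, q_max = q_max, d_eff = 2 * pi / q_max,
         prominence = prominence),
    class = "correlation_peak"
  )
}

#' @export
print.correlation_peak <- function(x, ...) {
  if (x$found) {
    cat(sprintf(
      "<correlation_peak> q_max = %.4f nm^-1, d_eff = 2*pi/q_max = %.2f nm (prominence %.3g)\n",
      x$q_max, x$d_eff, x$prominence
    ))
  } else {
    cat(sprintf("<correlation_peak> no peak (prominence %.3g)\n",
                x$prominence))
  }
  invisible(x)
}

#' Modified (cross-sectional) Guinier analysis for rod-like particles
#'
#' For long rods, `q * I(q)` decays as `exp(-q^2 * Rc^2 / 2)` in the
#' cross-section Guinier regime, where `Rc` is the radius of gyration of the
#' cross-section. The slope of `ln(q*I)` versus `q^2` therefore gives
#' `-Rc^2/2`, and for a homogeneous circular cylinder the geometric radius
#' follows as `r = Rc * sqrt(2)`. The analysis window is shrunk from the
#' high-q side until the validity condition `q_hi * Rc <= 1.3` holds.
#'
#' @param profile A [saxs_profile].
#' @param q_window Initial length-2 analysis window, nm^-1.
#' @param max_qrc Validity bound on `q * Rc` (default 1.3).
#' @return A `guinier_fit` list: `R_c` (nm), `implied_radius` (nm,
#'   `= R_c * sqrt(2)`), `q_range` actually used, `r_squared`, and a
#'   `warning` flag set when the window is non-linear (`r_squared < 0.98`)
#'   or the decay is absent.
#' @export
#' @examples
#' q <- exp(seq(log(0.05), log(0.45), length.out = 80))
#' p <- saxs_profile(q, cylinder_form_factor(q, r = 4, L = 1000))
#' cross_section_guinier(p, c(0.1, 0.45))$implied_radius # ~ 4 nm
cross_section_guinier <- function(profile, q_window = NULL, max_qrc = 1.3) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(q_window)) q_window <- range(profile$q)
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2] &
    profile$intensity > 0
  q <- profile$q[sel]
  I <- profile$intensity[sel]
  for (iter in 1:25) {
    if (length(q) < 5) {
      return(structure(
        list(R_c = NA_real_, implied_radius = NA_real_,
             q_range = range(q, na.rm = TRUE), r_squared = NA_real_,
             warning = TRUE,
             message = "window shrank below 5 points before q*Rc <= 1.3"),
        class = "guinier_fit"
      ))
    }
    fit <- stats::lm(log(q * I) ~ I(q^2))
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) {
      return(structure(
        list(R_c = NA_real_, implied_radius = NA_real_, q_range = range(q),
             r_squared = summary(fit)$r.squared, warning = TRUE,
             message = "no cross-sectional decay (non-negative slope)"),
        class = "guinier_fit"
      ))
    }
    rc <- sqrt(-2 * slope)
    if (max(q) * rc <= max_qrc) break
    q_cut <- max_qrc / rc
    keep <- q <= max(q_cut, q[5])
    if (all(keep)) keep[length(keep)] <- FALSE # guarantee progress
    q <- q[keep]
    I <- I[keep]
  }
  r2 <- summary(fit)$r.squared
  structure(
    list(R_c = rc, implied_radius = rc * sqrt(2), q_range = range(q),
         r_squared = r2, warning = r2 < 0.98, message = NULL),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> R_c = %.3f nm, implied cylinder radius = %.3f nm, q in [%.3g, %.3g], R^2 = %.4f%s\n",
    x$R_c, x$implied_radius, x$q_range[1], x$q_range[2], x$r_squared,
    if (isTRUE(x$warning)) " [warning]" else ""
  ))
  invisible(x)
}
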