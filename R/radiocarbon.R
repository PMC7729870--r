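# Radiocarbon calibration: curve parsing/interpolation, diet-weighted
# atmospheric/marine curve mixing with a local reservoir offset, calendar-age
# posteriors on a uniform grid, and multi-modal HPD range reporting.

#' Construct a radiocarbon date
#'
#' @param age_bp Conventional radiocarbon age, 14C years BP.
#' @param sigma One-sigma measurement error, 14C years (> 0).
#' @param lab_code Laboratory code, e.g. `"Beta-495523"`.
#' @return An object of class `radiocarbon_date`.
#' @export
radiocarbon_date <- function(age_bp, sigma, lab_code = "") {
  stopifnot(is.numeric(age_bp), is.finite(age_bp),
            is.numeric(sigma), is.finite(sigma))
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(lab_code = lab_code, age_bp = age_bp, sigma = sigma),
            class = "radiocarbon_date")
}

#' Construct a calibration curve
#'
#' @param name Curve name.
#' @param cal_bp Calendar ages, years BP (will be sorted ascending).
#' @param c14_age Radiocarbon ages at the calendar knots, 14C years BP.
#' @param c14_sigma One-sigma curve uncertainties, 14C years (>= 0).
#' @return An object of class `calibration_curve`: a data frame with columns
#'   `cal_bp`, `c14_age`, `c14_sigma`, sorted by `cal_bp`.
#' @export
calibration_curve <- function(name, cal_bp, c14_age, c14_sigma) {
  stopifnot(length(cal_bp) == length(c14_age),
            length(cal_bp) == length(c14_sigma))
  if (length(cal_bp) < 2L) stop("calibration curve needs >= 2 rows")
  if (any(c14_sigma < 0)) stop("curve sigmas must be non-negative")
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]
  if (anyDuplicated(cal_bp)) stop("cal_bp values must be distinct")
  df <- data.frame(cal_bp = cal_bp, c14_age = c14_age[o], c14_sigma = c14_sigma[o])
  attr(df, "name") <- name
  class(df) <- c("calibration_curve", "data.frame")
  df
}

#' Read a calibration curve in IntCal ".14c" format
#'
#' Parses the standard 5-column layout (cal BP, 14C age BP, sigma, Delta14C,
#' sigma), comma- or whitespace-separated, `#` comment lines ignored; the
#' first three columns are kept. Rows are sorted by calendar age.
#'
#' @param path Path to the `.14c` file.
#' @param name Curve name; defaults to the file base name.
#' @return A [calibration_curve()].
#' @export
read_curve <- function(path, name = sub("\\.14c$", "", basename(path), ignore.case = TRUE)) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 2L) stop("curve file has fewer than 2 data rows: ", path)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,\\s]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 3L || anyNA(vals[1:3])) {
      stop(sprintf("malformed curve row at line %d of %s: '%s'", i, path, lines[i]))
    }
    vals[1:3]
  })
  m <- do.call(rbind, rows)
  calibration_curve(name, m[, 1], m[, 2], m[, 3])
}

#' Evaluate a calibration curve at calendar ages
#'
#' Linear interpolation of both the curve mean and its one-sigma error
#' between tabulated knots; exact at knots; no extrapolation.
#'
#' @param curve A [calibration_curve()].
#' @param cal_bp Calendar ages (years BP) within the curve domain.
#' @return A list with numeric vectors `mu` and `sigma`.
#' @export
curve_at <- function(curve, cal_bp) {
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- range(curve$cal_bp)
  if (any(cal_bp < rng[1] | cal_bp > rng[2])) {
    stop(sprintf("query outside curve domain [%g, %g] cal BP", rng[1], rng[2]))
  }
  list(mu = stats::approx(curve$cal_bp, curve$c14_age, xout = cal_bp)$y,
       sigma = stats::approx(curve$cal_bp, curve$c14_sigma, xout = cal_bp)$y)
}

#' Local marine reservoir correction
#'
#' Offset of the regional marine reservoir from the global marine curve.
#'
#' @param delta_r Offset, 14C years.
#' @param delta_r_sigma One-sigma uncertainty of the offset (>= 0).
#' @return An object of class `reservoir_correction`.
#' @export
reservoir_correction <- function(delta_r = 0, delta_r_sigma = 0) {
  if (delta_r_sigma < 0) stop("delta_r_sigma must be >= 0")
  structure(list(delta_r = delta_r, delta_r_sigma = delta_r_sigma),
            class = "reservoir_correction")
}

#' Specify a diet-weighted mixed calibration curve
#'
#' Combines an atmospheric and a marine curve in proportion to the consumer's
#' marine dietary fraction `f`; the reservoir offset applies to the marine
#' component only. At a calendar age the mixture is
#' `mu = (1 - f) mu_atm + f (mu_mar + delta_r)` with
#' `sigma^2 = ((1 - f) sigma_atm)^2 + (f sigma_mar)^2 + (f sigma_deltaR)^2`.
#'
#' @param atmospheric,marine [calibration_curve()] objects with overlapping
#'   calendar domains.
#' @param marine_fraction Marine dietary fraction in `[0, 1]`.
#' @param correction A [reservoir_correction()].
#' @param marine_fraction_sigma Optional one-sigma uncertainty on the marine
#'   fraction (default 0 = point fraction). When positive, [calibrate()]
#'   averages the likelihood over `n_fraction_nodes` Gauss-Hermite nodes of
#'   a Normal fraction distribution (nodes clamped to `[0, 1]`).
#' @param n_fraction_nodes Number of quadrature nodes (default 7).
#' @return An object of class `mixed_curve_spec`.
#' @export
mixed_curve_spec <- function(atmospheric, marine, marine_fraction,
                             correction = reservoir_correction(),
                             marine_fraction_sigma = 0,
                             n_fraction_nodes = 7L) {
  stopifnot(inherits(atmospheric, "calibration_curve"),
            inherits(marine, "calibration_curve"),
            inherits(correction, "reservoir_correction"))
  if (marine_fraction < 0 || marine_fraction > 1) {
    stop("marine_fraction must be in [0, 1]")
  }
  if (marine_fraction_sigma < 0) stop("marine_fraction_sigma must be >= 0")
  lo <- max(min(atmospheric$cal_bp), min(marine$cal_bp))
  hi <- min(max(atmospheric$cal_bp), max(marine$cal_bp))
  if (lo >= hi) stop("curve calendar domains do not overlap")
  structure(list(atmospheric = atmospheric, marine = marine,
                 marine_fraction = marine_fraction, correction = correction,
                 marine_fraction_sigma = marine_fraction_sigma,
                 n_fraction_nodes = as.integer(n_fraction_nodes),
                 overlap = c(lo, hi)),
            class = "mixed_curve_spec")
}

# Gauss-Hermite nodes/weights by Golub-Welsch on the Jacobi matrix
# (physicists' weight exp(-x^2)); weights returned normalised to sum 1
.gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  w <- e$vectors[1, ]^2
  list(nodes = e$values, weights = w / sum(w))
}

#' Evaluate a mixed calibration curve
#'
#' @param spec A [mixed_curve_spec()].
#' @param cal_bp Calendar ages within the overlap domain.
#' @return A list with vectors `mu` and `sigma`.
#' @export
mix_curves <- function(spec, cal_bp) {
  stopifnot(inherits(spec, "mixed_curve_spec"))
  if (any(cal_bp < spec$overlap[1] | cal_bp > spec$overlap[2])) {
    stop(sprintf("query outside curve overlap [%g, %g] cal BP",
                 spec$overlap[1], spec$overlap[2]))
  }
  f <- spec$marine_fraction
  atm <- curve_at(spec$atmospheric, cal_bp)
  if (f == 0) return(atm)   # pure atmospheric: reservoir terms drop exactly
  mar <- curve_at(spec$marine, cal_bp)
  list(mu = (1 - f) * atm$mu + f * (mar$mu + spec$correction$delta_r),
       sigma = sqrt(((1 - f) * atm$sigma)^2 + (f * mar$sigma)^2 +
                      (f * spec$correction$delta_r_sigma)^2))
}

.curve_domain <- function(curve_or_spec) {
  if (inherits(curve_or_spec, "mixed_curve_spec")) curve_or_spec$overlap
  else range(curve_or_spec$cal_bp)
}

.curve_eval <- function(curve_or_spec, cal_bp) {
  if (inherits(curve_or_spec, "mixed_curve_spec")) mix_curves(curve_or_spec, cal_bp)
  else curve_at(curve_or_spec, cal_bp)
}

#' Calibrate a radiocarbon date
#'
#' Computes the calendar-age posterior on a uniform grid over the curve
#' domain under a flat calendar prior. At grid age `theta` the unnormalised
#' density is
#' `exp(-(age - mu(theta))^2 / (2 (sigma^2 + sigma_curve(theta)^2))) /
#'  sqrt(sigma^2 + sigma_curve(theta)^2)`.
#' The grid is trimmed to where the likelihood exceeds `support_tol` of its
#' maximum before normalisation (keeps grids small; mass beyond the cut is
#' negligible by construction).
#'
#' @param date A [radiocarbon_date()].
#' @param curve A [calibration_curve()] or [mixed_curve_spec()].
#' @param grid_step Grid spacing in calendar years (>= 1; default 1).
#' @param support_tol Relative likelihood threshold for grid trimming.
#' @return An object of class `calendar_posterior`: list with `grid`
#'   (cal BP, ascending), `density` (sums to 1), `grid_step`, `date`.
#' @export
calibrate <- function(date, curve, grid_step = 1, support_tol = 1e-12) {
  stopifnot(inherits(date, "radiocarbon_date"))
  if (grid_step < 1) stop("grid_step must be >= 1 year")
  dom <- .curve_domain(curve)
  grid <- seq(dom[1], dom[2], by = grid_step)
  lik_for <- function(cv) {
    ev <- .curve_eval(cv, grid)
    v <- date$sigma^2 + ev$sigma^2
    exp(-(date$age_bp - ev$mu)^2 / (2 * v)) / sqrt(v)
  }
  if (inherits(curve, "mixed_curve_spec") && curve$marine_fraction_sigma > 0) {
    # marginalise the marine fraction over Gauss-Hermite nodes of its
    # Normal distribution, clamped to the admissible [0, 1] interval
    gh <- .gauss_hermite(curve$n_fraction_nodes)
    f_nodes <- pmin(1, pmax(0, curve$marine_fraction +
                              sqrt(2) * curve$marine_fraction_sigma * gh$nodes))
    lik <- Reduce(`+`, lapply(seq_along(f_nodes), function(k) {
      cv_k <- curve
      cv_k$marine_fraction <- f_nodes[k]
      cv_k$marine_fraction_sigma <- 0
      gh$weights[k] * lik_for(cv_k)
    }))
  } else {
    lik <- lik_for(curve)
  }
  if (!any(lik > 0)) stop("no support: likelihood is zero over the whole grid")
  lik <- lik / max(lik)
  keep <- range(which(lik > support_tol))
  grid <- grid[keep[1]:keep[2]]
  lik <- lik[keep[1]:keep[2]]
  structure(list(grid = grid, density = lik / sum(lik),
                 grid_step = grid_step, date = date),
            class = "calendar_posterior")
}

#' Convert calendar years BP to calendar years AD
#'
#' @param cal_bp Calendar age(s), years BP (present = AD 1950).
#' @return `1950 - cal_bp`.
#' @export
cal_bp_to_ad <- function(cal_bp) 1950 - cal_bp

#' Highest-posterior-density ranges of a calendar posterior
#'
#' Selects grid points in decreasing density order until the cumulative mass
#' reaches `level`, merges adjacent selected points into contiguous ranges,
#' and reports each range in calAD with its probability mass.
#'
#' @param post A `calendar_posterior` from [calibrate()].
#' @param level Probability level in (0, 1); 0.954 mirrors the conventional
#'   two-sigma reporting.
#' @return An object of class `hpd_ranges`: list with `level` and `ranges`,
#'   a data frame with columns `cal_ad_start`, `cal_ad_end` (ascending,
#'   start <= end), `cal_bp_start`, `cal_bp_end`, and `mass`.
#' @export
hpd_ranges <- function(post, level = 0.954) {
  stopifnot(inherits(post, "calendar_posterior"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  o <- order(post$density, decreasing = TRUE)
  csum <- cumsum(post$density[o])
  n_take <- which(csum >= level)[1]
  if (is.na(n_take)) n_take <- length(o)
  sel <- sort(o[seq_len(n_take)])
  breaks <- which(diff(sel) > 1L)
  starts <- sel[c(1L, breaks + 1L)]
  ends <- sel[c(breaks, length(sel))]
  ranges <- data.frame(
    cal_bp_start = post$grid[ends],    # older bound (larger BP)
    cal_bp_end = post$grid[starts],
    mass = vapply(seq_along(starts), function(i) {
      sum(post$density[starts[i]:ends[i]])
    }, numeric(1))
  )
  ranges$cal_ad_start <- cal_bp_to_ad(ranges$cal_bp_start)
  ranges$cal_ad_end <- cal_bp_to_ad(ranges$cal_bp_end)
  ranges <- ranges[order(ranges$cal_ad_start),
                   c("cal_ad_start", "cal_ad_end", "cal_bp_start",
                     "cal_bp_end", "mass")]
  rownames(ranges) <- NULL
  structure(list(level = level, ranges = ranges), class = "hpd_ranges")
}

#' @export
print.hpd_ranges <- function(x, ...) {
  cat(sprintf("HPD ranges at %.1f%% probability:\n", 100 * x$level))
  for (i in seq_len(nrow(x$ranges))) {
    r <- x$ranges[i, ]
    cat(sprintf("  calAD %d-%d (%.1f%%)\n",
                round(r$cal_ad_start), round(r$cal_ad_end), 100 * r$mass))
  }
  invisible(x)
}

#' Posterior mean and standard deviation of a calendar posterior
#'
#' @param post A `calendar_posterior`.
#' @return Named numeric vector `c(mean, sd)` on the cal BP scale.
#' @export
posterior_summary <- function(post) {
  stopifnot(inherits(post, "calendar_posterior"))
  m <- sum(post$grid * post$density)
  c(mean = m, sd = sqrt(sum((post$grid - m)^2 * post$density)))
}
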