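# Collagen quality control and stable-isotope diet inference.

# molar masses (g/mol) used for the atomic C/N ratio; constants of the module
.MOLAR_MASS_C <- 12.011
.MOLAR_MASS_N <- 14.007

#' Construct an isotope measurement record
#'
#' Bundles one specimen's collagen measurements: stable carbon and nitrogen
#' isotope ratios (per mil vs VPDB / AIR) and elemental carbon and nitrogen
#' content in weight percent.
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param d13C Stable carbon isotope ratio, per mil vs VPDB.
#' @param d15N Stable nitrogen isotope ratio, per mil vs AIR.
#' @param carbon_pct Carbon content of the collagen extract, weight percent.
#' @param nitrogen_pct Nitrogen content, weight percent.
#' @param d13C_bounds,d15N_bounds Sanity bounds for the delta values;
#'   measurements outside them are rejected.
#' @return An object of class `isotope_measurement`.
#' @export
isotope_measurement <- function(specimen_id, d13C, d15N, carbon_pct, nitrogen_pct,
                                d13C_bounds = c(-40, 0), d15N_bounds = c(-5, 30)) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  for (v in list(d13C, d15N, carbon_pct, nitrogen_pct)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("isotope measurement fields must be finite numeric scalars")
    }
  }
  if (d13C < d13C_bounds[1] || d13C > d13C_bounds[2]) {
    stop(sprintf("d13C = %g outside sanity bounds [%g, %g]",
                 d13C, d13C_bounds[1], d13C_bounds[2]))
  }
  if (d15N < d15N_bounds[1] || d15N > d15N_bounds[2]) {
    stop(sprintf("d15N = %g outside sanity bounds [%g, %g]",
                 d15N, d15N_bounds[1], d15N_bounds[2]))
  }
  if (carbon_pct <= 0 || nitrogen_pct <= 0) {
    stop("carbon_pct and nitrogen_pct must be positive")
  }
  structure(list(specimen_id = specimen_id, d13C = d13C, d15N = d15N,
                 carbon_pct = carbon_pct, nitrogen_pct = nitrogen_pct),
            class = "isotope_measurement")
}

#' Read isotope measurements from CSV/TSV
#'
#' Expects header columns `specimen_id, d13C, d15N, carbon_pct, nitrogen_pct`.
#' Field separator is sniffed from the extension (`.tsv` = tab, else comma).
#'
#' @param path Path to the table.
#' @return A list of [isotope_measurement()] objects.
#' @export
read_isotope_measurements <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("specimen_id", "d13C", "d15N", "carbon_pct", "nitrogen_pct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    isotope_measurement(as.character(df$specimen_id[i]), df$d13C[i], df$d15N[i],
                        df$carbon_pct[i], df$nitrogen_pct[i])
  })
}

#' Atomic carbon/nitrogen ratio of collagen
#'
#' Converts weight-percent elemental composition to a molar C/N ratio,
#' `(C% / 12.011) / (N% / 14.007)`. Well-preserved bone collagen falls in
#' the 2.9--3.6 range; values outside it indicate degradation or
#' contamination (e.g. humic acids).
#'
#' @param carbon_pct Carbon content, weight percent (> 0).
#' @param nitrogen_pct Nitrogen content, weight percent (> 0).
#' @return The dimensionless atomic C/N ratio.
#' @examples
#' atomic_cn_ratio(15.82, 4.85) # ~3.8
#' @export
atomic_cn_ratio <- function(carbon_pct, nitrogen_pct) {
  if (!is.numeric(carbon_pct) || !is.numeric(nitrogen_pct) ||
      any(!is.finite(carbon_pct)) || any(!is.finite(nitrogen_pct))) {
    stop("carbon_pct and nitrogen_pct must be finite numerics")
  }
  if (any(carbon_pct <= 0) || any(nitrogen_pct <= 0)) {
    stop("carbon_pct and nitrogen_pct must be positive")
  }
  (carbon_pct / .MOLAR_MASS_C) / (nitrogen_pct / .MOLAR_MASS_N)
}

#' Collagen preservation quality control
#'
#' Flags whether a specimen's atomic C/N ratio lies inside the recommended
#' range for well-preserved collagen (default 2.9--3.6, boundaries
#' inclusive).
#'
#' @param m An [isotope_measurement()].
#' @param range Length-2 numeric, the recommended `[low, high]` interval.
#' @return A list of class `collagen_qc` with `atomic_cn_ratio`,
#'   `within_recommended` and `recommended_range`.
#' @export
collagen_qc <- function(m, range = c(2.9, 3.6)) {
  stopifnot(inherits(m, "isotope_measurement"))
  if (length(range) != 2L || !is.numeric(range) || range[1] >= range[2]) {
    stop("range must be numeric [low, high] with low < high")
  }
  ratio <- atomic_cn_ratio(m$carbon_pct, m$nitrogen_pct)
  structure(list(specimen_id = m$specimen_id,
                 atomic_cn_ratio = ratio,
                 within_recommended = ratio >= range[1] && ratio <= range[2],
                 recommended_range = range),
            class = "collagen_qc")
}

#' @export
print.collagen_qc <- function(x, ...) {
  cat(sprintf("Collagen QC for %s: atomic C/N = %.1f (%s recommended range [%g, %g])\n",
              x$specimen_id, x$atomic_cn_ratio,
              if (x$within_recommended) "within" else "OUTSIDE",
              x$recommended_range[1], x$recommended_range[2]))
  invisible(x)
}

#' Diet endmembers for carbon-isotope mixing
#'
#' Pure-terrestrial and pure-marine collagen d13C reference values between
#' which a consumer's d13C is interpolated. Defaults follow the Arneborg-style
#' two-endmember convention (-21.0 per mil terrestrial, -12.5 per mil marine).
#'
#' @param d13C_terrestrial,d13C_marine Endmember d13C values, per mil.
#' @return A list of class `diet_endmembers`.
#' @export
diet_endmembers <- function(d13C_terrestrial = -21.0, d13C_marine = -12.5) {
  if (d13C_terrestrial == d13C_marine) stop("endmembers must be distinct")
  structure(list(d13C_terrestrial = d13C_terrestrial, d13C_marine = d13C_marine),
            class = "diet_endmembers")
}

#' Marine dietary fraction from collagen d13C
#'
#' Linear two-endmember mixing:
#' `f = (d13C - d13C_terrestrial) / (d13C_marine - d13C_terrestrial)`,
#' clamped to `[0, 1]`.
#'
#' @param d13C Specimen collagen d13C, per mil.
#' @param em A [diet_endmembers()] object.
#' @return The marine fraction in `[0, 1]`.
#' @examples
#' marine_fraction(-18.87, diet_endmembers()) # ~0.251
#' @export
marine_fraction <- function(d13C, em = diet_endmembers()) {
  stopifnot(inherits(em, "diet_endmembers"))
  f <- (d13C - em$d13C_terrestrial) / (em$d13C_marine - em$d13C_terrestrial)
  pmin(1, pmax(0, f))
}

#' Invert the mixing model: d13C implied by a marine fraction
#'
#' @param f Marine fraction (unclamped; any numeric).
#' @param em A [diet_endmembers()] object.
#' @return The d13C value whose unclamped [marine_fraction()] equals `f`.
#' @export
d13C_from_fraction <- function(f, em = diet_endmembers()) {
  stopifnot(inherits(em, "diet_endmembers"))
  em$d13C_terrestrial + f * (em$d13C_marine - em$d13C_terrestrial)
}

#' Build a bivariate isotope reference cluster
#'
#' A reference population of (d13C, d15N) pairs with its sample mean and
#' covariance, used to ask whether a specimen plots inside the population's
#' dietary scatter.
#'
#' @param label Cluster label.
#' @param d13C,d15N Numeric vectors of equal length (>= 3 members).
#' @return A list of class `reference_cluster` with `label`, `members`
#'   (two-column matrix), `mean` and `covariance`.
#' @export
reference_cluster <- function(label, d13C, d15N) {
  stopifnot(is.character(label), length(d13C) == length(d15N))
  if (length(d13C) < 3L) stop("cluster needs >= 3 members to estimate covariance")
  members <- cbind(d13C = as.numeric(d13C), d15N = as.numeric(d15N))
  covm <- stats::cov(members)
  structure(list(label = label, members = members,
                 mean = colMeans(members), covariance = covm),
            class = "reference_cluster")
}

#' Read a reference cluster from CSV
#'
#' Expects columns `label, d13C, d15N`, one row per reference individual;
#' all rows must share one label.
#'
#' @param path CSV path.
#' @return A [reference_cluster()].
#' @export
read_reference_cluster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "d13C", "d15N")
  if (!all(need %in% names(df))) {
    stop("reference CSV needs columns: ", paste(need, collapse = ", "))
  }
  lab <- unique(df$label)
  if (length(lab) != 1L) stop("reference CSV must contain a single cluster label")
  reference_cluster(lab, df$d13C, df$d15N)
}

#' Mahalanobis distance of a specimen to a reference cluster
#'
#' Distance is computed under the cluster's sample covariance; the specimen
#' is called inside the cluster's ellipse when the squared distance does not
#' exceed the chi-square quantile with 2 degrees of freedom at `level`.
#'
#' @param point Length-2 numeric `(d13C, d15N)`.
#' @param cluster A [reference_cluster()].
#' @param level Coverage level of the ellipse (default 0.95).
#' @return A list with `mahalanobis_distance`, `inside_ellipse`, `level`.
#' @export
cluster_distance <- function(point, cluster, level = 0.95) {
  stopifnot(inherits(cluster, "reference_cluster"),
            is.numeric(point), length(point) == 2L)
  det_cov <- det(cluster$covariance)
  if (!is.finite(det_cov) || det_cov <= .Machine$double.eps * max(diag(cluster$covariance))^2) {
    stop("degenerate cluster: covariance is singular")
  }
  d2 <- as.numeric(stats::mahalanobis(matrix(point, nrow = 1),
                                      cluster$mean, cluster$covariance))
  list(mahalanobis_distance = sqrt(d2),
       inside_ellipse = d2 <= stats::qchisq(level, df = 2),
       level = level)
}
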