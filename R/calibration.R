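# Standard-curve construction and analytical validation.
#
# The calibration relates final green pixel intensity (y) to
# extraction-measured chlorophyll concentration (x, ug/ml) by ordinary least
# squares over the response's linear interval. Validation follows the usual
# spectrophotometric-method workflow: limit of blank and limit of detection by
# the mean + 1.645 SD convention, precision as the mean percent relative
# standard deviation of back-predicted concentrations, and pointwise 95%
# confidence bands for the fitted mean response.

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors (concentration and GPI). Alternatively `x` may
#'   be a data frame with columns `chl` and `gpi_final`.
#' @return A list with `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `r_squared`, `residual_sd` (root mean squared error on n - 2 df), `n`,
#'   `x_mean`, `ssx` (sum of squared x deviations) and `df_residual`.
#' @export
fit_linear <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("chl", "gpi_final") %in% names(x))) {
      stop_contract("calibration points must have columns chl and gpi_final")
    }
    y <- x$gpi_final
    x <- x$chl
  }
  if (length(x) != length(y)) stop_contract("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_contract("at least 3 points are required for a fit")
  if (diff(range(x)) == 0) stop_contract("singular fit: all x values identical")

  fit <- stats::lm(y ~ x)
  # noise-free inputs are legitimate here (exact fixtures); silence only the
  # "essentially perfect fit" notice that summary.lm emits for them
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  list(
    slope = unname(co["x", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["x", "Std. Error"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    n = n,
    x_mean = mean(x),
    ssx = sum((x - mean(x))^2),
    df_residual = n - 2L
  )
}

#' Detect the linear interval of a calibration dataset
#'
#' A colorimetric response saturates at high pigment concentration, so the
#' calibration is restricted to the range over which it is linear. Points are
#' sorted by concentration and the highest-concentration point is removed
#' repeatedly, recomputing the coefficient of determination after each
#' removal, for as long as removal improves it; the first prefix (of at least
#' 3 points) whose R-squared is not improved by further removal is retained.
#' Stopping at the first non-improvement - rather than taking the global
#' maximum over all prefix sizes - matters statistically: once the retained
#' range is noise-limited, shrinking it further shrinks the concentration
#' spread and R-squared can only exceed the linear-range value by chance, so
#' a global maximum is routinely captured by small near-collinear subsets and
#' would discard most of the genuine linear interval.
#'
#' @param points Data frame with columns `chl` and `gpi_final` (other columns
#'   are carried through).
#' @return A list with `points` (the retained subset, sorted by `chl`),
#'   `upper_limit_chl` (largest retained concentration), `upper_limit_gpi`
#'   (fitted GPI at that concentration), `fit` (the [fit_linear()] result on
#'   the retained subset) and `r2_by_size` (named vector of R-squared per
#'   prefix size, for diagnostics).
#' @export
find_linear_interval <- function(points) {
  if (!is.data.frame(points) || !all(c("chl", "gpi_final") %in% names(points))) {
    stop_contract("calibration points must have columns chl and gpi_final")
  }
  pts <- points[order(points$chl), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) stop_contract("at least 3 calibration points are required")
  if (length(unique(pts$chl)) < 3L) {
    stop_contract("at least 3 distinct concentrations are required")
  }

  r2 <- rep(NA_real_, n)
  for (k in 3:n) {
    r2[k] <- fit_linear(pts$chl[1:k], pts$gpi_final[1:k])$r_squared
  }
  # Walk down from the full set; stop as soon as dropping the top point no
  # longer strictly improves R^2 (ties stop too, keeping the wider interval).
  best_k <- n
  while (best_k > 3L && r2[best_k - 1L] > r2[best_k]) {
    best_k <- best_k - 1L
  }

  retained <- pts[1:best_k, , drop = FALSE]
  fit <- fit_linear(retained$chl, retained$gpi_final)
  upper_chl <- max(retained$chl)
  list(
    points = retained,
    upper_limit_chl = upper_chl,
    upper_limit_gpi = fit$slope * upper_chl + fit$intercept,
    fit = fit,
    r2_by_size = stats::setNames(r2[3:n], 3:n)
  )
}

#' Pointwise confidence band for the fitted mean response
#'
#' Classical t-based band for the conditional mean of a simple linear
#' regression: `yhat(x) +/- t(1 - alpha/2, n - 2) * s * sqrt(1/n +
#' (x - xbar)^2 / SSx)`.
#'
#' @param fit A [fit_linear()] result or a [calibration_curve()].
#' @param x_grid Concentrations at which to evaluate the band.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `x`, `fit`, `lwr`, `upr`, `half_width`.
#' @export
confidence_band <- function(fit, x_grid, level = 0.95) {
  fit <- as_line_fit(fit)
  if (length(x_grid) == 0L) stop_contract("x_grid must be non-empty")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_contract("level must lie in (0, 1)")
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df_residual)
  yhat <- fit$slope * x_grid + fit$intercept
  hw <- tq * fit$residual_sd * sqrt(1 / fit$n + (x_grid - fit$x_mean)^2 / fit$ssx)
  data.frame(x = x_grid, fit = yhat, lwr = yhat - hw, upr = yhat + hw,
             half_width = hw)
}

# Accept either a fit_linear() list or a calibration_curve for band/prediction
# arithmetic.
as_line_fit <- function(fit) {
  if (inherits(fit, "calibration_curve")) {
    need <- c("slope", "intercept", "residual_sd", "n_points", "x_mean", "ssx")
    if (any(vapply(fit[need], function(v) is.null(v) || is.na(v), logical(1)))) {
      stop_contract("curve lacks the fit statistics needed for a band")
    }
    return(list(slope = fit$slope, intercept = fit$intercept,
                residual_sd = fit$residual_sd, n = fit$n_points,
                x_mean = fit$x_mean, ssx = fit$ssx,
                df_residual = fit$n_points - 2L))
  }
  fit
}

#' Limit of blank
#'
#' Highest apparent GPI expected from replicate blank (media-only)
#' measurements: `LoB = mean(blanks) + 1.645 * SD(blanks)` (the standard
#' CLSI-style convention at 95% one-sided coverage). Blank `gpi_final` values
#' are approximately zero by construction and may be negative; they are used
#' as-is.
#'
#' @param blank_gpis At least 3 replicate blank `gpi_final` values.
#' @return The limit of blank in GPI units.
#' @export
limit_of_blank <- function(blank_gpis) {
  blank_gpis <- blank_gpis[is.finite(blank_gpis)]
  if (length(blank_gpis) < 3L) {
    stop_contract("at least 3 blank replicates are required")
  }
  mean(blank_gpis) + 1.645 * stats::sd(blank_gpis)
}

#' Limit of detection
#'
#' Lowest analyte response reliably distinguishable from blank noise:
#' `LoD(GPI) = LoB + 1.645 * SD(low-concentration replicates)`, converted to
#' concentration through the calibration line as
#' `(LoD_gpi - intercept) / slope`, floored at 0.
#'
#' @param lob_gpi Limit of blank in GPI units (from [limit_of_blank()]).
#' @param low_conc_gpis At least 3 replicate GPI measurements of a
#'   low-concentration sample.
#' @param curve A [calibration_curve()] or [fit_linear()] result with positive
#'   slope.
#' @return A list with `lod_gpi` and `lod_conc` (ug/ml).
#' @export
limit_of_detection <- function(lob_gpi, low_conc_gpis, curve) {
  low_conc_gpis <- low_conc_gpis[is.finite(low_conc_gpis)]
  if (length(low_conc_gpis) < 3L) {
    stop_contract("at least 3 low-concentration replicates are required")
  }
  slope <- curve_slope(curve)
  intercept <- curve_intercept(curve)
  if (!is.finite(slope) || slope <= 0) {
    stop_contract("invalid curve: slope must be positive")
  }
  lod_gpi <- lob_gpi + 1.645 * stats::sd(low_conc_gpis)
  list(lod_gpi = lod_gpi, lod_conc = max(0, (lod_gpi - intercept) / slope))
}

curve_slope <- function(curve) {
  if (is.list(curve) && !is.null(curve$slope)) curve$slope else
    stop_contract("curve must carry a slope")
}
curve_intercept <- function(curve) {
  if (is.list(curve) && !is.null(curve$intercept)) curve$intercept else
    stop_contract("curve must carry an intercept")
}

#' Assay precision as mean percent relative standard deviation
#'
#' For each calibration point with triplicate photograph GPIs, each replicate
#' GPI is back-predicted to a concentration through the calibration line and
#' the percent relative standard deviation (100 * SD / mean) of the three
#' predictions computed; the unweighted mean across points is returned.
#' Points whose mean back-predicted concentration is non-positive are excluded
#' with a warning (the ratio is meaningless there).
#'
#' @param points Data frame with replicate columns `gpi_rep1`, `gpi_rep2`,
#'   `gpi_rep3` (or a list column `replicate_gpis`).
#' @param curve Calibration line with positive slope.
#' @return Mean %RSD across usable points (a percentage).
#' @export
percent_rsd <- function(points, curve) {
  reps <- replicate_matrix(points)
  slope <- curve_slope(curve)
  intercept <- curve_intercept(curve)
  if (slope <= 0) stop_contract("invalid curve: slope must be positive")
  pred <- (reps - intercept) / slope
  means <- rowMeans(pred)
  sds <- apply(pred, 1L, stats::sd)
  usable <- means > 0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with non-positive mean back-predicted ",
            "concentration excluded from %RSD", call. = FALSE)
  }
  if (!any(usable)) stop_contract("no usable points for %RSD")
  mean(100 * sds[usable] / means[usable])
}

replicate_matrix <- function(points) {
  rep_cols <- c("gpi_rep1", "gpi_rep2", "gpi_rep3")
  if (is.data.frame(points) && all(rep_cols %in% names(points))) {
    m <- as.matrix(points[, rep_cols])
  } else if (is.data.frame(points) && "replicate_gpis" %in% names(points)) {
    m <- do.call(rbind, points$replicate_gpis)
  } else {
    stop_contract("points must carry replicate GPIs ",
                  "(columns gpi_rep1..3 or list column replicate_gpis)")
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L) stop_contract("no complete replicate triplets")
  m
}

#' Construct a calibration curve object
#'
#' Normally produced by [build_standard_curve()]; the constructor is exported
#' so that a curve can also be assembled from published regression
#' coefficients (e.g. to compare against a printed table).
#'
#' @param slope,intercept Line coefficients (GPI per ug/ml; GPI).
#' @param pigment One of `"a"`, `"b"`, `"total"`.
#' @param slope_se,intercept_se,r_squared,residual_sd,n_points,x_mean,ssx
#'   Fit statistics (optional for manually assembled curves).
#' @param upper_limit_chl Upper end of the linear interval (ug/ml); `Inf` if
#'   not determined.
#' @param upper_limit_gpi Fitted GPI at `upper_limit_chl`.
#' @param lob_gpi,lob_conc,lod_gpi,lod_conc Limits of blank/detection in GPI
#'   and concentration units.
#' @param percent_rsd Mean %RSD of back-predicted concentrations.
#' @param points Retained calibration points (optional).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept,
                              pigment = c("total", "a", "b"),
                              slope_se = NA_real_, intercept_se = NA_real_,
                              r_squared = NA_real_, residual_sd = NA_real_,
                              n_points = NA_integer_,
                              x_mean = NA_real_, ssx = NA_real_,
                              upper_limit_chl = Inf,
                              upper_limit_gpi = NA_real_,
                              lob_gpi = NA_real_, lob_conc = 0,
                              lod_gpi = NA_real_, lod_conc = 0,
                              percent_rsd = NA_real_,
                              points = NULL) {
  pigment <- match.arg(pigment)
  if (!is.finite(slope)) stop_contract("slope must be finite")
  if (!is.finite(intercept)) stop_contract("intercept must be finite")
  if (is.finite(upper_limit_chl) && is.na(upper_limit_gpi)) {
    upper_limit_gpi <- slope * upper_limit_chl + intercept
  }
  if (is.finite(lod_conc) && is.finite(lob_conc) && lod_conc < lob_conc) {
    stop_contract("lod_conc must be >= lob_conc")
  }
  structure(
    list(
      pigment = pigment,
      slope = slope, intercept = intercept,
      slope_se = slope_se, intercept_se = intercept_se,
      r_squared = r_squared, residual_sd = residual_sd,
      n_points = as.integer(n_points),
      x_mean = x_mean, ssx = ssx,
      upper_limit_chl = upper_limit_chl,
      upper_limit_gpi = upper_limit_gpi,
      lob_gpi = lob_gpi, lob_conc = lob_conc,
      lod_gpi = lod_gpi, lod_conc = lod_conc,
      percent_rsd = percent_rsd,
      points = points
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (chlorophyll %s)\n", x$pigment))
  cat(sprintf("  y = %.5g x + %.5g   (GPI vs ug/ml)\n", x$slope, x$intercept))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  R-squared %.4f on %d points\n", x$r_squared, x$n_points))
  }
  if (is.finite(x$upper_limit_chl)) {
    cat(sprintf("  linear interval up to %.4g ug/ml (GPI %.4g)\n",
                x$upper_limit_chl, x$upper_limit_gpi))
  }
  if (is.finite(x$lod_conc)) {
    cat(sprintf("  LoB %.3g ug/ml, LoD %.3g ug/ml", x$lob_conc, x$lod_conc))
    if (is.finite(x$percent_rsd)) cat(sprintf(", %%RSD %.3g", x$percent_rsd))
    cat("\n")
  }
  invisible(x)
}

#' Build and validate a standard curve
#'
#' Full calibration workflow for one pigment: detect the linear interval,
#' fit the line by ordinary least squares, compute the limit of blank from
#' blank replicates, the limit of detection from low-concentration replicates,
#' and precision as mean %RSD of back-predicted concentrations.
#'
#' @param points Data frame of calibration points: columns `chl`, `gpi_final`,
#'   optionally `sample_id` and replicate columns `gpi_rep1..3`.
#' @param blanks Numeric vector of blank (media-only) `gpi_final` replicates,
#'   at least 3.
#' @param pigment Pigment label: `"total"`, `"a"` or `"b"`.
#' @param low_conc_gpis Replicate GPIs of a low-concentration sample for the
#'   limit of detection. Default: the replicate GPIs of the
#'   lowest-concentration non-blank point retained in the linear interval
#'   (requires replicate columns); if replicates are absent the blank
#'   replicates are reused, which makes LoD = 2 * 1.645 * SD(blanks) above the
#'   blank mean.
#' @return A [calibration_curve()].
#' @export
build_standard_curve <- function(points, blanks,
                                 pigment = c("total", "a", "b"),
                                 low_conc_gpis = NULL) {
  pigment <- match.arg(pigment)
  interval <- find_linear_interval(points)
  fit <- interval$fit
  if (fit$slope <= 0) {
    stop_contract("calibration slope is non-positive; the response must ",
                  "increase with concentration")
  }
  lob_gpi <- limit_of_blank(blanks)
  lob_conc <- max(0, (lob_gpi - fit$intercept) / fit$slope)

  retained <- interval$points
  if (is.null(low_conc_gpis)) {
    rep_cols <- c("gpi_rep1", "gpi_rep2", "gpi_rep3")
    nonblank <- retained[retained$chl > 0, , drop = FALSE]
    if (all(rep_cols %in% names(retained)) && nrow(nonblank) > 0L) {
      lowest <- nonblank[which.min(nonblank$chl), rep_cols]
      low_conc_gpis <- as.numeric(lowest)
    } else {
      low_conc_gpis <- blanks
    }
  }
  lod <- limit_of_detection(lob_gpi, low_conc_gpis, fit)

  rsd <- NA_real_
  rep_cols <- c("gpi_rep1", "gpi_rep2", "gpi_rep3")
  has_reps <- all(rep_cols %in% names(retained)) ||
    "replicate_gpis" %in% names(retained)
  if (has_reps) {
    # The linear interval's lower limit is the LoD, so precision is assessed
    # over points the method can actually quantify.
    inside <- retained[retained$chl >= max(lod$lod_conc, .Machine$double.eps), ,
                       drop = FALSE]
    if (nrow(inside) > 0L) {
      rsd <- percent_rsd(inside, fit)
    }
  }

  calibration_curve(
    slope = fit$slope, intercept = fit$intercept, pigment = pigment,
    slope_se = fit$slope_se, intercept_se = fit$intercept_se,
    r_squared = fit$r_squared, residual_sd = fit$residual_sd,
    n_points = fit$n, x_mean = fit$x_mean, ssx = fit$ssx,
    upper_limit_chl = interval$upper_limit_chl,
    upper_limit_gpi = interval$upper_limit_gpi,
    lob_gpi = lob_gpi, lob_conc = lob_conc,
    lod_gpi = lod$lod_gpi, lod_conc = lod$lod_conc,
    percent_rsd = rsd,
    points = retained
  )
}

#' Inverse prediction of chlorophyll concentration from GPI
#'
#' Inverts the calibration line: `chl = (gpi_final - intercept) / slope`.
#' Each prediction carries a status flag: `"ok"` inside the validated range,
#' `"below_LoD"` when the estimate falls below the limit of detection, and
#' `"dilute_sample"` when the measured GPI exceeds the upper limit of the
#' linear interval (the response is saturating there; the sample should be
#' diluted and re-photographed). Values are reported in all cases.
#'
#' @param curve A [calibration_curve()] with positive slope.
#' @param gpi Measured `gpi_final` value(s).
#' @return Data frame with columns `gpi_final`, `chl`, `status`.
#' @export
predict_chlorophyll <- function(curve, gpi) {
  slope <- curve_slope(curve)
  intercept <- curve_intercept(curve)
  if (!is.finite(slope) || slope <= 0) {
    stop_contract("invalid curve: slope must be positive")
  }
  chl <- (gpi - intercept) / slope
  lod <- if (is.finite(curve$lod_conc)) curve$lod_conc else 0
  upper_gpi <- if (!is.null(curve$upper_limit_gpi) &&
                   is.finite(curve$upper_limit_gpi)) {
    curve$upper_limit_gpi
  } else {
    Inf
  }
  status <- ifelse(gpi > upper_gpi, "dilute_sample",
                   ifelse(chl < lod, "below_LoD", "ok"))
  data.frame(gpi_final = gpi, chl = chl, status = status,
             stringsAsFactors = FALSE)
}
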