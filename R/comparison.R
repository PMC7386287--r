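# Statistical comparison of calibration curves across conditions.
#
# Two calibration datasets (control vs an environmental condition) are
# compared ANCOVA-style: a full linear model with separate slopes and
# intercepts per group is fitted, the slope difference is F-tested via the
# group:concentration interaction, and - only when slopes are compatible -
# the interaction is dropped and the intercept difference F-tested via the
# group main effect. Residual normality is summarized, not enforced, mirroring
# the visual Q-Q inspection such analyses use.

#' Compare two calibration datasets by general linear model
#'
#' Fits `gpi_final ~ group + chl + group:chl` over the pooled points and tests
#' equality of slopes by the F-test on the interaction term. If the slopes are
#' not significantly different at `alpha`, the interaction is removed and
#' equality of intercepts tested by the F-test on the group term; otherwise
#' the intercept test is not reported (comparing intercepts of lines with
#' different slopes is not meaningful).
#'
#' @param control_points,variable_points Data frames with columns `chl` and
#'   `gpi_final`; at least 3 points each after filtering.
#' @param alpha Significance level for the sequential testing (default 0.05).
#' @param gpi_max Optional GPI cutoff: points with `gpi_final > gpi_max` are
#'   excluded from both groups before fitting, restricting the comparison to
#'   the shared linear interval (use the control curve's `upper_limit_gpi`).
#'   `NULL` (default) compares the datasets as given.
#' @return An object of class `curve_comparison`: F statistic, degrees of
#'   freedom and p-value for the slope test; the same for the intercept test
#'   when performed (`NA` otherwise); `slopes_equal` / `intercepts_equal`
#'   flags at `alpha`; per-group slopes and intercepts; and a residual
#'   normality summary (skewness and kurtosis of the full-model residuals).
#' @export
compare_curves <- function(control_points, variable_points, alpha = 0.05,
                           gpi_max = NULL) {
  check_pts <- function(p, what) {
    if (!is.data.frame(p) || !all(c("chl", "gpi_final") %in% names(p))) {
      stop_contract(what, " points must have columns chl and gpi_final")
    }
    p[is.finite(p$chl) & is.finite(p$gpi_final), c("chl", "gpi_final")]
  }
  ctl <- check_pts(control_points, "control")
  var_ <- check_pts(variable_points, "variable")
  if (!is.null(gpi_max)) {
    ctl <- ctl[ctl$gpi_final <= gpi_max, , drop = FALSE]
    var_ <- var_[var_$gpi_final <= gpi_max, , drop = FALSE]
  }
  if (nrow(ctl) < 3L || nrow(var_) < 3L) {
    stop_contract("each group needs at least 3 points within the compared range")
  }

  dat <- rbind(
    data.frame(chl = ctl$chl, gpi = ctl$gpi_final, group = "control"),
    data.frame(chl = var_$chl, gpi = var_$gpi_final, group = "variable")
  )
  dat$group <- factor(dat$group, levels = c("control", "variable"))

  full <- stats::lm(gpi ~ group + chl + group:chl, data = dat)
  common_slope <- stats::lm(gpi ~ group + chl, data = dat)
  slope_test <- stats::anova(common_slope, full)
  f_slope <- slope_test$F[2L]
  p_slope <- slope_test$`Pr(>F)`[2L]
  df_slope <- c(slope_test$Df[2L], slope_test$Res.Df[2L])

  f_intercept <- NA_real_
  p_intercept <- NA_real_
  df_intercept <- c(NA_integer_, NA_integer_)
  intercepts_equal <- NA
  if (p_slope >= alpha) {
    common_line <- stats::lm(gpi ~ chl, data = dat)
    int_test <- stats::anova(common_line, common_slope)
    f_intercept <- int_test$F[2L]
    p_intercept <- int_test$`Pr(>F)`[2L]
    df_intercept <- c(int_test$Df[2L], int_test$Res.Df[2L])
    intercepts_equal <- p_intercept >= alpha
  }

  co <- stats::coef(full)
  res <- stats::residuals(full)
  structure(
    list(
      alpha = alpha,
      n_control = nrow(ctl), n_variable = nrow(var_),
      f_slope = f_slope, df_slope = df_slope, p_slope = p_slope,
      slopes_equal = p_slope >= alpha,
      f_intercept = f_intercept, df_intercept = df_intercept,
      p_intercept = p_intercept, intercepts_equal = intercepts_equal,
      slope_control = unname(co["chl"]),
      slope_variable = unname(co["chl"] + co["groupvariable:chl"]),
      intercept_control = unname(co["(Intercept)"]),
      intercept_variable = unname(co["(Intercept)"] + co["groupvariable"]),
      residual_skewness = moment_skewness(res),
      residual_kurtosis = moment_kurtosis(res)
    ),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat("Calibration curve comparison (control vs variable)\n")
  cat(sprintf("  n = %d / %d points, alpha = %.3g\n",
              x$n_control, x$n_variable, x$alpha))
  cat(sprintf("  slope:     F(%d, %d) = %.3f, p = %.3g -> %s\n",
              x$df_slope[1L], x$df_slope[2L], x$f_slope, x$p_slope,
              if (x$slopes_equal) "no significant difference"
              else "slopes differ"))
  if (!is.na(x$f_intercept)) {
    cat(sprintf("  intercept: F(%d, %d) = %.3f, p = %.3g -> %s\n",
                x$df_intercept[1L], x$df_intercept[2L], x$f_intercept,
                x$p_intercept,
                if (isTRUE(x$intercepts_equal)) "no significant difference"
                else "intercepts differ"))
  } else {
    cat("  intercept: not tested (slopes differ)\n")
  }
  cat(sprintf("  residuals: skewness %.3f, kurtosis %.3f\n",
              x$residual_skewness, x$residual_kurtosis))
  invisible(x)
}

#' Interference error when reusing the control standard curve
#'
#' Quantifies the error committed by reading a sample measured under an
#' altered condition off the control standard curve. At the control curve's
#' maximum measurable concentration and at half that concentration, the
#' control line maps the concentration to a GPI; inverting the condition's own
#' line at that GPI gives the "actual" concentration a sample showing that GPI
#' would have, and the signed percentage error is
#' `100 * (predicted - actual) / actual` where predicted is the control-curve
#' concentration.
#'
#' @param control_curve A [calibration_curve()] with a finite
#'   `upper_limit_chl` (the errors are defined only within the control linear
#'   interval).
#' @param variable_curve A [calibration_curve()] for the altered condition
#'   (positive slope required).
#' @details When both intercepts are zero the error reduces to
#'   `100 * (slope_variable / slope_control - 1)` at every level — it is
#'   independent of concentration, and exchanging the two curves flips its
#'   sign (with the magnitude rescaled by the slope ratio). With unequal
#'   intercepts no such symmetry holds.
#' @return Data frame with one row per level (`"max"`, `"half_max"`):
#'   `conc_control` (the concentration read off the control curve), `gpi`,
#'   `conc_actual` (through the condition's line) and `pct_error` (signed).
#' @export
interference_error_table <- function(control_curve, variable_curve) {
  cs <- curve_slope(control_curve)
  vs <- curve_slope(variable_curve)
  if (!is.finite(cs) || cs <= 0) stop_contract("invalid control curve: slope must be positive")
  if (!is.finite(vs) || vs <= 0) stop_contract("invalid variable curve: slope must be positive")
  upper <- control_curve$upper_limit_chl
  if (is.null(upper) || !is.finite(upper)) {
    stop_contract("control curve must have a finite upper_limit_chl")
  }
  conc <- c(max = upper, half_max = upper / 2)
  g <- cs * conc + curve_intercept(control_curve)
  actual <- (g - curve_intercept(variable_curve)) / vs
  if (any(actual <= 0)) {
    stop_contract("condition line inverts to a non-positive concentration; ",
                  "percentage error undefined")
  }
  data.frame(
    level = names(conc),
    conc_control = unname(conc),
    gpi = unname(g),
    conc_actual = unname(actual),
    pct_error = unname(100 * (conc - actual) / actual),
    stringsAsFactors = FALSE
  )
}

#' Smallest detectable slope difference (sensitivity power analysis)
#'
#' Solves for the smallest absolute slope difference between two independent
#' simple linear regressions that a two-tailed t-test of slope equality
#' detects with the requested power. The test statistic is
#' `Delta / SE(Delta)` with `SE(Delta) = residual_sd * sqrt(1/SSx_control +
#' 1/SSx_variable)` on `n_control + n_variable - 4` degrees of freedom; power
#' is evaluated with the noncentral t distribution and the detectable
#' difference found by bisection.
#'
#' @param n_control,n_variable Group sample sizes (>= 3 each).
#' @param ssx_control,ssx_variable Sums of squared concentration deviations
#'   within each group (must be positive).
#' @param residual_sd Common residual standard deviation (GPI units).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param rel_tol Relative bisection tolerance (default 1e-10).
#' @return An object of class `power_spec`: the inputs plus
#'   `detectable_delta_slope`, `se_delta`, `df` and `achieved_power`.
#' @export
detectable_slope_difference <- function(n_control, n_variable,
                                        ssx_control, ssx_variable,
                                        residual_sd,
                                        alpha = 0.05, power = 0.80,
                                        rel_tol = 1e-10) {
  if (!is_count(n_control) || !is_count(n_variable) ||
      n_control < 3 || n_variable < 3) {
    stop_contract("group sizes must be integers >= 3")
  }
  if (ssx_control <= 0 || ssx_variable <= 0) stop_contract("SSx values must be positive")
  if (residual_sd <= 0) stop_contract("residual_sd must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) {
    stop_contract("require 0 < alpha < power < 1")
  }

  df <- n_control + n_variable - 4
  se <- residual_sd * sqrt(1 / ssx_control + 1 / ssx_variable)
  tcrit <- stats::qt(1 - alpha / 2, df)
  pw <- function(delta) {
    ncp <- delta / se
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  }

  lo <- 0
  hi <- se * (tcrit + stats::qt(power, df)) * 2  # generous upper bracket
  it <- 0L
  while (pw(hi) < power) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L) {
      stop("power solve failed to bracket: power(", format(hi), ") = ",
           format(pw(hi)), " < ", power, call. = FALSE)
    }
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power) lo <- mid else hi <- mid
    if ((hi - lo) <= rel_tol * hi) break
  }
  delta <- hi
  structure(
    list(
      alpha = alpha, power = power,
      n_control = n_control, n_variable = n_variable,
      ssx_control = ssx_control, ssx_variable = ssx_variable,
      residual_sd = residual_sd,
      df = df, se_delta = se,
      detectable_delta_slope = delta,
      achieved_power = pw(delta)
    ),
    class = "power_spec"
  )
}

#' @export
print.power_spec <- function(x, ...) {
  cat("Sensitivity power analysis: difference between two regression slopes\n")
  cat(sprintf("  alpha = %.3g (two-tailed), power = %.3g, df = %d\n",
              x$alpha, x$power, x$df))
  cat(sprintf("  SE(delta slope) = %.4g\n", x$se_delta))
  cat(sprintf("  detectable |delta slope| = %.5g GPI per ug/ml\n",
              x$detectable_delta_slope))
  invisible(x)
}
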