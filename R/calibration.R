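#' Fit a response-ratio calibration line
#'
#' Ordinary or weighted least squares of the analyte/IS peak-area ratio on
#' the nominal concentration, as used to quantify plasma samples. Blanks
#' and zero samples (role other than `"standard"`, or missing nominal) are
#' excluded from the fit. The correlation coefficient r is the weighted
#' Pearson correlation under the same weights as the fit.
#'
#' @param standards Data.frame with columns `nominal` (ng/mL) and `ratio`
#'   (analyte area / IS area); an optional `role` column restricts the fit
#'   to rows with role `"standard"`. Alternatively a run data.frame from
#'   [simulate_run()]/[read_run_csv()] (with `nominal_ng_ml`,
#'   `analyte_area`, `is_area`) for a single analyte.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`: weights 1,
#'   1/nominal or 1/nominal^2.
#' @param analyte Analyte label stored on the curve.
#' @return Object of class `calibration_curve` with fields `analyte`,
#'   `slope`, `intercept`, `r`, `weighting`, `range_low`, `range_high`,
#'   `n`.
#' @export
fit_calibration <- function(standards, weighting = c("none", "1/x", "1/x2"),
                            analyte = NA_character_) {
  weighting <- match.arg(weighting)
  df <- as.data.frame(standards)
  if (!"ratio" %in% names(df) &&
      all(c("analyte_area", "is_area") %in% names(df))) {
    df$ratio <- df$analyte_area / df$is_area
  }
  if (!"nominal" %in% names(df) && "nominal_ng_ml" %in% names(df)) {
    df$nominal <- df$nominal_ng_ml
  }
  stopifnot(all(c("nominal", "ratio") %in% names(df)))
  if ("role" %in% names(df)) df <- df[df$role == "standard", ]
  df <- df[is.finite(df$nominal) & df$nominal > 0, ]
  if (nrow(df) < 2) {
    stop("need at least 2 usable calibration standards", call. = FALSE)
  }
  if (length(unique(df$nominal)) < 2) {
    stop("calibration standards must span >= 2 distinct levels",
         call. = FALSE)
  }
  w <- switch(weighting,
              "none" = rep(1, nrow(df)),
              "1/x" = 1 / df$nominal,
              "1/x2" = 1 / df$nominal^2)
  fit <- stats::lm(ratio ~ nominal, data = df, weights = w)
  coefs <- stats::coef(fit)
  # weighted Pearson correlation under the fit weights
  wm <- function(v) sum(w * v) / sum(w)
  mx <- wm(df$nominal); my <- wm(df$ratio)
  sxy <- sum(w * (df$nominal - mx) * (df$ratio - my))
  sxx <- sum(w * (df$nominal - mx)^2)
  syy <- sum(w * (df$ratio - my)^2)
  r <- if (syy == 0) 1 else sxy / sqrt(sxx * syy)
  structure(list(analyte = analyte,
                 slope = unname(coefs[2]), intercept = unname(coefs[1]),
                 r = r, weighting = weighting,
                 range_low = min(df$nominal), range_high = max(df$nominal),
                 n = nrow(df)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s  Y = %.6gX %+.6g  r = %.4f  [%g, %g] ng/mL  (w: %s, n = %d)\n",
    x$analyte, x$slope, x$intercept, x$r, x$range_low, x$range_high,
    x$weighting, x$n))
  invisible(x)
}

#' Back-calculate concentrations from response ratios
#'
#' Inverts the calibration line: X = (ratio - intercept) / slope. Values
#' outside the validated range are flagged `out_of_range`; negative
#' back-calculated values are reported as-is with a `blq` flag so callers
#' can exclude them from summaries.
#'
#' @param curve A [fit_calibration()] result.
#' @param ratio Numeric vector of response ratios.
#' @return Data.frame with columns `ratio`, `conc_ng_ml`, `in_range`,
#'   `blq`.
#' @export
back_calculate <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  conc <- (ratio - curve$intercept) / curve$slope
  # tolerance so a standard at exactly range_low/high is not flagged by
  # floating-point round-off in the inversion
  eps <- 1e-9 * max(abs(curve$range_high), 1)
  data.frame(ratio = ratio, conc_ng_ml = conc,
             in_range = conc >= curve$range_low - eps &
               conc <= curve$range_high + eps,
             blq = conc < 0)
}

#' Assess a calibration curve against back-calculation acceptance rules
#'
#' Each standard is back-calculated through the fitted curve and its
#' accuracy (percent of nominal) computed. A standard passes when its
#' deviation from nominal is within +/-15% (inclusive), relaxed to +/-20%
#' at the lowest level (the LLOQ). The curve as a whole passes when at
#' least 75% of standards pass and both the LLOQ and the highest level
#' pass.
#'
#' @param curve A [fit_calibration()] result.
#' @param standards The standards the curve was fitted from (same accepted
#'   shapes as in [fit_calibration()]).
#' @param tol Acceptance half-width in percent for non-LLOQ levels
#'   (default 15).
#' @param tol_lloq Acceptance half-width at the lowest level (default 20).
#' @return List with `table` (per-standard nominal, back-calculated
#'   concentration, accuracy_pct, pass), `pass_fraction`, `lloq_pass`,
#'   `top_pass`, `curve_pass`.
#' @export
assess_curve <- function(curve, standards, tol = 15, tol_lloq = 20) {
  stopifnot(inherits(curve, "calibration_curve"))
  df <- as.data.frame(standards)
  if (!"ratio" %in% names(df) &&
      all(c("analyte_area", "is_area") %in% names(df))) {
    df$ratio <- df$analyte_area / df$is_area
  }
  if (!"nominal" %in% names(df) && "nominal_ng_ml" %in% names(df)) {
    df$nominal <- df$nominal_ng_ml
  }
  if ("role" %in% names(df)) df <- df[df$role == "standard", ]
  df <- df[is.finite(df$nominal) & df$nominal > 0, ]
  bc <- back_calculate(curve, df$ratio)
  acc <- accuracy_percent(bc$conc_ng_ml, df$nominal)
  lloq_level <- min(df$nominal)
  top_level <- max(df$nominal)
  lim <- ifelse(df$nominal == lloq_level, tol_lloq, tol)
  pass <- abs(acc - 100) <= lim
  tab <- data.frame(nominal = df$nominal, back_calc = bc$conc_ng_ml,
                    accuracy_pct = acc, pass = pass)
  lloq_pass <- all(pass[df$nominal == lloq_level])
  top_pass <- all(pass[df$nominal == top_level])
  frac <- mean(pass)
  list(table = tab, pass_fraction = frac, lloq_pass = lloq_pass,
       top_pass = top_pass,
       curve_pass = frac >= 0.75 && lloq_pass && top_pass)
}

#' Preset calibration designs for the MET/CFZ assay
#'
#' Eight non-zero calibration levels spanning the validated ranges
#' 50-5000 ng/mL (MET) and 10-1000 ng/mL (CFZ), and the reference
#' response-ratio lines Y = 0.0016 X - 0.0088 (MET) and
#' Y = 0.0056 X - 0.0036 (CFZ).
#'
#' @return List with `levels` (named list of nominal vectors), `slope`,
#'   `intercept` (named numerics) and `qc_levels` (named list of named
#'   LLOQ/LQC/MQC/HQC vectors).
#' @export
default_calibration_design <- function() {
  list(
    levels = list(
      MET = c(50, 100, 250, 500, 1000, 2000, 4000, 5000),
      CFZ = c(10, 20, 50, 100, 200, 400, 800, 1000)),
    slope = c(MET = 0.0016, CFZ = 0.0056),
    intercept = c(MET = -0.0088, CFZ = -0.0036),
    qc_levels = list(
      MET = c(LLOQ = 50, LQC = 150, MQC = 1000, HQC = 4000),
      CFZ = c(LLOQ = 10, LQC = 30, MQC = 200, HQC = 800))
  )
}
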