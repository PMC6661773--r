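# Independent oracles and shared fixtures for the test suite.

# Plain cumulative trapezoid, used as the integration oracle.
oracle_trapz <- function(t, y) {
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

# Weighted least squares by grid refinement over the slope (no lm), used
# as the calibration oracle. For each candidate slope the optimal
# intercept is the weighted mean residual, so the search is 1-D and the
# grid refinement cannot stall in the slope/intercept valley.
oracle_wls_grid <- function(x, y, w, n_iter = 10) {
  sse_at <- function(b) {
    a <- sum(w * (y - b * x)) / sum(w)
    sum(w * (y - a - b * x)^2)
  }
  b_best <- sum(w * x * y) / sum(w * x^2) # rough start
  span <- abs(b_best) + 1
  for (it in seq_len(n_iter)) {
    bs <- seq(b_best - span, b_best + span, length.out = 41)
    b_best <- bs[which.min(vapply(bs, sse_at, numeric(1)))]
    span <- span / 15
  }
  a_best <- sum(w * (y - b_best * x)) / sum(w)
  c(intercept = a_best, slope = b_best)
}

# Adjusted R^2 of ln(conc) on time computed via cor(), independent of the
# package's closed-form regression path.
oracle_adj_r2 <- function(t, logc) {
  n <- length(t)
  r2 <- stats::cor(t, logc)^2
  1 - (1 - r2) * (n - 1) / (n - 2)
}

# The 16-point single-dose sampling schedule used in worked examples.
pk_schedule <- c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 7, 8, 10, 12, 16, 24, 48, 72)

# Reference QC accuracy/precision table: per analyte and level, the
# reported intra-day and inter-day mean found concentrations and the
# accuracy percentages they imply.
qc_reference_table <- data.frame(
  analyte = rep(c("MET", "CFZ"), each = 4),
  level = rep(c("LLOQ", "LQC", "MQC", "HQC"), 2),
  nominal = c(50, 150, 1000, 4000, 10, 30, 200, 800),
  intra_mean = c(47.24, 152.17, 943.81, 3667.95,
                 11.31, 32.73, 181.30, 768.06),
  intra_accuracy = c(94.48, 101.45, 94.38, 91.70,
                     113.10, 109.10, 90.65, 96.01),
  inter_mean = c(48.55, 161.15, 935.77, 3734.26,
                 11.12, 29.95, 176.28, 738.32),
  inter_accuracy = c(97.10, 107.43, 93.58, 93.36,
                     111.20, 99.83, 88.14, 92.29))

# Reference stability table: condition x level mean found and implied
# accuracy for both analytes.
stability_reference_table <- data.frame(
  condition = rep(c("short_term", "freeze_thaw", "dry_extract",
                    "processed", "long_term"), each = 4),
  analyte = rep(c("CFZ", "CFZ", "MET", "MET"), 5),
  nominal = rep(c(30, 800, 150, 4000), 5),
  mean_found = c(26.30, 704.72, 132.38, 3565.06,
                 28.61, 713.42, 141.10, 3552.69,
                 28.54, 696.46, 139.01, 3699.81,
                 28.12, 698.63, 134.03, 3836.46,
                 29.77, 687.82, 130.40, 3619.81),
  accuracy = c(87.67, 88.09, 88.25, 89.13,
               95.37, 89.18, 94.07, 88.82,
               95.13, 87.06, 92.67, 92.50,
               93.73, 87.33, 89.35, 95.91,
               99.23, 85.98, 86.93, 90.50))

# Per-level extraction recoveries and their reported across-level means.
recovery_reference <- list(
  MET = list(per_level = c(LQC = 98.55, MQC = 97.69, HQC = 98.40),
             mean = 98.21),
  CFZ = list(per_level = c(LQC = 90.12, MQC = 94.04, HQC = 98.79),
             mean = 94.32))
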