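#' Round half away from zero
#'
#' Bioanalytical report tables conventionally round halves away from zero
#' (so 91.695 prints as 91.70), unlike [base::round()]'s round-half-even.
#' A tiny relative guard absorbs binary floating-point representation error
#' immediately below the .5 boundary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_away(c(91.695, -91.695, 2.345), 2)
round_half_away <- function(x, digits = 2) {
  scaled <- abs(x) * 10^digits
  sign(x) * floor(scaled + 0.5 + scaled * 1e-12 + 1e-9) / 10^digits
}

#' Sample relative standard deviation as a percentage
#'
#' 100 * sd / mean with the n-1 denominator, the precision statistic of
#' bioanalytical validation reports (often called CV%).
#'
#' @param values Numeric vector of at least two measurements.
#' @param digits Decimals for the reported value (default 2); use `NULL`
#'   for the unrounded statistic.
#' @return RSD as a percentage.
#' @export
#' @examples
#' rsd_percent(c(1, 2, 3)) # 50
rsd_percent <- function(values, digits = 2) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("rsd_percent() needs at least two values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("rsd_percent() undefined for zero mean", call. = FALSE)
  out <- 100 * stats::sd(values) / m
  if (is.null(digits)) out else round_half_away(out, digits)
}

#' Accuracy as percent of nominal
#'
#' 100 * mean found / nominal, the accuracy statistic reported per QC level.
#'
#' @param mean_found Mean back-calculated concentration (ng/mL).
#' @param nominal Nominal spiked concentration (ng/mL), > 0.
#' @param digits Decimals for the reported value (default 2); `NULL` for
#'   the unrounded value.
#' @return Accuracy percentage.
#' @export
#' @examples
#' accuracy_percent(47.24, 50) # 94.48
accuracy_percent <- function(mean_found, nominal, digits = 2) {
  if (any(nominal <= 0)) {
    stop("accuracy_percent() requires nominal > 0", call. = FALSE)
  }
  out <- 100 * mean_found / nominal
  if (is.null(digits)) out else round_half_away(out, digits)
}

# FNV-1a 32-bit hash of a string; used to stamp pipeline outputs with a
# config fingerprint without an external digest dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # modular multiply in two 16-bit halves so doubles stay exact
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a child seed from a base seed and a stage label, kept < 2^31.
derive_seed <- function(seed, label) {
  (as.numeric(seed) * 7919 + sum(as.integer(charToRaw(label)))) %% 2147483647
}
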