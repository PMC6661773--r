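# Non-compartmental analysis of single-dose concentration-time profiles.
#
# BLQ policy (configurable where noted): leading BLQ observations before the
# first measurable concentration are kept with concentration 0; embedded and
# trailing BLQ observations are excluded.

# Apply the BLQ policy; returns a list(time, conc) of usable points.
usable_points <- function(time, conc, blq) {
  stopifnot(length(time) == length(conc), length(blq) == length(conc))
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  blq <- as.logical(blq)
  meas <- which(!blq)
  if (length(meas) == 0) return(list(time = numeric(0), conc = numeric(0)))
  first <- meas[1]
  last <- meas[length(meas)]
  keep <- logical(length(time))
  keep[seq_len(first)] <- TRUE            # leading BLQ kept as zero
  keep[first:last][!blq[first:last]] <- TRUE
  conc2 <- conc
  conc2[seq_len(first - 1)] <- 0
  idx <- which(keep & seq_along(time) <= last)
  # drop embedded BLQ between first and last measurable
  idx <- idx[!(blq[idx] & idx > first)]
  list(time = time[idx], conc = conc2[idx])
}

#' Observed Cmax and tmax
#'
#' Maximum observed concentration and its time, ties broken by the
#' earliest time. BLQ observations are ignored.
#'
#' @param time Sampling times (h), strictly increasing.
#' @param conc Concentrations (ng/mL).
#' @param blq Logical/0-1 BLQ flags (default all measurable).
#' @return List with `cmax` and `tmax`; both `NA` (with `found = FALSE`)
#'   when every point is BLQ.
#' @export
cmax_tmax <- function(time, conc, blq = rep(FALSE, length(conc))) {
  blq <- as.logical(blq)
  ok <- which(!blq)
  if (length(ok) == 0) {
    return(list(cmax = NA_real_, tmax = NA_real_, found = FALSE))
  }
  i <- ok[which.max(conc[ok])] # which.max takes the first (earliest) tie
  list(cmax = conc[i], tmax = time[i], found = TRUE)
}

#' Trapezoidal AUC to the last measurable time
#'
#' Piecewise trapezoidal area under the concentration-time curve.
#' `"linear"` uses the arithmetic trapezoid everywhere;
#' `"linear_up_log_down"` (default) switches to the logarithmic trapezoid
#' `(C1 - C2) * dt / ln(C1/C2)` on segments where the concentration
#' declines between two positive values, which is exact on
#' mono-exponential decay. An interior `t_end` cuts the final segment with
#' interpolation consistent with the method.
#'
#' @inheritParams cmax_tmax
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @param t_end Upper limit of integration (default: last usable time);
#'   must not exceed the last sampling time.
#' @return AUC from time zero (first usable sample) to `t_end`, in
#'   ng*h/mL.
#' @export
auc_trapezoid <- function(time, conc, blq = rep(FALSE, length(conc)),
                          method = c("linear_up_log_down", "linear"),
                          t_end = NULL) {
  method <- match.arg(method)
  up <- usable_points(time, conc, blq)
  if (length(up$time) < 2) {
    stop("AUC needs >= 2 usable points", call. = FALSE)
  }
  t <- up$time
  c_ <- up$conc
  if (is.null(t_end)) t_end <- t[length(t)]
  if (t_end > max(time) + 1e-12) {
    stop("t_end exceeds the last sampling time", call. = FALSE)
  }
  if (t_end > t[length(t)]) t_end <- t[length(t)]
  seg_area <- function(t1, t2, c1, c2) {
    dt <- t2 - t1
    if (method == "linear_up_log_down" && c1 > c2 && c2 > 0) {
      (c1 - c2) * dt / log(c1 / c2)
    } else {
      (c1 + c2) / 2 * dt
    }
  }
  interp <- function(t1, t2, c1, c2, tq) {
    f <- (tq - t1) / (t2 - t1)
    if (method == "linear_up_log_down" && c1 > c2 && c2 > 0) {
      exp(log(c1) + f * (log(c2) - log(c1)))
    } else {
      c1 + f * (c2 - c1)
    }
  }
  auc <- 0
  for (i in seq_len(length(t) - 1)) {
    if (t[i] >= t_end) break
    if (t[i + 1] <= t_end) {
      auc <- auc + seg_area(t[i], t[i + 1], c_[i], c_[i + 1])
    } else {
      cq <- interp(t[i], t[i + 1], c_[i], c_[i + 1], t_end)
      auc <- auc + seg_area(t[i], t_end, c_[i], cq)
      break
    }
  }
  auc
}

#' Terminal elimination rate constant by log-linear regression
#'
#' In `"auto"` mode, every candidate terminal subset (the last 3, 4, ...
#' points strictly after tmax with positive, measurable concentrations)
#' is fitted by least squares of ln C on t; the subset with the highest
#' adjusted R-squared wins, ties going to the larger subset. The result is
#' rejected when the best slope is non-negative. When fewer than three
#' points lie strictly after tmax (a profile already in pure decay), the
#' point at tmax itself is admitted to the candidate pool.
#'
#' @inheritParams cmax_tmax
#' @param selection `"auto"` (default) or a vector of time points to use
#'   explicitly.
#' @return List with `lambda_z` (1/h), `n_points`, `r2_adj`,
#'   `t_half` (= ln 2 / lambda_z), `points` (times used), and `found`.
#'   `found = FALSE` (all else `NA`) when no valid subset exists.
#' @export
fit_lambda_z <- function(time, conc, blq = rep(FALSE, length(conc)),
                         selection = "auto") {
  blq <- as.logical(blq)
  ct <- cmax_tmax(time, conc, blq)
  none <- list(lambda_z = NA_real_, n_points = NA_integer_,
               r2_adj = NA_real_, t_half = NA_real_,
               points = numeric(0), found = FALSE)
  if (!ct$found) return(none)
  ok <- !blq & conc > 0 & time > ct$tmax
  if (sum(ok) < 3) {
    # fall back to including tmax itself (relevant for profiles that are
    # already in pure decay at the first sample)
    ok <- !blq & conc > 0 & time >= ct$tmax
  }
  tt <- time[ok]
  cc <- conc[ok]
  fit_subset <- function(ts, cs) {
    n <- length(ts)
    y <- log(cs)
    # closed-form simple regression; avoids summary.lm warnings on
    # numerically perfect fits
    sxx <- sum((ts - mean(ts))^2)
    sxy <- sum((ts - mean(ts)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    r2 <- if (syy == 0) 1 else min(sxy^2 / (sxx * syy), 1)
    r2a <- 1 - (1 - r2) * (n - 1) / (n - 2)
    list(slope = slope, r2_adj = r2a, n = n)
  }
  if (!identical(selection, "auto")) {
    sel <- time %in% selection & !blq & conc > 0
    if (sum(sel) < 3) return(none)
    f <- fit_subset(time[sel], conc[sel])
    if (f$slope >= 0) return(none)
    lz <- -f$slope
    return(list(lambda_z = lz, n_points = f$n, r2_adj = f$r2_adj,
                t_half = log(2) / lz, points = time[sel], found = TRUE))
  }
  m <- length(tt)
  if (m < 3) return(none)
  best <- NULL
  for (k in 3:m) {
    idx <- (m - k + 1):m
    f <- fit_subset(tt[idx], cc[idx])
    f$points <- tt[idx]
    # strict improvement required, so exact ties favour the larger
    # (later-considered) subset
    if (is.null(best) || f$r2_adj >= best$r2_adj - 1e-12) best <- f
  }
  if (best$slope >= 0) return(none)
  lz <- -best$slope
  list(lambda_z = lz, n_points = best$n, r2_adj = best$r2_adj,
       t_half = log(2) / lz, points = best$points, found = TRUE)
}

#' Extrapolate AUC to infinity
#'
#' `AUCinf = AUClast + Clast / lambda_z`; the extrapolated percentage
#' `100 * (AUCinf - AUClast) / AUCinf` is flagged with a warning above
#' 20%, the conventional reliability limit.
#'
#' @param auc_last AUC to the last measurable concentration (ng*h/mL).
#' @param c_last Last measurable concentration (ng/mL), > 0.
#' @param lambda_z Terminal rate constant (1/h), > 0.
#' @return List with `auc_inf`, `pct_extrapolated`, `reliable`
#'   (pct <= 20).
#' @export
extrapolate_auc <- function(auc_last, c_last, lambda_z) {
  if (!(lambda_z > 0)) stop("lambda_z must be > 0", call. = FALSE)
  if (!(c_last > 0)) stop("c_last must be > 0", call. = FALSE)
  auc_inf <- auc_last + c_last / lambda_z
  pct <- 100 * (auc_inf - auc_last) / auc_inf
  if (pct > 20) {
    warning(sprintf("%.1f%% of AUCinf is extrapolated (> 20%%)", pct))
  }
  list(auc_inf = auc_inf, pct_extrapolated = pct, reliable = pct <= 20)
}

#' Full non-compartmental analysis of one profile
#'
#' Computes Cmax, tmax, AUC to the last measurable point, the terminal
#' slope (auto-selected), half-life and the extrapolated AUCinf for a
#' single subject/analyte profile.
#'
#' @param profile Data.frame with columns `time_h`, `conc_ng_ml` and
#'   optionally `blq`, `subject_id`, `analyte` (as from
#'   [simulate_profile()] or [read_profiles_csv()]).
#' @param method AUC method, see [auc_trapezoid()].
#' @param lambda_selection Passed to [fit_lambda_z()] `selection`.
#' @return One-row data.frame of class `nca_result`: `subject_id,
#'   analyte, cmax, tmax, auc_last, auc_inf, lambda_z, kel, t_half,
#'   pct_extrapolated, n_lambda_points, lambda_r2_adj`.
#' @export
nca <- function(profile, method = c("linear_up_log_down", "linear"),
                lambda_selection = "auto") {
  method <- match.arg(method)
  stopifnot(all(c("time_h", "conc_ng_ml") %in% names(profile)))
  blq <- if ("blq" %in% names(profile)) as.logical(profile$blq)
         else rep(FALSE, nrow(profile))
  t <- profile$time_h
  c_ <- profile$conc_ng_ml
  ct <- cmax_tmax(t, c_, blq)
  auc_last <- auc_trapezoid(t, c_, blq, method = method)
  lz <- fit_lambda_z(t, c_, blq, selection = lambda_selection)
  up <- usable_points(t, c_, blq)
  c_last <- up$conc[length(up$conc)]
  if (lz$found && c_last > 0) {
    ext <- suppressWarnings(extrapolate_auc(auc_last, c_last, lz$lambda_z))
  } else {
    ext <- list(auc_inf = NA_real_, pct_extrapolated = NA_real_)
  }
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(profile))
      profile$subject_id[1] else NA_character_,
    analyte = if ("analyte" %in% names(profile))
      profile$analyte[1] else NA_character_,
    cmax = ct$cmax, tmax = ct$tmax, auc_last = auc_last,
    auc_inf = ext$auc_inf, lambda_z = lz$lambda_z, kel = lz$lambda_z,
    t_half = lz$t_half, pct_extrapolated = ext$pct_extrapolated,
    n_lambda_points = lz$n_points, lambda_r2_adj = lz$r2_adj)
  class(out) <- c("nca_result", "data.frame")
  out
}

#' Cohort summary of NCA results
#'
#' Mean and sample standard deviation (n - 1 denominator) of each PK
#' parameter per analyte, in the conventional `mean +/- SD` layout of a
#' PK parameter table. A single-subject cohort reports SD 0 by
#' convention.
#'
#' @param results Data.frame of [nca()] rows (rbind-ed).
#' @param parameters Which columns to summarise.
#' @return Data.frame with columns `analyte, parameter, mean, sd,
#'   formatted`.
#' @export
summarize_cohort <- function(results,
                             parameters = c("cmax", "tmax", "auc_last",
                                            "auc_inf", "t_half", "kel")) {
  stopifnot("analyte" %in% names(results))
  out <- do.call(rbind, lapply(
    split(results, results$analyte), function(g) {
      do.call(rbind, lapply(parameters, function(p) {
        v <- g[[p]]
        v <- v[is.finite(v)]
        m <- mean(v)
        s <- if (length(v) >= 2) stats::sd(v) else 0
        data.frame(analyte = g$analyte[1], parameter = p, mean = m, sd = s,
                   formatted = sprintf("%.2f ± %.2f",
                                       round_half_away(m, 2),
                                       round_half_away(s, 2)))
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Run NCA on a long-format profile table
#'
#' Splits a profile table by subject and analyte, runs [nca()] on each,
#' and returns the combined result table.
#'
#' @param profiles Data.frame with columns `subject_id, analyte, time_h,
#'   conc_ng_ml, blq`.
#' @inheritParams nca
#' @return Data.frame of one [nca()] row per subject x analyte.
#' @export
nca_by_subject <- function(profiles,
                           method = c("linear_up_log_down", "linear"),
                           lambda_selection = "auto") {
  method <- match.arg(method)
  out <- do.call(rbind, lapply(
    split(profiles, list(profiles$subject_id, profiles$analyte),
          drop = TRUE),
    function(g) nca(g[order(g$time_h), ], method = method,
                    lambda_selection = lambda_selection)))
  rownames(out) <- NULL
  out
}
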