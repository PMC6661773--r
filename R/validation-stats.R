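#' Intra-day and inter-day QC accuracy/precision battery
#'
#' Summarises back-calculated QC measurements per analyte and level.
#' Intra-day statistics use the replicates of a single run (`intra_day`,
#' default day 1); inter-day statistics pool the replicates of all runs
#' (n = replicates x days). A level passes when the accuracy deviates from
#' 100% by at most `tol` percentage points and RSD% is at most `tol`,
#' both relaxed to `tol_lloq` at the LLOQ level.
#'
#' @param measurements Data.frame with columns `analyte`, `level`,
#'   `nominal`, `day`, `found` (as from [simulate_qc_battery()]).
#' @param intra_day Which day provides the intra-day set (default 1).
#' @param tol Acceptance half-width (accuracy deviation and RSD) in
#'   percent, default 15.
#' @param tol_lloq Half-width at the LLOQ level, default 20.
#' @param lloq_level Name of the LLOQ level (default `"LLOQ"`).
#' @return List of class `qc_battery_result` with data.frames `intra_day`
#'   and `inter_day`, each with columns `analyte, level, nominal, n,
#'   mean_found, accuracy_pct, rsd_pct, passed`.
#' @export
qc_battery <- function(measurements, intra_day = 1, tol = 15,
                       tol_lloq = 20, lloq_level = "LLOQ") {
  need <- c("analyte", "level", "nominal", "day", "found")
  stopifnot(all(need %in% names(measurements)))
  summarise <- function(df) {
    out <- do.call(rbind, lapply(
      split(df, list(df$analyte, df$level), drop = TRUE),
      function(g) {
        if (nrow(g) < 2) {
          warning(sprintf("level %s/%s has < 2 replicates; skipped",
                          g$analyte[1], g$level[1]))
          return(NULL)
        }
        lim <- if (g$level[1] == lloq_level) tol_lloq else tol
        mf <- mean(g$found)
        acc <- accuracy_percent(mf, g$nominal[1])
        rsd <- rsd_percent(g$found)
        data.frame(analyte = g$analyte[1], level = g$level[1],
                   nominal = g$nominal[1], n = nrow(g), mean_found = mf,
                   accuracy_pct = acc, rsd_pct = rsd,
                   passed = abs(acc - 100) <= lim && rsd <= lim)
      }))
    rownames(out) <- NULL
    out
  }
  res <- list(intra_day = summarise(measurements[measurements$day == intra_day, ]),
              inter_day = summarise(measurements))
  class(res) <- c("qc_battery_result", "list")
  res
}

#' Extraction recovery at one QC level
#'
#' Recovery compares analyte peak areas from samples carried through the
#' whole extraction procedure with areas from blank extracts spiked after
#' extraction: `100 * mean(extracted) / mean(post_extraction)`. The RSD is
#' that of the individual extracted-over-post-mean recoveries.
#'
#' @param extracted_areas Peak areas of pre-extraction spiked samples.
#' @param post_extraction_areas Peak areas of post-extraction spiked
#'   samples at the same level.
#' @return List with `recovery_pct` and `rsd_pct` (both 2-decimal).
#' @export
recovery_percent <- function(extracted_areas, post_extraction_areas) {
  if (length(extracted_areas) == 0 || length(post_extraction_areas) == 0) {
    stop("both area vectors must be non-empty", call. = FALSE)
  }
  mp <- mean(post_extraction_areas)
  if (mp == 0) stop("zero post-extraction mean area", call. = FALSE)
  per_rep <- 100 * extracted_areas / mp
  list(recovery_pct = round_half_away(mean(per_rep), 2),
       rsd_pct = if (length(per_rep) >= 2) rsd_percent(per_rep) else NA_real_)
}

#' Recovery battery across QC levels
#'
#' Applies [recovery_percent()] per level and reports the across-level
#' mean recovery and the RSD of per-level recoveries, the two summary
#' numbers of a recovery table.
#'
#' @param extracted Data.frame with columns `level`, `area`.
#' @param post_extraction Data.frame with columns `level`, `area`.
#' @return List with `per_level` (level, recovery_pct, rsd_pct),
#'   `mean_recovery_pct`, `rsd_across_levels_pct`.
#' @export
recovery_battery <- function(extracted, post_extraction) {
  stopifnot(all(c("level", "area") %in% names(extracted)),
            all(c("level", "area") %in% names(post_extraction)))
  levels_ <- unique(extracted$level)
  per <- do.call(rbind, lapply(levels_, function(lv) {
    r <- recovery_percent(extracted$area[extracted$level == lv],
                          post_extraction$area[post_extraction$level == lv])
    data.frame(level = lv, recovery_pct = r$recovery_pct,
               rsd_pct = r$rsd_pct)
  }))
  list(per_level = per,
       mean_recovery_pct = round_half_away(mean(per$recovery_pct), 2),
       rsd_across_levels_pct = if (nrow(per) >= 2) {
         rsd_percent(per$recovery_pct)
       } else NA_real_)
}

#' Matrix factor across plasma lots
#'
#' The matrix factor (MF) of each lot is the peak area of blank matrix
#' spiked after extraction divided by the mean area of the neat solution
#' at the same concentration; ionisation suppression gives MF < 1,
#' enhancement MF > 1. The battery passes when the across-lot RSD% of the
#' MF does not exceed `tol`.
#'
#' @param post_spiked Data.frame with columns `lot`, `area` (one row per
#'   lot, or replicates per lot which are averaged first).
#' @param neat_areas Numeric vector of neat-solution areas.
#' @param tol RSD acceptance limit in percent (default 15).
#' @return List with `per_lot` (lot, mf), `rsd_pct`, `passed`.
#' @export
matrix_factor <- function(post_spiked, neat_areas, tol = 15) {
  stopifnot(all(c("lot", "area") %in% names(post_spiked)))
  if (length(neat_areas) == 0 || mean(neat_areas) == 0) {
    stop("neat-solution areas must be non-empty with non-zero mean",
         call. = FALSE)
  }
  if (length(unique(post_spiked$lot)) < 2) {
    stop("matrix factor needs >= 2 plasma lots", call. = FALSE)
  }
  neat <- mean(neat_areas)
  mf <- vapply(split(post_spiked$area, post_spiked$lot), mean, numeric(1)) /
    neat
  rsd <- rsd_percent(mf)
  list(per_lot = data.frame(lot = names(mf), mf = as.numeric(mf)),
       rsd_pct = rsd, passed = rsd <= tol)
}

#' Dilution integrity
#'
#' Verifies that diluting an above-range sample with blank matrix and
#' multiplying the measured concentration by the dilution factor recovers
#' the undiluted nominal: accuracy within +/-`tol`% and RSD <= `tol`%.
#'
#' @param measured_conc Measured concentrations of the diluted replicates
#'   (ng/mL).
#' @param dilution_factor Integer dilution factor, >= 2.
#' @param nominal_undiluted Nominal concentration before dilution (ng/mL).
#' @param tol Acceptance limit in percent (default 15).
#' @return List with `reported_conc`, `mean_reported`, `accuracy_pct`,
#'   `rsd_pct`, `passed`.
#' @export
dilution_integrity <- function(measured_conc, dilution_factor,
                               nominal_undiluted, tol = 15) {
  if (dilution_factor < 2) {
    stop("dilution_factor must be >= 2", call. = FALSE)
  }
  if (!(nominal_undiluted > 0)) {
    stop("nominal_undiluted must be > 0", call. = FALSE)
  }
  reported <- measured_conc * dilution_factor
  acc <- accuracy_percent(mean(reported), nominal_undiluted)
  rsd <- if (length(reported) >= 2) rsd_percent(reported) else NA_real_
  list(reported_conc = reported, mean_reported = mean(reported),
       accuracy_pct = acc, rsd_pct = rsd,
       passed = abs(acc - 100) <= tol &&
         (is.na(rsd) || rsd <= tol))
}

# the five stability experiments the battery understands
stability_conditions <- c("short_term", "freeze_thaw", "long_term",
                          "processed", "dry_extract")

#' Stability battery
#'
#' Summarises stressed QC measurements per stability condition and level.
#' The primary metric is accuracy against nominal; the ratio of stressed
#' to fresh mean is reported alongside, since stability is demonstrated
#' by comparison with freshly prepared samples. A cell passes when the
#' accuracy deviates from 100% by at most `tol` points and RSD <= `tol`.
#'
#' @param stressed Data.frame with columns `condition`, `level`,
#'   `nominal`, `found`; conditions must come from short_term,
#'   freeze_thaw, long_term, processed, dry_extract.
#' @param fresh Optional data.frame with columns `level`, `nominal`,
#'   `found` of freshly prepared comparators.
#' @param tol Acceptance limit in percent (default 15).
#' @return Data.frame of class `stability_result` with columns
#'   `condition, level, nominal, n, mean_found, accuracy_pct, rsd_pct,
#'   pct_of_fresh, passed`.
#' @export
stability_battery <- function(stressed, fresh = NULL, tol = 15) {
  need <- c("condition", "level", "nominal", "found")
  stopifnot(all(need %in% names(stressed)))
  bad <- setdiff(unique(stressed$condition), stability_conditions)
  if (length(bad)) {
    stop("unknown stability condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fresh_mean <- function(lv) {
    if (is.null(fresh)) return(NA_real_)
    v <- fresh$found[fresh$level == lv]
    if (length(v)) mean(v) else NA_real_
  }
  out <- do.call(rbind, lapply(
    split(stressed, list(stressed$condition, stressed$level), drop = TRUE),
    function(g) {
      mf <- mean(g$found)
      acc <- accuracy_percent(mf, g$nominal[1])
      rsd <- if (nrow(g) >= 2) rsd_percent(g$found) else NA_real_
      fm <- fresh_mean(g$level[1])
      data.frame(condition = g$condition[1], level = g$level[1],
                 nominal = g$nominal[1], n = nrow(g), mean_found = mf,
                 accuracy_pct = acc, rsd_pct = rsd,
                 pct_of_fresh = if (is.na(fm)) NA_real_ else
                   round_half_away(100 * mf / fm, 2),
                 passed = abs(acc - 100) <= tol &&
                   (is.na(rsd) || rsd <= tol))
    }))
  rownames(out) <- NULL
  class(out) <- c("stability_result", "data.frame")
  out
}

#' Selectivity check across blank plasma lots
#'
#' Compares the response of blank plasma lots at each analyte's retention
#' window with the mean response of LLOQ-spiked samples. Interference is
#' `100 * blank area / mean LLOQ area`; a lot passes when interference is
#' at most `tol_analyte` percent for analytes and `tol_is` percent for
#' internal standards.
#'
#' @param blank_areas Data.frame with columns `lot`, `analyte`, `area`.
#' @param lloq_areas Data.frame with columns `analyte`, `area` of
#'   LLOQ-spiked responses (all > 0 per analyte on average).
#' @param is_analytes Character vector naming internal-standard channels.
#' @param tol_analyte,tol_is Interference limits in percent (defaults 20
#'   and 5).
#' @return List with `table` (lot, analyte, interference_pct, passed) and
#'   `passed` (overall flag).
#' @export
selectivity_check <- function(blank_areas, lloq_areas,
                              is_analytes = character(),
                              tol_analyte = 20, tol_is = 5) {
  stopifnot(all(c("lot", "analyte", "area") %in% names(blank_areas)),
            all(c("analyte", "area") %in% names(lloq_areas)))
  lloq_mean <- vapply(split(lloq_areas$area, lloq_areas$analyte),
                      mean, numeric(1))
  if (any(lloq_mean <= 0)) {
    stop("LLOQ responses must be positive", call. = FALSE)
  }
  interf <- 100 * blank_areas$area /
    as.numeric(lloq_mean[blank_areas$analyte])
  lim <- ifelse(blank_areas$analyte %in% is_analytes, tol_is, tol_analyte)
  tab <- data.frame(lot = blank_areas$lot, analyte = blank_areas$analyte,
                    interference_pct = round_half_away(interf, 2),
                    passed = interf <= lim)
  list(table = tab, passed = all(tab$passed))
}
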