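#' Define an MRM transition
#'
#' An MRM (multiple reaction monitoring) transition identifies one monitored
#' precursor/product ion pair together with the analyte's expected retention
#' time and its internal-standard pairing. Source voltages (declustering
#' potential, entrance potential, collision energy, cell exit potential) are
#' carried as metadata only; nothing is computed on them.
#'
#' @param analyte Analyte name.
#' @param q1_mz Precursor ion m/z (must exceed `q3_mz`).
#' @param q3_mz Product ion m/z, > 0.
#' @param retention_time Expected retention time in minutes, in (0, 5].
#' @param is_internal_standard Logical; is this transition an internal
#'   standard channel?
#' @param paired_is Name of the paired internal standard, or `NA`.
#' @param dp,ep,ce,cep Source/collision voltages (V), metadata only.
#' @return An object of class `mrm_transition`.
#' @export
mrm_transition <- function(analyte, q1_mz, q3_mz, retention_time,
                           is_internal_standard = FALSE,
                           paired_is = NA_character_,
                           dp = NA_real_, ep = NA_real_,
                           ce = NA_real_, cep = NA_real_) {
  stopifnot(is.character(analyte), length(analyte) == 1)
  if (!(q1_mz > q3_mz && q3_mz > 0)) {
    stop("mrm_transition() requires q1_mz > q3_mz > 0", call. = FALSE)
  }
  if (!(retention_time > 0 && retention_time <= 5)) {
    stop("retention_time must lie in (0, 5] minutes", call. = FALSE)
  }
  structure(
    list(analyte = analyte, q1_mz = q1_mz, q3_mz = q3_mz,
         retention_time = retention_time,
         is_internal_standard = isTRUE(is_internal_standard),
         paired_is = paired_is,
         dp = dp, ep = ep, ce = ce, cep = cep),
    class = "mrm_transition"
  )
}

#' @export
print.mrm_transition <- function(x, ...) {
  cat(sprintf("<mrm_transition> %s  m/z %.1f -> %.1f  RT %.2f min%s\n",
              x$analyte, x$q1_mz, x$q3_mz, x$retention_time,
              if (x$is_internal_standard) "  [IS]" else ""))
  invisible(x)
}

#' Preset transitions for the metformin/canagliflozin plasma assay
#'
#' The four monitored channels: metformin (MET, quantified against
#' propranolol) and canagliflozin (CFZ, quantified against tadalafil),
#' with their precursor/product m/z, retention times and source voltages.
#'
#' @return A named list of [mrm_transition()] objects
#'   (`MET`, `CFZ`, `PPL`, `TDF`).
#' @export
default_transitions <- function() {
  list(
    MET = mrm_transition("MET", 130.2, 60.1, 0.9, FALSE, "PPL",
                         dp = 26, ep = 10, ce = 19, cep = 12),
    CFZ = mrm_transition("CFZ", 462.3, 191.0, 4.5, FALSE, "TDF",
                         dp = 61, ep = 10, ce = 15, cep = 18),
    PPL = mrm_transition("PPL", 260.2, 183.0, 1.1, TRUE,
                         dp = 120, ep = 10, ce = 28, cep = 12),
    TDF = mrm_transition("TDF", 390.2, 268.2, 3.0, TRUE,
                         dp = 73, ep = 10, ce = 50, cep = 17.4)
  )
}

#' Construct a chromatogram
#'
#' A single transition's time/intensity trace. Negative intensities are
#' clamped to zero (detector counts cannot be negative).
#'
#' @param times Acquisition times in minutes, strictly increasing, >= 2 points.
#' @param intensities Intensities in counts, same length as `times`.
#' @param transition Optional [mrm_transition()] or transition id string.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(times, intensities, transition = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop("times and intensities must have equal length", call. = FALSE)
  }
  if (length(times) < 2) stop("chromatogram needs >= 2 points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  intensities[intensities < 0] <- 0
  structure(list(times = times, intensities = intensities,
                 transition = transition),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  id <- if (inherits(x$transition, "mrm_transition")) x$transition$analyte
        else if (!is.null(x$transition)) as.character(x$transition) else "?"
  cat(sprintf("<chromatogram> %s  %d points  %.2f-%.2f min  max %.1f counts\n",
              id, length(x$times), min(x$times), max(x$times),
              max(x$intensities)))
  invisible(x)
}

#' Locate a peak near an expected retention time
#'
#' The apex is the maximum intensity within `expected_rt +/- window`. Peak
#' bounds are found by walking outward from the apex; the walk ends at the
#' first flanking local minimum encountered after the trace has dropped
#' below half the apex (so valleys between partially resolved peaks are
#' honoured while small fluctuations near the top are walked over), or
#' once the trace falls below 0.5% of the apex (tail floor), or at the
#' trace edge. On noisy traces the tail bound lands at the first noise dip
#' past half-height, so the reported height stays accurate while the area
#' of weak noisy peaks is better obtained from [integrate_peak()] with
#' explicit bounds.
#'
#' @param chrom A [chromatogram()].
#' @param expected_rt Expected retention time (min).
#' @param window Half-width of the search window (min), > 0. Default 0.2.
#' @param baseline_threshold Apex intensities at or below this value are
#'   reported as not found. Default 0.
#' @return A `peak_result` list: `apex_time`, `apex_index`, `height`
#'   (baseline-subtracted), `area` (baseline-subtracted trapezoid),
#'   `bounds` (times), `found`, `snr` (`NA` until [estimate_snr()]).
#' @export
find_peak <- function(chrom, expected_rt, window = 0.2,
                      baseline_threshold = 0) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  t <- chrom$times
  lo <- expected_rt - window
  hi <- expected_rt + window
  idx <- which(t >= lo & t <= hi)
  if (length(idx) == 0) {
    stop("search window lies outside the chromatogram time axis",
         call. = FALSE)
  }
  y <- chrom$intensities
  apex_rel <- which.max(y[idx])
  apex <- idx[apex_rel]
  if (y[apex] <= baseline_threshold) {
    return(structure(list(apex_time = NA_real_, apex_index = NA_integer_,
                          height = 0, area = 0, bounds = c(NA_real_, NA_real_),
                          found = FALSE, snr = NA_real_),
                     class = "peak_result"))
  }
  # bound walk runs on a lightly smoothed trace so single-sample noise
  # dips are not mistaken for the peak foot; thresholds are prominences
  # above the trace minimum, which keeps the rule offset-invariant
  k <- 2L
  ys <- as.numeric(stats::filter(y, rep(1 / (2 * k + 1), 2 * k + 1),
                                 sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  b0 <- min(ys)
  prom <- ys[apex] - b0
  half <- b0 + 0.5 * prom
  floor_ <- b0 + 0.005 * prom
  walk <- function(from, step, stop_at) {
    i <- from
    while (i != stop_at) {
      if (ys[i] <= floor_) break
      nxt <- ys[i + step]
      if (ys[i] <= half && nxt > ys[i]) break # flanking local minimum
      i <- i + step
    }
    i
  }
  left <- walk(apex, -1L, 1L)
  right <- walk(apex, 1L, length(y))
  bounds <- c(t[left], t[right])
  area <- integrate_peak(chrom, bounds, baseline = "linear")
  # baseline under the apex from the smoothed bound intensities
  base_apex <- ys[left] + (ys[right] - ys[left]) *
    (t[apex] - t[left]) / max(t[right] - t[left], .Machine$double.eps)
  structure(list(apex_time = t[apex], apex_index = apex,
                 height = y[apex] - base_apex, area = area,
                 bounds = bounds, found = TRUE, snr = NA_real_),
            class = "peak_result")
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integration of the trace between `bounds`. With
#' `baseline = "linear"` (default) the straight line joining the intensities
#' at the two bounds is subtracted first, which makes the area invariant to
#' a constant offset; with `"none"` the raw trace is integrated, which makes
#' area exactly additive over adjacent sub-intervals.
#'
#' @param chrom A [chromatogram()].
#' @param bounds Length-2 numeric, start and end times (min), start < end,
#'   both inside the time axis.
#' @param baseline `"linear"` or `"none"`.
#' @return Area in count*minutes (negative baseline-subtracted areas clamp
#'   to 0).
#' @export
integrate_peak <- function(chrom, bounds, baseline = c("linear", "none")) {
  stopifnot(inherits(chrom, "chromatogram"))
  baseline <- match.arg(baseline)
  if (length(bounds) != 2 || !is.finite(bounds[1]) || !is.finite(bounds[2])) {
    stop("bounds must be two finite times", call. = FALSE)
  }
  if (bounds[1] >= bounds[2]) stop("bounds are inverted", call. = FALSE)
  t <- chrom$times
  if (bounds[1] < min(t) - 1e-12 || bounds[2] > max(t) + 1e-12) {
    stop("bounds fall outside the chromatogram time axis", call. = FALSE)
  }
  keep <- t >= bounds[1] - 1e-12 & t <= bounds[2] + 1e-12
  tt <- t[keep]
  yy <- chrom$intensities[keep]
  if (length(tt) < 2) return(0)
  if (baseline == "linear") {
    base <- yy[1] + (yy[length(yy)] - yy[1]) *
      (tt - tt[1]) / (tt[length(tt)] - tt[1])
    yy <- yy - base
  }
  area <- sum(diff(tt) * (yy[-length(yy)] + yy[-1]) / 2)
  max(area, 0)
}

#' Estimate signal-to-noise for a detected peak
#'
#' S/N is the baseline-subtracted peak height divided by the standard
#' deviation of the intensities in a peak-free noise region. A quantitation
#' limit is conventionally supported when S/N >= 10, reported here as the
#' `lloq_supported` flag.
#'
#' @param chrom A [chromatogram()].
#' @param peak A `peak_result` from [find_peak()].
#' @param noise_region Length-2 times (min) of a region free of peaks;
#'   default `c(0, 0.4)`. Must not overlap the peak bounds.
#' @return List with `snr`, `lloq_supported`, `noise_sd`, and
#'   `zero_noise` (TRUE, with a warning, when the region has zero variance
#'   and `snr` is reported as `Inf`).
#' @export
estimate_snr <- function(chrom, peak, noise_region = c(0, 0.4)) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (isTRUE(peak$found) && !any(is.na(peak$bounds))) {
    if (noise_region[1] < peak$bounds[2] && peak$bounds[1] < noise_region[2]) {
      stop("noise_region overlaps the peak bounds", call. = FALSE)
    }
  }
  keep <- chrom$times >= noise_region[1] & chrom$times <= noise_region[2]
  if (sum(keep) < 2) stop("noise_region contains < 2 samples", call. = FALSE)
  noise_sd <- stats::sd(chrom$intensities[keep])
  height <- if (isTRUE(peak$found)) peak$height else 0
  if (noise_sd == 0) {
    warning("noise region has zero variance; S/N reported as Inf")
    snr <- if (height > 0) Inf else 0
    return(list(snr = snr, lloq_supported = snr >= 10,
                noise_sd = 0, zero_noise = TRUE))
  }
  snr <- height / noise_sd
  list(snr = snr, lloq_supported = snr >= 10,
       noise_sd = noise_sd, zero_noise = FALSE)
}

#' Read or write chromatograms as CSV
#'
#' Long-format CSV with columns `transition_id, time_min, intensity`.
#' Vendor raw files and mzML are out of scope for this package.
#'
#' @param chroms Named list of [chromatogram()] objects.
#' @param path File path.
#' @return `write_chromatograms_csv()` returns `path` invisibly;
#'   `read_chromatograms_csv()` returns a named list of chromatograms.
#' @export
write_chromatograms_csv <- function(chroms, path) {
  stopifnot(is.list(chroms), !is.null(names(chroms)))
  df <- do.call(rbind, lapply(names(chroms), function(id) {
    ch <- chroms[[id]]
    data.frame(transition_id = id, time_min = ch$times,
               intensity = ch$intensities)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatograms_csv
#' @export
read_chromatograms_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("transition_id", "time_min", "intensity") %in% names(df)))
  ids <- unique(df$transition_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$transition_id == id, ]
    chromatogram(sub$time_min, sub$intensity, transition = id)
  })
  names(out) <- ids
  out
}
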