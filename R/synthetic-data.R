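#' One-compartment oral PK model parameters
#'
#' Parameters of a one-compartment model with first-order absorption and
#' elimination, used to generate concentration-time profiles with known
#' ground truth. The apparent volume is `volume_over_F` (V/F), so the
#' noise-free curve is
#' \deqn{C(t) = \frac{F\,D\,k_a}{(V/F)\,F\,(k_a - k_e)}
#'   \left(e^{-k_e (t-t_{lag})} - e^{-k_a (t-t_{lag})}\right)}
#' for `t > tlag` and 0 otherwise, with analytic
#' `AUCinf = F*D / (F * V/F * ke)` and `tmax = ln(ka/ke)/(ka-ke) + tlag`.
#'
#' @param dose Administered dose in ng, > 0.
#' @param bioavailability Fraction absorbed F, in (0, 1].
#' @param volume_over_F Apparent volume of distribution V/F in mL, > 0.
#' @param ka First-order absorption rate constant (1/h), > 0.
#' @param ke First-order elimination rate constant (1/h), > 0, != `ka`.
#' @param tlag Absorption lag time (h), >= 0.
#' @return Object of class `pk_model_params`.
#' @export
pk_model_params <- function(dose, bioavailability = 1, volume_over_F,
                            ka, ke, tlag = 0) {
  if (!(dose > 0)) stop("dose must be > 0", call. = FALSE)
  if (!(bioavailability > 0 && bioavailability <= 1)) {
    stop("bioavailability must lie in (0, 1]", call. = FALSE)
  }
  if (!(volume_over_F > 0)) stop("volume_over_F must be > 0", call. = FALSE)
  if (!(ka > 0 && ke > 0)) stop("ka and ke must be > 0", call. = FALSE)
  if (ka == ke) {
    stop("ka == ke is degenerate for the two-exponential closed form",
         call. = FALSE)
  }
  if (tlag < 0) stop("tlag must be >= 0", call. = FALSE)
  structure(list(dose = dose, bioavailability = bioavailability,
                 volume_over_F = volume_over_F, ka = ka, ke = ke,
                 tlag = tlag),
            class = "pk_model_params")
}

#' Preset PK parameter sets
#'
#' Two documented presets whose noise-free kinetics resemble a single oral
#' dose of the fixed combination studied by the assay presets: `"MET-like"`
#' (850 mg metformin hydrochloride; ke = ln 2 / 6.03 h, ka = 0.58/h,
#' V/F chosen so AUCinf is about 12,576 ng h/mL, tmax about 3.48 h) and
#' `"CFZ-like"` (50 mg canagliflozin; ke = ln 2 / 8.19 h, ka = 0.55/h,
#' V/F giving AUCinf about 3,963 ng h/mL, tmax about 4.02 h). These are
#' simulation presets for testing the pipeline, not fitted estimates.
#'
#' @param name `"MET-like"` or `"CFZ-like"`.
#' @return A [pk_model_params()] object.
#' @export
preset_pk_params <- function(name = c("MET-like", "CFZ-like")) {
  name <- match.arg(name)
  switch(name,
    "MET-like" = pk_model_params(dose = 8.5e8, bioavailability = 1,
                                 volume_over_F = 5.88e5,
                                 ka = 0.58, ke = log(2) / 6.03),
    "CFZ-like" = pk_model_params(dose = 5e7, bioavailability = 1,
                                 volume_over_F = 1.491e5,
                                 ka = 0.55, ke = log(2) / 8.19)
  )
}

#' Measurement error model for simulated assays
#'
#' Combined proportional + additive Gaussian noise applied to a true value
#' c as `c * (1 + N(0, proportional_cv)) + N(0, additive_sd)`, truncated at
#' zero. Concentrations below `lloq` are retained but flagged BLQ (below
#' the lower limit of quantification), so downstream BLQ policies stay
#' testable.
#'
#' @param proportional_cv Proportional coefficient of variation, >= 0.
#' @param additive_sd Additive noise SD in concentration units, >= 0.
#' @param lloq Lower limit of quantification (ng/mL), > 0.
#' @param seed Integer RNG seed.
#' @return Object of class `assay_error_model`.
#' @export
assay_error_model <- function(proportional_cv = 0.05, additive_sd = 0,
                              lloq, seed = 1L) {
  if (proportional_cv < 0) stop("proportional_cv must be >= 0", call. = FALSE)
  if (additive_sd < 0) stop("additive_sd must be >= 0", call. = FALSE)
  if (!(lloq > 0)) stop("lloq must be > 0", call. = FALSE)
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd, lloq = lloq,
                 seed = as.integer(seed)),
            class = "assay_error_model")
}

#' Sampling schedule
#'
#' Strictly increasing sampling times in hours starting at 0. The default
#' is the 16-point single-dose schedule used throughout the package's
#' worked examples: 0, 0.5, 1, 1.5, 2, 3, 4, 6, 7, 8, 10, 12, 16, 24, 48
#' and 72 h.
#'
#' @param times Numeric vector of hours.
#' @return Object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(times = c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 7, 8,
                                        10, 12, 16, 24, 48, 72)) {
  times <- as.numeric(times)
  if (length(times) == 0) stop("schedule must be non-empty", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times), class = "sampling_schedule")
}

# Noise-free one-compartment concentration at times t (vectorised).
conc_one_compartment <- function(params, t) {
  tau <- t - params$tlag
  k_diff <- params$ka - params$ke
  scale <- params$bioavailability * params$dose * params$ka /
    (params$volume_over_F * k_diff)
  out <- scale * (exp(-params$ke * tau) - exp(-params$ka * tau))
  out[tau <= 0] <- 0
  out
}

#' Simulate a concentration-time profile
#'
#' Evaluates the one-compartment closed form on the schedule, applies the
#' error model, truncates at zero, and flags BLQ values. Identical inputs
#' and seed give bit-identical output.
#'
#' @param params A [pk_model_params()].
#' @param schedule A [sampling_schedule()].
#' @param error An [assay_error_model()].
#' @param subject_id Subject label (default `"S1"`).
#' @param analyte Analyte label (default `"MET"`).
#' @return A `pk_profile` data.frame with columns `subject_id`, `analyte`,
#'   `time_h`, `conc_ng_ml`, `blq` (0/1) and the noise-free truth in
#'   attribute `"true_conc"`.
#' @export
simulate_profile <- function(params, schedule, error,
                             subject_id = "S1", analyte = "MET") {
  stopifnot(inherits(params, "pk_model_params"),
            inherits(schedule, "sampling_schedule"),
            inherits(error, "assay_error_model"))
  t <- schedule$times
  true_c <- conc_one_compartment(params, t)
  set.seed(error$seed)
  n <- length(t)
  obs <- true_c * (1 + stats::rnorm(n, 0, error$proportional_cv)) +
    stats::rnorm(n, 0, error$additive_sd)
  obs[obs < 0] <- 0
  out <- data.frame(subject_id = subject_id, analyte = analyte,
                    time_h = t, conc_ng_ml = obs,
                    blq = as.integer(obs < error$lloq))
  attr(out, "true_conc") <- true_c
  class(out) <- c("pk_profile", "data.frame")
  out
}

#' Calibration / QC run design
#'
#' Declares the nominal levels per analyte, the replicate count, and the
#' true response-ratio line (ratio = slope * conc + intercept) from which
#' measurements are generated. `lot_effects` is a vector of multiplicative
#' plasma-lot factors cycled across replicates (all 1 = no lot effect).
#'
#' @param levels Named list: analyte -> numeric vector of nominal
#'   concentrations (ng/mL), all > 0.
#' @param replicates Replicates per level, >= 1.
#' @param true_slope,true_intercept Named numeric vectors (or scalars) of
#'   line parameters per analyte.
#' @param lot_effects Numeric vector of per-lot multiplicative factors.
#' @param role Sample role recorded in the output (default `"standard"`).
#' @return Object of class `run_design`.
#' @export
run_design <- function(levels, replicates = 1, true_slope, true_intercept,
                       lot_effects = 1, role = "standard") {
  stopifnot(is.list(levels), !is.null(names(levels)))
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  for (a in names(levels)) {
    if (any(levels[[a]] <= 0)) {
      stop("nominal concentrations must be > 0", call. = FALSE)
    }
  }
  get_par <- function(p, a) {
    if (is.null(names(p))) p[1] else unname(p[a])
  }
  structure(list(levels = levels, replicates = as.integer(replicates),
                 true_slope = true_slope, true_intercept = true_intercept,
                 lot_effects = lot_effects, role = role,
                 get_par = get_par),
            class = "run_design")
}

#' Simulate a calibration or QC run
#'
#' For each analyte, level and replicate the expected response ratio
#' `true_slope * conc + true_intercept` is scaled by the replicate's lot
#' factor and perturbed by the error model (additive noise, given in
#' concentration units, is mapped to ratio units through the slope).
#' The internal-standard area is drawn around `is_area_mean` and the
#' analyte area set so the recorded area pair reproduces the perturbed
#' ratio exactly.
#'
#' @param design A [run_design()].
#' @param error An [assay_error_model()].
#' @param is_area_mean Mean internal-standard area in counts (default 1e5).
#' @param is_area_cv CV of the internal-standard area (default 0.03).
#' @return A data.frame with columns `sample_id, analyte, role,
#'   nominal_ng_ml, analyte_area, is_area, lot`.
#' @export
simulate_run <- function(design, error, is_area_mean = 1e5,
                         is_area_cv = 0.03) {
  stopifnot(inherits(design, "run_design"),
            inherits(error, "assay_error_model"))
  set.seed(error$seed)
  rows <- list()
  k <- 0
  n_lots <- length(design$lot_effects)
  for (a in names(design$levels)) {
    slope <- design$get_par(design$true_slope, a)
    intercept <- design$get_par(design$true_intercept, a)
    for (x in design$levels[[a]]) {
      for (r in seq_len(design$replicates)) {
        k <- k + 1
        lot <- ((r - 1) %% n_lots) + 1
        ratio_true <- (slope * x + intercept) * design$lot_effects[lot]
        ratio <- ratio_true * (1 + stats::rnorm(1, 0, error$proportional_cv)) +
          stats::rnorm(1, 0, error$additive_sd * abs(slope))
        ratio <- max(ratio, 0)
        is_area <- is_area_mean * (1 + stats::rnorm(1, 0, is_area_cv))
        rows[[k]] <- data.frame(
          sample_id = sprintf("%s_%g_r%d", a, x, r),
          analyte = a, role = design$role, nominal_ng_ml = x,
          analyte_area = ratio * is_area, is_area = is_area, lot = lot)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate MRM chromatograms
#'
#' Each transition's trace is `baseline` plus a Gaussian peak centred at
#' its retention time with amplitude `response_factor * concentration`,
#' plus white Gaussian noise, clamped at zero. The time axis spans 0-5 min
#' sampled every 0.01 min (0.6 s, 501 points).
#'
#' @param transitions List of [mrm_transition()] objects.
#' @param concentrations Named numeric vector, analyte -> concentration
#'   (ng/mL), >= 0. Missing analytes default to 0.
#' @param noise_sd White-noise SD in counts (default 0).
#' @param seed RNG seed.
#' @param response_factor Counts of peak amplitude per ng/mL (default 1).
#' @param peak_sd Gaussian peak SD in minutes (default 0.05).
#' @param baseline Constant baseline offset in counts (default 0). Set it
#'   well above `noise_sd` to keep the zero clamp from biasing the noise.
#' @return Named list of [chromatogram()] objects.
#' @export
simulate_chromatogram <- function(transitions, concentrations,
                                  noise_sd = 0, seed = 1L,
                                  response_factor = 1, peak_sd = 0.05,
                                  baseline = 0) {
  stopifnot(is.list(transitions))
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  t <- seq(0, 5, by = 0.01)
  set.seed(as.integer(seed))
  out <- list()
  for (tr in transitions) {
    stopifnot(inherits(tr, "mrm_transition"))
    conc <- if (tr$analyte %in% names(concentrations)) {
      concentrations[[tr$analyte]]
    } else 0
    amp <- response_factor * conc
    y <- baseline + amp * exp(-(t - tr$retention_time)^2 / (2 * peak_sd^2))
    if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
    out[[tr$analyte]] <- chromatogram(t, y, transition = tr)
  }
  out
}

#' Simulate a QC accuracy/precision battery
#'
#' Generates back-calculated QC concentrations with a known relative bias
#' and proportional CV: `found = nominal * (1 + bias/100) * (1 + N(0, cv))`.
#' This is the ground-truth generator behind the validation-battery
#' calibration tests.
#'
#' @param levels Named numeric vector: level name (e.g. `"LLOQ"`) ->
#'   nominal concentration (ng/mL).
#' @param analyte Analyte label.
#' @param replicates Replicates per level per day (default 6).
#' @param days Number of runs/days (default 3).
#' @param bias_pct Systematic relative bias in percent (default 0).
#' @param cv Proportional CV as a fraction (default 0.05).
#' @param seed RNG seed.
#' @return Data.frame with columns `analyte, level, nominal, day,
#'   replicate, found`.
#' @export
simulate_qc_battery <- function(levels, analyte = "MET", replicates = 6,
                                days = 3, bias_pct = 0, cv = 0.05,
                                seed = 1L) {
  stopifnot(!is.null(names(levels)), all(levels > 0),
            replicates >= 1, days >= 1)
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(replicates),
                      day = seq_len(days),
                      level = names(levels),
                      stringsAsFactors = FALSE)
  nominal <- levels[grid$level]
  found <- nominal * (1 + bias_pct / 100) *
    (1 + stats::rnorm(nrow(grid), 0, cv))
  found[found < 0] <- 0
  data.frame(analyte = analyte, level = grid$level,
             nominal = as.numeric(nominal), day = grid$day,
             replicate = grid$replicate, found = found)
}

#' Read and write profile CSV files
#'
#' Long-format concentration-time CSV with columns
#' `subject_id, analyte, time_h, conc_ng_ml, blq`.
#'
#' @param profiles A data.frame of profiles (rows from
#'   [simulate_profile()] can be `rbind`-ed).
#' @param path File path.
#' @return The path (write) or a data.frame (read).
#' @export
write_profiles_csv <- function(profiles, path) {
  cols <- c("subject_id", "analyte", "time_h", "conc_ng_ml", "blq")
  stopifnot(all(cols %in% names(profiles)))
  utils::write.csv(profiles[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("subject_id", "analyte", "time_h", "conc_ng_ml", "blq")
  stopifnot(all(cols %in% names(df)))
  df
}

#' Read and write run-data CSV files
#'
#' Measurement-level CSV with columns `sample_id, analyte, role,
#' nominal_ng_ml, analyte_area, is_area, lot`. Roles are one of
#' blank/zero/standard/qc/subject.
#'
#' @param run A data.frame as produced by [simulate_run()].
#' @param path File path.
#' @return The path (write) or a data.frame (read).
#' @export
write_run_csv <- function(run, path) {
  cols <- c("sample_id", "analyte", "role", "nominal_ng_ml",
            "analyte_area", "is_area", "lot")
  stopifnot(all(cols %in% names(run)))
  utils::write.csv(run[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_run_csv
#' @export
read_run_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("sample_id", "analyte", "role", "nominal_ng_ml",
            "analyte_area", "is_area", "lot")
  stopifnot(all(cols %in% names(df)))
  df
}
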