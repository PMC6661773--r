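test_that("cmax/tmax take the observed maximum with earliest-time ties", {
  t <- c(0, 1, 2, 3, 4, 6)
  expect_equal(cmax_tmax(t, c(0, 100, 250, 383, 383, 200))[c("cmax", "tmax")],
               list(cmax = 383, tmax = 3))
  expect_equal(cmax_tmax(1, 10)[c("cmax", "tmax")],
               list(cmax = 10, tmax = 1))
  allblq <- cmax_tmax(t, rep(1, 6), blq = rep(TRUE, 6))
  expect_false(allblq$found)
  expect_true(is.na(allblq$cmax))
  # BLQ maxima are ignored
  expect_equal(cmax_tmax(t, c(0, 100, 900, 300, 200, 100),
                         blq = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))$cmax,
               300)
})

test_that("trapezoidal AUC matches oracles for both methods", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 2), method = "linear"), 1.0)

  conc <- 100 * exp(-0.1 * pk_schedule)
  analytic <- 100 / 0.1 * (1 - exp(-0.1 * 72))
  logdown <- auc_trapezoid(pk_schedule, conc,
                           method = "linear_up_log_down")
  expect_equal(logdown, analytic, tolerance = 1e-9)

  linear <- auc_trapezoid(pk_schedule, conc, method = "linear")
  expect_gt(linear, logdown) # linear over-estimates convex decay
  expect_equal(linear, oracle_trapz(pk_schedule, conc), tolerance = 1e-12)

  # AUC is monotone in t_end
  aucs <- vapply(c(8, 24, 48, 72),
                 function(te) auc_trapezoid(pk_schedule, conc, t_end = te),
                 numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_error(auc_trapezoid(c(0, 1), c(1, 2), t_end = 5), "exceeds")
  expect_error(auc_trapezoid(0, 1), "usable points")
})

test_that("BLQ policy: leading zeros kept, embedded and trailing dropped", {
  t <- c(0, 1, 2, 3, 4, 5)
  c_ <- c(2, 50, 3, 40, 20, 4)
  blq <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  # usable: (0,0) leading BLQ as zero, (1,50), (3,40), (4,20)
  expected <- oracle_trapz(c(0, 1), c(0, 50)) +
    (50 - 40) * 2 / log(50 / 40) + (40 - 20) * 1 / log(40 / 20)
  expect_equal(auc_trapezoid(t, c_, blq), expected, tolerance = 1e-12)
})

test_that("lambda_z is exact on mono-exponential decay", {
  # pure decay: tmax itself joins the pool when needed
  t3 <- c(24, 48, 72)
  lz0 <- fit_lambda_z(t3, 100 * exp(-0.1 * t3))
  expect_true(lz0$found)
  expect_equal(lz0$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(lz0$n_points, 3)
  # with an absorption phase, tmax is excluded as usual
  t <- c(0, 2, 24, 48, 72)
  conc <- c(0, 120, 100 * exp(-0.1 * c(24, 48, 72)))
  lz <- fit_lambda_z(t, conc)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(lz$t_half * lz$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(lz$n_points, 3)

  # full noise-free decay from t = 0: ties on adjusted R^2 go to the
  # largest subset (all 15 points after tmax)
  conc2 <- 100 * exp(-0.1 * pk_schedule)
  lz2 <- fit_lambda_z(pk_schedule, conc2)
  expect_equal(lz2$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(lz2$n_points, 15)
})

test_that("terminal slope of a one-compartment profile approximates ke", {
  params <- pk_model_params(dose = 8.5e8, volume_over_F = 5.88e5,
                            ka = 1, ke = 0.1)
  prof <- simulate_profile(params, sampling_schedule(pk_schedule),
                           assay_error_model(0, 0, lloq = 1e-9, seed = 1))
  lz <- fit_lambda_z(prof$time_h, prof$conc_ng_ml, prof$blq)
  expect_lt(abs(lz$lambda_z - 0.1) / 0.1, 0.02)
})

test_that("auto subset selection agrees with an exhaustive oracle", {
  params <- preset_pk_params("MET-like")
  sched <- sampling_schedule(pk_schedule)
  for (s in 1:40) {
    prof <- simulate_profile(params, sched,
                             assay_error_model(0.05, 0, lloq = 50,
                                               seed = s))
    keep <- prof$blq == 0 & prof$conc_ng_ml > 0
    ct <- cmax_tmax(prof$time_h, prof$conc_ng_ml, prof$blq)
    tt <- prof$time_h[keep & prof$time_h > ct$tmax]
    cc <- prof$conc_ng_ml[keep & prof$time_h > ct$tmax]
    m <- length(tt)
    if (m < 3) next
    # oracle: adjusted R^2 via cor() over every contiguous terminal subset
    r2a <- vapply(3:m, function(k) {
      idx <- (m - k + 1):m
      oracle_adj_r2(tt[idx], log(cc[idx]))
    }, numeric(1))
    ks <- (3:m)[r2a >= max(r2a) - 1e-12]
    k_oracle <- max(ks) # ties favour more points
    lz <- fit_lambda_z(prof$time_h, prof$conc_ng_ml, prof$blq)
    expect_equal(lz$n_points, k_oracle)
  }
})

test_that("extrapolation to infinity follows Clast/lambda_z", {
  expect_warning(e <- extrapolate_auc(90, 10, 0.1), "extrapolated")
  expect_equal(e$auc_inf, 190)
  expect_equal(round_half_away(e$pct_extrapolated, 2), 52.63)
  expect_false(e$reliable)

  # sampling a mono-exponential out to 5 half-lives leaves < 5% in the tail
  ke <- 0.1
  t5 <- seq(0, 5 * log(2) / ke, length.out = 40)
  conc <- 80 * exp(-ke * t5)
  auc_last <- auc_trapezoid(t5, conc)
  e2 <- extrapolate_auc(auc_last, conc[length(conc)], ke)
  expect_lt(e2$pct_extrapolated, 5)
  expect_gte(e2$auc_inf, auc_last)
  expect_error(extrapolate_auc(90, 10, -0.1), "lambda_z")
})

test_that("noise-free profiles recover ke and the analytic AUCinf", {
  for (preset in c("MET-like", "CFZ-like")) {
    params <- preset_pk_params(preset)
    prof <- simulate_profile(params, sampling_schedule(pk_schedule),
                             assay_error_model(0, 0, lloq = 1e-9,
                                               seed = 1))
    res <- nca(prof)
    expect_lt(abs(res$lambda_z - params$ke) / params$ke, 0.02)
    auc_analytic <- params$bioavailability * params$dose /
      (params$volume_over_F * params$ke)
    expect_lt(abs(res$auc_inf - auc_analytic) / auc_analytic, 0.03)
    expect_gte(res$auc_inf, res$auc_last)
    expect_equal(res$t_half * res$lambda_z, log(2), tolerance = 1e-12)
  }
})

test_that("cohort summaries use the n-1 SD convention", {
  two <- data.frame(analyte = "MET", tmax = c(3, 4), cmax = c(1, 2),
                    auc_last = c(1, 2), auc_inf = c(1, 2),
                    t_half = c(6, 6), kel = c(0.1, 0.1))
  s <- summarize_cohort(two)
  tmax_row <- s[s$parameter == "tmax", ]
  expect_equal(tmax_row$mean, 3.5)
  expect_equal(tmax_row$sd, sqrt(0.5), tolerance = 1e-12)
  expect_match(tmax_row$formatted, "3.50 ± 0.71", fixed = TRUE)

  one <- two[1, ]
  s1 <- summarize_cohort(one)
  expect_true(all(s1$sd == 0))
})

test_that("a synthetic cohort recovers the preset half-life", {
  params <- preset_pk_params("MET-like")
  sched <- sampling_schedule(pk_schedule)
  profiles <- do.call(rbind, lapply(1:12, function(s) {
    simulate_profile(params, sched,
                     assay_error_model(0.05, 0, lloq = 50, seed = 100 + s),
                     subject_id = sprintf("S%02d", s))
  }))
  res <- nca_by_subject(profiles)
  coh <- summarize_cohort(res)
  th <- coh[coh$parameter == "t_half", ]
  expect_lt(abs(th$mean - log(2) / params$ke) / (log(2) / params$ke), 0.15)
})
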