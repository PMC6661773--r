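test_that("accuracy and RSD match hand-computed values and scale-invariance", {
  expect_equal(accuracy_percent(47.24, 50), 94.48)
  expect_equal(accuracy_percent(26.30, 30), 87.67)
  expect_identical(accuracy_percent(123.4, 123.4), 100)
  expect_error(accuracy_percent(50, 0), "nominal")

  expect_equal(rsd_percent(c(5, 5, 5)), 0)
  expect_equal(rsd_percent(c(1, 2, 3)), 50)
  expect_error(rsd_percent(7), "two values")

  set.seed(21)
  for (i in 1:20) {
    v <- runif(sample(3:12, 1), 1, 100)
    c_ <- runif(1, 0.1, 50)
    # brute-force formula oracle, unrounded comparison
    oracle <- 100 * sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / mean(v)
    expect_equal(rsd_percent(v, digits = NULL), oracle, tolerance = 1e-12)
    expect_equal(rsd_percent(c_ * v), rsd_percent(v))
    expect_equal(accuracy_percent(c_ * v[1], c_ * v[2]),
                 accuracy_percent(v[1], v[2]))
  }
  # round-half-away-from-zero at the boundary
  expect_equal(round_half_away(91.695, 2), 91.70)
  expect_equal(round_half_away(-91.695, 2), -91.70)
})

test_that("QC battery recovers known bias and applies the pass rules", {
  levels <- c(LLOQ = 50, LQC = 150, MQC = 1000, HQC = 4000)
  meas <- simulate_qc_battery(levels, replicates = 6, days = 3,
                              bias_pct = 5, cv = 0.03, seed = 13)
  res <- qc_battery(meas)
  expect_equal(nrow(res$inter_day), 4)
  expect_true(all(res$inter_day$n == 18))
  expect_true(all(res$intra_day$n == 6))
  expect_true(all(abs(res$inter_day$accuracy_pct - 105) < 2))
  expect_true(all(res$inter_day$passed))

  # boundary: LQC at 84.9% accuracy fails, LLOQ at 84.9% passes (20% band)
  fixed <- data.frame(
    analyte = "MET",
    level = rep(c("LQC", "LLOQ"), each = 4),
    nominal = rep(c(150, 50), each = 4),
    day = rep(1:2, 4),
    found = c(rep(150 * 0.849, 4), rep(50 * 0.849, 4)))
  resb <- qc_battery(fixed)
  lqc <- resb$inter_day[resb$inter_day$level == "LQC", ]
  lloq <- resb$inter_day[resb$inter_day$level == "LLOQ", ]
  expect_false(lqc$passed)
  expect_true(lloq$passed)
  expect_equal(lqc$accuracy_pct, 84.90)
})

test_that("inter-day statistics pool replicates across days", {
  levels <- c(MQC = 1000)
  meas <- simulate_qc_battery(levels, replicates = 6, days = 3,
                              bias_pct = 0, cv = 0.05, seed = 4)
  res <- qc_battery(meas)
  pooled <- meas$found
  expect_equal(res$inter_day$mean_found, mean(pooled), tolerance = 1e-12)
  expect_equal(res$inter_day$rsd_pct,
               round_half_away(100 * sd(pooled) / mean(pooled), 2))
  d1 <- meas$found[meas$day == 1]
  expect_equal(res$intra_day$mean_found, mean(d1), tolerance = 1e-12)
})

test_that("recovery reproduces per-level values and across-level means", {
  # identical lists -> 100%
  r0 <- recovery_percent(c(10, 11, 12), c(10, 11, 12))
  expect_equal(r0$recovery_pct, 100)

  for (a in c("MET", "CFZ")) {
    ref <- recovery_reference[[a]]
    post <- data.frame(level = rep(names(ref$per_level), each = 3),
                       area = rep(1000, 9))
    extracted <- data.frame(
      level = rep(names(ref$per_level), each = 3),
      area = rep(1000 * ref$per_level / 100, each = 3))
    res <- recovery_battery(extracted, post)
    expect_equal(res$per_level$recovery_pct, unname(ref$per_level))
    expect_equal(res$mean_recovery_pct, ref$mean)
  }
  expect_error(recovery_percent(c(1, 2), c(0, 0)), "zero")
})

test_that("matrix factor flags excessive across-lot variability", {
  clean <- matrix_factor(data.frame(lot = 1:6, area = rep(500, 6)),
                         neat_areas = rep(500, 3))
  expect_equal(clean$per_lot$mf, rep(1, 6))
  expect_equal(clean$rsd_pct, 0)
  expect_true(clean$passed)

  bad <- matrix_factor(data.frame(lot = 1:6,
                                  area = c(250, rep(500, 5))),
                       neat_areas = rep(500, 3))
  expect_gt(bad$rsd_pct, 15)
  expect_false(bad$passed)

  set.seed(31)
  mc <- matrix_factor(data.frame(lot = 1:6,
                                 area = 500 * (1 + rnorm(6, 0, 0.05))),
                      neat_areas = rep(500, 3))
  expect_lte(mc$rsd_pct, 15)
  expect_true(mc$passed)
  expect_error(matrix_factor(data.frame(lot = 1, area = 1), 1), "lots")
  expect_error(matrix_factor(data.frame(lot = 1:2, area = 1:2),
                             numeric(0)), "neat")
})

test_that("dilution integrity multiplies back through the dilution factor", {
  perfect <- dilution_integrity(rep(8000 / 2, 6), 2, 8000)
  expect_equal(perfect$accuracy_pct, 100)
  expect_true(perfect$passed)

  met <- dilution_integrity(rep(3696, 6), 2, 8000)
  expect_equal(met$accuracy_pct, 92.40)
  expect_true(met$passed)

  set.seed(17)
  sim <- dilution_integrity(3720 * (1 + rnorm(6, 0, 0.05)), 2, 8000)
  expect_lt(abs(sim$accuracy_pct - 93), 5)
  expect_true(sim$passed)
  expect_error(dilution_integrity(100, 1, 200), "dilution_factor")
})

test_that("stability battery computes accuracy vs nominal and vs fresh", {
  stressed <- data.frame(
    condition = c(rep("freeze_thaw", 3), rep("long_term", 3)),
    level = c(rep("LQC", 3), rep("LQC", 3)),
    nominal = c(rep(150, 3), rep(30, 3)),
    found = c(rep(141.10, 3), rep(29.77, 3)))
  fresh <- data.frame(level = "LQC", nominal = 150, found = rep(150, 3))
  res <- stability_battery(stressed)
  ft <- res[res$condition == "freeze_thaw", ]
  lt <- res[res$condition == "long_term", ]
  expect_equal(ft$accuracy_pct, 94.07)
  expect_equal(lt$accuracy_pct, 99.23)
  expect_true(all(res$passed))

  # stressed == fresh == nominal -> 100% on both metrics
  eq <- stability_battery(
    data.frame(condition = "short_term", level = "HQC", nominal = 800,
               found = rep(800, 3)),
    fresh = data.frame(level = "HQC", nominal = 800, found = rep(800, 3)))
  expect_equal(eq$accuracy_pct, 100)
  expect_equal(eq$pct_of_fresh, 100)
  expect_true(eq$passed)

  expect_error(stability_battery(
    data.frame(condition = "microwave", level = "LQC", nominal = 30,
               found = 29)), "unknown stability condition")
})

test_that("selectivity compares blank lots with LLOQ responses", {
  lloq <- data.frame(analyte = rep(c("MET", "PPL"), each = 3),
                     area = rep(c(100, 5000), each = 3))
  clean <- selectivity_check(
    data.frame(lot = 1:6, analyte = "MET", area = rep(0, 6)), lloq,
    is_analytes = "PPL")
  expect_true(clean$passed)
  expect_equal(clean$table$interference_pct, rep(0, 6))

  dirty <- selectivity_check(
    data.frame(lot = 1, analyte = "MET", area = 25), lloq,
    is_analytes = "PPL")
  expect_equal(dirty$table$interference_pct, 25)
  expect_false(dirty$passed)

  # IS channel uses the tighter 5% threshold
  is_dirty <- selectivity_check(
    data.frame(lot = 1, analyte = "PPL", area = 0.06 * 5000), lloq,
    is_analytes = "PPL")
  expect_false(is_dirty$passed)
  expect_error(selectivity_check(
    data.frame(lot = 1, analyte = "MET", area = 1),
    data.frame(analyte = "MET", area = 0)), "positive")
})

test_that("battery accuracy concentrates around the generated bias", {
  # property: with bias b and cv v over n pooled replicates, the battery
  # accuracy lands within a few standard errors of 100 + b
  for (b in c(-8, 0, 8)) {
    accs <- vapply(1:20, function(s) {
      meas <- simulate_qc_battery(c(MQC = 1000), replicates = 6, days = 3,
                                  bias_pct = b, cv = 0.05, seed = s)
      qc_battery(meas)$inter_day$accuracy_pct
    }, numeric(1))
    se <- 100 * 0.05 / sqrt(18)
    expect_lt(abs(mean(accs) - (100 + b)), 3 * se)
  }
})
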