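test_that("default profile reproduces the study service volumes and mix", {
  p <- default_study_profile()
  expect_equal(p$rt_courses_by_modality,
               c(cobalt = 583, linac2d = 222, `3dcrt` = 77, imrt = 57))
  expect_equal(sum(p$rt_courses_by_modality), 939)
  expect_equal(p$treatment_mix,
               c(rt_only = 0.554, rt_chemo = 0.293, surg_rt = 0.100,
                 surg_rt_chemo = 0.053))
  expect_equal(sum(p$treatment_mix), 1)
  expect_equal(p$opd_visits_radiotherapy, 1227)
  expect_equal(p$admissions, 225)
  expect_silent(validate_study_profile(p))
})

test_that("facility generation is deterministic under a fixed seed and seed-sensitive otherwise", {
  ds1 <- generate_facility(generator_config(seed = 1))
  ds2 <- generate_facility(generator_config(seed = 1))
  expect_identical(ds1, ds2)
  ds3 <- generate_facility(generator_config(seed = 2))
  expect_false(isTRUE(all.equal(ds1$recurrent$price, ds3$recurrent$price)))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_facility(generator_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("noise-free generation round-trips to the target cost structure through the costing engine", {
  cfg <- generator_config(noise_scale = 0)
  ds <- generate_facility(cfg)
  ac <- compute_annual_costs(ds)
  dept <- c("opd_radiotherapy", "inpatient", "rt_2drt_cobalt",
            "rt_2drt_linac", "rt_3dcrt", "rt_imrt_linac", "rt_imrt_igrt")
  dept_total <- sum(ac$allocations$cost[ac$allocations$service %in% dept])
  expect_equal(dept_total, cfg$profile$total_annual_cost, tolerance = 1e-8)

  shares <- compute_cost_shares(ac, services = dept)
  target <- 100 * cfg$profile$target_input_shares[shares$group]
  expect_true(all(abs(shares$percent - target) < 1))  # within 1 percentage point

  uc <- compute_unit_costs(ac, ds$volumes)
  tuc <- cfg$profile$target_unit_costs
  tuc <- tuc[!is.na(tuc)]
  got <- stats::setNames(uc$unit_cost, uc$service)[names(tuc)]
  expect_equal(got, tuc, tolerance = 1e-8)
})

test_that("generated staff time fractions are valid and every resource category is populated", {
  ds <- generate_facility(generator_config(seed = 3))
  sums <- tapply(ds$staff_time$fraction, ds$staff_time$staff_id, sum)
  expect_true(all(sums <= 1 + 1e-9))
  expect_true(all(ds$staff_time$fraction >= 0))
  cats <- c(unique(ds$capital$category), unique(ds$recurrent$category),
            "salary", "space")
  expect_true(all(c("salary", "equipment", "furniture", "space",
                    "drugs_consumables", "stationery_sanitary",
                    "overhead_water", "overhead_electricity", "laundry",
                    "dietetics", "lab_test") %in% cats))
})

test_that("patient records carry exact totals, cohort labels near the study split, and configured means", {
  cfg <- generator_config(seed = 4)
  rec <- generate_patient_records(cfg)
  expect_equal(nrow(rec), 474)
  dh_cols <- grep("^dh_", names(rec), value = TRUE)
  dnh_cols <- grep("^dnh_", names(rec), value = TRUE)
  expect_equal(rowSums(rec[dh_cols]), rec$direct_health_total)
  expect_equal(rowSums(rec[dnh_cols]), rec$direct_non_health_total)
  expect_true(all(rec$direct_health_total >= 0))
  # cohort counts follow the 159/315 proportions of the study
  expect_equal(unname(table(rec$cohort)["prospective"]), 159)

  # zero noise: every record sits exactly at its combination's mean
  rec0 <- generate_patient_records(generator_config(seed = 4,
                                                    noise_scale = 0))
  lv <- cfg$profile$oop_levels
  m <- lv$mean_health[match(rec0$combination, lv$combination)]
  expect_equal(rec0$direct_health_total, m)
})

test_that("large-sample spending means and combination frequencies converge to the configuration", {
  cfg <- generator_config(seed = 6, n_patients = 10000)
  rec <- generate_patient_records(cfg)

  x <- rec$direct_health_total[rec$combination == "2drt"]
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 12575), 2 * se)

  # empirical base-combination frequencies within 3 SE of the mix
  base <- ifelse(grepl("^surgery", rec$combination),
                 ifelse(grepl("chemo", rec$combination), "surg_rt_chemo",
                        "surg_rt"),
                 ifelse(grepl("^chemo", rec$combination), "rt_chemo",
                        "rt_only"))
  mix <- cfg$profile$treatment_mix
  for (cmb in names(mix)) {
    p_hat <- mean(base == cmb)
    se_p <- sqrt(mix[[cmb]] * (1 - mix[[cmb]]) / nrow(rec))
    expect_lt(abs(p_hat - mix[[cmb]]), 3 * se_p)
  }
})

test_that("unknown treatment combinations in the profile are rejected", {
  cfg <- generator_config(seed = 1)
  cfg$profile$oop_levels <-
    cfg$profile$oop_levels[cfg$profile$oop_levels$combination != "2drt", ]
  expect_error(generate_patient_records(cfg), "no spending level")
})
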