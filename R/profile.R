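# Study profile: the service volumes, treatment mix, cost structure and
# out-of-pocket spending levels that the synthetic facility generator
# emulates. The defaults describe one accounting year of a tertiary-care
# radiotherapy department in North India treating head and neck cancer.

#' Default study profile
#'
#' Returns the profile of the emulated department for the 2014-15 accounting
#' year: 1227 outpatient consultations, 225 admissions, and 939 radiotherapy
#' courses (583 on a cobalt-60 machine, 222 conventional 2-D courses on
#' linear accelerators, 77 3D-CRT and 57 IMRT). The treatment mix is 55.4%
#' primary radiotherapy alone, 29.3% radiotherapy with chemotherapy, 10%
#' surgery followed by radiotherapy and 5.3% surgery plus radiotherapy and
#' chemotherapy. The target input-cost structure is 42.6% salaries, 29%
#' equipment/furniture, 20.7% space rent and 7.7% overheads and consumables,
#' over a total annual department cost of INR 40,993,017.
#'
#' Out-of-pocket spending levels per treatment combination are the per-course
#' direct-health and direct-non-health means the generator draws around.
#'
#' @return object of class `study_profile`.
#' @export
default_study_profile <- function() {
  rt_courses <- c(cobalt = 583, linac2d = 222, `3dcrt` = 77, imrt = 57)
  # IMRT split between the image-guided machine and the plain linacs is a
  # synthetic choice (not a recorded figure): 40 IGRT / 17 DBX-DHX.
  imrt_igrt <- 40

  target_unit_costs <- c(
    opd_radiotherapy   = 538,
    opd_otolaryngology = 302,
    inpatient          = NA,     # residual: closes the department total
    diagnostics        = 4108,
    surgery            = 47191,
    rt_2drt_cobalt     = 17896,
    rt_2drt_linac      = 35246,
    rt_3dcrt           = 52133,
    rt_imrt_linac      = 69920,
    rt_imrt_igrt       = 163728
  )

  volumes <- c(
    opd_radiotherapy   = 1227,
    opd_otolaryngology = 1250,
    inpatient          = 3334,   # bed-days over 225 admissions
    diagnostics        = 1227,
    surgery            = 144,    # 15.3% of 939 radiotherapy patients
    rt_2drt_cobalt     = unname(rt_courses["cobalt"]),
    rt_2drt_linac      = unname(rt_courses["linac2d"]),
    rt_3dcrt           = unname(rt_courses["3dcrt"]),
    rt_imrt_linac      = unname(rt_courses["imrt"]) - imrt_igrt,
    rt_imrt_igrt       = imrt_igrt
  )

  units <- c(
    opd_radiotherapy = "per_visit", opd_otolaryngology = "per_visit",
    inpatient = "per_bed_day", diagnostics = "per_patient",
    surgery = "per_patient", rt_2drt_cobalt = "per_patient",
    rt_2drt_linac = "per_patient", rt_3dcrt = "per_patient",
    rt_imrt_linac = "per_patient", rt_imrt_igrt = "per_patient"
  )

  # Direct-health / direct-non-health mean OOP spend (INR per treatment
  # course) by treatment combination label.
  oop <- rbind(
    surgery                = c(30768, 13330),
    `2drt`                 = c(12575, 18912),
    `chemo+2drt`           = c(17061, 18410),
    `surgery+2drt`         = c(32650, 19945),
    `surgery+2drt+chemo`   = c(32595, 25278),
    `3dcrt`                = c(21026, 19351),
    `chemo+3dcrt`          = c(25675, 21793),
    `surgery+3dcrt`        = c(37213, 21611),
    `surgery+3dcrt+chemo`  = c(56351, 22025),
    imrt                   = c(21007, 21398),
    `chemo+imrt`           = c(26029, 21966),
    `surgery+imrt`         = c(53619, 22643),
    `surgery+imrt+chemo`   = c(65257, 21435)
  )
  oop_levels <- data.frame(
    combination = rownames(oop),
    mean_health = oop[, 1],
    mean_non_health = oop[, 2],
    cv = 0.65,
    stringsAsFactors = FALSE
  )
  rownames(oop_levels) <- NULL

  structure(
    list(
      opd_visits_radiotherapy = 1227,
      opd_visits_otolaryngology = 1250,
      admissions = 225,
      bed_days = 3334,
      rt_courses_by_modality = rt_courses,
      imrt_igrt_courses = imrt_igrt,
      treatment_mix = c(rt_only = 0.554, rt_chemo = 0.293,
                        surg_rt = 0.100, surg_rt_chemo = 0.053),
      target_input_shares = c(salary = 0.426, equipment = 0.290,
                              space = 0.207, other = 0.077),
      total_annual_cost = 40993017,
      target_unit_costs = target_unit_costs,
      volumes = volumes,
      units = units,
      oop_levels = oop_levels,
      pre_hospital = c(mean = 20435, cv = 0.8),
      cohort_split = c(prospective = 159, retrospective = 315)
    ),
    class = "study_profile"
  )
}

#' Validate a study profile
#'
#' @param profile a `study_profile`.
#' @return the profile, invisibly, after checking that treatment-mix
#'   fractions sum to 1, modality counts sum to the radiotherapy total, and
#'   all counts are non-negative.
#' @export
validate_study_profile <- function(profile) {
  stopifnot(inherits(profile, "study_profile"))
  assert_that(abs(sum(profile$treatment_mix) - 1) <= 1e-9,
              "treatment_mix fractions must sum to 1")
  assert_that(all(profile$rt_courses_by_modality >= 0) &&
                all(profile$volumes >= 0) && profile$admissions >= 0,
              "all counts must be >= 0")
  rt_services <- c("rt_2drt_cobalt", "rt_2drt_linac", "rt_3dcrt",
                   "rt_imrt_linac", "rt_imrt_igrt")
  assert_that(
    sum(profile$volumes[rt_services]) == sum(profile$rt_courses_by_modality),
    "radiotherapy service volumes must sum to the modality totals"
  )
  assert_that(abs(sum(profile$target_input_shares) - 1) <= 1e-9,
              "target_input_shares must sum to 1")
  invisible(profile)
}

#' Generator configuration
#'
#' @param profile a `study_profile` (default [default_study_profile()]).
#' @param seed integer RNG seed; identical configurations produce identical
#'   synthetic datasets.
#' @param noise_scale dimensionless dispersion multiplier (>= 0). It scales
#'   both the lognormal jitter on facility prices (sd `0.05 * noise_scale`)
#'   and the coefficient of variation of patient spending. `0` produces the
#'   fully deterministic calibrated dataset; `1` (default) is the intended
#'   level of realism.
#' @param n_patients number of patient expenditure records to simulate
#'   (default 474: 159 followed prospectively, 315 interviewed at follow-up).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(profile = default_study_profile(), seed = 1L,
                             noise_scale = 1, n_patients = 474L) {
  validate_study_profile(profile)
  assert_that(noise_scale >= 0, "noise_scale must be >= 0")
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  structure(
    list(profile = profile, seed = as.integer(seed),
         noise_scale = noise_scale, n_patients = as.integer(n_patients)),
    class = "generator_config"
  )
}

# Iterative proportional fitting: adjust an initial service x group mix
# matrix (rows sum to 1) so that the pool-weighted column totals hit the
# target global shares while rows stay on the simplex.
rake_mixes <- function(init, pool_weights, targets, tol = 1e-12,
                       max_iter = 500) {
  m <- init
  for (iter in seq_len(max_iter)) {
    col_tot <- colSums(m * pool_weights)
    m <- sweep(m, 2, targets / col_tot, `*`)
    m <- m / rowSums(m)
    col_tot <- colSums(m * pool_weights)
    if (max(abs(col_tot - targets)) < tol) break
  }
  m
}
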