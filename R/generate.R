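# Synthetic facility generator. Builds a facility resource inventory whose
# bottom-up costing reproduces the profile's target unit costs, total annual
# cost and input-cost shares when noise is off, and emulates them under
# realistic price dispersion otherwise.

# Initial per-service input mixes (rows: service, cols: share group).
# Seeded from the known structure of the emulated department -- equipment
# dominates linac-based techniques (57-69%) while cobalt delivery is
# salary-led (~40% salaries, 27% equipment) -- then raked so the
# pool-weighted global shares hit the profile targets exactly.
initial_service_mixes <- function() {
  m <- rbind(
    opd_radiotherapy = c(salary = 0.60, equipment = 0.05, space = 0.25, other = 0.10),
    inpatient        = c(salary = 0.45, equipment = 0.08, space = 0.27, other = 0.20),
    rt_2drt_cobalt   = c(salary = 0.40, equipment = 0.27, space = 0.23, other = 0.10),
    rt_2drt_linac    = c(salary = 0.25, equipment = 0.57, space = 0.13, other = 0.05),
    rt_3dcrt         = c(salary = 0.35, equipment = 0.41, space = 0.18, other = 0.06),
    rt_imrt_linac    = c(salary = 0.32, equipment = 0.46, space = 0.16, other = 0.06),
    rt_imrt_igrt     = c(salary = 0.18, equipment = 0.69, space = 0.10, other = 0.03)
  )
  m / rowSums(m)
}

# Sub-split of the "other" group into recurrent/overhead categories.
other_category_mix <- function(service) {
  if (service == "inpatient") {
    c(drugs_consumables = 0.35, dietetics = 0.25, overhead_electricity = 0.12,
      laundry = 0.12, stationery_sanitary = 0.10, overhead_water = 0.06)
  } else {
    c(drugs_consumables = 0.55, stationery_sanitary = 0.15,
      overhead_electricity = 0.15, laundry = 0.08, overhead_water = 0.07)
  }
}

RT_DEPT_SERVICES <- c("opd_radiotherapy", "inpatient", "rt_2drt_cobalt",
                      "rt_2drt_linac", "rt_3dcrt", "rt_imrt_linac",
                      "rt_imrt_igrt")

# lognormal price jitter with unit mean; sd 0.05 * noise_scale
price_jitter <- function(n, noise_scale) {
  sdlog <- 0.05 * noise_scale
  if (sdlog <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Target annual cost pool per service: printed unit costs x volumes, with
# the inpatient pool defined as the residual closing the department total.
service_pools <- function(profile) {
  uc <- profile$target_unit_costs
  vol <- profile$volumes
  pools <- uc * vol[names(uc)]
  dept_other <- setdiff(RT_DEPT_SERVICES, "inpatient")
  pools["inpatient"] <- profile$total_annual_cost - sum(pools[dept_other])
  assert_that(pools[["inpatient"]] > 0,
              "profile inconsistency: residual inpatient pool is negative")
  pools
}

#' Generate a synthetic facility dataset
#'
#' Builds one accounting year of facility records -- staff roster with time
#' allocations, capital items with prices and lifespans, floor space,
#' consumables and overhead bills, service volumes and apportionment rules --
#' calibrated so that costing the dataset reproduces the profile's target
#' unit costs and input shares. Capital prices are back-calculated through
#' the annuity factor at the supplied discount rate, so annualization
#' recovers the intended annual charge. With `noise_scale = 0` the
#' round trip is exact; at the default noise level every price carries
#' lognormal jitter of about 5%.
#'
#' @param config a [generator_config()].
#' @param costing a [costing_config()]; its discount rate and rental price
#'   are the ones the calibration assumes.
#' @return object of class `facility_dataset`: list of data.frames `staff`,
#'   `staff_time`, `capital`, `space`, `recurrent`, `volumes`, plus the
#'   apportionment `rules` for shared overheads.
#' @export
generate_facility <- function(config = generator_config(),
                              costing = costing_config()) {
  stopifnot(inherits(config, "generator_config"))
  profile <- validate_study_profile(config$profile)
  assert_that(all(profile$volumes > 0),
              "invalid config: zero service volumes cannot be costed")

  with_private_seed(sub_seed(config$seed, 1), {
    noise <- config$noise_scale
    pools <- service_pools(profile)

    # rake per-service mixes to the global input-share targets
    dept_pools <- pools[RT_DEPT_SERVICES]
    mixes <- rake_mixes(
      initial_service_mixes()[RT_DEPT_SERVICES, ],
      pool_weights = dept_pools / sum(dept_pools),
      targets = profile$target_input_shares
    )
    # services outside the radiotherapy department (not share-constrained)
    extra <- rbind(
      opd_otolaryngology = c(salary = 0.65, equipment = 0.05, space = 0.20, other = 0.10),
      surgery            = c(salary = 0.50, equipment = 0.20, space = 0.12, other = 0.18)
    )
    mixes <- rbind(mixes, extra)

    services <- rownames(mixes)
    group_pool <- mixes * pools[services]   # service x group INR targets

    staff <- list(); staff_time <- list()
    capital <- list(); space <- list(); recurrent <- list()

    ## ---- salaries ------------------------------------------------------
    sal <- group_pool[, "salary"]
    dept_sal <- sal[RT_DEPT_SERVICES]
    st_dept <- sum(dept_sal)

    # shared senior staff work across all department services in proportion
    # to each service's salary pool; they carry 30% of the salary budget
    shared <- data.frame(
      staff_id = c(paste0("oncologist_", 1:4), paste0("physicist_", 1:2)),
      cadre = c(rep("oncologist", 4), rep("physicist", 2)),
      base = c(rep(2400000, 4), rep(1200000, 2)),
      stringsAsFactors = FALSE
    )
    shared$gross_salary <- shared$base * (0.30 * st_dept / sum(shared$base)) *
      price_jitter(nrow(shared), noise)
    frac <- dept_sal / st_dept
    for (i in seq_len(nrow(shared))) {
      staff_time[[length(staff_time) + 1]] <- data.frame(
        staff_id = shared$staff_id[i], service = names(frac),
        fraction = unname(frac), stringsAsFactors = FALSE
      )
    }
    staff[[1]] <- shared[, c("staff_id", "cadre", "gross_salary")]

    # dedicated staff fill the remaining 70% of each department service's
    # salary pool, and the full pool for surgery / otolaryngology OPD
    cadres <- data.frame(
      cadre = c("resident", "technician", "nurse"),
      base = c(1000000, 600000, 550000), stringsAsFactors = FALSE
    )
    for (s in services) {
      target <- if (s %in% RT_DEPT_SERVICES) 0.70 * sal[[s]] else sal[[s]]
      n <- max(1, round(target / 750000))
      idx <- rep(seq_len(nrow(cadres)), length.out = n)
      base <- cadres$base[idx] * price_jitter(n, noise)
      gross <- base * (target / sum(base))
      ids <- paste0(cadres$cadre[idx], "_", s, "_", seq_len(n))
      staff[[length(staff) + 1]] <- data.frame(
        staff_id = ids, cadre = cadres$cadre[idx], gross_salary = gross,
        stringsAsFactors = FALSE
      )
      staff_time[[length(staff_time) + 1]] <- data.frame(
        staff_id = ids, service = s, fraction = 1, stringsAsFactors = FALSE
      )
    }

    ## ---- equipment and furniture --------------------------------------
    equip_specs <- list(
      c(label = "main_unit", frac = 0.80, life = 12),
      c(label = "accessories", frac = 0.20, life = 8)
    )
    for (s in services) {
      eq_pool <- 0.90 * group_pool[s, "equipment"]
      fu_pool <- 0.10 * group_pool[s, "equipment"]
      for (spec in equip_specs) {
        annual <- eq_pool * as.numeric(spec["frac"])
        life <- as.numeric(spec["life"])
        capital[[length(capital) + 1]] <- data.frame(
          item_id = paste0("cap_", s, "_", spec["label"]),
          category = "equipment", service = s,
          price = annual * annuity_factor(life, costing$discount_rate) *
            price_jitter(1, noise),
          quantity = 1, lifespan_years = life, stringsAsFactors = FALSE
        )
      }
      capital[[length(capital) + 1]] <- data.frame(
        item_id = paste0("cap_", s, "_furniture"), category = "furniture",
        service = s,
        price = fu_pool * annuity_factor(10, costing$discount_rate) *
          price_jitter(1, noise),
        quantity = 1, lifespan_years = 10, stringsAsFactors = FALSE
      )
    }

    ## ---- space ---------------------------------------------------------
    for (s in services) {
      space[[length(space) + 1]] <- data.frame(
        item_id = paste0("room_", s), service = s,
        area_sqft = group_pool[s, "space"] / costing$space_rent_per_sqft *
          price_jitter(1, noise),
        stringsAsFactors = FALSE
      )
    }

    ## ---- recurrent consumables and overheads ---------------------------
    shared_cat <- c("overhead_water", "overhead_electricity", "laundry")
    shared_target <- stats::setNames(
      rep(0, length(shared_cat)), shared_cat
    )
    shared_weights <- stats::setNames(
      vector("list", length(shared_cat)), shared_cat
    )
    for (s in services) {
      split <- other_category_mix(s)
      amounts <- group_pool[s, "other"] * split
      for (cat in names(amounts)) {
        if (cat %in% shared_cat && s %in% RT_DEPT_SERVICES) {
          shared_target[[cat]] <- shared_target[[cat]] + amounts[[cat]]
          shared_weights[[cat]] <- c(shared_weights[[cat]],
                                     stats::setNames(amounts[[cat]], s))
          next
        }
        qty <- switch(cat,
          drugs_consumables = max(1, round(profile$volumes[[s]] * 10)),
          dietetics = max(1, round(profile$bed_days * 3)),
          max(1, round(profile$volumes[[s]]))
        )
        recurrent[[length(recurrent) + 1]] <- data.frame(
          item_id = paste0("rec_", s, "_", cat), category = cat, service = s,
          price = amounts[[cat]] / qty * price_jitter(1, noise),
          quantity = qty, stringsAsFactors = FALSE
        )
      }
    }
    rules <- list()
    rule_stat <- c(overhead_water = "floor_area",
                   overhead_electricity = "patient_time_proportion",
                   laundry = "patient_proportion")
    for (cat in shared_cat) {
      w <- shared_weights[[cat]]
      rules[[cat]] <- apportionment_rule(cat, rule_stat[[cat]], w / sum(w))
      recurrent[[length(recurrent) + 1]] <- data.frame(
        item_id = paste0("rec_shared_", cat), category = cat,
        service = NA_character_,
        price = shared_target[[cat]] * price_jitter(1, noise), quantity = 1,
        stringsAsFactors = FALSE
      )
    }

    # diagnostics: indirect cost centre charged as a priced per-patient input
    recurrent[[length(recurrent) + 1]] <- data.frame(
      item_id = "rec_diagnostics_panel", category = "lab_test",
      service = "diagnostics",
      price = profile$target_unit_costs[["diagnostics"]] *
        price_jitter(1, noise),
      quantity = profile$volumes[["diagnostics"]], stringsAsFactors = FALSE
    )

    staff <- do.call(rbind, staff)
    dataset <- structure(
      list(
        staff = staff,
        staff_time = do.call(rbind, staff_time),
        capital = do.call(rbind, capital),
        space = do.call(rbind, space),
        recurrent = do.call(rbind, recurrent),
        volumes = data.frame(
          service = names(profile$volumes),
          unit = unname(profile$units[names(profile$volumes)]),
          volume = unname(profile$volumes), stringsAsFactors = FALSE
        ),
        rules = rules,
        profile = profile
      ),
      class = "facility_dataset"
    )
    rownames(dataset$staff) <- rownames(dataset$capital) <- NULL
    rownames(dataset$staff_time) <- rownames(dataset$recurrent) <- NULL
    rownames(dataset$space) <- NULL
    if (nrow(dataset$staff) == 0 || nrow(dataset$capital) == 0) {
      stop("invalid config: no staff or capital items generated for ",
           "nonzero service volumes", call. = FALSE)
    }
    dataset
  })
}

#' @export
print.facility_dataset <- function(x, ...) {
  cat("Synthetic facility dataset:",
      nrow(x$staff), "staff,", nrow(x$capital), "capital items,",
      nrow(x$recurrent), "recurrent items,", nrow(x$volumes), "services\n")
  invisible(x)
}

# map a (mix combination, modality class) pair to its expenditure label
oop_label <- function(mix_combo, modality) {
  switch(mix_combo,
    rt_only = modality,
    rt_chemo = paste0("chemo+", modality),
    surg_rt = paste0("surgery+", modality),
    surg_rt_chemo = paste0("surgery+", modality, "+chemo"),
    stop("unknown treatment-mix combination: ", mix_combo, call. = FALSE)
  )
}

# itemization of spending within the health / non-health groups
OOP_HEALTH_ITEMS <- c(diagnostics = 0.22, radiotherapy = 0.18, drugs = 0.38,
                      hospitalization = 0.12, user_fee = 0.10)
OOP_NON_HEALTH_ITEMS <- c(transport = 0.42, boarding = 0.33, food = 0.25)

#' Generate synthetic patient expenditure records
#'
#' Simulates per-patient out-of-pocket spending for one treatment course.
#' Each patient gets a treatment-combination label drawn from the profile's
#' treatment mix (with the radiotherapy technique drawn from the modality
#' distribution), a prospective/retrospective cohort label, and itemized
#' direct-health (diagnostics, radiotherapy charges, drugs including
#' chemotherapy, hospitalization, user fee) and direct-non-health
#' (transport, boarding, food) amounts drawn from gamma distributions
#' whose means match the profile's spending level for that combination.
#' Costs are non-negative and right-skewed, hence the gamma family.
#' The cohort label is metadata only: both cohorts share one spending
#' distribution, and pre-hospital spending is carried separately, never
#' added into course totals.
#'
#' @param config a [generator_config()].
#' @return data.frame of class `patient_records`, one row per patient, with
#'   per-item columns (`dh_*`, `dnh_*`), exact totals `direct_health_total`
#'   and `direct_non_health_total`, and `pre_hospital`.
#' @export
generate_patient_records <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  profile <- validate_study_profile(config$profile)
  n <- config$n_patients
  assert_that(n >= 1, "n_patients must be >= 1")

  with_private_seed(sub_seed(config$seed, 2), {
    noise <- config$noise_scale
    mix <- profile$treatment_mix
    rt <- profile$rt_courses_by_modality
    modality_p <- c(`2drt` = unname(rt["cobalt"] + rt["linac2d"]),
                    `3dcrt` = unname(rt["3dcrt"]),
                    imrt = unname(rt["imrt"]))
    modality_p <- modality_p / sum(modality_p)

    combo <- sample(names(mix), n, replace = TRUE, prob = mix)
    modality <- sample(names(modality_p), n, replace = TRUE, prob = modality_p)
    label <- mapply(oop_label, combo, modality, USE.NAMES = FALSE)

    levels_tab <- profile$oop_levels
    miss <- setdiff(unique(label), levels_tab$combination)
    if (length(miss)) {
      stop("invalid config: no spending level configured for combination(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    row_idx <- match(label, levels_tab$combination)
    mh <- levels_tab$mean_health[row_idx]
    mnh <- levels_tab$mean_non_health[row_idx]
    cv_val <- levels_tab$cv[1] * noise

    # the configured cv applies to the per-course total; items are a fixed
    # split of the drawn total, so itemized amounts sum to it exactly
    total_h <- rgamma_mean_cv(n, mh, cv_val)
    total_nh <- rgamma_mean_cv(n, mnh, cv_val)
    dh <- outer(total_h, OOP_HEALTH_ITEMS)
    dnh <- outer(total_nh, OOP_NON_HEALTH_ITEMS)
    n_pro <- round(n * profile$cohort_split[["prospective"]] /
                     sum(profile$cohort_split))
    cohort <- sample(rep(c("prospective", "retrospective"),
                         c(n_pro, n - n_pro)))

    rec <- data.frame(
      patient_id = sprintf("pt_%04d", seq_len(n)),
      cohort = cohort,
      combination = label,
      stringsAsFactors = FALSE
    )
    colnames(dh) <- paste0("dh_", names(OOP_HEALTH_ITEMS))
    colnames(dnh) <- paste0("dnh_", names(OOP_NON_HEALTH_ITEMS))
    rec <- cbind(rec, as.data.frame(dh), as.data.frame(dnh))
    rec$direct_health_total <- rowSums(dh)
    rec$direct_non_health_total <- rowSums(dnh)
    rec$pre_hospital <- rgamma_mean_cv(n, profile$pre_hospital[["mean"]],
                                       profile$pre_hospital[["cv"]] * noise)
    class(rec) <- c("patient_records", "data.frame")
    rec
  })
}
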