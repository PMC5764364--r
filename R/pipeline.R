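# Pipeline: tie generation, costing, OOP aggregation, PSA and package
# composition into one reproducible run with CSV/JSON outputs and a
# structured JSON-lines log.

money2 <- function(x) round_half_up(x, 2)

# money_cols are written as 2-decimal fixed point (presentation rounding);
# everything else keeps full precision so datasets round-trip through CSV.
write_csv_table <- function(df, path, money_cols = NULL) {
  for (cl in intersect(money_cols, names(df))) {
    if (is.numeric(df[[cl]])) df[[cl]] <- money2(df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

MONEY_COLS <- c("annual_cost", "unit_cost", "ci_low", "ci_high", "percent",
                "cost", "mean_incl_non_health", "incl_ci_low",
                "incl_ci_high", "mean_excl_non_health", "excl_ci_low",
                "excl_ci_high", "inr", "rate_inr", "computed_inr",
                "difference_inr")

#' Write a facility dataset and patient records as CSV
#'
#' One CSV per entity (staff, time allocations, capital, space, recurrent
#' items, service volumes, patient records) plus a JSON manifest carrying
#' the apportionment rules, seed and package version.
#'
#' @param dataset a `facility_dataset`.
#' @param records a `patient_records` data.frame (optional).
#' @param dir output directory (created if needed).
#' @param config the [generator_config()] used, recorded in the manifest
#'   and as `generator_config.yaml`.
#' @return invisibly, the vector of files written.
#' @export
write_facility_csv <- function(dataset, records = NULL, dir,
                               config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  tables <- list(staff = dataset$staff, staff_time = dataset$staff_time,
                 capital = dataset$capital, space = dataset$space,
                 recurrent = dataset$recurrent, volumes = dataset$volumes)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write_csv_table(tables[[nm]], f)
    files <- c(files, f)
  }
  if (!is.null(records)) {
    f <- file.path(dir, "patients.csv")
    write_csv_table(as.data.frame(records), f)
    files <- c(files, f)
  }
  manifest <- list(
    package = "hnccost",
    version = as.character(utils::packageVersion("hnccost")),
    seed = if (!is.null(config)) config$seed,
    noise_scale = if (!is.null(config)) config$noise_scale,
    n_patients = if (!is.null(config)) config$n_patients,
    rules = lapply(dataset$rules, function(r) {
      list(resource_category = r$resource_category, statistic = r$statistic,
           weights = as.list(r$weights))
    }),
    tables = basename(files)
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(config)) {
    yaml::write_yaml(
      list(seed = config$seed, noise_scale = config$noise_scale,
           n_patients = config$n_patients),
      file.path(dir, "generator_config.yaml")
    )
  }
  invisible(c(files, mf))
}

#' Read a facility dataset written by [write_facility_csv()]
#'
#' @param dir directory holding the CSV tables and `manifest.json`.
#' @return a `facility_dataset`.
#' @export
read_facility_csv <- function(dir) {
  rd <- function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                     stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rules <- lapply(manifest$rules, function(r) {
    apportionment_rule(r$resource_category, r$statistic,
                       unlist(r$weights))
  })
  cap <- rd("capital"); cap$service <- as.character(cap$service)
  rec <- rd("recurrent"); rec$service <- as.character(rec$service)
  cap$service[cap$service == ""] <- NA_character_
  rec$service[rec$service == ""] <- NA_character_
  structure(
    list(staff = rd("staff"), staff_time = rd("staff_time"), capital = cap,
         space = rd("space"), recurrent = rec, volumes = rd("volumes"),
         rules = rules),
    class = "facility_dataset"
  )
}

#' Read patient expenditure records from CSV
#'
#' @param path path to a `patients.csv` written by [write_facility_csv()].
#' @return a `patient_records` data.frame.
#' @export
read_patient_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(rec) <- c("patient_records", "data.frame")
  rec
}

#' Simulate a study dataset and write it to disk
#'
#' Generates the synthetic facility inventory and patient expenditure
#' records for the configured profile and writes them as CSV tables with a
#' JSON manifest. Rerunning with the same configuration reproduces the
#' files byte for byte.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @param costing a [costing_config()].
#' @return invisibly, list with `dataset`, `records` and `files`.
#' @export
simulate_study <- function(config = generator_config(), out_dir,
                           costing = costing_config()) {
  dataset <- generate_facility(config, costing)
  records <- generate_patient_records(config)
  files <- write_facility_csv(dataset, records, out_dir, config)
  invisible(list(dataset = dataset, records = records, files = files))
}

log_line <- function(con, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full costing pipeline
#'
#' End-to-end run: generate (or load) the facility dataset and patient
#' records, compute annual and unit costs, run the price PSA for interval
#' estimates, summarize out-of-pocket spending, compose package rates and
#' compare them with insurance-scheme reference rates. All stages are
#' seeded from one global seed via a deterministic splitting rule, so a
#' repeated run with the same seed writes byte-identical outputs.
#'
#' Written outputs: `unit_costs.csv` (per-service unit costs with PSA
#' intervals and USD), `input_shares.csv` (input-category cost structure of
#' the radiotherapy department), `annual_costs.csv` (service x category
#' matrix), `oop_summary.csv`, `package_rates.csv`, `scheme_comparison.csv`,
#' `manifest.json`, and a JSON-lines `log.jsonl` recording the rules and
#' settings applied.
#'
#' @param out_dir output directory; created if needed.
#' @param seed global integer seed.
#' @param config a [generator_config()]; its seed is overridden by `seed`.
#'   Mutually exclusive with `input_dir`.
#' @param input_dir directory of facility CSVs (from [simulate_study()])
#'   to load instead of generating.
#' @param costing a [costing_config()].
#' @param psa a [psa_config()] or `NULL` to skip the PSA (point estimates
#'   only, empty CI columns); its seed is overridden by the global seed.
#' @param currency a [currency_config()].
#' @param package_defs named list of [package_definition()]s.
#' @return invisibly, list of all computed objects.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = NULL,
                         input_dir = NULL,
                         costing = costing_config(), psa = psa_config(),
                         currency = currency_config(),
                         package_defs = default_package_definitions()) {
  if (!is.null(config) && !is.null(input_dir)) {
    stop("supply exactly one of a generator config or an input directory",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(logf), add = TRUE)

  if (is.null(input_dir)) {
    config <- config %||% generator_config()
    config$seed <- as.integer(seed)
    dataset <- generate_facility(config, costing)
    records <- generate_patient_records(config)
    log_line(logf, "simulate", seed = config$seed,
             noise_scale = config$noise_scale,
             n_patients = config$n_patients)
  } else {
    dataset <- read_facility_csv(input_dir)
    records <- read_patient_csv(file.path(input_dir, "patients.csv"))
    log_line(logf, "load", input_dir = input_dir)
  }

  annual <- compute_annual_costs(dataset, costing)
  for (r in dataset$rules) {
    log_line(logf, "apportion", category = r$resource_category,
             statistic = r$statistic, weights = as.list(r$weights))
  }
  unit_costs <- compute_unit_costs(annual, dataset$volumes)
  dept <- intersect(RT_DEPT_SERVICES, unique(annual$allocations$service))
  shares <- compute_cost_shares(annual, services = dept)
  log_line(logf, "costing", total_inr = annual$total)

  psa_result <- NULL
  if (!is.null(psa)) {
    psa$seed <- sub_seed(seed, 3)
    psa_result <- run_psa(dataset, costing, psa)
    unit_costs <- add_psa_intervals(unit_costs, psa_result)
    log_line(logf, "psa", n_draws = psa$n_draws,
             n_excluded = attr(psa_result, "n_excluded"))
  }

  oop <- summarize_oop(records)
  # packages whose OOP combination never occurred in the cohort cannot be
  # priced on this run; they are skipped and logged, not imputed
  priceable <- vapply(package_defs, function(d) {
    is.na(d$oop_combination) || d$oop_combination %in% oop$combination
  }, logical(1))
  for (nm in names(package_defs)[!priceable]) {
    log_line(logf, "package_skipped", package = nm,
             reason = "combination absent from cohort")
  }
  rates <- lapply(package_defs[priceable], compose_package,
                  unit_costs = unit_costs, oop = oop, currency = currency)
  schemes <- scheme_rate_table()
  alone <- rates[intersect(names(rates), unique(schemes$technique))]
  for (nm in setdiff(unique(schemes$technique), names(alone))) {
    log_line(logf, "scheme_comparison_skipped", technique = nm)
  }
  comparison <- compare_schemes(
    alone, schemes[schemes$technique %in% names(alone), ]
  )
  log_line(logf, "packages", n_packages = length(rates))

  # ---- write outputs ----
  uc_out <- as.data.frame(unit_costs)
  uc_out$usd <- to_usd(uc_out$unit_cost, currency)
  write_csv_table(uc_out, file.path(out_dir, "unit_costs.csv"), MONEY_COLS)
  write_csv_table(shares, file.path(out_dir, "input_shares.csv"), MONEY_COLS)
  write_csv_table(annual$summary, file.path(out_dir, "annual_costs.csv"),
                  MONEY_COLS)

  oop_out <- as.data.frame(oop)
  oop_out$mean_incl_usd <- to_usd(oop_out$mean_incl_non_health, currency)
  oop_out$mean_excl_usd <- to_usd(oop_out$mean_excl_non_health, currency)
  write_csv_table(oop_out, file.path(out_dir, "oop_summary.csv"), MONEY_COLS)

  rates_out <- do.call(rbind, lapply(rates, function(p) {
    data.frame(package = p$label, inr = p$inr, usd = p$usd,
               ci_low = p$ci_low, ci_high = p$ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(rates_out) <- NULL
  write_csv_table(rates_out, file.path(out_dir, "package_rates.csv"),
                  MONEY_COLS)
  write_csv_table(comparison, file.path(out_dir, "scheme_comparison.csv"),
                  MONEY_COLS)

  manifest <- list(
    package = "hnccost",
    version = as.character(utils::packageVersion("hnccost")),
    seed = as.integer(seed),
    total_annual_cost_inr = annual$total,
    psa_draws = if (!is.null(psa)) psa$n_draws else 0L,
    inr_per_usd = currency$inr_per_usd
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    dataset = dataset, records = records, annual = annual,
    unit_costs = unit_costs, shares = shares, psa = psa_result, oop = oop,
    package_rates = rates, scheme_comparison = comparison
  ))
}
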