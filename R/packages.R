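# Provider-payment package rates: health-system unit costs x episode
# quantities, plus diagnostics and the patient's direct-health OOP
# spending, converted to USD and compared against insurance-scheme rates.

#' Currency configuration
#'
#' @param inr_per_usd exchange rate, INR per USD (default 61.02, the
#'   World Bank rate for the costing year).
#' @return object of class `currency_config`.
#' @export
currency_config <- function(inr_per_usd = 61.02) {
  assert_that(inr_per_usd > 0, "inr_per_usd must be > 0")
  structure(list(inr_per_usd = inr_per_usd), class = "currency_config")
}

#' Convert INR to whole USD
#'
#' Divides by the configured exchange rate and rounds half-up to an
#' integer dollar amount, the convention used for all reported conversions.
#'
#' @param amount amount in INR (>= 0); vectorized.
#' @param currency a [currency_config()].
#' @return integer USD.
#' @examples
#' to_usd(47191)   # 773
#' to_usd(61.02)   # 1
#' @export
to_usd <- function(amount, currency = currency_config()) {
  assert_that(all(amount >= 0), "amount must be >= 0")
  as.integer(round_half_up(amount / currency$inr_per_usd))
}

#' Ratio of two costs
#'
#' @param numerator,denominator INR amounts; denominator must be > 0.
#' @return the ratio `numerator / denominator`.
#' @export
cost_ratio <- function(numerator, denominator) {
  assert_that(all(denominator > 0), "denominator must be > 0")
  numerator / denominator
}

#' Package definition
#'
#' One treatment episode expressed as priced components: services with
#' quantities (consultations, bed-days, a treatment course), plus flags for
#' including per-patient diagnostics and the patient's direct-health OOP
#' spending for the matching treatment combination.
#'
#' @param label human-readable package label.
#' @param components data.frame with columns `service` and `quantity`.
#' @param oop_combination treatment-combination label whose mean
#'   direct-health OOP spend is added, or `NA` to exclude OOP.
#' @param include_diagnostics add the per-patient diagnostics cost?
#' @return object of class `package_definition`.
#' @export
package_definition <- function(label, components,
                               oop_combination = NA_character_,
                               include_diagnostics = TRUE) {
  assert_that(all(components$quantity >= 0), "quantities must be >= 0")
  structure(
    list(label = label, components = components,
         oop_combination = oop_combination,
         include_diagnostics = include_diagnostics),
    class = "package_definition"
  )
}

#' Default package definitions
#'
#' One package per cell of the treatment grid: each radiotherapy technique
#' alone or combined with surgery and/or chemotherapy, plus surgery without
#' radiotherapy. Episode quantities (outpatient visits, bed-days) are not
#' observable from published figures and are configuration: the defaults
#' are 3 radiotherapy-department consultations per episode and 7 bed-days
#' when surgery is part of the package.
#'
#' @param opd_visits consultations per episode (default 3).
#' @param surgical_bed_days inpatient bed-days for packages that include
#'   surgery (default 7).
#' @return named list of [package_definition()]s.
#' @export
default_package_definitions <- function(opd_visits = 3,
                                        surgical_bed_days = 7) {
  techniques <- c(rt_2drt_cobalt = "2drt", rt_2drt_linac = "2drt",
                  rt_3dcrt = "3dcrt", rt_imrt_linac = "imrt",
                  rt_imrt_igrt = "imrt")
  variants <- list(
    alone = c(surgery = FALSE, chemo = FALSE),
    surgery = c(surgery = TRUE, chemo = FALSE),
    chemo = c(surgery = FALSE, chemo = TRUE),
    surgery_chemo = c(surgery = TRUE, chemo = TRUE)
  )
  defs <- list()
  for (svc in names(techniques)) {
    for (v in names(variants)) {
      has_surg <- variants[[v]][["surgery"]]
      has_chemo <- variants[[v]][["chemo"]]
      comp <- data.frame(
        service = c("opd_radiotherapy", svc,
                    if (has_surg) c("surgery", "inpatient")),
        quantity = c(opd_visits, 1,
                     if (has_surg) c(1, surgical_bed_days)),
        stringsAsFactors = FALSE
      )
      modality <- techniques[[svc]]
      oop <- if (has_surg && has_chemo) {
        paste0("surgery+", modality, "+chemo")
      } else if (has_surg) {
        paste0("surgery+", modality)
      } else if (has_chemo) {
        paste0("chemo+", modality)
      } else {
        modality
      }
      key <- if (v == "alone") svc else paste0(svc, "_", v)
      defs[[key]] <- package_definition(
        label = key, components = comp, oop_combination = oop
      )
    }
  }
  defs[["surgery_only"]] <- package_definition(
    label = "surgery_only",
    components = data.frame(
      service = c("opd_otolaryngology", "surgery", "inpatient"),
      quantity = c(opd_visits, 1, surgical_bed_days),
      stringsAsFactors = FALSE
    ),
    oop_combination = "surgery"
  )
  defs
}

#' Compose a package rate
#'
#' Adds up the health-system cost of the package components (unit cost x
#' quantity), the per-patient diagnostics cost when included, and the mean
#' direct-health OOP spend of the matching treatment combination when
#' included. Interval bounds are the sums of the component bounds
#' (conservative interval arithmetic): PSA percentile bounds for unit
#' costs, t-interval bounds for the OOP mean.
#'
#' @param defn a [package_definition()].
#' @param unit_costs a `unit_cost_table` (with PSA intervals merged for CI
#'   propagation).
#' @param oop an `oop_summary`, required when the definition includes OOP.
#' @param currency a [currency_config()].
#' @return object of class `package_rate`: list with `label`, `inr`, `usd`,
#'   `ci_low`, `ci_high`.
#' @export
compose_package <- function(defn, unit_costs, oop = NULL,
                            currency = currency_config()) {
  stopifnot(inherits(defn, "package_definition"))
  comp <- defn$components
  if (defn$include_diagnostics) {
    comp <- rbind(comp, data.frame(service = "diagnostics", quantity = 1))
  }
  comp <- comp[comp$quantity > 0, , drop = FALSE]

  i <- match(comp$service, unit_costs$service)
  if (anyNA(i)) {
    stop("package '", defn$label, "': no unit cost for service(s) ",
         paste(comp$service[is.na(i)], collapse = ", "), call. = FALSE)
  }
  point <- sum(unit_costs$unit_cost[i] * comp$quantity)
  lo <- unit_costs$ci_low[i]
  hi <- unit_costs$ci_high[i]
  ci_low <- sum(ifelse(is.na(lo), unit_costs$unit_cost[i], lo) * comp$quantity)
  ci_high <- sum(ifelse(is.na(hi), unit_costs$unit_cost[i], hi) * comp$quantity)

  if (!is.na(defn$oop_combination)) {
    if (is.null(oop)) {
      stop("package '", defn$label, "': OOP summary required for ",
           "combination ", defn$oop_combination, call. = FALSE)
    }
    j <- match(defn$oop_combination, oop$combination)
    if (is.na(j)) {
      stop("package '", defn$label, "': no OOP entry for combination ",
           defn$oop_combination, call. = FALSE)
    }
    point <- point + oop$mean_excl_non_health[j]
    ci_low <- ci_low + oop$excl_ci_low[j]
    ci_high <- ci_high + oop$excl_ci_high[j]
  }

  structure(
    list(label = defn$label, inr = point, usd = to_usd(point, currency),
         ci_low = ci_low, ci_high = ci_high),
    class = "package_rate"
  )
}

#' Reference insurance-scheme package rates
#'
#' Static reference table of radiotherapy package rates under Indian health
#' insurance schemes (CGHS, ESIS, RSBY-plus, RAS, RGJAY) and the costed
#' reference department, by radiotherapy technique. Shipped as CSV;
#' missing cells are techniques a scheme does not price.
#'
#' @return data.frame with columns `technique`, `scheme`, `rate_inr`.
#' @export
scheme_rate_table <- function() {
  path <- system.file("extdata", "scheme_rates.csv", package = "hnccost")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare computed package rates against scheme rates
#'
#' @param packages named list of `package_rate`s keyed like the default
#'   definitions (technique `alone` keys match scheme techniques).
#' @param schemes long data.frame from [scheme_rate_table()].
#' @return data.frame with one row per (technique, scheme): the scheme
#'   rate, the computed rate, and the signed difference
#'   (computed - scheme); `NA` where the scheme does not price the
#'   technique. Techniques with no computed package are skipped with a
#'   warning.
#' @export
compare_schemes <- function(packages, schemes = scheme_rate_table()) {
  computed <- vapply(packages, function(p) p$inr, numeric(1))
  out <- schemes
  out$computed_inr <- unname(computed[out$technique])
  unmatched <- setdiff(unique(out$technique), names(computed))
  if (length(unmatched)) {
    warning("no computed package for technique(s): ",
            paste(unmatched, collapse = ", "), "; rows skipped")
    out <- out[!out$technique %in% unmatched, ]
  }
  out$difference_inr <- ifelse(
    is.na(out$rate_inr), NA_real_, out$computed_inr - out$rate_inr
  )
  out
}
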