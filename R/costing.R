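# Costing engine: capital annualization, apportionment of shared resources,
# staff time allocation, and aggregation into per-service unit costs.

RESOURCE_CATEGORIES <- c(
  "salary", "equipment", "furniture", "space", "drugs_consumables",
  "stationery_sanitary", "overhead_water", "overhead_electricity",
  "laundry", "dietetics", "lab_test"
)

APPORTIONMENT_STATISTICS <- c(
  "time_fraction", "patient_proportion", "patient_time_proportion",
  "floor_area", "diet_count", "item_count"
)

#' Costing configuration
#'
#' Parameters of the costing engine: the discount rate used to annualize
#' capital, the accounting year label, the rental price applied to floor
#' space, and the market-to-hospital price adjustment applied to non-medical
#' items bought at market rather than procurement prices.
#'
#' @param discount_rate annual discount rate as a fraction (default 0.05,
#'   the conventional rate for public-sector costing).
#' @param accounting_year label for the costing year.
#' @param space_rent_per_sqft rental value of space, INR per square foot per
#'   year. Space is costed as rent, not as annualized construction cost.
#' @param market_to_hospital_ratio multiplier deflating market prices of
#'   non-medical items to an estimated hospital procurement price.
#' @return object of class `costing_config`.
#' @export
costing_config <- function(discount_rate = 0.05,
                           accounting_year = "2014-15",
                           space_rent_per_sqft = 1200,
                           market_to_hospital_ratio = 0.85) {
  assert_that(discount_rate >= 0 && discount_rate < 1,
              "discount_rate must lie in [0, 1)")
  assert_that(space_rent_per_sqft > 0, "space_rent_per_sqft must be > 0")
  assert_that(market_to_hospital_ratio > 0 && market_to_hospital_ratio <= 1,
              "market_to_hospital_ratio must lie in (0, 1]")
  structure(
    list(
      discount_rate = discount_rate,
      accounting_year = accounting_year,
      space_rent_per_sqft = space_rent_per_sqft,
      market_to_hospital_ratio = market_to_hospital_ratio
    ),
    class = "costing_config"
  )
}

#' Annuity factor for equivalent annual costing
#'
#' @param lifespan_years useful life of the capital item in years.
#' @param discount_rate annual discount rate as a fraction.
#' @return the present value of a 1-per-year annuity over the lifespan:
#'   `(1 - (1 + r)^-L) / r` for `r > 0`, and `L` in the zero-rate limit.
#' @export
annuity_factor <- function(lifespan_years, discount_rate) {
  assert_that(all(lifespan_years >= 1), "lifespan_years must be >= 1")
  assert_that(all(discount_rate >= 0 & discount_rate < 1),
              "discount_rate must lie in [0, 1)")
  n <- max(length(lifespan_years), length(discount_rate))
  L <- rep_len(lifespan_years, n)
  r <- rep_len(discount_rate, n)
  ifelse(r == 0, L, (1 - (1 + r)^(-L)) / r)
}

#' Equivalent annual cost of a capital item
#'
#' Converts a purchase price into the constant annual charge that, discounted
#' at `discount_rate` over `lifespan_years`, has the same present value.
#' This is the standard annuitization used in health-facility costing;
#' at a zero discount rate it reduces to straight-line `price / lifespan`.
#'
#' @param price purchase (procurement) price, INR.
#' @param lifespan_years useful life in years (>= 1).
#' @param discount_rate annual discount rate as a fraction.
#' @return equivalent annual cost in INR/year.
#' @examples
#' annualize_capital(1000, 1, 0.05)       # one-period annuity: 1050
#' annualize_capital(500, 5, 0)           # straight line: 100
#' annualize_capital(100000, 10, 0.05)    # 12950.46
#' @export
annualize_capital <- function(price, lifespan_years, discount_rate) {
  assert_that(all(price >= 0), "price must be >= 0")
  price / annuity_factor(lifespan_years, discount_rate)
}

#' Apportionment rule for a shared resource category
#'
#' Describes how the annual cost of a resource shared across services is
#' split: the allocation statistic it is based on (staff time, patient
#' proportions, floor area, diet counts, item counts) and the resulting
#' normalized weights.
#'
#' @param resource_category one of the resource categories (e.g.
#'   `"overhead_water"`).
#' @param statistic the apportioning statistic the weights were derived from.
#' @param weights named non-negative numeric vector over target services,
#'   summing to 1.
#' @return object of class `apportionment_rule`.
#' @export
apportionment_rule <- function(resource_category, statistic, weights) {
  resource_category <- match.arg(resource_category, RESOURCE_CATEGORIES)
  statistic <- match.arg(statistic, APPORTIONMENT_STATISTICS)
  assert_that(length(weights) >= 1 && !is.null(names(weights)),
              "weights must be a named numeric vector")
  assert_that(all(weights >= 0), "weights must be non-negative")
  assert_that(sum(weights) > 0, "degenerate rule: all weights are zero")
  assert_that(abs(sum(weights) - 1) <= 1e-9, "weights must sum to 1")
  structure(
    list(resource_category = resource_category, statistic = statistic,
         weights = weights),
    class = "apportionment_rule"
  )
}

#' Apportion a shared cost across services
#'
#' Splits `total_cost` according to the weights of an apportionment rule;
#' the shares are exactly `total_cost * weight` and conserve the total.
#'
#' @param total_cost annual cost to split, INR.
#' @param rule an [apportionment_rule()], or a bare named weight vector.
#' @return named numeric vector of INR shares per service.
#' @examples
#' apportion(100, c(a = 0.4, b = 0.6))
#' @export
apportion <- function(total_cost, rule) {
  weights <- if (inherits(rule, "apportionment_rule")) rule$weights else rule
  assert_that(!is.null(names(weights)), "weights must be named by service")
  assert_that(all(weights >= 0), "weights must be non-negative")
  s <- sum(weights)
  assert_that(s > 0, "degenerate rule: all weights are zero")
  assert_that(abs(s - 1) <= 1e-9, "weights must sum to 1")
  total_cost * weights
}

#' Allocate a staff member's gross salary over activities
#'
#' Splits a gross annual salary by proportional time contribution. Fractions
#' may sum to less than 1 (time spent outside the costed services); the
#' unallocated remainder is reported separately rather than redistributed.
#'
#' @param gross_salary gross annual salary, INR.
#' @param time_fractions named vector of time fractions per activity,
#'   non-negative, summing to at most 1.
#' @return list with `by_activity` (named INR vector, salary x fraction) and
#'   `remainder` (INR not attributed to any listed activity).
#' @examples
#' allocate_staff_cost(120000, c(opd = 0.5, planning = 0.5))
#' @export
allocate_staff_cost <- function(gross_salary, time_fractions) {
  assert_that(gross_salary >= 0, "gross_salary must be >= 0")
  assert_that(all(time_fractions >= 0), "time fractions must be >= 0")
  total <- sum(time_fractions)
  if (total > 1 + 1e-9) {
    stop("invalid allocation: time fractions sum to ", format(total),
         " (> 1)", call. = FALSE)
  }
  list(
    by_activity = gross_salary * time_fractions,
    remainder = gross_salary * max(0, 1 - total)
  )
}

# Item-level allocation table: one row per (item, service) with the item's
# annualized cost share. This long table is the engine's workhorse: the
# service x category summary, unit costs, and every PSA draw derive from it.
build_item_allocations <- function(dataset, config, rules) {
  rows <- list()

  add_rows <- function(item_id, category, annual, service, rule_label = NA) {
    if (is.na(service) || identical(service, "")) {
      rule <- rules[[category]]
      if (is.null(rule)) {
        stop("missing apportionment rule for shared resource '", item_id,
             "' (category ", category, ")", call. = FALSE)
      }
      shares <- apportion(annual, rule)
      data.frame(
        item_id = item_id, category = category,
        service = names(shares), cost = unname(shares),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(item_id = item_id, category = category, service = service,
                 cost = annual, stringsAsFactors = FALSE)
    }
  }

  # salaries via time allocation
  st <- dataset$staff_time
  for (i in seq_len(nrow(dataset$staff))) {
    s <- dataset$staff[i, ]
    fr <- st[st$staff_id == s$staff_id, ]
    fractions <- stats::setNames(fr$fraction, fr$service)
    alloc <- allocate_staff_cost(s$gross_salary, fractions)
    by <- alloc$by_activity[alloc$by_activity > 0]
    if (length(by)) {
      rows[[length(rows) + 1]] <- data.frame(
        item_id = s$staff_id, category = "salary",
        service = names(by), cost = unname(by), stringsAsFactors = FALSE
      )
    }
    if (alloc$remainder > 1e-9) {
      rows[[length(rows) + 1]] <- data.frame(
        item_id = s$staff_id, category = "salary",
        service = "unallocated", cost = alloc$remainder,
        stringsAsFactors = FALSE
      )
    }
  }

  # capital: annualize, then allocate
  cap <- dataset$capital
  if (!is.null(cap) && nrow(cap)) {
    annual <- annualize_capital(cap$price * cap$quantity, cap$lifespan_years,
                                config$discount_rate)
    for (i in seq_len(nrow(cap))) {
      rows[[length(rows) + 1]] <-
        add_rows(cap$item_id[i], cap$category[i], annual[i], cap$service[i])
    }
  }

  # space costed as rent on floor area
  sp <- dataset$space
  if (!is.null(sp) && nrow(sp)) {
    annual <- sp$area_sqft * config$space_rent_per_sqft
    for (i in seq_len(nrow(sp))) {
      rows[[length(rows) + 1]] <-
        add_rows(sp$item_id[i], "space", annual[i], sp$service[i])
    }
  }

  # recurrent items: price x annual quantity
  rec <- dataset$recurrent
  if (!is.null(rec) && nrow(rec)) {
    annual <- rec$price * rec$quantity
    for (i in seq_len(nrow(rec))) {
      rows[[length(rows) + 1]] <-
        add_rows(rec$item_id[i], rec$category[i], annual[i], rec$service[i])
    }
  }

  do.call(rbind, rows)
}

#' Compute annual costs by service and input category
#'
#' Runs the full bottom-up costing of a facility dataset: salaries are split
#' by staff time allocation, capital is annualized at the configured discount
#' rate then attributed to its service (or apportioned by its category's
#' rule when shared), space is costed as rent on floor area, and recurrent
#' items enter at price x annual quantity. The result conserves cost: the
#' grand total equals the sum of all annualized item costs.
#'
#' @param dataset a `facility_dataset` (see [generate_facility()] or
#'   [read_facility_csv()]).
#' @param config a [costing_config()].
#' @param rules named list of [apportionment_rule()]s by resource category;
#'   defaults to the rules carried by the dataset.
#' @return object of class `annual_costs`: list with `allocations` (item x
#'   service long table), `summary` (service x category totals), and `total`.
#' @export
compute_annual_costs <- function(dataset, config = costing_config(),
                                 rules = NULL) {
  stopifnot(inherits(dataset, "facility_dataset"))
  rules <- rules %||% dataset$rules
  alloc <- build_item_allocations(dataset, config, rules)
  summary <- stats::aggregate(cost ~ service + category, data = alloc, FUN = sum)
  structure(
    list(allocations = alloc, summary = summary, total = sum(alloc$cost)),
    class = "annual_costs"
  )
}

#' @export
print.annual_costs <- function(x, ...) {
  cat("Annual costs: INR", format(round(x$total), big.mark = ","),
      "over", length(unique(x$summary$service)), "services\n")
  invisible(x)
}

#' Per-service unit costs
#'
#' Divides each service's annual cost pool by its service volume, carrying
#' the service's natural unit (visit, bed-day, treated patient).
#'
#' @param annual_costs an `annual_costs` object.
#' @param volumes data.frame with columns `service`, `unit`, `volume`.
#' @return object of class `unit_cost_table`: data.frame with columns
#'   `service`, `unit`, `volume`, `annual_cost`, `unit_cost`, `ci_low`,
#'   `ci_high` (CIs filled by [run_psa()], `NA` until then).
#' @export
compute_unit_costs <- function(annual_costs, volumes) {
  stopifnot(inherits(annual_costs, "annual_costs"))
  pools <- stats::aggregate(cost ~ service, data = annual_costs$allocations,
                            FUN = sum)
  tab <- merge(volumes, pools, by = "service", all.x = TRUE)
  tab$cost[is.na(tab$cost)] <- 0
  bad <- tab$volume <= 0 & tab$cost > 0
  if (any(bad)) {
    stop("zero volume with nonzero cost for service(s): ",
         paste(tab$service[bad], collapse = ", "), call. = FALSE)
  }
  tab$unit_cost <- ifelse(tab$volume > 0, tab$cost / tab$volume, NA_real_)
  out <- data.frame(
    service = tab$service, unit = tab$unit, volume = tab$volume,
    annual_cost = tab$cost, unit_cost = tab$unit_cost,
    ci_low = NA_real_, ci_high = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$service), ]
  rownames(out) <- NULL
  class(out) <- c("unit_cost_table", "data.frame")
  out
}

#' Default grouping of input categories for cost shares
#'
#' Groups the detailed resource categories into the four headline input
#' classes used when reporting the cost structure of radiotherapy care:
#' salaries, equipment/furniture, space rent, and overheads/consumables.
#'
#' @return named list mapping group label to resource categories.
#' @export
default_share_groups <- function() {
  list(
    salary = "salary",
    equipment = c("equipment", "furniture"),
    space = "space",
    other = c("drugs_consumables", "stationery_sanitary", "overhead_water",
              "overhead_electricity", "laundry", "dietetics", "lab_test")
  )
}

#' Input-wise percentage shares of annual cost
#'
#' @param annual_costs an `annual_costs` object.
#' @param groups named list mapping share groups to resource categories
#'   (default [default_share_groups()]); pass `NULL` for ungrouped
#'   per-category shares.
#' @param services optional character vector restricting the share
#'   computation to a subset of services (e.g. one department).
#' @return data.frame with columns `group` and `percent`, summing to 100.
#' @export
compute_cost_shares <- function(annual_costs, groups = default_share_groups(),
                                services = NULL) {
  stopifnot(inherits(annual_costs, "annual_costs"))
  alloc <- annual_costs$allocations
  if (!is.null(services)) alloc <- alloc[alloc$service %in% services, ]
  assert_that(nrow(alloc) > 0 && sum(alloc$cost) > 0,
              "empty cost map: nothing to share")
  by_cat <- stats::aggregate(cost ~ category, data = alloc, FUN = sum)
  total <- sum(by_cat$cost)
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(by_cat$category), by_cat$category)
  }
  percent <- vapply(groups, function(cats) {
    100 * sum(by_cat$cost[by_cat$category %in% cats]) / total
  }, numeric(1))
  data.frame(group = names(groups), percent = unname(percent),
             stringsAsFactors = FALSE)
}
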