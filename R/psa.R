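# Probabilistic sensitivity analysis: resource prices are drawn from gamma
# or normal distributions spanning stated ranges around the base price, the
# costing is re-evaluated per draw, and unit costs are summarized as the
# draw mean with percentile 95% intervals.

#' Price variation rule
#'
#' Describes how the price of one resource category is varied in the PSA:
#' the distribution family and the stated range below/above the base price.
#' For the normal family the range is interpreted as the central
#' `ci_level` interval; for the gamma family the distribution is
#' moment-matched to mean = base and SD = `(lower + upper) * base / (2 z)`,
#' with the range asymmetry absorbed into the gamma's natural right skew.
#'
#' @param resource_category resource category the rule applies to.
#' @param family `"gamma"` or `"normal"`.
#' @param lower_frac fraction of the base price the lower limit sits below
#'   base (in `[0, 1]`: prices cannot go below zero).
#' @param upper_frac fraction above base (>= 0).
#' @return object of class `price_variation_rule`.
#' @export
price_variation_rule <- function(resource_category, family, lower_frac,
                                 upper_frac) {
  resource_category <- match.arg(resource_category, RESOURCE_CATEGORIES)
  family <- match.arg(family, c("gamma", "normal"))
  assert_that(lower_frac >= 0 && lower_frac <= 1,
              "lower_frac must lie in [0, 1]")
  assert_that(upper_frac >= 0, "upper_frac must be >= 0")
  structure(
    list(resource_category = resource_category, family = family,
         lower_frac = lower_frac, upper_frac = upper_frac),
    class = "price_variation_rule"
  )
}

#' Default price variation rules
#'
#' The base-case variation ranges for the five resource groups: salaries
#' -75%/+20% (gamma: strongly asymmetric, positive), radiotherapy equipment
#' and furniture-type items +/-40% and +/-25% (normal), drugs and
#' consumables +/-100% (gamma: widest variation, bounded at zero),
#' building/space and laboratory-test prices +/-50% (normal).
#'
#' @return named list of [price_variation_rule()]s covering every resource
#'   category.
#' @export
default_variation_rules <- function() {
  groups <- list(
    list(cats = "salary", family = "gamma", lower = 0.75, upper = 0.20),
    list(cats = "equipment", family = "normal", lower = 0.40, upper = 0.40),
    list(cats = "drugs_consumables", family = "gamma", lower = 1.00,
         upper = 1.00),
    list(cats = c("furniture", "stationery_sanitary"), family = "normal",
         lower = 0.25, upper = 0.25),
    list(cats = c("space", "lab_test"), family = "normal", lower = 0.50,
         upper = 0.50)
  )
  rules <- list()
  for (g in groups) {
    for (cat in g$cats) {
      rules[[cat]] <- price_variation_rule(cat, g$family, g$lower, g$upper)
    }
  }
  # overheads behave like consumable bills: modest symmetric variation
  for (cat in c("overhead_water", "overhead_electricity", "laundry",
                "dietetics")) {
    rules[[cat]] <- price_variation_rule(cat, "normal", 0.25, 0.25)
  }
  rules
}

#' PSA configuration
#'
#' @param n_draws number of Monte Carlo price draws (default 1000).
#' @param seed integer RNG seed.
#' @param ci_level level of the percentile interval (default 0.95).
#' @param rules named list of [price_variation_rule()]s by category
#'   (default [default_variation_rules()]).
#' @return object of class `psa_config`.
#' @export
psa_config <- function(n_draws = 1000L, seed = 1L, ci_level = 0.95,
                       rules = default_variation_rules()) {
  assert_that(n_draws >= 1, "n_draws must be >= 1")
  assert_that(ci_level > 0 && ci_level < 1, "ci_level must lie in (0, 1)")
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         ci_level = ci_level, rules = rules),
    class = "psa_config"
  )
}

#' Build a price sampler for one resource
#'
#' Returns a function `f(n)` drawing `n` prices around `base_price`
#' according to the rule. The sampler is mean-preserving: its expectation
#' is the base price. Normal draws use SD `(lower + upper) * base / (2 z)`
#' so that the stated range is the central `ci_level` interval; draws are
#' truncated at zero (relevant only when the lower limit approaches 100%).
#' Gamma draws are moment-matched to the same mean and SD and are positive
#' by construction. A degenerate rule (0% both sides) returns the base
#' price exactly.
#'
#' @param base_price base price, INR (> 0).
#' @param rule a [price_variation_rule()].
#' @param ci_level interval level defining the z used in the SD mapping.
#' @return function of `n` returning `n` price draws.
#' @export
build_sampler <- function(base_price, rule, ci_level = 0.95) {
  assert_that(base_price > 0, "base_price must be > 0")
  stopifnot(inherits(rule, "price_variation_rule"))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  sdev <- (rule$lower_frac + rule$upper_frac) * base_price / (2 * z)
  if (sdev == 0) return(function(n) rep(base_price, n))
  if (rule$family == "normal") {
    function(n) pmax(0, stats::rnorm(n, mean = base_price, sd = sdev))
  } else {
    shape <- (base_price / sdev)^2
    function(n) stats::rgamma(n, shape = shape, rate = shape / base_price)
  }
}

# one draw factor matrix: items x draws, each entry the multiplicative price
# perturbation for that item in that draw. Annualization and apportionment
# are linear in price, so scaling the item-level allocations by these
# factors is identical to re-running the costing engine on resampled prices.
psa_draw_factors <- function(item_categories, psa) {
  n_items <- length(item_categories)
  z <- stats::qnorm(1 - (1 - psa$ci_level) / 2)
  factors <- matrix(1, nrow = n_items, ncol = psa$n_draws)
  for (i in seq_len(n_items)) {
    rule <- psa$rules[[item_categories[i]]]
    if (is.null(rule)) next  # unvaried category keeps its base price
    sampler <- build_sampler(1, rule, psa$ci_level)
    factors[i, ] <- sampler(psa$n_draws)
  }
  factors
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every resource price independently from its category's variation
#' rule, re-evaluates the unit costs for each of `n_draws` price vectors,
#' and summarizes each service's unit cost as the draw mean with empirical
#' percentile intervals (2.5th/97.5th at the default level). A fixed seed
#' gives an identical result. Draws yielding a negative service total are
#' excluded and counted (possible only under extreme normal rules).
#'
#' @param dataset a `facility_dataset`.
#' @param config a [costing_config()].
#' @param psa a [psa_config()].
#' @param volumes service volume data.frame (default: the dataset's).
#' @return object of class `psa_result`: data.frame with per-service
#'   `mean`, `ci_low`, `ci_high`; the per-draw unit-cost matrix is attached
#'   as attribute `"draws"`, the number of excluded draws as `"n_excluded"`.
#' @export
run_psa <- function(dataset, config = costing_config(), psa = psa_config(),
                    volumes = NULL) {
  stopifnot(inherits(dataset, "facility_dataset"))
  volumes <- volumes %||% dataset$volumes
  ac <- compute_annual_costs(dataset, config)
  alloc <- ac$allocations

  items <- unique(alloc[, c("item_id", "category")])
  with_private_seed(psa$seed, {
    factors <- psa_draw_factors(items$category, psa)
    rownames(factors) <- items$item_id

    # service x draw matrix of annual pools under each price draw
    svc <- sort(unique(alloc$service))
    base <- matrix(0, nrow = length(svc), ncol = nrow(items),
                   dimnames = list(svc, items$item_id))
    idx <- cbind(match(alloc$service, svc), match(alloc$item_id, items$item_id))
    base[idx] <- base[idx] + alloc$cost
    pools <- base %*% factors   # services x draws

    keep <- colSums(pools < 0) == 0
    n_excluded <- sum(!keep)
    if (n_excluded > 0) {
      warning(n_excluded, " draw(s) produced a negative service total and ",
              "were excluded")
      pools <- pools[, keep, drop = FALSE]
    }

    vol <- stats::setNames(volumes$volume, volumes$service)
    svc_keep <- intersect(svc, names(vol))
    unit <- pools[svc_keep, , drop = FALSE] / vol[svc_keep]

    a <- (1 - psa$ci_level) / 2
    qs <- t(apply(unit, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE))
    out <- data.frame(
      service = svc_keep,
      mean = rowMeans(unit),
      ci_low = qs[, 1],
      ci_high = qs[, 2],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "draws") <- unit
    attr(out, "n_excluded") <- n_excluded
    class(out) <- c("psa_result", "data.frame")
    out
  })
}

#' Merge PSA percentile intervals into a unit-cost table
#'
#' @param unit_costs a `unit_cost_table` from [compute_unit_costs()].
#' @param psa_result a `psa_result` from [run_psa()].
#' @return the unit-cost table with `ci_low`/`ci_high` filled.
#' @export
add_psa_intervals <- function(unit_costs, psa_result) {
  i <- match(unit_costs$service, psa_result$service)
  unit_costs$ci_low <- psa_result$ci_low[i]
  unit_costs$ci_high <- psa_result$ci_high[i]
  unit_costs
}
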