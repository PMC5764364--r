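# Tiny hand-built facility fixtures for engine tests, constructed in code.

# One service, one fully allocated staff member and one direct consumable:
# total annual cost 150, all attributed to "clinic".
tiny_single_service <- function() {
  structure(
    list(
      staff = data.frame(staff_id = "s1", cadre = "nurse",
                         gross_salary = 100, stringsAsFactors = FALSE),
      staff_time = data.frame(staff_id = "s1", service = "clinic",
                              fraction = 1, stringsAsFactors = FALSE),
      capital = data.frame(item_id = character(), category = character(),
                           service = character(), price = numeric(),
                           quantity = numeric(), lifespan_years = numeric(),
                           stringsAsFactors = FALSE),
      space = data.frame(item_id = character(), service = character(),
                         area_sqft = numeric(), stringsAsFactors = FALSE),
      recurrent = data.frame(item_id = "r1", category = "drugs_consumables",
                             service = "clinic", price = 50, quantity = 1,
                             stringsAsFactors = FALSE),
      volumes = data.frame(service = "clinic", unit = "per_visit",
                           volume = 10, stringsAsFactors = FALSE),
      rules = list()
    ),
    class = "facility_dataset"
  )
}

# One shared capital item (price 1000, 1-year lifespan) split 50/50 between
# two services via an item_count rule.
tiny_shared_capital <- function() {
  ds <- tiny_single_service()
  ds$staff <- ds$staff[0, ]
  ds$staff_time <- ds$staff_time[0, ]
  ds$recurrent <- ds$recurrent[0, ]
  ds$capital <- data.frame(
    item_id = "machine", category = "equipment", service = NA_character_,
    price = 1000, quantity = 1, lifespan_years = 1, stringsAsFactors = FALSE
  )
  ds$rules <- list(
    equipment = apportionment_rule("equipment", "item_count",
                                   c(a = 0.5, b = 0.5))
  )
  ds$volumes <- data.frame(service = c("a", "b"), unit = "per_visit",
                           volume = c(1, 1), stringsAsFactors = FALSE)
  ds
}

# Single resource, single service: unit cost is a pass-through of the one
# price (volume 1), used to study PSA distribution pass-through.
tiny_one_price <- function(price = 100, category = "equipment") {
  ds <- tiny_single_service()
  ds$staff <- ds$staff[0, ]
  ds$staff_time <- ds$staff_time[0, ]
  ds$recurrent <- data.frame(
    item_id = "only", category = category, service = "clinic",
    price = price, quantity = 1, stringsAsFactors = FALSE
  )
  ds$volumes$volume <- 1
  ds
}

# PSA rule set with zero variation everywhere (degenerate draws).
zero_variation_rules <- function() {
  lapply(default_variation_rules(), function(r) {
    price_variation_rule(r$resource_category, r$family, 0, 0)
  })
}
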