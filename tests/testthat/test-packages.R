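unit_table <- function(services, costs, lows = NA, highs = NA) {
  out <- data.frame(
    service = services, unit = "per_patient", volume = 1,
    annual_cost = costs, unit_cost = costs,
    ci_low = rep_len(lows, length(services)),
    ci_high = rep_len(highs, length(services)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("unit_cost_table", "data.frame")
  out
}

oop_table <- function(combination, mean_excl, low = mean_excl,
                      high = mean_excl) {
  structure(
    data.frame(
      combination = combination, n = 10,
      mean_incl_non_health = mean_excl, incl_ci_low = low,
      incl_ci_high = high, mean_excl_non_health = mean_excl,
      excl_ci_low = low, excl_ci_high = high, stringsAsFactors = FALSE
    ),
    class = c("oop_summary", "data.frame")
  )
}

test_that("INR to USD conversion reproduces every printed pair at rate 61.02", {
  pairs <- rbind(
    c(538, 9), c(302, 5), c(3096, 51), c(4108, 67), c(47191, 773),
    c(163728, 2683), c(69920, 1146), c(52133, 854), c(35246, 578),
    c(17896, 293),                     # unit costs of services
    c(44098, 723), c(30768, 504), c(31487, 516), c(12575, 206),
    c(21026, 345), c(21007, 344), c(17061, 280), c(65257, 1069),
    c(20435, 335),                     # out-of-pocket levels
    c(38714, 634), c(192914, 3161),    # cheapest and costliest packages
    c(61.02, 1)
  )
  expect_equal(to_usd(pairs[, 1]), as.integer(pairs[, 2]))
  expect_error(to_usd(-5), "amount")
})

test_that("USD rounding is half-up and round-trips within half a dollar", {
  cc <- currency_config()
  expect_equal(to_usd(61.02 * 10.5), 11L)  # exact half rounds up
  set.seed(41)
  x <- stats::runif(500, 0, 3e5)
  usd <- to_usd(x, cc)
  expect_true(all(abs(usd * cc$inr_per_usd - x) <= cc$inr_per_usd / 2))
})

test_that("cost ratios reproduce the technology-cost multiples", {
  expect_equal(cost_ratio(163728, 17896), 9.149, tolerance = 1e-3)
  expect_equal(round(cost_ratio(163728, 17896)), 9)
  expect_equal(cost_ratio(52133, 17896), 2.913, tolerance = 1e-3)
  expect_equal(round(cost_ratio(52133, 17896)), 3)
  expect_equal(cost_ratio(77, 77), 1)
  expect_error(cost_ratio(1, 0), "denominator")
})

test_that("package composition adds components, diagnostics and OOP spending", {
  uc <- unit_table(c("rt_2drt_cobalt", "diagnostics"), c(17896, 4108))
  oop <- oop_table("2drt", 12575)

  # single component, nothing else: identity
  d0 <- package_definition(
    "rt_only", data.frame(service = "rt_2drt_cobalt", quantity = 1),
    include_diagnostics = FALSE
  )
  expect_equal(compose_package(d0, uc)$inr, 17896)

  # course + diagnostics + direct-health OOP
  d1 <- package_definition(
    "cobalt", data.frame(service = "rt_2drt_cobalt", quantity = 1),
    oop_combination = "2drt", include_diagnostics = TRUE
  )
  p1 <- compose_package(d1, uc, oop)
  expect_equal(p1$inr, 17896 + 4108 + 12575)  # 34579

  # zero-quantity components: OOP passes through alone
  d2 <- package_definition(
    "oop_only", data.frame(service = "rt_2drt_cobalt", quantity = 0),
    oop_combination = "2drt", include_diagnostics = FALSE
  )
  expect_equal(compose_package(d2, uc, oop)$inr, 12575)

  # missing pieces are named in the error
  d3 <- package_definition(
    "gap", data.frame(service = "rt_3dcrt", quantity = 1),
    include_diagnostics = FALSE
  )
  expect_error(compose_package(d3, uc), "rt_3dcrt")
  d4 <- package_definition(
    "gap2", data.frame(service = "rt_2drt_cobalt", quantity = 1),
    oop_combination = "imrt", include_diagnostics = FALSE
  )
  expect_error(compose_package(d4, uc, oop), "imrt")
})

test_that("composition is order-independent and strictly monotone in added components", {
  uc <- unit_table(c("a", "b", "diagnostics"), c(100, 250, 40))
  comp <- data.frame(service = c("a", "b"), quantity = c(2, 1))
  p_fwd <- compose_package(package_definition("f", comp,
                                              include_diagnostics = FALSE),
                           uc)
  p_rev <- compose_package(package_definition("r", comp[2:1, ],
                                              include_diagnostics = FALSE),
                           uc)
  expect_equal(p_fwd$inr, p_rev$inr)

  more <- rbind(comp, data.frame(service = "diagnostics", quantity = 1))
  p_more <- compose_package(package_definition("m", more,
                                               include_diagnostics = FALSE),
                            uc)
  expect_gt(p_more$inr, p_fwd$inr)
})

test_that("interval bounds propagate as sums of component bounds", {
  uc <- unit_table("rt_2drt_cobalt", 17896, lows = 17728, highs = 18063)
  oop <- oop_table("2drt", 12575, low = 11485, high = 13713)
  d <- package_definition(
    "cobalt", data.frame(service = "rt_2drt_cobalt", quantity = 1),
    oop_combination = "2drt", include_diagnostics = FALSE
  )
  p <- compose_package(d, uc, oop)
  expect_equal(p$ci_low, 17728 + 11485)
  expect_equal(p$ci_high, 18063 + 13713)
  expect_true(p$ci_low <= p$inr && p$inr <= p$ci_high)
})

test_that("scheme comparison reports signed differences and marks unpriced techniques", {
  schemes <- scheme_rate_table()
  expect_setequal(unique(schemes$scheme),
                  c("CGHS", "ESIS", "RSBY_plus", "RAS", "RGJAY",
                    "present_study"))
  pkgs <- list(
    rt_2drt_cobalt = structure(list(label = "rt_2drt_cobalt", inr = 38714,
                                    usd = 634L, ci_low = 38714,
                                    ci_high = 38714), class = "package_rate"),
    rt_2drt_linac = structure(list(label = "rt_2drt_linac", inr = 56064,
                                   usd = 919L, ci_low = 56064,
                                   ci_high = 56064), class = "package_rate")
  )
  cmp <- suppressWarnings(compare_schemes(pkgs, schemes))
  cobalt_cghs <- cmp[cmp$technique == "rt_2drt_cobalt" &
                       cmp$scheme == "CGHS", ]
  expect_equal(cobalt_cghs$difference_inr, 38714 - 78689)  # -39975
  # a technique the scheme does not price stays absent
  linac_cghs <- cmp[cmp$technique == "rt_2drt_linac" & cmp$scheme == "CGHS", ]
  expect_true(is.na(linac_cghs$difference_inr))
  # identical tables give all-zero differences
  self <- schemes[schemes$scheme == "present_study", ]
  pkgs2 <- lapply(stats::setNames(self$rate_inr, self$technique), function(v)
    structure(list(label = "x", inr = v, usd = to_usd(v), ci_low = v,
                   ci_high = v), class = "package_rate"))
  cmp2 <- compare_schemes(pkgs2, self)
  expect_true(all(cmp2$difference_inr == 0))
})
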