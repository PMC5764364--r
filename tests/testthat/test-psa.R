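test_that("default variation rules encode the stated ranges and families", {
  rules <- default_variation_rules()
  expect_equal(rules$salary$lower_frac, 0.75)
  expect_equal(rules$salary$upper_frac, 0.20)
  expect_equal(rules$equipment$lower_frac, 0.40)
  expect_equal(rules$drugs_consumables$lower_frac, 1.00)
  expect_equal(rules$drugs_consumables$upper_frac, 1.00)
  expect_equal(rules$furniture$lower_frac, 0.25)
  expect_equal(rules$stationery_sanitary$lower_frac, 0.25)
  expect_equal(rules$space$lower_frac, 0.50)
  expect_equal(rules$lab_test$lower_frac, 0.50)
  # five stated category groups, one rule each, no duplicates
  ranges <- sapply(rules[c("salary", "equipment", "drugs_consumables",
                           "furniture", "space")],
                   function(r) paste(r$lower_frac, r$upper_frac))
  expect_equal(anyDuplicated(ranges), 0)
  expect_error(price_variation_rule("salary", "gamma", 1.5, 0.2),
               "lower_frac")
})

test_that("samplers are mean-preserving and match the assigned distribution", {
  set.seed(31)
  # degenerate rule: every draw is the base price
  s0 <- build_sampler(100, price_variation_rule("equipment", "normal", 0, 0))
  expect_equal(s0(50), rep(100, 50))

  # normal +/-40%: stated limits are the central 95% quantiles
  sn <- build_sampler(100, price_variation_rule("equipment", "normal",
                                                0.40, 0.40))
  x <- sn(1e5)
  expect_equal(mean(x), 100, tolerance = 0.01)
  q <- unname(stats::quantile(x, c(0.025, 0.975)))
  expect_equal(q[1], 60, tolerance = 0.02)
  expect_equal(q[2], 140, tolerance = 0.02)

  # gamma +/-100%: positive draws, moment-matched mean
  sg <- build_sampler(100, price_variation_rule("drugs_consumables", "gamma",
                                                1, 1))
  y <- sg(1e5)
  expect_true(all(y > 0))
  expect_equal(mean(y), 100, tolerance = 0.01)
  # skewed right: mean above median
  expect_gt(mean(y), stats::median(y))
})

test_that("a degenerate PSA reproduces the deterministic unit costs with zero-width intervals", {
  ds <- generate_facility(generator_config(seed = 8, noise_scale = 0))
  psa0 <- psa_config(n_draws = 25, seed = 2, rules = zero_variation_rules())
  res <- run_psa(ds, psa = psa0)
  uc <- compute_unit_costs(compute_annual_costs(ds), ds$volumes)
  got <- stats::setNames(res$mean, res$service)[uc$service]
  expect_equal(unname(got), uc$unit_cost, tolerance = 1e-12)
  expect_equal(res$ci_low, res$ci_high, tolerance = 1e-12)
  expect_equal(attr(res, "n_excluded"), 0)
})

test_that("PSA is deterministic under a fixed seed", {
  ds <- generate_facility(generator_config(seed = 8))
  r1 <- run_psa(ds, psa = psa_config(n_draws = 100, seed = 5))
  r2 <- run_psa(ds, psa = psa_config(n_draws = 100, seed = 5))
  expect_identical(r1, r2)
})

test_that("a one-resource model passes the price distribution through to the unit cost", {
  ds <- tiny_one_price(100)
  rules <- zero_variation_rules()
  rules$equipment <- price_variation_rule("equipment", "normal", 0.40, 0.40)
  res <- run_psa(ds, psa = psa_config(n_draws = 20000, seed = 9,
                                      rules = rules))
  expect_equal(res$mean, 100, tolerance = 0.02)
  expect_equal(res$ci_low, 60, tolerance = 0.03)
  expect_equal(res$ci_high, 140, tolerance = 0.03)
})

test_that("interval mean sits inside the percentile bounds and draws stay linear in price", {
  ds <- generate_facility(generator_config(seed = 8))
  res <- run_psa(ds, psa = psa_config(n_draws = 400, seed = 10))
  expect_true(all(res$ci_low <= res$mean & res$mean <= res$ci_high))
  # symmetric-rule linear model: PSA mean near the deterministic cost
  uc <- compute_unit_costs(compute_annual_costs(ds), ds$volumes)
  det <- stats::setNames(uc$unit_cost, uc$service)
  eq_heavy <- res[res$service == "rt_imrt_igrt", ]
  expect_equal(eq_heavy$mean, det[["rt_imrt_igrt"]], tolerance = 0.05)
})

test_that("widening a rule's range widens the resulting interval", {
  ds <- tiny_one_price(100)
  width <- function(frac) {
    rules <- zero_variation_rules()
    rules$equipment <- price_variation_rule("equipment", "normal", frac, frac)
    r <- run_psa(ds, psa = psa_config(n_draws = 3000, seed = 11,
                                      rules = rules))
    r$ci_high - r$ci_low
  }
  expect_lt(width(0.10), width(0.25))
  expect_lt(width(0.25), width(0.40))
})

test_that("percentile intervals are equivariant under positive scaling of all prices", {
  ds <- tiny_one_price(100)
  ds2 <- ds
  ds2$recurrent$price <- ds2$recurrent$price * 3
  rules <- zero_variation_rules()
  rules$equipment <- price_variation_rule("equipment", "gamma", 0.5, 0.5)
  r1 <- run_psa(ds, psa = psa_config(n_draws = 2000, seed = 12,
                                     rules = rules))
  r2 <- run_psa(ds2, psa = psa_config(n_draws = 2000, seed = 12,
                                      rules = rules))
  expect_equal(r2$ci_low, 3 * r1$ci_low, tolerance = 1e-9)
  expect_equal(r2$ci_high, 3 * r1$ci_high, tolerance = 1e-9)
})

test_that("gamma-rule asymmetry shows up as right skew of the unit cost", {
  ds <- tiny_one_price(100, category = "salary")
  rules <- zero_variation_rules()
  rules$salary <- price_variation_rule("salary", "gamma", 0.75, 0.20)
  r <- run_psa(ds, psa = psa_config(n_draws = 20000, seed = 13,
                                    rules = rules))
  draws <- attr(r, "draws")[1, ]
  expect_gt(mean(draws), stats::median(draws))
  expect_gt(r$ci_high - r$mean, r$mean - r$ci_low)
})
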