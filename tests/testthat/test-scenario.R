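test_that("a fitted scenario is reproducible and internally consistent", {
  f1 <- sodium_cra(test_inputs, "au_hfp", draws = 60, seed = 4)
  f2 <- sodium_cra(test_inputs, "au_hfp", draws = 60, seed = 4)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws, f2$draws)
  # report percentages recompute from the report's own absolute columns
  s <- summary(f1)
  expect_equal(s$table$pct, 100 * s$table$averted / s$table$baseline)
  # the per-draw total is the sum of the per-cause columns
  cause_cols <- paste0("deaths.", test_inputs$burden$causes$cause_id)
  expect_equal(unname(f1$draws[, "deaths.total"]),
               unname(rowSums(f1$draws[, cause_cols])), tolerance = 1e-12)
  # simulate() with the stored seed reproduces the stored draws
  expect_equal(as.matrix(simulate(f1)), f1$draws, tolerance = 0)
})

test_that("an uncovered scenario averts nothing", {
  null_targets <- data.frame(category_id = character(),
                             max_mg_100g = numeric())
  f <- sodium_cra(test_inputs, targets = null_targets, draws = 10, seed = 1)
  expect_equal(unname(f$point$vector[["deaths.total"]]), 0)
  expect_true(all(f$draws[, "deaths.total"] == 0))
  expect_equal(unname(f$point$vector[["delta_mean"]]), 0)
})

test_that("stratified and population summaries partition correctly", {
  f <- sodium_cra(test_inputs, "au_hfp", draws = 0)
  v <- f$point$vector
  expect_equal(v[["deaths.men"]] + v[["deaths.women"]], v[["deaths.total"]],
               tolerance = 1e-9)
  expect_equal(v[["deaths.under70"]] + v[["deaths.age70plus"]],
               v[["deaths.total"]], tolerance = 1e-9)
  ps <- population_summary(f$delta, f$strata)
  w <- f$strata$pop_weight
  expect_equal(ps$overall,
               weighted.mean(f$delta$delta_mg_d[
                 match(f$strata$stratum_id, f$delta$stratum_id)], w))
})

test_that("scenario comparison works per draw and flags mismatches", {
  fits <- list(au = sodium_cra(test_inputs, "au_hfp", draws = 80, seed = 2),
               uk = sodium_cra(test_inputs, "uk_2017", draws = 80, seed = 2))
  cmp <- compare_scenarios(fits, reference = "au")
  row <- cmp[cmp$quantity == "deaths.total", ]
  expect_gte(row$central, 0)  # broader, stricter coverage cannot avert fewer
  # a scenario against itself: zero with a zero-width interval
  self <- compare_scenarios(list(a = fits$au, b = fits$au), reference = "a")
  srow <- self[self$quantity == "deaths.total", ]
  expect_equal(srow$central, 0)
  expect_equal(srow$upper - srow$lower, 0)
  # per-draw differencing is not naive interval subtraction
  s_au <- fits$au$summary
  s_uk <- fits$uk$summary
  naive_width <- (s_uk$upper[s_uk$quantity == "deaths.total"] -
                    s_au$lower[s_au$quantity == "deaths.total"]) -
    (s_uk$lower[s_uk$quantity == "deaths.total"] -
       s_au$upper[s_au$quantity == "deaths.total"])
  expect_false(isTRUE(all.equal(row$upper - row$lower, naive_width)))
  expect_lt(row$upper - row$lower, naive_width)
  # mismatched draw counts are rejected
  short <- sodium_cra(test_inputs, "uk_2017", draws = 40, seed = 2)
  expect_error(compare_scenarios(list(fits$au, short)), "mismatched")
  other_seed <- sodium_cra(test_inputs, "uk_2017", draws = 80, seed = 3)
  expect_error(compare_scenarios(list(fits$au, other_seed)), "seed")
})

test_that("company attribution matches independent single-company reruns", {
  inputs <- generate_inputs(small_config(seed = 12))
  rk <- company_ranking(inputs, "au_hfp")
  total <- attr(rk, "total_averted")
  for (i in 1:3) {
    co <- rk$company_id[i]
    refit <- sodium_cra(inputs, "au_hfp", company = co, draws = 0)
    expect_equal(rk$averted_deaths[i],
                 unname(refit$point$vector[["deaths.total"]]),
                 tolerance = 1e-9, info = co)
    expect_equal(rk$share_pct[i], 100 * rk$averted_deaths[i] / total)
  }
  expect_true(all(diff(rk$averted_deaths) <= 1e-9))  # sorted descending
  # single-company supply holds 100% of the attributable impact
  mono <- inputs
  mono$products$company_id <- "co01"
  mono$products$company_type <- "retailer"
  rk1 <- company_ranking(mono, "au_hfp")
  expect_equal(rk1$share_pct[1], 100, tolerance = 1e-9)
})

test_that("category shares normalise to 100% of the covered total", {
  inputs <- generate_inputs(small_config(seed = 14))
  ca <- category_attribution(inputs, "au_hfp")
  expect_equal(sum(ca$share_pct), 100, tolerance = 1e-9)
  expect_true(all(ca$averted_deaths >= 0))
  expect_setequal(ca$category_id, inputs$targets$au_hfp$category_id)
})

test_that("sensitivity suite reruns the documented four variants", {
  ss <- sensitivity_suite(test_inputs, "au_hfp", draws = 40, seed = 6)
  expect_setequal(ss$analysis, c("primary", "tmrel_low", "tmrel_high",
                                 "intake_minus10", "share_75"))
  expect_equal(ss$proportion_of_primary[ss$analysis == "primary"], 1)
  fits <- attr(ss, "fits")
  # the 75% share run scales all pre-reform intakes by 75/85
  expect_equal(fits$share_75$pre$mean_mg_d,
               fits$primary$pre$mean_mg_d * 75 / 85, tolerance = 1e-9)
  expect_equal(fits$intake_minus10$pre$mean_mg_d,
               fits$primary$pre$mean_mg_d * 0.9, tolerance = 1e-9)
})

test_that("print, summary, coef and plot methods run cleanly", {
  f <- sodium_cra(test_inputs, "au_hfp", draws = 30, seed = 1)
  expect_output(print(f), "comparative risk assessment")
  expect_output(print(summary(f)), "averted events per year")
  co <- coef(f)
  expect_true("deaths.total" %in% names(co))
  pdf(NULL)
  on.exit(dev.off())
  vals <- plot(f)
  expect_equal(rownames(vals), paste0("deaths.",
                                      c("cvd", "ckd", "stomach_cancer",
                                        "total")))
})
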