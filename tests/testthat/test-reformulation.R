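mini_supply <- function() {
  products <- data.frame(
    product_id = c("p1", "p2", "p3"),
    company_id = c("coA", "coA", "coB"),
    company_type = c("retailer", "retailer", "manufacturer"),
    category_id = c("bread", "bread", "cheese"),
    sodium_mg_100g = c(400, 800, 600),
    stringsAsFactors = FALSE)
  sales <- data.frame(product_id = c("p1", "p2", "p3"),
                      kg_year = c(3, 1, 2), stringsAsFactors = FALSE)
  list(products = products, sales = sales)
}

test_that("sales-weighted mean is the kg-weighted density average", {
  ms <- mini_supply()
  expect_equal(sales_weighted_mean(ms$products, ms$sales, "bread"), 500)
  # equal sales -> simple mean; single product -> its density
  eq <- ms$sales
  eq$kg_year <- 1
  expect_equal(sales_weighted_mean(ms$products, eq, "bread"), 600)
  expect_equal(sales_weighted_mean(ms$products, ms$sales, "cheese"), 600)
  expect_error(sales_weighted_mean(ms$products, ms$sales, "nope"),
               "no positive sales")
})

test_that("applying targets clamps only covered products above the target", {
  ms <- mini_supply()
  targets <- data.frame(category_id = "bread", max_mg_100g = 500)
  post <- apply_targets(ms$products, targets)
  expect_equal(post$sodium_mg_100g, c(400, 500, 600))
  expect_equal(compliance_stats(post, ms$sales, targets)$product_compliance, 1)
  # company scope leaves the other company's products untouched
  post_b <- apply_targets(ms$products, targets, company = "coB")
  expect_equal(post_b$sodium_mg_100g, ms$products$sodium_mg_100g)
})

test_that("proportional reduction follows 1 - post/pre", {
  expect_equal(proportional_reduction(500, 425), 0.15)
  expect_equal(proportional_reduction(500, 500), 0)
  expect_error(proportional_reduction(0, 0), "must be > 0")
  # random supplies: effects equal a brute-force recomputation from raw rows
  for (seed in 1:5) {
    inputs <- generate_inputs(small_config(seed = seed))
    tg <- inputs$targets$au_hfp
    eff <- reformulation_effects(inputs$products, inputs$sales, tg)
    gt <- ground_truth(inputs$products, inputs$sales, tg)
    expect_equal(eff$reduction, gt$reduction$reduction, tolerance = 1e-12)
  }
})

test_that("sales-weighted percentile targets use the left-continuous rule", {
  products <- data.frame(product_id = paste0("p", 1:4),
                         company_id = "c", company_type = "manufacturer",
                         category_id = "snacks",
                         sodium_mg_100g = c(300, 100, 400, 200),
                         stringsAsFactors = FALSE)
  sales <- data.frame(product_id = paste0("p", 1:4), kg_year = 1)
  t25 <- derive_percentile_targets(products, sales, q = 0.25)
  expect_equal(t25$max_mg_100g, 100)
  # brute-force weighted-quantile oracle on a random supply
  set.seed(31)
  products2 <- products[sample(4, 40, TRUE), ]
  products2$product_id <- paste0("q", 1:40)
  products2$sodium_mg_100g <- runif(40, 50, 900)
  sales2 <- data.frame(product_id = products2$product_id,
                       kg_year = runif(40, 1, 10))
  for (q in c(0.1, 0.25, 0.5, 0.9)) {
    got <- derive_percentile_targets(products2, sales2, q = q)$max_mg_100g
    d <- sort(products2$sodium_mg_100g)
    w <- sales2$kg_year[match(products2$product_id[
      order(products2$sodium_mg_100g)], sales2$product_id)]
    want <- d[min(which(cumsum(w) / sum(w) >= q))]
    expect_equal(got, want, info = paste("q =", q))
  }
  # degenerate: all densities equal -> that value
  products$sodium_mg_100g <- 350
  expect_equal(derive_percentile_targets(products, sales, 0.25)$max_mg_100g,
               350)
  # scale invariance of weights
  sales3 <- sales2
  sales3$kg_year <- 2 * sales3$kg_year
  expect_equal(derive_percentile_targets(products2, sales2, 0.25),
               derive_percentile_targets(products2, sales3, 0.25))
  expect_error(derive_percentile_targets(products, sales, 1.5), "in \\(0, 1\\)")
})

test_that("percentile targets guarantee at least q of sales compliant", {
  inputs <- generate_inputs(small_config(seed = 13))
  tg <- derive_percentile_targets(inputs$products, inputs$sales, q = 0.25)
  cs <- compliance_stats(inputs$products, inputs$sales, tg)
  expect_true(all(cs$sales_compliance >= 0.25))
  expect_true(all(cs$product_compliance >= 0 & cs$product_compliance <= 1))
  # brute-force count agreement
  for (i in 1:3) {
    sel <- inputs$products$category_id == cs$category_id[i]
    ok <- inputs$products$sodium_mg_100g[sel] <= tg$max_mg_100g[i]
    expect_equal(cs$product_compliance[i], mean(ok))
  }
})

test_that("intake change is the reduction-weighted category sum", {
  intakes <- data.frame(stratum_id = "s1", category_id = c("bread", "other"),
                        mean_mg_d = c(1000, 500), se_mg_d = c(50, 20),
                        stringsAsFactors = FALSE)
  eff <- data.frame(category_id = "bread", reduction = 0.1)
  d <- scenario_intake_change(intakes, eff)
  expect_equal(d$delta_mg_d, 100)
  expect_equal(d$delta_se_mg_d, 5)
  # null scenario -> zero everywhere
  d0 <- scenario_intake_change(intakes, eff[0, ])
  expect_equal(d0$delta_mg_d, 0)
  # unknown category -> error
  expect_error(scenario_intake_change(
    intakes, data.frame(category_id = "soup", reduction = 0.1)), "soup")
})

test_that("stricter targets and broader coverage never reduce the effect", {
  inputs <- generate_inputs(small_config(seed = 21))
  intakes <- category_intake(inputs$recalls, inputs$composition,
                             inputs$mapping, inputs$persons)
  tg <- inputs$targets$au_hfp
  eff <- reformulation_effects(inputs$products, inputs$sales, tg)
  d <- scenario_intake_change(intakes, eff)
  # element-wise stricter targets
  tg_strict <- tg
  tg_strict$max_mg_100g <- tg$max_mg_100g * 0.8
  eff_s <- reformulation_effects(inputs$products, inputs$sales, tg_strict)
  d_s <- scenario_intake_change(intakes, eff_s)
  expect_true(all(eff_s$reduction >= eff$reduction - 1e-12))
  expect_true(all(d_s$delta_mg_d >= d$delta_mg_d - 1e-12))
  # broader coverage (UK superset at the same levels for shared categories)
  tg_broad <- rbind(tg, data.frame(category_id = "cat08", max_mg_100g = 1))
  eff_b <- reformulation_effects(inputs$products, inputs$sales, tg_broad)
  d_b <- scenario_intake_change(intakes, eff_b)
  expect_true(all(d_b$delta_mg_d >= d$delta_mg_d - 1e-12))
})

test_that("per-company intake reductions are dominated by and sum to the total", {
  inputs <- generate_inputs(small_config(seed = 8))
  intakes <- category_intake(inputs$recalls, inputs$composition,
                             inputs$mapping, inputs$persons)
  tg <- inputs$targets$au_hfp
  d_all <- scenario_intake_change(
    intakes, reformulation_effects(inputs$products, inputs$sales, tg))
  companies <- unique(inputs$products$company_id)
  d_sum <- 0
  for (co in companies) {
    d_co <- scenario_intake_change(
      intakes, reformulation_effects(inputs$products, inputs$sales, tg,
                                     company = co))
    expect_true(all(d_co$delta_mg_d <= d_all$delta_mg_d + 1e-9), info = co)
    d_sum <- d_sum + d_co$delta_mg_d
  }
  # company-level clamp excesses partition the total excess, so the
  # single-company reductions sum exactly to the all-company reduction
  expect_equal(d_sum, d_all$delta_mg_d, tolerance = 1e-9)
  # same exactness on a hand-built supply with disjoint company-category sales
  products <- data.frame(product_id = c("p1", "p2", "p3", "p4"),
                         company_id = c("coA", "coA", "coB", "coB"),
                         company_type = "manufacturer",
                         category_id = c("bread", "bread", "cheese", "cheese"),
                         sodium_mg_100g = c(700, 300, 900, 500),
                         stringsAsFactors = FALSE)
  sales <- data.frame(product_id = products$product_id, kg_year = 1)
  intakes2 <- data.frame(stratum_id = "s1",
                         category_id = c("bread", "cheese"),
                         mean_mg_d = c(600, 400), se_mg_d = 0,
                         stringsAsFactors = FALSE)
  tg2 <- data.frame(category_id = c("bread", "cheese"),
                    max_mg_100g = c(400, 600))
  dj_all <- scenario_intake_change(
    intakes2, reformulation_effects(products, sales, tg2))
  dj_sum <- sapply(c("coA", "coB"), function(co) {
    scenario_intake_change(
      intakes2, reformulation_effects(products, sales, tg2,
                                      company = co))$delta_mg_d
  })
  expect_equal(sum(dj_sum), dj_all$delta_mg_d, tolerance = 1e-12)
})
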