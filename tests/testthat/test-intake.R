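test_that("category intake reproduces definitional arithmetic", {
  tw <- tiny_survey()
  # one person, one food: 200 g/d of a 500 mg/100 g item -> 1,000 mg/d
  one <- category_intake(tw$recalls[1, ], tw$composition, tw$mapping)
  got <- one[one$stratum_id == "men_25-29" & one$category_id == "bread", ]
  expect_equal(got$mean_mg_d, 1000)
  expect_equal(got$se_mg_d, 0)  # single person, no variance
  # zero-food persons pull the weighted mean down
  with_p3 <- category_intake(tw$recalls, tw$composition, tw$mapping,
                             persons = tw$persons)
  men_bread <- with_p3[with_p3$stratum_id == "men_25-29" &
                         with_p3$category_id == "bread", ]
  expect_equal(men_bread$mean_mg_d, (1 * 1000 + 3 * 0) / 4)
})

test_that("identical persons give zero standard error", {
  rec <- data.frame(person_id = c("a", "b", "c"),
                    stratum_id = "men_25-29", survey_weight = c(1, 2, 5),
                    food_id = "fA", grams_day = 100,
                    stringsAsFactors = FALSE)
  comp <- data.frame(food_id = "fA", sodium_mg_100g = 400)
  map <- data.frame(food_id = "fA", category_id = "bread")
  out <- category_intake(rec, comp, map)
  expect_equal(out$mean_mg_d, 400)
  expect_equal(out$se_mg_d, 0)
})

test_that("unmapped foods are a hard error listing offenders", {
  tw <- tiny_survey()
  bad <- tw$recalls
  bad$food_id[1] <- "mystery"
  expect_error(category_intake(bad, tw$composition, tw$mapping), "mystery")
})

test_that("stratum x category means match a brute-force weighted oracle", {
  inputs <- generate_inputs(small_config(seed = 4, n_persons = 60))
  got <- category_intake(inputs$recalls, inputs$composition, inputs$mapping,
                         inputs$persons)
  want <- brute_force_intake(inputs$recalls, inputs$composition,
                             inputs$mapping, inputs$persons)
  key <- paste(got$stratum_id, got$category_id)
  expect_equal(got$mean_mg_d[match(paste(want$stratum_id, want$category_id),
                                   key)],
               want$mean_mg_d, tolerance = 1e-10)
})

test_that("survey-weight invariance: duplicating persons at half weight", {
  inputs <- generate_inputs(small_config(seed = 6, n_persons = 50))
  base <- category_intake(inputs$recalls, inputs$composition, inputs$mapping,
                          inputs$persons)
  dup_p <- inputs$persons
  dup_p$survey_weight <- dup_p$survey_weight / 2
  dup_p2 <- dup_p
  dup_p2$person_id <- paste0(dup_p2$person_id, "_b")
  dup_r <- inputs$recalls
  dup_r$survey_weight <- dup_r$survey_weight / 2
  dup_r2 <- dup_r
  dup_r2$person_id <- paste0(dup_r2$person_id, "_b")
  doubled <- category_intake(rbind(dup_r, dup_r2), inputs$composition,
                             inputs$mapping, rbind(dup_p, dup_p2))
  expect_equal(doubled$mean_mg_d, base$mean_mg_d, tolerance = 1e-12)
})

test_that("underreporting adjustment rescales uniformly to the urinary anchor", {
  tw <- tiny_survey()
  intakes <- category_intake(tw$recalls, tw$composition, tw$mapping)
  # direct arithmetic: recall total 2,000, urinary 3,200, share 0.85 -> 1.36
  one_sex <- data.frame(stratum_id = "men_25-29", category_id = c("a", "b"),
                        mean_mg_d = c(1500, 500), se_mg_d = c(10, 5),
                        stringsAsFactors = FALSE)
  adj <- adjust_underreporting(one_sex, tw$strata[1, ],
                               c(men = 3200), share = 0.85)
  expect_equal(attr(adj, "factors")[["men"]], 1.36)
  expect_equal(adj$mean_mg_d, c(1500, 500) * 1.36)
  expect_equal(adj$se_mg_d, c(10, 5) * 1.36)
  # identity: recall total already at share * urinary -> factor 1
  adj1 <- adjust_underreporting(one_sex, tw$strata[1, ],
                                c(men = 2000 / 0.85), share = 0.85)
  expect_equal(attr(adj1, "factors")[["men"]], 1)
  expect_equal(adj1$mean_mg_d, one_sex$mean_mg_d)
  # lowering the share 0.85 -> 0.75 scales everything by 75/85
  adj75 <- adjust_underreporting(one_sex, tw$strata[1, ],
                                 c(men = 3200), share = 0.75)
  expect_equal(adj75$mean_mg_d, adj$mean_mg_d * 75 / 85)
})

test_that("post-adjustment sex totals equal share x urinary and shares persist", {
  inputs <- test_inputs
  intakes <- category_intake(inputs$recalls, inputs$composition,
                             inputs$mapping, inputs$persons)
  adj <- adjust_underreporting(intakes, inputs$strata, inputs$urinary,
                               share = 0.85)
  tot <- total_intake(adj, inputs$strata)
  for (s in c("men", "women")) {
    ids <- inputs$strata$stratum_id[inputs$strata$sex == s]
    pw <- inputs$strata$pop_weight[match(ids, inputs$strata$stratum_id)]
    sex_mean <- weighted.mean(tot$mean_mg_d[match(ids, tot$stratum_id)], pw)
    expect_equal(sex_mean, 0.85 * inputs$urinary[[s]], tolerance = 1e-9)
  }
  # uniform scaling preserves each category's share of the stratum total
  s1 <- intakes$stratum_id == intakes$stratum_id[1]
  expect_equal(adj$mean_mg_d[s1] / sum(adj$mean_mg_d[s1]),
               intakes$mean_mg_d[s1] / sum(intakes$mean_mg_d[s1]),
               tolerance = 1e-12)
})

test_that("total intake sums categories and combines SEs independently", {
  intakes <- data.frame(stratum_id = "s1", category_id = c("a", "b", "c"),
                        mean_mg_d = c(800, 1200, 900),
                        se_mg_d = c(30, 40, 0), stringsAsFactors = FALSE)
  strata <- data.frame(stratum_id = "s1", pop_weight = 10)
  tot <- total_intake(intakes, strata)
  expect_equal(tot$mean_mg_d, 2900)
  expect_equal(tot$se_mg_d, sqrt(30^2 + 40^2))
  expect_equal(attr(tot, "population_mean"), 2900)
})
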