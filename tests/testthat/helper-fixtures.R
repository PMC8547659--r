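# Shared fixtures, built in code.  `test_inputs` is a mid-sized bundle
# reused across files; `small_config()` builds quick supplies for
# property loops.

small_config <- function(seed = 1, n_persons = 150, ...) {
  synth_config(seed = seed, n_persons = n_persons,
               n_products_per_category = 8,
               n_companies = 10, n_retailers = 2, n_categories_au = 4,
               n_categories_uk = 8, n_foods_per_category = 2, ...)
}

test_inputs <- generate_inputs(synth_config(seed = 42, n_persons = 300))

# A tiny hand-built survey: 2 strata, 3 persons, 2 foods.
tiny_survey <- function() {
  strata <- data.frame(
    stratum_id = c("men_25-29", "women_25-29"),
    sex = c("men", "women"),
    age_band = "25-29", age_lo = 25, age_mid = 27.5,
    sbp_mean = 120, hyp_prev = 0.1, hyp_prev_se = 0.02,
    pop_weight = c(1000, 1000),
    stringsAsFactors = FALSE)
  composition <- data.frame(food_id = c("fA", "fB"),
                            sodium_mg_100g = c(500, 250),
                            stringsAsFactors = FALSE)
  mapping <- data.frame(food_id = c("fA", "fB"),
                        category_id = c("bread", "other"),
                        stringsAsFactors = FALSE)
  recalls <- data.frame(
    person_id = c("p1", "p2", "p2"),
    stratum_id = c("men_25-29", "women_25-29", "women_25-29"),
    survey_weight = c(1, 2, 2),
    food_id = c("fA", "fA", "fB"),
    grams_day = c(200, 100, 400),
    stringsAsFactors = FALSE)
  persons <- data.frame(
    person_id = c("p1", "p2", "p3"),
    stratum_id = c("men_25-29", "women_25-29", "men_25-29"),
    survey_weight = c(1, 2, 3),
    stringsAsFactors = FALSE)
  list(strata = strata, composition = composition, mapping = mapping,
       recalls = recalls, persons = persons)
}

# Brute-force survey-weighted stratum x category means over persons,
# independent of the matrix path in category_intake().
brute_force_intake <- function(recalls, composition, mapping, persons) {
  categories <- sort(unique(mapping$category_id))
  out <- list()
  for (s in sort(unique(persons$stratum_id))) {
    pp <- persons[persons$stratum_id == s, ]
    for (cc in categories) {
      y <- numeric(nrow(pp))
      for (j in seq_len(nrow(pp))) {
        rows <- recalls[recalls$person_id == pp$person_id[j], ]
        tot <- 0
        for (k in seq_len(nrow(rows))) {
          if (mapping$category_id[mapping$food_id == rows$food_id[k]] == cc) {
            dens <- composition$sodium_mg_100g[
              composition$food_id == rows$food_id[k]]
            tot <- tot + rows$grams_day[k] * dens / 100
          }
        }
        y[j] <- tot
      }
      m <- sum(pp$survey_weight * y) / sum(pp$survey_weight)
      out[[paste(s, cc)]] <- data.frame(stratum_id = s, category_id = cc,
                                        mean_mg_d = m,
                                        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
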