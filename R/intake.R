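# Stage 1: pre-reformulation sodium intake per food category per stratum,
# estimated from 24-hour diet recalls and rescaled for underreporting
# against urinary-excretion-based intake.

#' Survey-weighted sodium intake by food category and stratum
#'
#' Converts person x food recall rows into mean daily sodium intake (mg/d)
#' per food category per age-sex stratum.  Each recall row contributes
#' `grams_day * sodium_mg_100g / 100` mg/d of sodium to its food's
#' category.  Persons with no recall rows (zero foods) contribute zero
#' intake in every category.  Means are survey-weighted; standard errors
#' use the ratio-estimator variance of the weighted mean.
#'
#' @param recalls data.frame with `person_id`, `stratum_id`,
#'   `survey_weight`, `food_id`, `grams_day`.
#' @param composition data.frame with `food_id`, `sodium_mg_100g`.
#' @param mapping data.frame with `food_id`, `category_id`; every recall
#'   food must be mapped (unmapped foods are a hard error listing the
#'   offenders).
#' @param persons optional roster (`person_id`, `stratum_id`,
#'   `survey_weight`) including zero-food persons; defaults to the persons
#'   present in `recalls`.
#' @return data.frame with `stratum_id`, `category_id`, `mean_mg_d`,
#'   `se_mg_d`, one row per stratum x category (all mapped categories,
#'   zero-filled where nobody consumed the category).
#' @export
category_intake <- function(recalls, composition, mapping, persons = NULL) {
  check_cols(recalls, c("person_id", "stratum_id", "survey_weight",
                        "food_id", "grams_day"), "recalls")
  check_cols(composition, c("food_id", "sodium_mg_100g"), "composition")
  check_cols(mapping, c("food_id", "category_id"), "mapping")
  bad <- setdiff(unique(recalls$food_id),
                 intersect(mapping$food_id, composition$food_id))
  if (length(bad)) {
    stop("unmapped food ids in recalls: ", paste(sort(bad), collapse = ", "))
  }
  if (is.null(persons)) {
    persons <- unique(recalls[, c("person_id", "stratum_id", "survey_weight")])
  }
  check_cols(persons, c("person_id", "stratum_id", "survey_weight"), "persons")
  if (anyDuplicated(persons$person_id)) {
    stop("duplicated person_id in 'persons'")
  }
  categories <- sort(unique(mapping$category_id))
  mg <- recalls$grams_day *
    composition$sodium_mg_100g[match(recalls$food_id, composition$food_id)] / 100
  cat_of <- mapping$category_id[match(recalls$food_id, mapping$food_id)]
  # person x category sodium matrix, zero-filled
  Y <- matrix(0, nrow(persons), length(categories),
              dimnames = list(persons$person_id, categories))
  agg <- stats::aggregate(mg,
                          by = list(person_id = recalls$person_id,
                                    category_id = cat_of),
                          FUN = sum)
  Y[cbind(match(agg$person_id, persons$person_id),
          match(agg$category_id, categories))] <- agg$x
  strata_ids <- sort(unique(persons$stratum_id))
  out <- vector("list", length(strata_ids))
  for (si in seq_along(strata_ids)) {
    rows <- persons$stratum_id == strata_ids[si]
    w <- persons$survey_weight[rows]
    if (sum(w) <= 0) {
      stop("zero total survey weight in stratum ", strata_ids[si])
    }
    ms <- apply(Y[rows, , drop = FALSE], 2, weighted_mean_se, w = w)
    out[[si]] <- data.frame(stratum_id = strata_ids[si],
                            category_id = categories,
                            mean_mg_d = ms["mean", ],
                            se_mg_d = ms["se", ],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rescale recall-based intakes to urinary-excretion-based intake
#'
#' 24-hour diet recalls underestimate sodium.  For each sex `s` the recall
#' totals are rescaled by a single factor
#' `f_s = share * urinary_s / recall_total_s`, where `recall_total_s` is
#' the population-weighted mean of the stratum intake totals for that sex
#' and `share` is the nondiscretionary fraction of urinary-excretion-based
#' intake (0.85 in the primary model: the remaining 15% is discretionary
#' salt added in cooking or at the table).  The factor is applied uniformly
#' across categories, so each category's share of total intake within a
#' sex is preserved, and the post-adjustment sex totals equal
#' `share * urinary_s` exactly.
#'
#' @param intakes category-intake table from [category_intake()].
#' @param strata stratum table (for `sex` and `pop_weight`).
#' @param urinary named vector of mean 24-hour urinary sodium excretion
#'   (mg/d) per sex.
#' @param share nondiscretionary share of urinary-based intake, in (0, 1].
#' @return the intake table with `mean_mg_d` and `se_mg_d` rescaled; the
#'   per-sex factors are attached as attribute `factors`.
#' @export
adjust_underreporting <- function(intakes, strata, urinary, share = 0.85) {
  check_cols(intakes, c("stratum_id", "category_id", "mean_mg_d", "se_mg_d"),
             "intakes")
  check_cols(strata, c("stratum_id", "sex", "pop_weight"), "strata")
  if (!(share > 0 && share <= 1)) stop("'share' must be in (0, 1]")
  sex_of <- strata$sex[match(intakes$stratum_id, strata$stratum_id)]
  if (anyNA(sex_of)) stop("intake strata missing from 'strata' table")
  totals <- tapply(intakes$mean_mg_d, intakes$stratum_id, sum)
  factors <- c()
  for (s in unique(strata$sex)) {
    if (!s %in% names(urinary)) stop("no urinary mean supplied for sex ", s)
    ids <- strata$stratum_id[strata$sex == s]
    ids <- ids[ids %in% names(totals)]
    rt <- stats::weighted.mean(totals[ids],
                               strata$pop_weight[match(ids, strata$stratum_id)])
    if (!isTRUE(rt > 0)) {
      stop("recall-based total is zero for sex ", s,
           "; cannot compute adjustment factor")
    }
    factors[s] <- share * urinary[[s]] / rt
  }
  f <- factors[sex_of]
  out <- intakes
  out$mean_mg_d <- intakes$mean_mg_d * f
  out$se_mg_d <- intakes$se_mg_d * f
  attr(out, "factors") <- factors
  out
}

#' Total sodium intake per stratum
#'
#' Sums the category intakes (including the untargeted remainder) into a
#' per-stratum total, combining standard errors under the documented
#' assumption of independence across categories.  The population-weighted
#' grand mean across strata is attached as attribute `population_mean`.
#'
#' @param intakes category-intake table.
#' @param strata stratum table (for `pop_weight`).
#' @return data.frame with `stratum_id`, `mean_mg_d`, `se_mg_d`.
#' @export
total_intake <- function(intakes, strata) {
  check_cols(intakes, c("stratum_id", "category_id", "mean_mg_d", "se_mg_d"),
             "intakes")
  m <- tapply(intakes$mean_mg_d, intakes$stratum_id, sum)
  v <- tapply(intakes$se_mg_d^2, intakes$stratum_id, sum)
  out <- data.frame(stratum_id = names(m),
                    mean_mg_d = as.numeric(m),
                    se_mg_d = sqrt(as.numeric(v)),
                    stringsAsFactors = FALSE)
  pw <- strata$pop_weight[match(out$stratum_id, strata$stratum_id)]
  attr(out, "population_mean") <- stats::weighted.mean(out$mean_mg_d, pw)
  out
}
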