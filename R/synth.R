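# Synthetic data generator.  Every input table the pipeline consumes
# (strata, branded products, annual sales, diet recalls, food composition,
# disease burden, relative risks, reformulation targets) can be generated
# with known ground truth, so all downstream stages are testable without
# any proprietary download.

#' Configuration for the synthetic input generator
#'
#' Collects every tunable of the generator in one validated list.  Defaults
#' emulate the Australian setting the model was designed for: 24 age-sex
#' strata (adults 25+ in 5-year bands, both sexes), right-skewed (lognormal)
#' food intakes and within-category sodium densities, a concentrated
#' food-company market with a few dominant retailers, nondiscretionary
#' sodium intake anchored to sex-specific 24-hour urinary excretion, and
#' disease-burden magnitudes on the order of the Australian 2017 totals
#' for cardiovascular disease (CVD), chronic kidney disease (CKD) and
#' stomach cancer.
#'
#' Food categories are generic (`cat01`, `cat02`, ...).  The first
#' `n_categories_au` categories are covered by the Australian-style target
#' set; all `n_categories_uk` are covered by the broader UK-style set, so
#' the two scenario scopes differ as they do for the real programs (27 vs
#' 76 food groups; the synthetic counts are scaled down and configurable).
#' An extra `other` category holds foods outside any reformulation program
#' (restaurant, takeaway and scratch-cooked foods).
#'
#' @param seed integer seed; a fixed seed makes every generated table
#'   byte-identical across runs.
#' @param n_persons number of survey respondents.
#' @param n_products_per_category branded products per food category.
#' @param n_companies number of food companies.
#' @param n_retailers how many of the largest companies are supermarket
#'   retailers (selling private-label products); the rest are manufacturers.
#' @param company_concentration Zipf-like exponent for company market
#'   shares; larger values concentrate sales in fewer companies.
#' @param n_categories_au,n_categories_uk number of food categories covered
#'   by the Australian-style and UK-style target sets
#'   (`n_categories_au <= n_categories_uk`).
#' @param n_foods_per_category generic recall foods per category.
#' @param category_sodium_log_mean per-category mean of log sodium density
#'   (log mg/100 g); default evenly spaced between log(150) and log(1000).
#' @param category_sodium_log_sd lognormal sigma of sodium density within a
#'   category; the default 0.5 gives the wide within-category spreads seen
#'   in branded-food databases, so some products exceed and some undercut
#'   any mid-distribution target.
#' @param other_sodium_log_mean log mean sodium density of untargeted foods.
#' @param intake_log_mean,intake_log_sd lognormal parameters of the g/d
#'   amount of each consumed food.
#' @param mean_foods_per_person Poisson mean of foods per respondent (zero
#'   foods is allowed and contributes zero intake).
#' @param urinary_sodium_mean named vector (`men`, `women`) of mean 24-hour
#'   urinary sodium excretion, mg/d.
#' @param burden_scale multiplies every disease event count (events/yr).
#' @param age_breaks lower bounds of the age bands; the last band is
#'   open-ended.  The default gives 12 bands (25-29 ... 75-79, 80+), hence
#'   24 age-sex strata.
#' @param au_quantile,uk_quantile,optimistic_quantile sales-weighted
#'   density quantiles at which the three synthetic target sets are placed.
#'   Lower quantiles mean stricter targets; the defaults order the
#'   scenarios Australian (lenient, narrow) < UK (stricter, broad) <
#'   optimistic (25th percentile, broad).
#' @param sbp_effect list of coefficients of the systolic blood pressure
#'   (SBP) response to sodium reduction: `main` (mm Hg per 100 mmol/d at
#'   the reference age in normotensives), `age_int` (additional mm Hg per
#'   year of age offset from `ref_age`), `hyp_int` (additional mm Hg in
#'   hypertensives), their standard errors, and `ref_age`.  Defaults follow
#'   published meta-regression of sodium reduction trials.
#' @param rr_base named vector of relative risks per 10 mm Hg SBP at age 55
#'   for the blood-pressure-mediated causes; `rr_stomach_per_g` relative
#'   risk of stomach cancer per 1 g/d sodium.
#' @param rr_stomach_per_g see `rr_base`.
#'
#' @return object of class `synth_config` (a validated list).
#' @seealso [generate_inputs()]
#' @export
synth_config <- function(seed = 1L,
                         n_persons = 500L,
                         n_products_per_category = 12L,
                         n_companies = 30L,
                         n_retailers = 3L,
                         company_concentration = 1.15,
                         n_categories_au = 8L,
                         n_categories_uk = 16L,
                         n_foods_per_category = 3L,
                         category_sodium_log_mean = NULL,
                         category_sodium_log_sd = 0.5,
                         other_sodium_log_mean = log(250),
                         intake_log_mean = log(80),
                         intake_log_sd = 0.7,
                         mean_foods_per_person = 8,
                         urinary_sodium_mean = c(men = 3900, women = 2900),
                         burden_scale = 1,
                         age_breaks = seq(25L, 80L, by = 5L),
                         au_quantile = 0.60,
                         uk_quantile = 0.40,
                         optimistic_quantile = 0.25,
                         sbp_effect = list(main = 3.74, main_se = 0.35,
                                           age_int = 0.105, age_int_se = 0.03,
                                           hyp_int = 2.49, hyp_int_se = 0.60,
                                           ref_age = 50),
                         rr_base = c(ihd = 1.25, ischemic_stroke = 1.30,
                                     hemorrhagic_stroke = 1.35,
                                     aortic_aneurysm = 1.15,
                                     endocarditis = 1.10,
                                     hypertensive_hd = 1.40,
                                     rheumatic_hd = 1.10,
                                     other_cvd = 1.15, ckd = 1.20),
                         rr_stomach_per_g = 1.25) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_persons >= 1, n_products_per_category >= 2,
            n_companies >= 1, n_retailers >= 0, n_retailers <= n_companies,
            company_concentration > 0,
            n_categories_au >= 1, n_categories_au <= n_categories_uk,
            n_foods_per_category >= 1,
            category_sodium_log_sd > 0, intake_log_sd > 0,
            mean_foods_per_person > 0, burden_scale > 0,
            au_quantile > 0, au_quantile < 1,
            uk_quantile > 0, uk_quantile < 1,
            optimistic_quantile > 0, optimistic_quantile < 1,
            length(age_breaks) >= 2, all(diff(age_breaks) > 0))
  if (!all(c("men", "women") %in% names(urinary_sodium_mean))) {
    stop("'urinary_sodium_mean' needs named entries 'men' and 'women'")
  }
  if (any(urinary_sodium_mean <= 0)) stop("urinary sodium means must be > 0")
  n_uk <- as.integer(n_categories_uk)
  if (is.null(category_sodium_log_mean)) {
    category_sodium_log_mean <- seq(log(150), log(1000), length.out = n_uk)
  }
  if (length(category_sodium_log_mean) != n_uk) {
    stop("'category_sodium_log_mean' must have one value per UK-covered category")
  }
  cfg <- list(seed = as.integer(seed),
              n_persons = as.integer(n_persons),
              n_products_per_category = as.integer(n_products_per_category),
              n_companies = as.integer(n_companies),
              n_retailers = as.integer(n_retailers),
              company_concentration = company_concentration,
              n_categories_au = as.integer(n_categories_au),
              n_categories_uk = n_uk,
              n_foods_per_category = as.integer(n_foods_per_category),
              category_sodium_log_mean = category_sodium_log_mean,
              category_sodium_log_sd = category_sodium_log_sd,
              other_sodium_log_mean = other_sodium_log_mean,
              intake_log_mean = intake_log_mean,
              intake_log_sd = intake_log_sd,
              mean_foods_per_person = mean_foods_per_person,
              urinary_sodium_mean = urinary_sodium_mean,
              burden_scale = burden_scale,
              age_breaks = as.integer(age_breaks),
              au_quantile = au_quantile,
              uk_quantile = uk_quantile,
              optimistic_quantile = optimistic_quantile,
              sbp_effect = sbp_effect,
              rr_base = rr_base,
              rr_stomach_per_g = rr_stomach_per_g)
  class(cfg) <- "synth_config"
  cfg
}

synth_categories <- function(config) {
  sprintf("cat%02d", seq_len(config$n_categories_uk))
}

synth_companies <- function(config) {
  data.frame(
    company_id = sprintf("co%02d", seq_len(config$n_companies)),
    company_type = ifelse(seq_len(config$n_companies) <= config$n_retailers,
                          "retailer", "manufacturer"),
    stringsAsFactors = FALSE)
}

#' Generate the age-sex stratum table
#'
#' Produces one row per age band and sex with mean systolic blood pressure,
#' hypertension prevalence (Beta-distributed, so always in `[0, 1]`, with a
#' stratum-level standard error used by the Monte Carlo draws), and a
#' survey-population weight.  Both blood pressure and prevalence rise with
#' age, as in national health surveys.
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `stratum_id`, `sex`, `age_band`,
#'   `age_lo`, `age_mid`, `sbp_mean` (mm Hg), `hyp_prev`, `hyp_prev_se`,
#'   `pop_weight` (persons).
#' @export
generate_strata <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 101L)
  lo <- config$age_breaks
  hi <- c(lo[-1] - 1L, NA)
  band <- ifelse(is.na(hi), paste0(lo, "+"), paste(lo, hi, sep = "-"))
  mid <- ifelse(is.na(hi), lo + 5, (lo + hi + 1) / 2)
  n_band <- length(lo)
  sexes <- c("men", "women")
  df <- data.frame(
    sex = rep(sexes, each = n_band),
    age_band = rep(band, times = 2),
    age_lo = rep(lo, times = 2),
    age_mid = rep(mid, times = 2),
    stringsAsFactors = FALSE)
  df$stratum_id <- paste(df$sex, df$age_band, sep = "_")
  n <- nrow(df)
  df$sbp_mean <- 114 + 0.38 * (df$age_mid - 25) +
    ifelse(df$sex == "men", 3, 0) + stats::rnorm(n, 0, 1.5)
  mu <- stats::plogis(-2.6 + 0.065 * (df$age_mid - 25))
  conc <- 60
  df$hyp_prev <- stats::rbeta(n, mu * conc, (1 - mu) * conc)
  df$hyp_prev_se <- pmax(0.02, 0.10 * df$hyp_prev)
  df$pop_weight <- 760000 * exp(-0.024 * (df$age_mid - 27)) *
    stats::runif(n, 0.95, 1.05)
  if (any(df$pop_weight <= 0)) stop("non-positive population weight generated")
  df[, c("stratum_id", "sex", "age_band", "age_lo", "age_mid",
         "sbp_mean", "hyp_prev", "hyp_prev_se", "pop_weight")]
}

#' Generate branded products and their annual sales
#'
#' Each UK-covered category receives `n_products_per_category` products.
#' Sodium densities are lognormal within category.  Products are assigned
#' to companies with Zipf-like probabilities (`share of company j
#' proportional to j^-concentration`), so a handful of large companies --
#' the first few of which are retailers -- dominate sales, reproducing the
#' concentrated market structure of real grocery panels.
#'
#' @param config a [synth_config()].
#' @return list with `products` (columns `product_id`, `company_id`,
#'   `company_type`, `category_id`, `sodium_mg_100g`) and `sales`
#'   (`product_id`, `kg_year`).
#' @export
generate_products_and_sales <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 202L)
  cats <- synth_categories(config)
  comp <- synth_companies(config)
  w <- seq_len(config$n_companies)^(-config$company_concentration)
  p <- w / sum(w)
  n_tot <- length(cats) * config$n_products_per_category
  idx <- sample.int(config$n_companies, n_tot, replace = TRUE, prob = p)
  cat_of <- rep(cats, each = config$n_products_per_category)
  meanlog <- config$category_sodium_log_mean[match(cat_of, cats)]
  products <- data.frame(
    product_id = sprintf("p%04d", seq_len(n_tot)),
    company_id = comp$company_id[idx],
    company_type = comp$company_type[idx],
    category_id = cat_of,
    sodium_mg_100g = stats::rlnorm(n_tot, meanlog, config$category_sodium_log_sd),
    stringsAsFactors = FALSE)
  sales <- data.frame(
    product_id = products$product_id,
    kg_year = stats::rlnorm(n_tot, log(5e4), 0.8),
    stringsAsFactors = FALSE)
  tot <- tapply(sales$kg_year, products$category_id, sum)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("zero total sales generated in a category")
  }
  list(products = products, sales = sales)
}

#' Generate the generic recall foods: composition and category mapping
#'
#' Foods are the units that appear in 24-hour diet recalls.  Each food maps
#' to exactly one category; its sodium density is drawn from the same
#' lognormal distribution as the category's branded products, so the
#' recall-side composition lookup is consistent with the product-side
#' sodium distribution.  The `other` category collects foods outside any
#' reformulation program.
#'
#' @param config a [synth_config()].
#' @return list with `composition` (`food_id`, `sodium_mg_100g`) and
#'   `mapping` (`food_id`, `category_id`).
#' @export
generate_foods <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 303L)
  cats <- c(synth_categories(config), "other")
  meanlog <- c(config$category_sodium_log_mean, config$other_sodium_log_mean)
  cat_of <- rep(cats, each = config$n_foods_per_category)
  ml <- rep(meanlog, each = config$n_foods_per_category)
  n <- length(cat_of)
  food_id <- sprintf("f%03d", seq_len(n))
  list(
    composition = data.frame(
      food_id = food_id,
      sodium_mg_100g = stats::rlnorm(n, ml, config$category_sodium_log_sd),
      stringsAsFactors = FALSE),
    mapping = data.frame(
      food_id = food_id,
      category_id = cat_of,
      stringsAsFactors = FALSE))
}

#' Generate a synthetic 24-hour diet recall survey
#'
#' One row per person x consumed food, with g/d amounts (lognormal) and a
#' survey weight.  Every stratum receives at least one respondent; the
#' remainder are allocated proportionally to population weight.  A person
#' may consume zero foods, in which case they appear in the `persons`
#' attribute (and contribute zero intake) but have no recall rows.
#'
#' @param config a [synth_config()].
#' @param composition,mapping tables from [generate_foods()].
#' @param strata table from [generate_strata()].
#' @return data.frame with columns `person_id`, `stratum_id`,
#'   `survey_weight`, `food_id`, `grams_day`; the full person roster
#'   (including zero-food persons) is attached as attribute `persons`.
#' @export
generate_recalls <- function(config, composition, mapping, strata) {
  stopifnot(inherits(config, "synth_config"))
  check_cols(composition, c("food_id", "sodium_mg_100g"), "composition")
  check_cols(strata, c("stratum_id", "pop_weight"), "strata")
  set.seed(config$seed + 404L)
  n <- config$n_persons
  ns <- nrow(strata)
  if (n < ns) stop("n_persons must be at least the number of strata")
  stratum <- c(strata$stratum_id,
               sample(strata$stratum_id, n - ns, replace = TRUE,
                      prob = strata$pop_weight))
  persons <- data.frame(
    person_id = sprintf("i%04d", seq_len(n)),
    stratum_id = stratum,
    survey_weight = stats::rlnorm(n, 0, 0.3),
    stringsAsFactors = FALSE)
  n_foods <- pmin(stats::rpois(n, config$mean_foods_per_person),
                  nrow(composition))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_foods[i]
    if (k == 0) next
    rows[[i]] <- data.frame(
      person_id = persons$person_id[i],
      stratum_id = persons$stratum_id[i],
      survey_weight = persons$survey_weight[i],
      food_id = sample(composition$food_id, k),
      grams_day = stats::rlnorm(k, config$intake_log_mean, config$intake_log_sd),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "persons") <- persons
  out
}

# Central cause list with the magnitudes (events/yr at burden_scale = 1)
# the generator emulates.  Inflammatory heart diseases (endocarditis,
# rheumatic heart disease) develop independently of blood pressure, so they
# count toward mortality but are excluded from incidence and DALY totals.
synth_causes <- function() {
  data.frame(
    cause_id = c("ihd", "ischemic_stroke", "hemorrhagic_stroke",
                 "aortic_aneurysm", "endocarditis", "hypertensive_hd",
                 "rheumatic_hd", "other_cvd", "ckd", "stomach_cancer"),
    group = c(rep("cvd", 8), "ckd", "stomach_cancer"),
    pathway = c(rep("bp_mediated", 9), "direct"),
    include_in_mortality = TRUE,
    include_in_morbidity = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                             TRUE, TRUE, TRUE),
    deaths_total = c(27000, 6500, 3500, 1300, 600, 4000, 300, 7200,
                     4400, 1900),
    inc_mult = c(2.3, 2.5, 2.5, 3, 3, 3, 3, 3, 19, 1.9),
    daly_mult = c(13, 13, 13, 13, 13, 13, 13, 13, 16, 17),
    stringsAsFactors = FALSE)
}

#' Generate the disease burden table
#'
#' Deaths, incident cases and DALYs per cause and stratum with 95%
#' uncertainty intervals (multiplicative, lognormal).  Causes comprise 8
#' CVD subtypes, CKD and stomach cancer.  Event counts are skewed toward
#' older ages and men.  The inflammatory heart diseases carry
#' `include_in_morbidity = FALSE` (mortality-only), every cause carries
#' `include_in_mortality = TRUE`.
#'
#' @param config a [synth_config()].
#' @param strata table from [generate_strata()].
#' @return list with `events` (columns `cause_id`, `stratum_id`, `metric`
#'   in deaths/incidence/dalys, `events`, `lo`, `hi`) and `causes`
#'   (`cause_id`, `group`, `pathway`, inclusion flags).
#' @export
generate_burden <- function(config, strata) {
  stopifnot(inherits(config, "synth_config"))
  check_cols(strata, c("stratum_id", "sex", "age_mid", "pop_weight"), "strata")
  set.seed(config$seed + 505L)
  causes <- synth_causes()
  sdlog_ui <- 0.06
  z <- stats::qnorm(0.975)
  out <- vector("list", nrow(causes) * 3L)
  j <- 0L
  for (ci in seq_len(nrow(causes))) {
    shape <- strata$pop_weight * exp(0.09 * (strata$age_mid - 25)) *
      ifelse(strata$sex == "men", 1.3, 1) *
      stats::rlnorm(nrow(strata), 0, 0.1)
    shape <- shape / sum(shape)
    for (metric in c("deaths", "incidence", "dalys")) {
      mult <- switch(metric, deaths = 1,
                     incidence = causes$inc_mult[ci],
                     dalys = causes$daly_mult[ci])
      ev <- shape * causes$deaths_total[ci] * mult * config$burden_scale
      j <- j + 1L
      out[[j]] <- data.frame(
        cause_id = causes$cause_id[ci],
        stratum_id = strata$stratum_id,
        metric = metric,
        events = ev,
        lo = ev * exp(-z * sdlog_ui),
        hi = ev * exp(z * sdlog_ui),
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  burden <- list(events = events,
                 causes = causes[, c("cause_id", "group", "pathway",
                                     "include_in_mortality",
                                     "include_in_morbidity")])
  validate_burden(burden)
  burden
}

#' Validate a burden table
#'
#' Checks that uncertainty bounds bracket the central values
#' (`lo <= events <= hi`, no inverted intervals) and that the cause flags
#' are present.  Called by the generator and by [read_input_tables()].
#'
#' @param burden list with `events` and `causes` as in [generate_burden()].
#' @return `burden`, invisibly, or an error.
#' @export
validate_burden <- function(burden) {
  check_cols(burden$events, c("cause_id", "stratum_id", "metric",
                              "events", "lo", "hi"), "burden$events")
  check_cols(burden$causes, c("cause_id", "group", "pathway",
                              "include_in_mortality", "include_in_morbidity"),
             "burden$causes")
  ev <- burden$events
  if (any(ev$lo > ev$events | ev$events > ev$hi)) {
    stop("inverted uncertainty bounds in burden table")
  }
  if (any(ev$events < 0)) stop("negative event counts in burden table")
  invisible(burden)
}

#' Generate the relative-risk table
#'
#' One row per cause and age band.  Blood-pressure-mediated causes carry
#' the log relative risk per 10 mm Hg SBP (attenuating with age, as in
#' pooled cohort analyses); stomach cancer carries the log relative risk
#' per 1 g/d sodium (age-constant).  Standard errors feed the Monte Carlo
#' draws.  Deterministic given the config (no random component).
#'
#' @param config a [synth_config()].
#' @param strata table from [generate_strata()].
#' @return data.frame with `cause_id`, `age_band`, `lnrr`, `se`, `unit`.
#' @export
generate_rr <- function(config, strata) {
  stopifnot(inherits(config, "synth_config"))
  bands <- unique(strata[, c("age_band", "age_mid")])
  causes <- synth_causes()
  rows <- list()
  for (ci in seq_len(nrow(causes))) {
    id <- causes$cause_id[ci]
    if (causes$pathway[ci] == "bp_mediated") {
      base <- log(config$rr_base[[id]])
      lnrr <- base * exp(-0.015 * (bands$age_mid - 55))
      rows[[id]] <- data.frame(cause_id = id, age_band = bands$age_band,
                               lnrr = lnrr, se = 0.12 * lnrr,
                               unit = "per_10mmHg", stringsAsFactors = FALSE)
    } else {
      lnrr <- log(config$rr_stomach_per_g)
      rows[[id]] <- data.frame(cause_id = id, age_band = bands$age_band,
                               lnrr = lnrr, se = 0.06,
                               unit = "per_g_day", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the three scenario target sets
#'
#' Places each scenario's maximum sodium levels at a sales-weighted density
#' quantile of the current supply: the Australian-style set covers the
#' first `n_categories_au` categories at `au_quantile`, the UK-style set
#' covers all categories at the stricter `uk_quantile`, and the optimistic
#' set covers all categories at `optimistic_quantile` (the sales-weighted
#' 25th percentile by default).  This guarantees UK coverage is a superset
#' of Australian coverage and optimistic targets are at or below UK
#' targets, mirroring the relative stringency of the real programs.
#'
#' @param config a [synth_config()].
#' @param products,sales tables from [generate_products_and_sales()].
#' @return named list (`au_hfp`, `uk_2017`, `optimistic_p25`) of target
#'   data.frames (`category_id`, `max_mg_100g`).
#' @export
generate_targets <- function(config, products, sales) {
  stopifnot(inherits(config, "synth_config"))
  cats <- synth_categories(config)
  au_cats <- cats[seq_len(config$n_categories_au)]
  list(
    au_hfp = derive_percentile_targets(products, sales,
                                       q = config$au_quantile,
                                       categories = au_cats),
    uk_2017 = derive_percentile_targets(products, sales,
                                        q = config$uk_quantile,
                                        categories = cats),
    optimistic_p25 = derive_percentile_targets(products, sales,
                                               q = config$optimistic_quantile,
                                               categories = cats))
}

#' Generate the complete synthetic input bundle
#'
#' Runs every generator and assembles the full set of pipeline inputs.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return object of class `cra_inputs`: a list with `config`, `strata`,
#'   `products`, `sales`, `composition`, `mapping`, `recalls`, `persons`,
#'   `burden`, `rr`, `sbp_model`, `urinary` and `targets`.
#' @examples
#' inputs <- generate_inputs(synth_config(seed = 7, n_persons = 100))
#' nrow(inputs$strata)  # 24 age-sex strata
#' @export
generate_inputs <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  strata <- generate_strata(config)
  ps <- generate_products_and_sales(config)
  foods <- generate_foods(config)
  recalls <- generate_recalls(config, foods$composition, foods$mapping, strata)
  persons <- attr(recalls, "persons")
  attr(recalls, "persons") <- NULL
  burden <- generate_burden(config, strata)
  rr <- generate_rr(config, strata)
  targets <- generate_targets(config, ps$products, ps$sales)
  out <- list(config = config,
              strata = strata,
              products = ps$products,
              sales = ps$sales,
              composition = foods$composition,
              mapping = foods$mapping,
              recalls = recalls,
              persons = persons,
              burden = burden,
              rr = rr,
              sbp_model = config$sbp_effect,
              urinary = config$urinary_sodium_mean,
              targets = targets)
  class(out) <- "cra_inputs"
  out
}

#' Analytic ground truth for a target set
#'
#' Recomputes, directly from the product and sales tables, the proportional
#' sodium reduction each category undergoes under a target set, using the
#' one-pass identity `r_c = sum(kg * max(d - t, 0)) / sum(kg * d)` (the
#' sales-weighted excess over the target divided by the sales-weighted
#' density).  If a category-intake table is supplied, also returns the
#' implied per-stratum intake reduction `delta_s = sum_c intake_sc * r_c`
#' computed by an explicit loop.  Both computations are independent of the
#' clamp-then-average pipeline path, so they serve as a self-consistency
#' check on the end-to-end estimates.
#'
#' @param products,sales supply tables.
#' @param targets a target data.frame (`category_id`, `max_mg_100g`).
#' @param intakes optional category-intake table (`stratum_id`,
#'   `category_id`, `mean_mg_d`).
#' @return list with `reduction` (`category_id`, `reduction`) and, when
#'   `intakes` is given, `delta` (`stratum_id`, `delta_mg_d`).
#' @export
ground_truth <- function(products, sales, targets, intakes = NULL) {
  check_cols(products, c("product_id", "category_id", "sodium_mg_100g"),
             "products")
  check_cols(sales, c("product_id", "kg_year"), "sales")
  check_cols(targets, c("category_id", "max_mg_100g"), "targets")
  kg <- sales$kg_year[match(products$product_id, sales$product_id)]
  red <- data.frame(category_id = targets$category_id, reduction = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(targets))) {
    sel <- products$category_id == targets$category_id[i]
    d <- products$sodium_mg_100g[sel]
    w <- kg[sel]
    t <- targets$max_mg_100g[i]
    red$reduction[i] <- sum(w * pmax(d - t, 0)) / sum(w * d)
  }
  out <- list(reduction = red)
  if (!is.null(intakes)) {
    check_cols(intakes, c("stratum_id", "category_id", "mean_mg_d"), "intakes")
    strata_ids <- unique(intakes$stratum_id)
    delta <- numeric(length(strata_ids))
    for (si in seq_along(strata_ids)) {
      acc <- 0
      for (i in seq_len(nrow(red))) {
        row <- intakes[intakes$stratum_id == strata_ids[si] &
                         intakes$category_id == red$category_id[i], ]
        if (nrow(row) == 1) acc <- acc + row$mean_mg_d * red$reduction[i]
      }
      delta[si] <- acc
    }
    out$delta <- data.frame(stratum_id = strata_ids, delta_mg_d = delta,
                            stringsAsFactors = FALSE)
  }
  out
}
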