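# Reporting layer: percentage/aggregation arithmetic, scenario
# comparison, company attribution and the sensitivity suite.

#' Shares of a total, in percent
#'
#' `100 * x / total`; the report convention for expressing company or
#' category contributions as a percentage of the program total.
#'
#' @param x contributions.
#' @param total denominator (defaults to `sum(x)`).
#' @return percentages.
#' @export
averted_share <- function(x, total = sum(x)) 100 * x / total

#' Percent of baseline burden averted
#'
#' `100 * averted / baseline`: averted events out of the total disease
#' events, the "% averted" column of the report tables (also used for the
#' intake reduction as a percent of baseline intake).
#'
#' @param averted averted counts.
#' @param baseline baseline totals.
#' @return percentages.
#' @export
percent_averted <- function(averted, baseline) 100 * averted / baseline

#' Population summary of per-stratum sodium reductions
#'
#' Population-weighted mean reduction overall, by sex, and by broad age
#' group (<70 vs >= 70 years).  With equal sex population weights the
#' overall mean equals the simple average of the sex means.
#'
#' @param delta per-stratum reduction table (`stratum_id`, `delta_mg_d`).
#' @param strata stratum table (`sex`, `age_lo`, `pop_weight`).
#' @return list with `overall`, `by_sex`, `by_age` (mg/d).
#' @export
population_summary <- function(delta, strata) {
  check_cols(delta, c("stratum_id", "delta_mg_d"), "delta")
  check_cols(strata, c("stratum_id", "sex", "age_lo", "pop_weight"), "strata")
  i <- match(delta$stratum_id, strata$stratum_id)
  if (anyNA(i)) stop("delta strata missing from 'strata'")
  w <- strata$pop_weight[i]
  sex <- strata$sex[i]
  old <- ifelse(strata$age_lo[i] >= 70, "age70plus", "under70")
  wm <- function(sel) stats::weighted.mean(delta$delta_mg_d[sel], w[sel])
  list(overall = stats::weighted.mean(delta$delta_mg_d, w),
       by_sex = vapply(split(seq_along(i), sex), wm, numeric(1)),
       by_age = vapply(split(seq_along(i), factor(old, c("under70",
                                                         "age70plus"))),
                       wm, numeric(1)))
}

#' Compare fitted scenarios draw by draw
#'
#' Incremental effects of each scenario relative to a reference scenario.
#' Differences are computed per draw and then summarised, so the interval
#' reflects the correlation induced by the shared inputs and seed -- a
#' naive subtraction of the two scenarios' interval endpoints would
#' overstate the uncertainty of the increment.
#'
#' @param fits named list of [sodium_cra()] fits sharing inputs, draw
#'   count and seed.
#' @param reference index or name of the baseline fit.
#' @return data.frame (`comparison`, `quantity`, `central`, `lower`,
#'   `upper`) of per-draw differences (fit minus reference).
#' @export
compare_scenarios <- function(fits, reference = 1) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$scenario, "")
  }
  ref <- fits[[reference]]
  if (is.null(ref$draws)) stop("fits must carry Monte Carlo draws")
  for (f in fits) {
    if (is.null(f$draws) || nrow(f$draws) != nrow(ref$draws)) {
      stop("mismatched draw counts across scenarios")
    }
    if (f$assumptions$seed != ref$assumptions$seed) {
      stop("scenarios must share the Monte Carlo seed")
    }
  }
  ref_name <- if (is.character(reference)) reference else
    names(fits)[reference]
  out <- list()
  for (nm in setdiff(names(fits), ref_name)) {
    d <- fits[[nm]]$draws - ref$draws[, colnames(fits[[nm]]$draws)]
    s <- summarize_draws(d)
    s <- data.frame(comparison = paste(nm, "-", ref_name), s,
                    stringsAsFactors = FALSE)
    out[[nm]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank companies by their reformulation health impact
#'
#' Runs an independent single-company scenario for every company (only
#' that company's products are clamped to the targets, all sales volumes
#' unchanged) and ranks companies by the central estimate of averted
#' deaths, expressed also as a share of the all-company total.  For each
#' company the top 3 contributing food categories are identified by the
#' averted deaths attributable to that company's reduction in each
#' category alone.  Ties are broken by company id.
#'
#' @param inputs a `cra_inputs` bundle.
#' @param scenario,targets,share,tmrel,intake_multiplier,mode,cv as in
#'   [sodium_cra()]; rankings use deterministic central runs.
#' @param top_k how many leading companies the print method shows.
#' @return data.frame of class `company_ranking` with one row per company:
#'   `rank`, `company_id`, `company_type`, `averted_deaths`, `share_pct`,
#'   `top_categories`; the all-company total is attached as attribute
#'   `total_averted`.
#' @export
company_ranking <- function(inputs, scenario = "au_hfp", targets = NULL,
                            top_k = 5, share = 0.85,
                            tmrel = c(mean = 2.0, sd = 0.2),
                            intake_multiplier = 1,
                            mode = "delta", cv = 0.25) {
  if (is.null(targets)) targets <- inputs$targets[[scenario]]
  if (is.null(targets)) stop("no target set named '", scenario, "'")
  intakes <- prepare_intakes(inputs, share, intake_multiplier)
  pre <- total_intake(intakes, inputs$strata)
  static <- build_engine_static(inputs$strata, inputs$burden, inputs$rr,
                                inputs$sbp_model, mode = mode, cv = cv)
  deaths_for_delta <- function(delta_tab) {
    spec <- build_draw_spec(pre, delta_tab, inputs$strata, inputs$sbp_model,
                            tmrel, static)
    cra_point(central_parameters(spec), static)$vector[["deaths.total"]]
  }
  eff_all <- reformulation_effects(inputs$products, inputs$sales, targets)
  total <- deaths_for_delta(scenario_intake_change(intakes, eff_all))
  companies <- sort(unique(inputs$products$company_id))
  type_of <- inputs$products$company_type[match(companies,
                                                inputs$products$company_id)]
  deaths <- numeric(length(companies))
  top_cats <- character(length(companies))
  for (i in seq_along(companies)) {
    eff <- reformulation_effects(inputs$products, inputs$sales, targets,
                                 company = companies[i])
    delta <- scenario_intake_change(intakes, eff)
    deaths[i] <- deaths_for_delta(delta)
    contrib <- attr(delta, "by_category")
    cats <- unique(contrib$category_id[contrib$delta_mg_d > 0])
    if (length(cats)) {
      per_cat <- vapply(cats, function(cc) {
        sub <- contrib[contrib$category_id == cc, ]
        d1 <- data.frame(stratum_id = sub$stratum_id,
                         delta_mg_d = sub$delta_mg_d,
                         delta_se_mg_d = 0)
        deaths_for_delta(d1)
      }, numeric(1))
      ord <- order(-per_cat, cats)
      top_cats[i] <- paste(cats[ord][seq_len(min(3, length(cats)))],
                           collapse = ", ")
    }
  }
  ord <- order(-deaths, companies)
  out <- data.frame(rank = seq_along(companies),
                    company_id = companies[ord],
                    company_type = type_of[ord],
                    averted_deaths = deaths[ord],
                    share_pct = averted_share(deaths[ord], total),
                    top_categories = top_cats[ord],
                    stringsAsFactors = FALSE)
  attr(out, "total_averted") <- total
  attr(out, "top_k") <- top_k
  class(out) <- c("company_ranking", "data.frame")
  out
}

#' @export
print.company_ranking <- function(x, ...) {
  k <- min(attr(x, "top_k"), nrow(x))
  top <- x[seq_len(k), ]
  cat(sprintf("Top %d companies by averted deaths (of %.0f total; ties broken by company id)\n",
              k, attr(x, "total_averted")))
  top$averted_deaths <- round(top$averted_deaths, 1)
  top$share_pct <- round(top$share_pct, 1)
  print(as.data.frame(top), row.names = FALSE)
  cat(sprintf("Others: %.1f deaths (%.1f%%)\n",
              sum(x$averted_deaths[-seq_len(k)]),
              sum(x$share_pct[-seq_len(k)])))
  invisible(x)
}

#' Attribute averted deaths to food categories
#'
#' Runs a single-category scenario for every covered category (only that
#' category's reduction applied) and expresses each category's averted
#' deaths as a share of the covered total, normalised to sum to 100%.
#'
#' @inheritParams company_ranking
#' @return data.frame (`category_id`, `averted_deaths`, `share_pct`),
#'   sorted by impact.
#' @export
category_attribution <- function(inputs, scenario = "au_hfp", targets = NULL,
                                 share = 0.85,
                                 tmrel = c(mean = 2.0, sd = 0.2),
                                 intake_multiplier = 1,
                                 mode = "delta", cv = 0.25) {
  if (is.null(targets)) targets <- inputs$targets[[scenario]]
  if (is.null(targets)) stop("no target set named '", scenario, "'")
  intakes <- prepare_intakes(inputs, share, intake_multiplier)
  pre <- total_intake(intakes, inputs$strata)
  static <- build_engine_static(inputs$strata, inputs$burden, inputs$rr,
                                inputs$sbp_model, mode = mode, cv = cv)
  eff <- reformulation_effects(inputs$products, inputs$sales, targets)
  delta_all <- scenario_intake_change(intakes, eff)
  contrib <- attr(delta_all, "by_category")
  deaths <- vapply(eff$category_id, function(cc) {
    sub <- contrib[contrib$category_id == cc, ]
    d1 <- data.frame(stratum_id = sub$stratum_id,
                     delta_mg_d = sub$delta_mg_d, delta_se_mg_d = 0)
    spec <- build_draw_spec(pre, d1, inputs$strata, inputs$sbp_model,
                            tmrel, static)
    cra_point(central_parameters(spec), static)$vector[["deaths.total"]]
  }, numeric(1))
  ord <- order(-deaths, eff$category_id)
  out <- data.frame(category_id = eff$category_id[ord],
                    averted_deaths = unname(deaths[ord]),
                    share_pct = averted_share(unname(deaths[ord])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Deterministic sensitivity analyses
#'
#' Re-runs a scenario under the four alternative assumptions -- TMREL
#' 1.0 +/- 0.2 g/d, TMREL 3.0 +/- 0.6 g/d, 10% lower baseline intake, and
#' a 75% (instead of 85%) nondiscretionary sodium share -- reusing the
#' primary run's seed so differences reflect the changed assumption, not
#' Monte Carlo noise.  Central averted deaths are reported alongside their
#' proportion of the primary estimate.
#'
#' @param inputs a `cra_inputs` bundle.
#' @param scenario,targets,share,tmrel,mode,cv,draws,seed as in
#'   [sodium_cra()]; these define the primary model.
#' @return data.frame (`analysis`, `deaths`, `lower`, `upper`,
#'   `proportion_of_primary`), with the five fits attached as attribute
#'   `fits`.
#' @export
sensitivity_suite <- function(inputs, scenario = "au_hfp", targets = NULL,
                              share = 0.85, tmrel = c(mean = 2.0, sd = 0.2),
                              mode = "delta", cv = 0.25,
                              draws = 1000L, seed = 1L) {
  run <- function(tm = tmrel, sh = share, mult = 1) {
    sodium_cra(inputs, scenario = scenario, targets = targets, share = sh,
               tmrel = tm, intake_multiplier = mult, mode = mode, cv = cv,
               draws = draws, seed = seed)
  }
  fits <- list(primary = run(),
               tmrel_low = run(tm = c(1.0, 0.2)),
               tmrel_high = run(tm = c(3.0, 0.6)),
               intake_minus10 = run(mult = 0.9),
               share_75 = run(sh = 0.75))
  rows <- lapply(names(fits), function(nm) {
    q <- fit_quantity(fits[[nm]], "deaths.total")
    data.frame(analysis = nm, deaths = q[1], lower = q[2], upper = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$proportion_of_primary <- out$deaths / out$deaths[1]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
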