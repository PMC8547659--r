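# The central model run: one reformulation scenario, end to end.

# Shared stage-1 preparation: category intakes from recalls, underreporting
# adjustment, optional baseline multiplier.
prepare_intakes <- function(inputs, share, intake_multiplier) {
  intakes <- category_intake(inputs$recalls, inputs$composition,
                             inputs$mapping, inputs$persons)
  intakes <- adjust_underreporting(intakes, inputs$strata, inputs$urinary,
                                   share = share)
  factors <- attr(intakes, "factors")
  intakes$mean_mg_d <- intakes$mean_mg_d * intake_multiplier
  intakes$se_mg_d <- intakes$se_mg_d * intake_multiplier
  attr(intakes, "factors") <- factors
  intakes
}

#' Fit a sodium-reformulation comparative risk assessment
#'
#' Runs the full four-stage model for one scenario: (1) survey-weighted
#' pre-reformulation sodium intake per food category and age-sex stratum,
#' adjusted to the nondiscretionary share of urinary-excretion-based
#' intake; (2) pre/post sales-weighted sodium content of each targeted
#' category under full compliance; (3) per-stratum intake reductions; and
#' (4) potential impact fractions converted into averted deaths, incident
#' cases and DALYs per cause, with Monte Carlo uncertainty intervals.
#'
#' @param inputs a `cra_inputs` bundle (see [generate_inputs()]), or any
#'   list with the same named tables.
#' @param scenario name of a target set in `inputs$targets`
#'   (`"au_hfp"`, `"uk_2017"`, `"optimistic_p25"` for synthetic bundles),
#'   ignored when `targets` is supplied directly.
#' @param targets optional explicit target data.frame
#'   (`category_id`, `max_mg_100g`).
#' @param company if non-`NULL`, a single-company scenario: only this
#'   company's products are reformulated.
#' @param share nondiscretionary share of urinary-based sodium intake
#'   (0.85 primary, 0.75 in sensitivity analysis).
#' @param tmrel theoretical-minimum-risk exposure level, `c(mean, sd)` in
#'   g/d (2.0 +/- 0.2 primary; 1.0 +/- 0.2 and 3.0 +/- 0.6 in sensitivity
#'   analyses).
#' @param intake_multiplier scales all pre-reformulation intakes (0.9 in
#'   the lower-baseline sensitivity analysis).
#' @param mode exposure-distribution mode for the PIF: `"delta"`
#'   (shift-in-mean closed form) or `"lognormal"` (numerical integration).
#' @param cv coefficient of variation of the lognormal intake
#'   distribution (used only in `"lognormal"` mode).
#' @param draws Monte Carlo simulations (1,000 primary; 0 for a
#'   deterministic point run only).
#' @param seed integer seed for the Monte Carlo draws.
#' @return object of class `sodium_cra` with components `point` (the
#'   deterministic central run), `draws` (per-draw output matrix),
#'   `summary` (central estimates and 95% UIs, plus percent of baseline
#'   burden), `effects`, `delta`, `intake`, `pre`, `baseline` and the run
#'   assumptions.  Methods: [print.sodium_cra()], [summary.sodium_cra()],
#'   [coef.sodium_cra()], [plot.sodium_cra()], [simulate.sodium_cra()].
#' @examples
#' inputs <- generate_inputs(synth_config(seed = 3, n_persons = 120))
#' fit <- sodium_cra(inputs, "au_hfp", draws = 50, seed = 1)
#' print(fit)
#' head(summary(fit)$table)
#' @export
sodium_cra <- function(inputs, scenario = "au_hfp", targets = NULL,
                       company = NULL, share = 0.85,
                       tmrel = c(mean = 2.0, sd = 0.2),
                       intake_multiplier = 1,
                       mode = c("delta", "lognormal"), cv = 0.25,
                       draws = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(intake_multiplier > 0, draws >= 0)
  if (is.null(targets)) {
    if (is.null(inputs$targets[[scenario]])) {
      stop("no target set named '", scenario, "' in inputs$targets")
    }
    targets <- inputs$targets[[scenario]]
  }
  intakes <- prepare_intakes(inputs, share, intake_multiplier)
  effects <- reformulation_effects(inputs$products, inputs$sales, targets,
                                   company = company)
  delta <- scenario_intake_change(intakes, effects)
  pre <- total_intake(intakes, inputs$strata)
  static <- build_engine_static(inputs$strata, inputs$burden, inputs$rr,
                                inputs$sbp_model, mode = mode, cv = cv)
  spec <- build_draw_spec(pre, delta, inputs$strata, inputs$sbp_model,
                          tmrel, static)
  point <- cra_point(central_parameters(spec), static)
  if (point$k_clamped > 0) {
    warning(point$k_clamped,
            " strata had a negative SBP effect clamped to zero")
  }
  engine <- function(params) cra_point(params, static)$vector
  dm <- NULL
  summ <- NULL
  if (draws > 0) {
    dm <- run_draws(engine, spec, n = draws, seed = seed)
    summ <- summarize_draws(dm)
  } else {
    summ <- data.frame(quantity = names(point$vector),
                       central = unname(point$vector),
                       lower = NA_real_, upper = NA_real_,
                       stringsAsFactors = FALSE)
  }
  baseline <- baseline_totals(static)
  out <- list(call = match.call(),
              scenario = if (is.null(company)) scenario
                         else paste0(scenario, ":", company),
              company = company,
              assumptions = list(share = share, tmrel = unname(tmrel),
                                 intake_multiplier = intake_multiplier,
                                 mode = mode, cv = cv,
                                 draws = as.integer(draws),
                                 seed = as.integer(seed)),
              targets = targets,
              intake = intakes,
              effects = effects,
              delta = delta,
              pre = pre,
              strata = static$strata,
              static = static,
              spec = spec,
              engine = engine,
              point = point,
              draws = dm,
              summary = summ,
              baseline = baseline)
  class(out) <- "sodium_cra"
  out
}

fit_quantity <- function(fit, quantity) {
  i <- match(quantity, fit$summary$quantity)
  if (is.na(i)) stop("no summary quantity '", quantity, "'")
  unlist(fit$summary[i, c("central", "lower", "upper")])
}

fmt_ui <- function(x, digits = 0) {
  if (is.na(x[2])) return(formatC(x[1], format = "f", digits = digits))
  sprintf("%s (%s, %s)",
          formatC(x[1], format = "f", digits = digits, big.mark = ","),
          formatC(x[2], format = "f", digits = digits, big.mark = ","),
          formatC(x[3], format = "f", digits = digits, big.mark = ","))
}

#' @export
print.sodium_cra <- function(x, ...) {
  a <- x$assumptions
  cat("Sodium reformulation comparative risk assessment\n")
  cat(sprintf("  scenario: %s   (%d Monte Carlo draws, seed %d)\n",
              x$scenario, a$draws, a$seed))
  cat(sprintf("  assumptions: TMREL %.1f +/- %.1f g/d, nondiscretionary share %.2f,\n",
              a$tmrel[1], a$tmrel[2], a$share))
  cat(sprintf("               intake x%.2f, exposure mode '%s'\n",
              a$intake_multiplier, a$mode))
  cat(sprintf("  population sodium reduction: %s mg/d (from %s to %s mg/d)\n",
              fmt_ui(fit_quantity(x, "delta_mean")),
              formatC(x$point$vector[["pre_mean"]], format = "f", digits = 0,
                      big.mark = ","),
              formatC(x$point$vector[["post_mean"]], format = "f", digits = 0,
                      big.mark = ",")))
  cat("  averted per year (central, 95% UI):\n")
  cat(sprintf("    deaths:    %s\n", fmt_ui(fit_quantity(x, "deaths.total"))))
  cat(sprintf("    incidence: %s\n",
              fmt_ui(fit_quantity(x, "incidence.total"))))
  cat(sprintf("    DALYs:     %s\n", fmt_ui(fit_quantity(x, "dalys.total"))))
  invisible(x)
}

#' Summary tables for a fitted scenario
#'
#' Builds a burden-table-style summary: averted deaths, incident cases and
#' DALYs per cause (with the CVD subtype rows, the CVD aggregate, CKD and
#' stomach cancer), each as a count and as a percent of the baseline
#' burden, with 95% uncertainty intervals; plus the population sodium
#' reduction stratified by sex and broad age group.
#'
#' @param object a [sodium_cra()] fit.
#' @param ... unused.
#' @return object of class `summary.sodium_cra` with components `table`
#'   (per metric x cause), `intake` (sodium reduction summary) and
#'   `assumptions`.
#' @export
summary.sodium_cra <- function(object, ...) {
  s <- object$summary
  base <- object$baseline
  rows <- s[grepl("^(deaths|incidence|dalys)\\.", s$quantity), ]
  parts <- strsplit(rows$quantity, ".", fixed = TRUE)
  rows$metric <- vapply(parts, `[`, "", 1)
  rows$cause <- vapply(parts, `[`, "", 2)
  rows <- rows[!rows$cause %in% c("men", "women", "under70", "age70plus"), ]
  b <- base[rows$quantity]
  # drop causes excluded from a metric (zero baseline by construction)
  keep <- b > 0
  rows <- rows[keep, ]
  b <- b[keep]
  tab <- data.frame(metric = rows$metric, cause = rows$cause,
                    averted = rows$central,
                    averted_lo = rows$lower, averted_hi = rows$upper,
                    baseline = unname(b),
                    pct = percent_averted(rows$central, b),
                    pct_lo = percent_averted(rows$lower, b),
                    pct_hi = percent_averted(rows$upper, b),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  intake <- list(
    delta = fit_quantity(object, "delta_mean"),
    pre = object$point$vector[["pre_mean"]],
    post = object$point$vector[["post_mean"]],
    pct_of_intake = percent_averted(fit_quantity(object, "delta_mean")[1],
                                    object$point$vector[["pre_mean"]]),
    by_sex = c(men = object$point$vector[["deaths.men"]],
               women = object$point$vector[["deaths.women"]]),
    by_age = c(under70 = object$point$vector[["deaths.under70"]],
               age70plus = object$point$vector[["deaths.age70plus"]]),
    delta_by_group = population_summary(object$delta, object$strata))
  out <- list(scenario = object$scenario, table = tab, intake = intake,
              assumptions = object$assumptions)
  class(out) <- "summary.sodium_cra"
  out
}

#' @export
print.summary.sodium_cra <- function(x, digits = 1, ...) {
  cat(sprintf("Scenario %s: averted events per year\n", x$scenario))
  cat(sprintf("Population sodium reduction %.0f mg/d (%.1f%% of baseline intake %.0f mg/d)\n\n",
              x$intake$delta[1], x$intake$pct_of_intake, x$intake$pre))
  tab <- x$table
  tab$averted <- round(tab$averted)
  tab$averted_lo <- round(tab$averted_lo)
  tab$averted_hi <- round(tab$averted_hi)
  tab$baseline <- round(tab$baseline)
  tab$pct <- round(tab$pct, 2)
  tab$pct_lo <- round(tab$pct_lo, 2)
  tab$pct_hi <- round(tab$pct_hi, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sodium_cra <- function(object, metric = "deaths", ...) {
  s <- object$summary
  sel <- grepl(paste0("^", metric, "\\."), s$quantity) &
    !s$quantity %in% paste0(metric, c(".men", ".women", ".under70",
                                      ".age70plus"))
  stats::setNames(s$central[sel], s$quantity[sel])
}

#' Plot averted events with uncertainty intervals
#'
#' Bar chart of the central averted counts for the major cause groups
#' (CVD, CKD, stomach cancer and the total), with 95% UI error bars.
#'
#' @param x a [sodium_cra()] fit.
#' @param metric `"deaths"`, `"incidence"` or `"dalys"`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix of plotted values.
#' @export
plot.sodium_cra <- function(x, metric = "deaths", ...) {
  q <- paste0(metric, ".", c("cvd", "ckd", "stomach_cancer", "total"))
  vals <- t(vapply(q, function(qq) fit_quantity(x, qq), numeric(3)))
  bp <- graphics::barplot(vals[, 1],
                          names.arg = c("CVD", "CKD", "Stomach\ncancer",
                                        "Total"),
                          ylim = c(0, max(vals, na.rm = TRUE) * 1.1),
                          ylab = sprintf("Averted %s per year", metric),
                          main = x$scenario, ...)
  if (!anyNA(vals[, 2])) {
    graphics::arrows(bp, vals[, 2], bp, vals[, 3], angle = 90, code = 3,
                     length = 0.05)
  }
  invisible(vals)
}

#' Draw additional Monte Carlo simulations from a fitted scenario
#'
#' Re-runs the fit's Monte Carlo loop with a new seed (or the original
#' one, reproducing the stored draws exactly).
#'
#' @param object a [sodium_cra()] fit.
#' @param nsim number of draws.
#' @param seed integer seed; defaults to the fit's seed.
#' @param ... unused.
#' @return data.frame of per-draw outputs.
#' @export
simulate.sodium_cra <- function(object, nsim = object$assumptions$draws,
                                seed = object$assumptions$seed, ...) {
  as.data.frame(run_draws(object$engine, object$spec, n = nsim, seed = seed))
}
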