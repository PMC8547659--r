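# Stage 4: potential impact fractions and averted events.  The relative
# risk of the cardiovascular and kidney outcomes is mediated by systolic
# blood pressure (SBP); stomach cancer responds to sodium directly.

#' SBP effect of sodium reduction for a stratum
#'
#' The SBP reduction (mm Hg per 100 mmol/d of sodium reduction) in an
#' age-sex stratum, adjusted for hypertension prevalence:
#' `k = main + age_int * (age_mid - ref_age) + hyp_int * prevalence`.
#' The effect grows with age and with hypertension prevalence.  Parameter
#' draws can occasionally push `k` negative in the youngest strata; such
#' values are clamped to zero (no protective effect of raising sodium is
#' modelled) and counted in the `clamped` attribute.
#'
#' @param sbp_model list with `main`, `age_int`, `hyp_int`, `ref_age`
#'   (mm Hg per 100 mmol/d, per year, per unit prevalence, years).
#' @param age_mid stratum age-band midpoints (years).
#' @param hyp_prev hypertension prevalence in `[0, 1]`.
#' @return vector of `k` values (mm Hg per 100 mmol/d), never negative.
#' @export
k_for_stratum <- function(sbp_model, age_mid, hyp_prev) {
  stopifnot(all(hyp_prev >= 0), all(hyp_prev <= 1))
  k <- sbp_model$main +
    sbp_model$age_int * (age_mid - sbp_model$ref_age) +
    sbp_model$hyp_int * hyp_prev
  n_clamped <- sum(k < 0)
  k <- pmax(k, 0)
  attr(k, "clamped") <- n_clamped
  k
}

#' Relative risk of a blood-pressure-mediated outcome
#'
#' Piecewise-exponential dose response in sodium intake `x` (mmol/d):
#' `RR(x) = exp(lnrr10 * (k/10) * (x - tmrel)/100)` for `x >= tmrel` and 1
#' below the theoretical-minimum-risk exposure level.  `lnrr10` is the log
#' relative risk per 10 mm Hg SBP and `k` the SBP response per 100 mmol/d
#' sodium, so the exponent chains sodium -> SBP -> outcome.
#'
#' @param x sodium intake, mmol/d.
#' @param lnrr10 log relative risk per 10 mm Hg SBP.
#' @param k SBP effect, mm Hg per 100 mmol/d (see [k_for_stratum()]).
#' @param tmrel theoretical-minimum-risk exposure level, mmol/d.
#' @return relative risk (>= 1 when `lnrr10, k >= 0`).
#' @export
rr_bp_mediated <- function(x, lnrr10, k, tmrel) {
  ifelse(x >= tmrel, exp(lnrr10 * (k / 10) * ((x - tmrel) / 100)), 1)
}

#' Relative risk of stomach cancer
#'
#' Direct (non-BP-mediated) dose response: `RR(x) = exp(lnrr_g * M_Na *
#' (x - tmrel) / 1000)` for `x >= tmrel`, else 1, where `lnrr_g` is the
#' log relative risk per 1 g/d sodium and `M_Na = 22.99` g/mol converts
#' the mmol/d excess into g/d.
#'
#' @param x sodium intake, mmol/d.
#' @param lnrr_g log relative risk per 1 g/d sodium.
#' @param tmrel theoretical-minimum-risk exposure level, mmol/d.
#' @return relative risk.
#' @export
rr_stomach <- function(x, lnrr_g, tmrel) {
  ifelse(x >= tmrel, exp(lnrr_g * M_NA * (x - tmrel) / 1000), 1)
}

#' Potential impact fraction of an exposure shift
#'
#' The proportional reduction in disease events when the sodium intake
#' distribution moves from a pre-intervention state `P` to a
#' post-intervention state `P'`:
#' `PIF = (int RR P - int RR P') / (int RR P)` over `[0, m]`.
#'
#' Two exposure-distribution modes are supported.  In `delta` mode the
#' whole stratum sits at its mean and the closed form
#' `1 - RR(post)/RR(pre)` is used.  In `lognormal` mode each state is a
#' lognormal with the given mean and coefficient of variation `cv`, and
#' the integrals are evaluated by the trapezoid rule on a fixed grid of
#' `n_grid` points on `[0, m]`, where `m` is the larger of
#' `max(pre, post) * (1 + 8 cv)` (mean + 8 SD) and the `1 - 1e-8`
#' quantile of either distribution -- the lognormal right tail is heavier
#' than 8 normal SDs, so the bound follows the quantile when needed.  The
#' grid must capture at least `1 - 1e-6` of each distribution's mass or
#' an error is raised.
#'
#' @param pre,post pre- and post-intervention mean intakes, mmol/d.
#' @param rr vectorised relative-risk function of intake in mmol/d.
#' @param mode `"delta"` or `"lognormal"`.
#' @param cv coefficient of variation of the lognormal intake distribution.
#' @param n_grid number of integration grid points.
#' @return the PIF, in `[0, 1)` for any reduction with `RR >= 1` monotone.
#' @export
pif <- function(pre, post, rr, mode = c("delta", "lognormal"),
                cv = 0.25, n_grid = 2001L) {
  mode <- match.arg(mode)
  stopifnot(pre >= 0, post >= 0)
  if (mode == "delta") {
    return(1 - rr(post) / rr(pre))
  }
  if (pre <= 0 || post <= 0) {
    stop("lognormal mode requires positive means")
  }
  sdlog <- sqrt(log1p(cv^2))
  mlog_pre <- log(pre) - sdlog^2 / 2
  mlog_post <- log(post) - sdlog^2 / 2
  m <- max(max(pre, post) * (1 + 8 * cv),
           stats::qlnorm(1 - 1e-8, mlog_pre, sdlog),
           stats::qlnorm(1 - 1e-8, mlog_post, sdlog))
  cover <- min(stats::plnorm(m, mlog_pre, sdlog),
               stats::plnorm(m, mlog_post, sdlog))
  if (cover < 1 - 1e-6) {
    stop("integration upper bound captures < 1 - 1e-6 of the intake mass")
  }
  x <- seq(0, m, length.out = n_grid)
  rx <- rr(x)
  f_pre <- rx * stats::dlnorm(x, mlog_pre, sdlog)
  f_post <- rx * stats::dlnorm(x, mlog_post, sdlog)
  h <- x[2] - x[1]
  int_pre <- h * (sum(f_pre) - (f_pre[1] + f_pre[n_grid]) / 2)
  int_post <- h * (sum(f_post) - (f_post[1] + f_post[n_grid]) / 2)
  out <- (int_pre - int_post) / int_pre
  if (!is.finite(out)) stop("non-finite PIF integral")
  out
}

#' Averted events from stratum- and cause-specific PIFs
#'
#' Multiplies each age-, sex- and cause-specific PIF by the current
#' (pre-reformulation) number of events in the same stratum.  Causes
#' flagged `include_in_morbidity = FALSE` (the inflammatory heart
#' diseases) are skipped for incidence and DALYs but kept for deaths.
#'
#' @param pif_tab data.frame (`stratum_id`, `cause_id`, `pif`).
#' @param burden burden list (`events`, `causes`) as from
#'   [generate_burden()].
#' @param metric `"deaths"`, `"incidence"` or `"dalys"`.
#' @return data.frame (`stratum_id`, `cause_id`, `events`, `averted`).
#' @export
averted_events <- function(pif_tab, burden,
                           metric = c("deaths", "incidence", "dalys")) {
  metric <- match.arg(metric)
  check_cols(pif_tab, c("stratum_id", "cause_id", "pif"), "pif_tab")
  validate_burden(burden)
  flag <- if (metric == "deaths") "include_in_mortality" else
    "include_in_morbidity"
  keep_causes <- burden$causes$cause_id[burden$causes[[flag]]]
  tab <- pif_tab[pif_tab$cause_id %in% keep_causes, ]
  ev <- burden$events[burden$events$metric == metric, ]
  key <- paste(ev$cause_id, ev$stratum_id)
  events <- ev$events[match(paste(tab$cause_id, tab$stratum_id), key)]
  if (anyNA(events)) {
    stop("missing burden cells for metric ", metric)
  }
  data.frame(stratum_id = tab$stratum_id,
             cause_id = tab$cause_id,
             events = events,
             averted = tab$pif * events,
             stringsAsFactors = FALSE)
}

#' Averted-event totals by sex and broad age group
#'
#' Partitions a table of averted events into totals by sex and by age
#' (<70 vs >= 70 years); each partition sums to the grand total.
#'
#' @param averted table from [averted_events()].
#' @param strata stratum table (for `sex` and `age_lo`).
#' @return list with `total`, `by_sex` and `by_age` (named sums).
#' @export
stratified_report <- function(averted, strata) {
  check_cols(averted, c("stratum_id", "averted"), "averted")
  check_cols(strata, c("stratum_id", "sex", "age_lo"), "strata")
  i <- match(averted$stratum_id, strata$stratum_id)
  if (anyNA(i)) stop("averted strata missing from 'strata'")
  sex <- strata$sex[i]
  old <- ifelse(strata$age_lo[i] >= 70, "age70plus", "under70")
  list(total = sum(averted$averted),
       by_sex = tapply(averted$averted, sex, sum),
       by_age = tapply(averted$averted, factor(old, c("under70", "age70plus")),
                       sum))
}
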