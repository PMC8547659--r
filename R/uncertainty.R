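# Monte Carlo propagation of input uncertainty.  Each simulation draws
# one value for every uncertain input -- (a) pre-reformulation intake and
# reformulation effect per stratum, (b) hypertension prevalence, (c) the
# SBP-response coefficients, (d) the log relative risks of the
# BP-mediated causes, (e) the stomach-cancer log relative risk, (f) the
# TMREL, (g) baseline event counts -- re-runs the deterministic engine,
# and the results are summarised by percentiles across draws.

#' Build the draw specification for a scenario
#'
#' Collects the central value and dispersion of every uncertain input.
#' Distribution families: normal for intake means, reformulation effects
#' and SBP coefficients (parameterised by SE, truncated at zero where the
#' quantity is nonnegative); moment-matched Beta for prevalence (support
#' `[0, 1]`); normal on the log-relative-risk scale; truncated normal
#' (> 0) for the TMREL; lognormal for event counts (sdlog recovered from
#' the 95% uncertainty interval).  Draws are independent across
#' parameters.
#'
#' @param pre_tab per-stratum total intake (`stratum_id`, `mean_mg_d`,
#'   `se_mg_d`).
#' @param delta_tab per-stratum intake reduction (`stratum_id`,
#'   `delta_mg_d`, `delta_se_mg_d`).
#' @param strata stratum table with `hyp_prev`, `hyp_prev_se`.
#' @param sbp_model SBP-response coefficient list with `*_se` entries.
#' @param tmrel length-2 vector `c(mean, sd)` in g/d.
#' @param static engine context from the fitted object (internal callers
#'   pass the one built for the scenario).
#' @return object of class `draw_spec`.
#' @export
build_draw_spec <- function(pre_tab, delta_tab, strata, sbp_model, tmrel,
                            static) {
  s_ids <- static$strata$stratum_id
  i_pre <- match(s_ids, pre_tab$stratum_id)
  i_del <- match(s_ids, delta_tab$stratum_id)
  i_str <- match(s_ids, strata$stratum_id)
  if (anyNA(i_pre) || anyNA(i_del) || anyNA(i_str)) {
    stop("intake, delta and strata tables must cover every stratum")
  }
  tm <- unname(tmrel)
  if (length(tm) != 2 || tm[1] <= 0 || tm[2] < 0) {
    stop("'tmrel' must be c(mean > 0, sd >= 0)")
  }
  spec <- list(
    stratum_id = s_ids,
    pre = stats::setNames(pre_tab$mean_mg_d[i_pre], s_ids),
    pre_se = stats::setNames(pre_tab$se_mg_d[i_pre], s_ids),
    delta = stats::setNames(delta_tab$delta_mg_d[i_del], s_ids),
    delta_se = stats::setNames(delta_tab$delta_se_mg_d[i_del], s_ids),
    prev = stats::setNames(strata$hyp_prev[i_str], s_ids),
    prev_se = stats::setNames(strata$hyp_prev_se[i_str], s_ids),
    sbp = c(main = sbp_model$main, age_int = sbp_model$age_int,
            hyp_int = sbp_model$hyp_int),
    sbp_se = c(main = sbp_model$main_se %||% 0,
               age_int = sbp_model$age_int_se %||% 0,
               hyp_int = sbp_model$hyp_int_se %||% 0),
    lnrr = static$lnrr_central,
    lnrr_se = static$lnrr_se,
    tmrel_mean = tm[1], tmrel_sd = tm[2],
    events = static$events_central,
    events_sdlog = static$events_sdlog)
  class(spec) <- "draw_spec"
  spec
}

#' Remove all uncertainty from a draw specification
#'
#' Sets every dispersion parameter to zero, so every draw reproduces the
#' central parameter set exactly.  Useful for verifying that uncertainty
#' intervals collapse onto the deterministic estimate.
#'
#' @param spec a [build_draw_spec()] object.
#' @return the spec with all SEs, SDs and sdlogs zeroed.
#' @export
zero_draw_spec <- function(spec) {
  stopifnot(inherits(spec, "draw_spec"))
  spec$pre_se[] <- 0
  spec$delta_se[] <- 0
  spec$prev_se[] <- 0
  spec$sbp_se[] <- 0
  spec$lnrr_se[] <- 0
  spec$tmrel_sd <- 0
  spec$events_sdlog[] <- 0
  spec
}

central_parameters <- function(spec) {
  list(pre = spec$pre, delta = spec$delta, hyp_prev = spec$prev,
       sbp = spec$sbp, lnrr = spec$lnrr, tmrel_g = spec$tmrel_mean,
       events = spec$events)
}

# Normal draw with an exact zero-SE branch (so zero-uncertainty specs
# reproduce central values bit-identically).
draw_norm <- function(m, s) {
  out <- m
  idx <- which(s > 0)
  if (length(idx)) out[idx] <- stats::rnorm(length(idx), m[idx], s[idx])
  out
}

draw_beta <- function(m, s) {
  out <- m
  for (i in seq_along(m)) {
    if (s[i] <= 0 || m[i] <= 0 || m[i] >= 1) next
    v <- s[i]^2
    kappa <- m[i] * (1 - m[i]) / v - 1
    if (kappa > 0) {
      out[i] <- stats::rbeta(1, m[i] * kappa, (1 - m[i]) * kappa)
    } else {
      out[i] <- min(max(stats::rnorm(1, m[i], s[i]), 0), 1)
    }
  }
  out
}

#' Draw one Monte Carlo parameter set
#'
#' Deterministic given `(seed, index)`: draw `index` of a run always uses
#' the same substream regardless of how many draws are requested, so a
#' longer run reproduces the draws of a shorter one as its prefix.
#' Truncations keep pre-intake and the reformulation effect nonnegative
#' (with effect at most the pre-intake), prevalence in `[0, 1]`, the
#' TMREL positive, and event counts positive.
#'
#' @param spec a [build_draw_spec()].
#' @param seed integer run seed.
#' @param index draw number (1-based).
#' @return parameter list consumable by the engine.
#' @export
draw_parameters <- function(spec, seed, index) {
  stopifnot(inherits(spec, "draw_spec"))
  set.seed(as.integer((as.numeric(seed) * 1000003 + index) %% 2147483647))
  pre <- pmax(draw_norm(spec$pre, spec$pre_se), 0)
  delta <- pmin(pmax(draw_norm(spec$delta, spec$delta_se), 0), pre)
  prev <- draw_beta(spec$prev, spec$prev_se)
  sbp <- draw_norm(spec$sbp, spec$sbp_se)
  lnrr <- spec$lnrr
  lnrr[] <- draw_norm(as.numeric(spec$lnrr), as.numeric(spec$lnrr_se))
  if (spec$tmrel_sd > 0) {
    u <- stats::runif(1, stats::pnorm(0, spec$tmrel_mean, spec$tmrel_sd), 1)
    tmrel_g <- stats::qnorm(u, spec$tmrel_mean, spec$tmrel_sd)
  } else {
    tmrel_g <- spec$tmrel_mean
  }
  events <- spec$events
  idx <- which(spec$events_sdlog > 0)
  if (length(idx)) {
    events[idx] <- stats::rlnorm(length(idx), log(spec$events[idx]),
                                 spec$events_sdlog[idx])
  }
  list(pre = pre, delta = delta, hyp_prev = prev, sbp = sbp, lnrr = lnrr,
       tmrel_g = tmrel_g, events = events)
}

#' Run the Monte Carlo simulation
#'
#' Evaluates a deterministic pipeline closure on `n` independently drawn
#' parameter sets.  A failing draw aborts the run with its index (no
#' silent skipping).
#'
#' @param pipeline function taking a parameter list and returning a named
#'   numeric vector.
#' @param spec a [build_draw_spec()].
#' @param n number of draws (1,000 in the primary analysis).
#' @param seed integer run seed.
#' @return numeric matrix, one row per draw.
#' @export
run_draws <- function(pipeline, spec, n = 1000L, seed = 1L) {
  stopifnot(n >= 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    params <- draw_parameters(spec, seed, i)
    res <- tryCatch(pipeline(params), error = function(e) e)
    if (inherits(res, "error")) {
      stop(sprintf("draw %d failed: %s", i, conditionMessage(res)))
    }
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Percentile summary of Monte Carlo draws
#'
#' Central estimate (50th percentile) and 95% uncertainty interval (2.5th
#' and 97.5th percentiles, linear interpolation between order statistics)
#' for every output column.  Aggregate quantities are summarised from
#' per-draw sums, so the median of an aggregate need not equal the sum of
#' the component medians.
#'
#' @param draws matrix from [run_draws()] (>= 2 rows for intervals; with a
#'   single draw the interval is `NA`).
#' @return data.frame (`quantity`, `central`, `lower`, `upper`).
#' @export
summarize_draws <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0) stop("no draws to summarize")
  central <- apply(draws, 2, stats::median)
  if (nrow(draws) >= 2) {
    qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                type = 7, names = FALSE)
    lower <- qs[1, ]
    upper <- qs[2, ]
  } else {
    lower <- upper <- rep(NA_real_, ncol(draws))
  }
  data.frame(quantity = colnames(draws), central = unname(central),
             lower = unname(lower), upper = unname(upper),
             stringsAsFactors = FALSE)
}
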