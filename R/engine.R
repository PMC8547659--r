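# Internal deterministic engine: one complete stage-4 evaluation for a
# given parameter set.  The Monte Carlo loop re-runs this engine on drawn
# parameter sets, so the deterministic point run and every draw share one
# code path.

# Static (non-drawn) context: stratum ordering and metadata, cause flags,
# the exposure-distribution mode, and the reference age of the SBP model.
build_engine_static <- function(strata, burden, rr, sbp_model,
                                mode = "delta", cv = 0.25) {
  strata <- strata[order(strata$stratum_id), ]
  causes <- burden$causes[order(burden$causes$cause_id), ]
  s_ids <- strata$stratum_id
  c_ids <- causes$cause_id
  bands <- unique(strata$age_band)
  # central lnRR matrix [cause x band] and its SEs
  lnrr <- se <- matrix(NA_real_, length(c_ids), length(bands),
                       dimnames = list(c_ids, bands))
  for (i in seq_len(nrow(rr))) {
    lnrr[rr$cause_id[i], rr$age_band[i]] <- rr$lnrr[i]
    se[rr$cause_id[i], rr$age_band[i]] <- rr$se[i]
  }
  if (anyNA(lnrr)) stop("relative-risk table does not cover every cause x age band")
  # central events array [cause x stratum x metric] and lognormal sdlog
  metrics <- c("deaths", "incidence", "dalys")
  ev <- sdlog <- array(NA_real_, c(length(c_ids), length(s_ids), 3),
                       dimnames = list(c_ids, s_ids, metrics))
  z <- stats::qnorm(0.975)
  b <- burden$events
  ci <- match(b$cause_id, c_ids)
  si <- match(b$stratum_id, s_ids)
  mi <- match(b$metric, metrics)
  ev[cbind(ci, si, mi)] <- b$events
  sdlog[cbind(ci, si, mi)] <- ifelse(b$events > 0 & b$hi > b$lo,
                                     (log(b$hi) - log(b$lo)) / (2 * z), 0)
  if (anyNA(ev)) stop("burden table does not cover every cause x stratum x metric")
  list(strata = strata, causes = causes, bands = bands,
       band_of = match(strata$age_band, bands),
       mort_mask = causes$include_in_mortality,
       morb_mask = causes$include_in_morbidity,
       lnrr_central = lnrr, lnrr_se = se,
       events_central = ev, events_sdlog = sdlog,
       ref_age = sbp_model$ref_age,
       mode = mode, cv = cv)
}

# One engine evaluation.  `params` carries every drawn quantity:
#   pre, delta, hyp_prev : per-stratum vectors (mg/d, mg/d, fraction)
#   sbp                  : c(main, age_int, hyp_int)
#   lnrr                 : [cause x band] matrix
#   tmrel_g              : scalar, g/d
#   events               : [cause x stratum x metric] array
cra_point <- function(params, static) {
  strata <- static$strata
  causes <- static$causes
  S <- nrow(strata)
  k <- k_for_stratum(list(main = params$sbp[[1]], age_int = params$sbp[[2]],
                          hyp_int = params$sbp[[3]], ref_age = static$ref_age),
                     strata$age_mid, params$hyp_prev)
  n_clamped <- attr(k, "clamped")
  tmrel <- g_to_mmol(params$tmrel_g)
  pre <- mg_to_mmol(params$pre)
  post <- mg_to_mmol(pmax(params$pre - params$delta, 0))
  P <- matrix(NA_real_, S, nrow(causes),
              dimnames = list(strata$stratum_id, causes$cause_id))
  for (ci in seq_len(nrow(causes))) {
    lnrr_s <- params$lnrr[ci, static$band_of]
    if (causes$pathway[ci] == "bp_mediated") {
      if (static$mode == "delta") {
        P[, ci] <- 1 - rr_bp_mediated(post, lnrr_s, k, tmrel) /
          rr_bp_mediated(pre, lnrr_s, k, tmrel)
      } else {
        for (s in seq_len(S)) {
          P[s, ci] <- pif(pre[s], post[s],
                          function(x) rr_bp_mediated(x, lnrr_s[s], k[s], tmrel),
                          mode = "lognormal", cv = static$cv)
        }
      }
    } else {
      if (static$mode == "delta") {
        P[, ci] <- 1 - rr_stomach(post, lnrr_s, tmrel) /
          rr_stomach(pre, lnrr_s, tmrel)
      } else {
        for (s in seq_len(S)) {
          P[s, ci] <- pif(pre[s], post[s],
                          function(x) rr_stomach(x, lnrr_s[s], tmrel),
                          mode = "lognormal", cv = static$cv)
        }
      }
    }
  }
  pw <- strata$pop_weight
  out <- c(delta_mean = stats::weighted.mean(params$delta, pw),
           pre_mean = stats::weighted.mean(params$pre, pw),
           post_mean = stats::weighted.mean(params$pre - params$delta, pw))
  metrics <- c("deaths", "incidence", "dalys")
  averted <- list()
  for (m in seq_along(metrics)) {
    mask <- if (metrics[m] == "deaths") static$mort_mask else static$morb_mask
    A <- t(P) * params$events[, , m]        # [cause x stratum]
    A[!mask, ] <- 0
    by_cause <- rowSums(A)
    grp_cvd <- sum(by_cause[causes$group == "cvd"])
    vals <- c(sum(by_cause), grp_cvd, by_cause)
    names(vals) <- paste0(metrics[m], ".",
                          c("total", "cvd", causes$cause_id))
    out <- c(out, vals)
    averted[[metrics[m]]] <- A
  }
  # deaths stratified by sex and broad age
  dA <- averted$deaths
  by_str <- colSums(dA)
  men <- strata$sex == "men"
  old <- strata$age_lo >= 70
  out <- c(out,
           deaths.men = sum(by_str[men]),
           deaths.women = sum(by_str[!men]),
           deaths.under70 = sum(by_str[!old]),
           deaths.age70plus = sum(by_str[old]))
  list(vector = out, pif = P, averted = averted, k_clamped = n_clamped)
}

# Central baseline totals matching the averted-output naming, used as
# denominators for "% averted".
baseline_totals <- function(static) {
  metrics <- c("deaths", "incidence", "dalys")
  out <- c()
  for (m in seq_along(metrics)) {
    mask <- if (metrics[m] == "deaths") static$mort_mask else static$morb_mask
    E <- static$events_central[, , m]
    E[!mask, ] <- 0
    by_cause <- rowSums(E)
    vals <- c(sum(by_cause), sum(by_cause[static$causes$group == "cvd"]),
              by_cause)
    names(vals) <- paste0(metrics[m], ".",
                          c("total", "cvd", static$causes$cause_id))
    out <- c(out, vals)
  }
  out
}
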