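# Internal helpers shared across modules.

check_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    stop(sprintf("'%s' must be a data.frame", what), call. = FALSE)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("'%s' is missing columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Survey-weighted mean with a ratio-estimator standard error.  The SE is
# sqrt(sum((w_i/W)^2 (y_i - m)^2)), the first-order variance of the weighted
# ratio m = sum(w y)/sum(w) treating weights as fixed.
weighted_mean_se <- function(y, w) {
  W <- sum(w)
  if (!isTRUE(W > 0)) stop("total weight is zero", call. = FALSE)
  m <- sum(w * y) / W
  se <- sqrt(sum((w / W)^2 * (y - m)^2))
  c(mean = m, se = se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
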