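# Stages 2-3: sales-weighted sodium statistics, product-level target
# compliance simulation, proportional category reductions, and attribution
# of intake reductions to scenarios, categories and companies.

#' Sales-weighted mean sodium density
#'
#' Mean sodium content (mg/100 g) of a category's products, each weighted
#' by its annual sales volume (kg): `sum(density * kg) / sum(kg)`.
#'
#' @param products product table (`product_id`, `category_id`,
#'   `sodium_mg_100g`).
#' @param sales sales table (`product_id`, `kg_year`).
#' @param category single category id, or `NULL` for all categories.
#' @return a scalar (single category) or a data.frame
#'   (`category_id`, `mean_mg_100g`).
#' @export
sales_weighted_mean <- function(products, sales, category = NULL) {
  check_cols(products, c("product_id", "category_id", "sodium_mg_100g"),
             "products")
  check_cols(sales, c("product_id", "kg_year"), "sales")
  kg <- sales$kg_year[match(products$product_id, sales$product_id)]
  if (anyNA(kg)) stop("products without sales records")
  if (!is.null(category)) {
    sel <- products$category_id == category
    if (!any(sel) || sum(kg[sel]) <= 0) {
      stop("category ", category, " has no positive sales")
    }
    return(sum(products$sodium_mg_100g[sel] * kg[sel]) / sum(kg[sel]))
  }
  num <- tapply(products$sodium_mg_100g * kg, products$category_id, sum)
  den <- tapply(kg, products$category_id, sum)
  if (any(den <= 0)) stop("category with zero total sales")
  data.frame(category_id = names(num),
             mean_mg_100g = as.numeric(num / den),
             stringsAsFactors = FALSE)
}

#' Simulate full compliance with a target set
#'
#' Clamps each covered product's sodium density to its category's maximum
#' (`density' = min(density, target)`); products already at or below the
#' target, products in uncovered categories, and (under a company scope)
#' other companies' products are unchanged.
#'
#' @param products product table.
#' @param targets target set (`category_id`, `max_mg_100g`).
#' @param company if non-`NULL`, only this company's products are
#'   reformulated (single-company scenario).
#' @return the product table with post-reformulation densities.
#' @export
apply_targets <- function(products, targets, company = NULL) {
  check_cols(products, c("product_id", "company_id", "category_id",
                         "sodium_mg_100g"), "products")
  check_cols(targets, c("category_id", "max_mg_100g"), "targets")
  if (any(targets$max_mg_100g <= 0)) stop("targets must be > 0")
  t <- targets$max_mg_100g[match(products$category_id, targets$category_id)]
  idx <- !is.na(t)
  if (!is.null(company)) idx <- idx & products$company_id == company
  out <- products
  out$sodium_mg_100g[idx] <- pmin(products$sodium_mg_100g[idx], t[idx])
  out
}

#' Proportional reduction between pre- and post-reformulation means
#'
#' `r = 1 - post/pre`, the fraction by which the sales-weighted mean
#' sodium density of a category falls under full compliance.
#'
#' @param pre,post sales-weighted mean densities (mg/100 g); `pre` must be
#'   positive.
#' @return fraction(s) in `[0, 1]` for any clamping reformulation.
#' @export
proportional_reduction <- function(pre, post) {
  if (any(pre <= 0)) stop("'pre' must be > 0")
  1 - post / pre
}

#' Sales-weighted percentile targets
#'
#' Derives a target set by placing each category's maximum at the
#' sales-weighted `q`-quantile of current sodium densities: the smallest
#' density whose cumulative sales share reaches `q`, so at least a
#' fraction `q` of the sales volume is already at or below the target
#' (left-continuous rule, no interpolation).  With `q = 0.25` this is the
#' optimistic-scenario rule: a quarter of the volume already complies.
#'
#' @param products,sales supply tables.
#' @param q quantile in (0, 1).
#' @param categories categories to cover; default all in `products`.
#' @return data.frame (`category_id`, `max_mg_100g`).
#' @export
derive_percentile_targets <- function(products, sales, q = 0.25,
                                      categories = NULL) {
  if (!(is.numeric(q) && length(q) == 1 && q > 0 && q < 1)) {
    stop("'q' must be a single value in (0, 1)")
  }
  check_cols(products, c("product_id", "category_id", "sodium_mg_100g"),
             "products")
  check_cols(sales, c("product_id", "kg_year"), "sales")
  if (is.null(categories)) categories <- sort(unique(products$category_id))
  kg <- sales$kg_year[match(products$product_id, sales$product_id)]
  out <- data.frame(category_id = categories, max_mg_100g = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(categories)) {
    sel <- which(products$category_id == categories[i])
    if (!length(sel)) stop("category ", categories[i], " has no products")
    ord <- sel[order(products$sodium_mg_100g[sel])]
    cw <- cumsum(kg[ord]) / sum(kg[ord])
    out$max_mg_100g[i] <-
      products$sodium_mg_100g[ord][which(cw >= q - 1e-9)[1]]
  }
  out
}

#' Pre/post sales-weighted means and proportional reductions per category
#'
#' Computes, for every covered category, the pre-reformulation
#' sales-weighted mean density, the post-reformulation mean after clamping
#' to the targets (optionally for a single company's products only, with
#' all sales volumes unchanged), and the proportional reduction.
#'
#' @inheritParams apply_targets
#' @param sales sales table.
#' @return data.frame (`category_id`, `pre_mg_100g`, `post_mg_100g`,
#'   `reduction`).
#' @export
reformulation_effects <- function(products, sales, targets, company = NULL) {
  post_products <- apply_targets(products, targets, company)
  pre <- sales_weighted_mean(products, sales)
  post <- sales_weighted_mean(post_products, sales)
  cats <- targets$category_id
  pre_v <- pre$mean_mg_100g[match(cats, pre$category_id)]
  post_v <- post$mean_mg_100g[match(cats, post$category_id)]
  if (anyNA(pre_v)) stop("target categories missing from product table")
  data.frame(category_id = cats,
             pre_mg_100g = pre_v,
             post_mg_100g = post_v,
             reduction = proportional_reduction(pre_v, post_v),
             stringsAsFactors = FALSE)
}

#' Per-stratum sodium intake reduction implied by category reductions
#'
#' Multiplies each stratum's pre-reformulation intake from every covered
#' category by that category's proportional reduction and sums:
#' `delta_s = sum_c intake_sc * r_c` (mg/d).  The standard error combines
#' the category intake SEs scaled by `r_c` under independence.
#'
#' @param intakes category-intake table (adjusted for underreporting).
#' @param effects table from [reformulation_effects()]; every effect
#'   category must be present in `intakes`.
#' @return data.frame (`stratum_id`, `delta_mg_d`, `delta_se_mg_d`) with
#'   the per-category contributions attached as attribute `by_category`.
#' @export
scenario_intake_change <- function(intakes, effects) {
  check_cols(intakes, c("stratum_id", "category_id", "mean_mg_d", "se_mg_d"),
             "intakes")
  check_cols(effects, c("category_id", "reduction"), "effects")
  miss <- setdiff(effects$category_id, intakes$category_id)
  if (length(miss)) {
    stop("effect categories missing from intakes: ",
         paste(miss, collapse = ", "))
  }
  if (nrow(effects) == 0) {
    # null scenario: no category covered, no reduction anywhere
    ids <- sort(unique(intakes$stratum_id))
    out <- data.frame(stratum_id = ids, delta_mg_d = 0, delta_se_mg_d = 0,
                      stringsAsFactors = FALSE)
    attr(out, "by_category") <- data.frame(stratum_id = character(),
                                           category_id = character(),
                                           delta_mg_d = numeric())
    return(out)
  }
  sub <- intakes[intakes$category_id %in% effects$category_id, ]
  r <- effects$reduction[match(sub$category_id, effects$category_id)]
  contrib <- data.frame(stratum_id = sub$stratum_id,
                        category_id = sub$category_id,
                        delta_mg_d = sub$mean_mg_d * r,
                        stringsAsFactors = FALSE)
  d <- tapply(contrib$delta_mg_d, contrib$stratum_id, sum)
  v <- tapply((sub$se_mg_d * r)^2, sub$stratum_id, sum)
  out <- data.frame(stratum_id = names(d),
                    delta_mg_d = as.numeric(d),
                    delta_se_mg_d = sqrt(as.numeric(v)),
                    stringsAsFactors = FALSE)
  attr(out, "by_category") <- contrib
  out
}

#' Compliance with a target set in the current supply
#'
#' For each covered category, the fraction of products and the fraction of
#' sales volume already at or below the target.
#'
#' @inheritParams reformulation_effects
#' @return data.frame (`category_id`, `product_compliance`,
#'   `sales_compliance`), fractions in `[0, 1]`.
#' @export
compliance_stats <- function(products, sales, targets) {
  check_cols(products, c("product_id", "category_id", "sodium_mg_100g"),
             "products")
  check_cols(targets, c("category_id", "max_mg_100g"), "targets")
  kg <- sales$kg_year[match(products$product_id, sales$product_id)]
  out <- data.frame(category_id = targets$category_id,
                    product_compliance = NA_real_,
                    sales_compliance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(targets))) {
    sel <- products$category_id == targets$category_id[i]
    ok <- products$sodium_mg_100g[sel] <= targets$max_mg_100g[i] + 1e-9
    out$product_compliance[i] <- mean(ok)
    out$sales_compliance[i] <- sum(kg[sel][ok]) / sum(kg[sel])
  }
  out
}
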