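## Supermarket flyer promotion coding: one record per promoted product,
## with placement (cover vs inside), NOVA group, WHO category and boolean
## flags for promotional characters, premium offers, fresh fruit/veg and a
## displayed Nutri-Score.

validate_promotions <- function(records) {
  check_columns(records, c("supermarket_id", "week", "placement",
                           "who_category", "nova",
                           "has_promotional_character", "has_premium_offer",
                           "is_fresh_fruit_veg"),
                what = "promotion records")
  bad <- setdiff(unique(records$placement), c("cover", "inside"))
  if (length(bad) > 0L) {
    fb_stop("promotion records have unknown placement '%s'", bad[[1L]])
  }
  records
}

.promo_ind_row <- function(rec, scope) {
  n <- nrow(rec)
  pct <- function(x) 100 * sum(x) / n
  data.frame(
    scope = scope,
    n_promotions = n,
    pct_upf = pct(rec$nova == 4L),
    pct_fresh_fruit_veg = pct(rec$is_fresh_fruit_veg),
    pct_characters = pct(rec$has_promotional_character),
    pct_premium_offers = pct(rec$has_premium_offer),
    pct_nutriscore_shown = if (is.null(rec$displays_nutriscore)) NA_real_
                           else pct(rec$displays_nutriscore %in% TRUE),
    pct_AB = if (is.null(rec$klass)) NA_real_
             else pct(as.character(rec$klass) %in% c("A", "B")),
    stringsAsFactors = FALSE
  )
}

#' Promotion indicators for one supermarket
#'
#' Percentages of flyer promotions that are ultra-processed, fresh fruit
#' and vegetables, carry promotional characters, carry premium offers, or
#' display a Nutri-Score -- computed over all records and, separately, over
#' cover-placement records only.
#'
#' @param records promotion record table (see `validate_promotions`).
#' @param supermarket_id company to analyse.
#' @return data.frame with rows `all` and `cover` (cover row omitted when
#'   the supermarket had no cover promotions) plus the WHO-category share
#'   distribution as attribute `"category_shares"`.
#' @export
promotion_indicators <- function(records, supermarket_id) {
  records <- validate_promotions(records)
  rec <- records[records$supermarket_id == supermarket_id, , drop = FALSE]
  if (nrow(rec) == 0L) {
    fb_stop("no promotion records for supermarket '%s'", supermarket_id)
  }
  out <- .promo_ind_row(rec, "all")
  cov <- rec[rec$placement == "cover", , drop = FALSE]
  if (nrow(cov) > 0L) out <- rbind(out, .promo_ind_row(cov, "cover"))
  out <- cbind(supermarket_id = supermarket_id, out)
  shares <- 100 * table(rec$who_category) / nrow(rec)
  attr(out, "category_shares") <-
    data.frame(who_category = names(shares), share = as.numeric(shares),
               stringsAsFactors = FALSE)
  out
}

#' Top promoted WHO categories
#'
#' Ranks WHO-model categories by their share of promotions; ties are broken
#' deterministically by category identifier (lexical order).
#'
#' @param records promotion record table.
#' @param k number of categories to return (truncated with a warning if it
#'   exceeds the number of observed categories).
#' @return data.frame `who_category`, `share` (percent), sorted by
#'   decreasing share.
#' @export
top_categories <- function(records, k) {
  records <- validate_promotions(records)
  if (k < 1L) fb_stop("'k' must be >= 1")
  shares <- 100 * table(records$who_category) / nrow(records)
  df <- data.frame(who_category = names(shares), share = as.numeric(shares),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$share, df$who_category), , drop = FALSE]
  if (k > nrow(df)) {
    fb_warn("k = %d exceeds the %d observed categories; truncated", k, nrow(df))
    k <- nrow(df)
  }
  out <- df[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
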