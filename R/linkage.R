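## Commitment-practice linkage: Spearman correlations between BIA-Obesity
## domain scores and portfolio performance indicators, with the
## interpretation conventions |rho| > 0.5 = strong and p < 0.05 =
## significant.

## the benchmark's fixed pairings: domain, indicator, and the sign the
## indicator carries when healthier practice means a larger value
.linkage_pairings <- function() {
  data.frame(
    domain = c("product_formulation", "product_formulation",
               "product_formulation", "product_formulation", "promotion"),
    indicator = c("pct_AB", "pct_DE", "median_class_num", "pct_upf",
                  "pct_not_permitted"),
    direction = c(1, -1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Commitment-practice correlation table
#'
#' Runs [spearman_test()] for each of the benchmark's fixed pairings:
#' the product-formulation domain score against the portfolio's %A/B,
#' %D/E, median Nutri-Score class (as its 1-5 numeric code) and
#' %ultra-processed, and the promotion domain score against the
#' %not-permitted-to-market-to-children.  Companies flagged as too small
#' to report are excluded pairwise; pairings with a constant column are
#' emitted with an undefined-rho marker rather than dropped.
#' A Holm-adjusted p-value column is appended as a clearly marked
#' extension (the benchmark convention applies no multiplicity
#' correction).
#'
#' @param bia_scores output of [score_commitments()] (columns
#'   `company_id`, the six domain scores, `overall`).
#' @param summaries output of [summarize_portfolios()].
#' @return data.frame: `domain`, `indicator`, `direction`, `n`, `rho`,
#'   `p_value`, `method`, `strong`, `significant`, `p_holm`,
#'   `n_excluded`.
#' @export
linkage_suite <- function(bia_scores, summaries) {
  check_columns(bia_scores, c("company_id", "product_formulation", "promotion"),
                what = "bia_scores")
  check_columns(summaries, c("company_id", "pct_AB", "pct_DE", "pct_upf",
                             "pct_not_permitted", "median_class"),
                what = "summaries")
  merged <- merge(bia_scores, summaries, by = "company_id")
  if (nrow(merged) == 0L) fb_stop("join of scores and summaries is empty")
  merged$median_class_num <- as.integer(factor(merged$median_class,
                                               levels = c("A", "B", "C", "D", "E")))
  n_all <- nrow(merged)
  if (!is.null(merged$reported)) {
    merged <- merged[merged$reported, , drop = FALSE]
  }
  pairs <- .linkage_pairings()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    dom <- pairs$domain[i]; ind <- pairs$indicator[i]
    x <- merged[[dom]]; y <- merged[[ind]]
    keep <- !is.na(x) & !is.na(y)
    res <- if (sum(keep) >= 3L) spearman_test(x[keep], y[keep]) else
      list(rho = NA_real_, p_value = NA_real_, n = sum(keep),
           method = "undefined", strong = NA, significant = NA)
    data.frame(domain = dom, indicator = ind, direction = pairs$direction[i],
               n = res$n, rho = res$rho, p_value = res$p_value,
               method = res$method, strong = res$strong,
               significant = res$significant,
               n_excluded = n_all - sum(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # extension beyond the benchmark convention: Holm-adjusted p-values
  def <- !is.na(out$p_value)
  out$p_holm <- NA_real_
  out$p_holm[def] <- stats::p.adjust(out$p_value[def], method = "holm")
  out
}
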