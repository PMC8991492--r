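## BIA-Obesity commitment scoring: indicator-level raw/max scores are
## aggregated to per-domain percentages, then to a weighted overall score
## per company, with industry-specific domain weights.

#' The six BIA-Obesity policy domains
#' @export
bia_domains <- c("corporate_strategy", "product_formulation",
                 "nutrition_labelling", "promotion", "accessibility",
                 "relationships")

#' The three benchmarked food industries
#' @export
industries <- c("manufacturer", "supermarket", "quick_service")

#' Default domain weight table
#'
#' The weights recommended for the published tool are distributed as
#' supplementary material and are not part of this package; the shipped
#' default is uniform (1/6 per domain for every industry) and is clearly
#' illustrative.  Provide a study-specific table to [bia_overall_score()]
#' for a faithful reproduction.
#'
#' @return data.frame with columns `industry`, `domain`, `weight`; weights
#'   sum to 1 within each industry.
#' @export
default_domain_weights <- function() {
  expand.grid(industry = industries, domain = bia_domains,
              stringsAsFactors = FALSE)[, c("industry", "domain")] |>
    transform(weight = 1 / length(bia_domains))
}

validate_weights <- function(weights) {
  check_columns(weights, c("industry", "domain", "weight"),
                what = "weight table")
  if (any(weights$weight < 0)) fb_stop("weight table contains negative weights")
  sums <- tapply(weights$weight, weights$industry, sum)
  bad <- abs(sums - 1) > 1e-9
  if (any(bad)) {
    fb_stop("weights for industry '%s' sum to %.6f, not 1",
            names(sums)[bad][[1L]], sums[bad][[1L]])
  }
  weights
}

validate_sheet <- function(sheet) {
  check_columns(sheet, c("company_id", "domain", "indicator_id",
                         "raw", "max", "applicable"),
                what = "commitment sheet")
  bad_dom <- setdiff(unique(sheet$domain), bia_domains)
  if (length(bad_dom) > 0L) {
    fb_stop("commitment sheet has unknown domain '%s'", bad_dom[[1L]])
  }
  app <- sheet$applicable
  if (any(app & (sheet$raw < 0 | sheet$raw > sheet$max))) {
    fb_stop("commitment sheet has raw scores outside [0, max]")
  }
  sheet
}

#' Per-domain BIA-Obesity score
#'
#' `100 * sum(raw) / sum(max)` over the applicable indicators of one
#' domain.  Inapplicable indicators are excluded from both sums.  A domain
#' whose indicators are all inapplicable has an undefined score, returned
#' as `NA` (never imputed as 0, which would penalise inapplicability).
#'
#' @param sheet commitment sheet data.frame for a single company (columns
#'   `company_id`, `domain`, `indicator_id`, `raw`, `max`, `applicable`).
#' @param domain one of [bia_domains].
#' @return percentage in \[0, 100\], or `NA` when undefined.
#' @export
bia_domain_score <- function(sheet, domain) {
  sheet <- validate_sheet(sheet)
  if (!domain %in% sheet$domain) fb_stop("domain '%s' not present in sheet", domain)
  rows <- sheet[sheet$domain == domain & sheet$applicable, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA_real_)
  100 * sum(rows$raw) / sum(rows$max)
}

#' All six domain scores for one company sheet
#' @inheritParams bia_domain_score
#' @return named numeric vector over [bia_domains] (NA = undefined).
#' @export
bia_domain_scores <- function(sheet) {
  sheet <- validate_sheet(sheet)
  miss <- setdiff(bia_domains, unique(sheet$domain))
  if (length(miss) > 0L) {
    fb_stop("commitment sheet is missing domain '%s'", miss[[1L]])
  }
  vapply(bia_domains, function(d) bia_domain_score(sheet, d), numeric(1))
}

#' Weighted overall BIA-Obesity score
#'
#' Weighted mean of the six domain scores using the industry's domain
#' weights.  Domains with undefined scores are dropped and the remaining
#' weights renormalised (logged via a message); the result is always a
#' convex combination of the defined domain scores.
#'
#' @param domain_scores named numeric vector as returned by
#'   [bia_domain_scores()].
#' @param industry one of [industries].
#' @param weights weight table (see [default_domain_weights()]).
#' @return percentage in \[0, 100\].
#' @export
bia_overall_score <- function(domain_scores, industry,
                              weights = default_domain_weights()) {
  weights <- validate_weights(weights)
  w <- weights[weights$industry == industry, , drop = FALSE]
  if (nrow(w) == 0L) fb_stop("no weights defined for industry '%s'", industry)
  wv <- w$weight[match(bia_domains, w$domain)]
  if (any(is.na(wv))) fb_stop("weights for industry '%s' do not cover all domains", industry)
  sc <- domain_scores[bia_domains]
  def <- !is.na(sc)
  if (!any(def)) fb_stop("all domain scores undefined; overall score cannot be computed")
  if (!all(def)) {
    message(sprintf("renormalising weights over %d defined domains", sum(def)))
  }
  wv <- wv[def] / sum(wv[def])
  if (abs(sum(wv) - 1) > 1e-9) fb_stop("weights do not sum to 1 after renormalization")
  sum(wv * sc[def])
}

#' Score all companies in a commitments table
#'
#' @param commitments long-format table: `company_id`, `industry`, `stage`,
#'   `domain`, `indicator_id`, `raw`, `max`, `applicable`.
#' @param weights weight table.
#' @param stage which sheet to score: `"verified"` (default) or
#'   `"public_only"`; ignored when the table carries no `stage` column.
#' @return data.frame: one row per company with the six domain score
#'   columns and `overall`.
#' @export
score_commitments <- function(commitments, weights = default_domain_weights(),
                              stage = "verified") {
  if (!is.null(commitments$stage)) {
    commitments <- commitments[commitments$stage == stage, , drop = FALSE]
    if (nrow(commitments) == 0L) fb_stop("no commitment rows for stage '%s'", stage)
  }
  check_columns(commitments, "industry", what = "commitments")
  validate_sheet(commitments)
  weights <- validate_weights(weights)
  ids <- unique(commitments$company_id)
  # vectorised domain scores: sum raw and max per company x domain over
  # applicable indicators (same arithmetic as bia_domain_score)
  app <- commitments[commitments$applicable, , drop = FALSE]
  key <- interaction(factor(app$company_id, levels = ids),
                     factor(app$domain, levels = bia_domains), drop = FALSE)
  sum_raw <- tapply(app$raw, key, sum)
  sum_max <- tapply(app$max, key, sum)
  dmat <- matrix(100 * sum_raw / sum_max, nrow = length(ids),
                 dimnames = list(ids, bia_domains))
  present <- table(factor(commitments$company_id, levels = ids),
                   factor(commitments$domain, levels = bia_domains))
  if (any(present == 0)) {
    fb_stop("commitment sheet is missing domain '%s'",
            bia_domains[which(colSums(present == 0) > 0)][[1L]])
  }
  industry <- commitments$industry[match(ids, commitments$company_id)]
  overall <- vapply(seq_along(ids), function(i)
    bia_overall_score(dmat[i, ], industry[i], weights), numeric(1))
  out <- data.frame(company_id = ids, industry = industry,
                    as.data.frame(dmat), overall = overall,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pre/post engagement comparison (one-sided signed-rank)
#'
#' Compares overall scores before and after company engagement with a
#' one-sided Wilcoxon signed-rank test of post > pre.  Zero differences
#' are dropped by default (see [wilcoxon_signed_rank()]).
#'
#' @param pre,post numeric score vectors for the same companies, in the
#'   same order (or named identically; names are aligned).
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return see [wilcoxon_signed_rank()].
#' @export
engagement_effect <- function(pre, post, ...) {
  if (!is.null(names(pre)) && !is.null(names(post))) {
    if (!setequal(names(pre), names(post))) {
      fb_stop("pre and post scores must cover the same companies")
    }
    post <- post[names(pre)]
  }
  wilcoxon_signed_rank(pre, post, alternative = "greater", ...)
}

#' Participant vs non-participant comparison (two-sided rank-sum)
#'
#' @param participant_scores,nonparticipant_scores numeric score vectors.
#' @param ... passed to [wilcoxon_rank_sum()].
#' @return see [wilcoxon_rank_sum()].
#' @export
participation_gap <- function(participant_scores, nonparticipant_scores, ...) {
  wilcoxon_rank_sum(participant_scores, nonparticipant_scores,
                    alternative = "two.sided", ...)
}
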