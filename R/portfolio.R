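## Per-company performance indicators computed from profiled portfolios.

.class_levels <- c("A", "B", "C", "D", "E")

## ordinal median of Nutri-Score classes (A=1..E=5); even-n midpoint rounds
## toward the less healthy class (ceiling)
median_class <- function(klass) {
  code <- sort(as.integer(factor(as.character(klass), levels = .class_levels)))
  n <- length(code)
  med <- if (n %% 2 == 1L) code[(n + 1L) / 2L] else {
    lo <- code[n / 2L]; hi <- code[n / 2L + 1L]
    as.integer(ceiling((lo + hi) / 2))
  }
  factor(.class_levels[med], levels = .class_levels)
}

#' Summarise one company's profiled portfolio
#'
#' Computes the portfolio performance indicators: ordinal median
#' Nutri-Score class (even-n ties round toward the less healthy class),
#' percentage of products in classes A/B and D/E, percentage
#' ultra-processed (NOVA 4), percentage not-permitted to be marketed to
#' children, and percentage displaying the Nutri-Score on pack.
#' Portfolios below `min_size` products are flagged (`reported = FALSE`)
#' rather than summarised into the benchmark, mirroring the exclusion of
#' marginal portfolios from reported results.
#'
#' @param profiled data.frame for one company as returned by
#'   [profile_products()] (columns `klass`, `is_upf`, `permitted`; optional
#'   `displays_nutriscore`, `company_id`).
#' @param min_size minimum portfolio size for reporting (default 3).
#' @return one-row data.frame with `company_id`, `n_products`,
#'   `median_class`, `pct_AB`, `pct_C`, `pct_DE`, `pct_upf`,
#'   `pct_not_permitted`, `pct_displaying_label`, `reported`.
#' @export
summarize_portfolio <- function(profiled, min_size = 3L) {
  if (is.null(profiled) || nrow(profiled) == 0L) {
    fb_stop("summarize_portfolio refused: empty portfolio")
  }
  check_columns(profiled, c("klass", "is_upf", "permitted"),
                what = "profiled portfolio")
  n <- nrow(profiled)
  kl <- as.character(profiled$klass)
  pct <- function(x) 100 * sum(x) / n
  disp <- profiled$displays_nutriscore %||% rep(NA, n)
  data.frame(
    company_id = (profiled$company_id %||% NA_character_)[[1L]],
    n_products = n,
    median_class = as.character(median_class(profiled$klass)),
    median_score = stats::median(profiled$final_score %||% NA_integer_),
    pct_AB = pct(kl %in% c("A", "B")),
    pct_C = pct(kl == "C"),
    pct_DE = pct(kl %in% c("D", "E")),
    pct_upf = pct(profiled$is_upf),
    pct_not_permitted = pct(!profiled$permitted),
    pct_displaying_label = if (all(is.na(disp))) NA_real_ else pct(disp %in% TRUE),
    reported = n >= min_size,
    stringsAsFactors = FALSE
  )
}

#' Summarise every company in a profiled product table
#'
#' @param profiled profiled product table with a `company_id` column.
#' @param min_size minimum portfolio size for reporting.
#' @return data.frame with one row per company (see
#'   [summarize_portfolio()]), ordered by `company_id`.
#' @export
summarize_portfolios <- function(profiled, min_size = 3L) {
  check_columns(profiled, "company_id", what = "profiled products")
  parts <- split(profiled, profiled$company_id)
  out <- do.call(rbind, lapply(parts[sort(names(parts))], summarize_portfolio,
                               min_size = min_size))
  rownames(out) <- NULL
  out
}

#' Aggregate portfolio indicators across companies of one industry
#'
#' Median, minimum and maximum of each indicator across the reported
#' companies of the given industry (the paper-style "median (range)"
#' aggregation).
#'
#' @param summaries output of [summarize_portfolios()], carrying an
#'   `industry` column.
#' @param industry one of [industries], or `"all"`.
#' @return data.frame with one row per indicator: `indicator`, `median`,
#'   `min`, `max`, `n_companies`.
#' @export
aggregate_industry <- function(summaries, industry) {
  check_columns(summaries, "industry", what = "summaries")
  if (industry != "all") {
    if (!industry %in% summaries$industry) {
      fb_stop("no summaries for industry '%s'", industry)
    }
    summaries <- summaries[summaries$industry == industry, , drop = FALSE]
  }
  if (!is.null(summaries$reported)) {
    summaries <- summaries[summaries$reported, , drop = FALSE]
  }
  if (nrow(summaries) == 0L) fb_stop("no reportable summaries for industry '%s'", industry)
  inds <- c("pct_AB", "pct_DE", "pct_upf", "pct_not_permitted",
            "pct_displaying_label")
  inds <- intersect(inds, names(summaries))
  rows <- lapply(inds, function(ind) {
    v <- summaries[[ind]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(data.frame(indicator = ind, median = NA_real_, min = NA_real_,
                        max = NA_real_, n_companies = 0L))
    }
    data.frame(indicator = ind, median = stats::median(v), min = min(v),
               max = max(v), n_companies = length(v))
  })
  out <- do.call(rbind, rows)
  out$industry <- industry
  out
}
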