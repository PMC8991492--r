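## WHO-Europe nutrient profile model: category-specific per-100 g thresholds
## deciding whether a food may be marketed to children.  Some categories are
## prohibited outright; for the rest a product is permitted iff every active
## threshold is satisfied (inclusive "<= limit" semantics).

#' Default WHO-Europe nutrient profile rule table
#'
#' Returns the package's default encoding of the 17 food categories of the
#' WHO Regional Office for Europe nutrient profile model, with per-category
#' maxima per 100 g (energy in kJ).  Thresholds are illustrative defaults
#' that follow the structure and approximate magnitudes of the published
#' 2015 model; deployments reproducing a regulatory analysis should load a
#' verified table with [read_who_rules()] instead.  `NA` deactivates a
#' threshold (e.g. added-sugar limits when labels report only total sugars).
#'
#' @return data.frame with columns `who_category`, `label`,
#'   `always_prohibited`, `energy_kj_max`, `total_fat_g_max`,
#'   `saturated_fat_g_max`, `total_sugars_g_max`, `added_sugars_g_max`,
#'   `salt_g_max`, `no_sweeteners`.
#' @export
default_who_rules <- function() {
  df <- read.csv(system.file("extdata", "who_rules.csv", package = "foodbench"),
                 stringsAsFactors = FALSE)
  df$always_prohibited <- as.logical(df$always_prohibited)
  df$no_sweeteners <- as.logical(df$no_sweeteners)
  df
}

#' Read a WHO rule table from a delimited file
#'
#' @param path CSV file with the columns documented in
#'   [default_who_rules()].
#' @return validated rule table data.frame
#' @export
read_who_rules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_who_rules(df)
}

.who_threshold_cols <- c("energy_kj_max", "total_fat_g_max",
                         "saturated_fat_g_max", "total_sugars_g_max",
                         "added_sugars_g_max", "salt_g_max")

validate_who_rules <- function(rules) {
  check_columns(rules, c("who_category", "always_prohibited",
                         .who_threshold_cols, "no_sweeteners"),
                what = "WHO rule table")
  if (anyDuplicated(rules$who_category)) {
    fb_stop("WHO rule table has duplicated category '%s'",
            rules$who_category[duplicated(rules$who_category)][[1L]])
  }
  for (cl in .who_threshold_cols) {
    v <- rules[[cl]]
    if (any(!is.na(v) & v < 0)) {
      fb_stop("WHO rule table column '%s' contains negative limits", cl)
    }
  }
  rules$always_prohibited <- as.logical(rules$always_prohibited)
  rules$no_sweeteners <- as.logical(rules$no_sweeteners)
  has_thr <- rowSums(!is.na(rules[.who_threshold_cols])) > 0 |
    rules$no_sweeteners
  bad <- !rules$always_prohibited & !has_thr
  if (any(bad)) {
    fb_stop("WHO rule table category '%s' is neither prohibited nor carries a threshold",
            rules$who_category[bad][[1L]])
  }
  rules
}

## split an ingredient_markers field ("flavouring;colour") into tokens
split_markers <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}

#' Decide marketing-to-children permission under the WHO-Europe model
#'
#' Evaluates every active threshold of the product's WHO category and
#' returns the decision together with the complete list of violated
#' thresholds (evaluation is never short-circuited).  Threshold semantics
#' are inclusive: a value exactly at the limit passes.  Salt is taken from
#' `salt_g` when present, otherwise derived as `sodium_mg * 2.5 / 1000`.
#' Categories flagged `always_prohibited` are not-permitted with reason
#' `"category"` regardless of composition.
#'
#' @param products data.frame with columns `who_category` plus the nutrient
#'   columns required by the active thresholds of each product's category
#'   (`energy_kj`, `total_fat_g`, `saturated_fat_g`, `sugars_g`,
#'   `added_sugars_g`, `salt_g`/`sodium_mg`, `ingredient_markers`).
#' @param rules WHO rule table, see [default_who_rules()].
#' @return data.frame with `who_category`, `permitted` (logical) and
#'   `violations` (character, ";"-separated names of violated thresholds,
#'   `"category"` for prohibited categories, `""` when permitted).
#' @export
who_permitted <- function(products, rules = default_who_rules()) {
  rules <- validate_who_rules(rules)
  check_columns(products, "who_category", what = "products")
  unknown <- setdiff(unique(products$who_category), rules$who_category)
  if (length(unknown) > 0L) {
    fb_stop("unknown WHO category '%s'", unknown[[1L]])
  }
  idx <- match(products$who_category, rules$who_category)
  n <- nrow(products)

  get_val <- function(col, needed) {
    # fetch a nutrient column, erroring (not silently permitting) when a
    # product with an active threshold lacks the value
    v <- products[[col]]
    if (is.null(v)) v <- rep(NA_real_, n)
    bad <- needed & is.na(v)
    if (col == "salt_g" && any(bad)) {
      sod <- products$sodium_mg
      if (!is.null(sod)) {
        conv <- bad & !is.na(sod)
        v[conv] <- sod[conv] * 2.5 / 1000
        bad <- needed & is.na(v)
      }
    }
    if (any(bad)) {
      fb_stop("product '%s' lacks nutrient '%s' required by an active WHO threshold",
              as.character((products$product_id %||% seq_len(n))[bad][[1L]]), col)
    }
    v
  }

  thr_map <- c(energy_kj_max = "energy_kj",
               total_fat_g_max = "total_fat_g",
               saturated_fat_g_max = "saturated_fat_g",
               total_sugars_g_max = "sugars_g",
               added_sugars_g_max = "added_sugars_g",
               salt_g_max = "salt_g")

  prohibited <- rules$always_prohibited[idx]
  viol <- vector("list", n)
  for (i in which(prohibited)) viol[[i]] <- "category"

  active_any <- !prohibited
  for (tc in names(thr_map)) {
    lim <- rules[[tc]][idx]
    needed <- active_any & !is.na(lim)
    if (!any(needed)) next
    val <- get_val(thr_map[[tc]], needed)
    exceeded <- needed & val > lim
    for (i in which(exceeded)) viol[[i]] <- c(viol[[i]], tc)
  }
  ns <- rules$no_sweeteners[idx] & active_any
  if (any(ns)) {
    toks <- split_markers(products$ingredient_markers %||%
                            rep("", n))
    has_sw <- vapply(toks, function(t) "sweetener" %in% t, logical(1))
    for (i in which(ns & has_sw)) viol[[i]] <- c(viol[[i]], "sweetener_present")
  }

  violations <- vapply(viol, function(v) paste(v, collapse = ";"), character(1))
  out <- data.frame(
    who_category = products$who_category,
    permitted = violations == "",
    violations = violations,
    stringsAsFactors = FALSE
  )
  if (!is.null(products$product_id)) {
    out <- cbind(product_id = products$product_id, out)
  }
  out
}
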