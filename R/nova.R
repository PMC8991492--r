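## NOVA processing classification (groups 1-4; group 4 = ultra-processed).
## The study this package emulates hand-classified products; the automated
## classifier here is rule-based: a curated per-product override wins, then
## marker tokens typical of ultra-processed formulations, then a category
## default, then a global fallback.

#' Default NOVA classification rules
#'
#' Marker tokens characteristic of ultra-processed formulations (cosmetic
#' additives and industrial ingredients) map to group 4; category defaults
#' cover products without markers; a global fallback (group 3) closes the
#' rule set.
#'
#' @return list with elements `marker_tokens` (character vector; any of
#'   these in `ingredient_markers` implies group 4), `category_defaults`
#'   (named integer vector keyed by `who_category`) and `default_group`.
#' @export
default_nova_rules <- function() {
  list(
    marker_tokens = c("flavouring", "colour", "emulsifier", "sweetener",
                      "hydrolysed_protein", "maltodextrin",
                      "glucose_fructose_syrup", "modified_starch"),
    category_defaults = c(
      fresh_fruit_veg = 1L, fresh_meat_fish = 1L, pasta_rice_grains = 1L,
      butter_oils = 2L,
      juices = 3L, milk_drinks = 3L, yoghurts = 3L, cheese = 3L,
      bread = 3L, processed_meat = 3L, processed_fruit_veg = 3L,
      confectionery = 4L, sweet_bakery = 4L, savoury_snacks = 4L,
      edible_ices = 4L, soft_drinks = 4L, energy_drinks = 4L,
      breakfast_cereals = 4L, ready_meals = 4L, sauces = 4L
    ),
    default_group = 3L
  )
}

validate_nova_rules <- function(rules) {
  if (!is.list(rules) || is.null(rules$default_group)) {
    fb_stop("NOVA rules must be a list with a 'default_group'")
  }
  grp <- c(rules$category_defaults, rules$default_group)
  if (any(!grp %in% 1:4)) {
    fb_stop("NOVA rule groups must be integers in 1-4")
  }
  rules
}

#' Assign NOVA processing groups
#'
#' @param products data.frame with columns `who_category`,
#'   `ingredient_markers` (";"-separated tokens, may be empty) and optional
#'   `nova_group_override` (integer 1-4 or NA; a curated label that takes
#'   precedence over all rules).
#' @param rules rule list, see [default_nova_rules()].
#' @return integer vector of NOVA groups (1-4), one per product.
#' @export
nova_group <- function(products, rules = default_nova_rules()) {
  rules <- validate_nova_rules(rules)
  n <- nrow(products)
  markers <- split_markers(products$ingredient_markers %||% rep("", n))
  has_upf_marker <- vapply(
    markers, function(t) any(t %in% rules$marker_tokens), logical(1))

  cat_default <- rules$category_defaults[
    as.character(products$who_category %||% rep(NA_character_, n))]
  cat_default[is.na(cat_default)] <- rules$default_group

  group <- ifelse(has_upf_marker, 4L, as.integer(cat_default))

  override <- products$nova_group_override %||% rep(NA_integer_, n)
  if (any(!is.na(override) & !override %in% 1:4)) {
    fb_stop("nova_group_override outside 1-4")
  }
  ifelse(is.na(override), group, as.integer(override))
}

#' Profile products under all three nutrient-profile systems
#'
#' Convenience wrapper running [nutri_score()], [who_permitted()] and
#' [nova_group()] on a product table and returning one row per product with
#' all three classifications plus the Nutri-Score points breakdown.
#'
#' @param products product table (see [nutri_score()] and
#'   [who_permitted()] for required columns).
#' @param who_rules WHO rule table.
#' @param nova_rules NOVA rule list.
#' @return data.frame: product identifiers, Nutri-Score breakdown and class,
#'   WHO `permitted` flag and `violations`, `nova` group and `is_upf`.
#' @export
profile_products <- function(products,
                             who_rules = default_who_rules(),
                             nova_rules = default_nova_rules()) {
  ns <- nutri_score(products)
  who <- who_permitted(products, who_rules)
  nova <- nova_group(products, nova_rules)
  out <- cbind(
    products[intersect(c("product_id", "company_id", "name", "who_category",
                         "displays_nutriscore"), names(products))],
    ns[setdiff(names(ns), "product_id")],
    permitted = who$permitted,
    violations = who$violations,
    nova = nova,
    is_upf = nova == 4L
  )
  rownames(out) <- NULL
  out
}
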