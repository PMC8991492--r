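## Nutri-Score points model (2017 Sante Publique France algorithm, the
## version in force in Belgium 2019-2020; NOT the 2023 revision).
##
## Unfavourable ("negative") points N: energy, total sugars, saturated fat,
## sodium -- each 0-10, one point per threshold strictly exceeded.
## Favourable ("positive") points: fruit/veg/nuts %, fibre (AOAC), protein.
## Foods and beverages use different energy/sugars/fruit-veg tables; added
## fats replace saturated-fat points with a saturated/total fat ratio scale;
## waters are always class A.

# threshold tables ----------------------------------------------------------

.ns_thresholds <- list(
  food = list(
    energy_kj = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350),
    sugars_g  = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
    satfat_g  = 1:10,
    sodium_mg = seq(90, 900, by = 90),
    fibre_g   = c(0.9, 1.9, 2.8, 3.7, 4.7),
    protein_g = c(1.6, 3.2, 4.8, 6.4, 8.0)
  ),
  beverage = list(
    energy_kj = seq(0, 270, by = 30),
    sugars_g  = seq(0, 13.5, by = 1.5)
  ),
  # saturated-fat / total-fat ratio scale for added fats; a point is scored
  # when the percentage reaches the bound (>=), matching the official
  # 10-<16, 16-<22, ... >=64 bands
  fat_ratio_pct = seq(10, 64, by = 6)
)

.pts_gt <- function(x, thr) {
  # points = number of thresholds strictly exceeded
  rowSums(outer(x, thr, ">"))
}

.pts_ge <- function(x, thr) {
  rowSums(outer(x, thr, ">="))
}

.fv_points <- function(fv, beverage) {
  # fruit/veg/nuts percentage bands; beverages score double (max 10)
  base <- ifelse(fv > 80, 5L, ifelse(fv > 60, 2L, ifelse(fv > 40, 1L, 0L)))
  ifelse(beverage, 2L * base, base)
}

#' Classify products with the Nutri-Score points model
#'
#' Computes the full Nutri-Score points breakdown and final class (A-E) for
#' each product, using the 2017 algorithm: per-100 g/ml thresholds for
#' unfavourable nutrients (energy, sugars, saturated fat, sodium) and
#' favourable components (fruit/vegetables/nuts, fibre, protein), separate
#' beverage tables, the added-fat saturated/total-fat ratio scale, the
#' water-is-A rule, and the protein-exclusion rule (protein points are not
#' counted when N >= 11 unless the product is a cheese or scores maximal
#' fruit/veg points).
#'
#' @param products data.frame with one row per product.  Required columns:
#'   `energy_kj`, `sugars_g`, `saturated_fat_g`, `sodium_mg`, `fibre_g`,
#'   `protein_g`, `fruit_veg_pct` (all per 100 g/ml, non-negative) and the
#'   logical flags `is_beverage`, `is_cheese`, `is_added_fat`, `is_water`.
#'   `total_fat_g` is required for added fats.  A missing `fruit_veg_pct`
#'   (NA) is imputed as 0 with a warning (conservative).
#' @return data.frame with one row per product: points for each component
#'   (`energy_pts`, `sugars_pts`, `satfat_pts`, `sodium_pts`, `fv_pts`,
#'   `fibre_pts`, `protein_pts`), the negative total `n_points`, the final
#'   score `final_score`, `protein_counted`, and the class `klass`
#'   (factor A-E).
#' @examples
#' p <- data.frame(energy_kj = 0, sugars_g = 0, saturated_fat_g = 0,
#'                 total_fat_g = 0, sodium_mg = 0, fibre_g = 0,
#'                 protein_g = 0, fruit_veg_pct = 100,
#'                 is_beverage = FALSE, is_cheese = FALSE,
#'                 is_added_fat = FALSE, is_water = FALSE)
#' nutri_score(p)$klass  # "A"
#' @export
nutri_score <- function(products) {
  req <- c("energy_kj", "sugars_g", "saturated_fat_g", "sodium_mg",
           "fibre_g", "protein_g")
  check_columns(products, c(req, "is_beverage"), what = "products")
  for (fl in c("is_cheese", "is_added_fat", "is_water")) {
    if (is.null(products[[fl]])) products[[fl]] <- FALSE
  }
  if (is.null(products$fruit_veg_pct)) products$fruit_veg_pct <- NA_real_
  n_na <- sum(is.na(products$fruit_veg_pct))
  if (n_na > 0L) {
    fb_warn("fruit_veg_pct missing for %d product(s); imputed as 0", n_na)
    products$fruit_veg_pct[is.na(products$fruit_veg_pct)] <- 0
  }
  check_nonneg(products, req, what = "products")
  if (any(products$fruit_veg_pct < 0 | products$fruit_veg_pct > 100)) {
    fb_stop("products column 'fruit_veg_pct' must lie in [0, 100]")
  }
  if (any(products$is_water & !products$is_beverage)) {
    fb_stop("products flag 'is_water' requires 'is_beverage'")
  }
  if (any(products$is_cheese + products$is_added_fat + products$is_water > 1L)) {
    fb_stop("products flags 'is_cheese', 'is_added_fat', 'is_water' are mutually exclusive")
  }
  if (any(products$is_added_fat) && is.null(products$total_fat_g)) {
    fb_stop("products is missing required column 'total_fat_g' (needed for added fats)")
  }

  bev <- products$is_beverage
  thr_f <- .ns_thresholds$food
  thr_b <- .ns_thresholds$beverage

  energy_pts <- ifelse(bev,
                       .pts_gt(products$energy_kj, thr_b$energy_kj),
                       .pts_gt(products$energy_kj, thr_f$energy_kj))
  sugars_pts <- ifelse(bev,
                       .pts_gt(products$sugars_g, thr_b$sugars_g),
                       .pts_gt(products$sugars_g, thr_f$sugars_g))

  satfat_pts <- .pts_gt(products$saturated_fat_g, thr_f$satfat_g)
  if (any(products$is_added_fat)) {
    tf <- products$total_fat_g
    ratio <- ifelse(tf > 0, 100 * products$saturated_fat_g / tf, 0)
    ratio_pts <- .pts_ge(ratio, .ns_thresholds$fat_ratio_pct)
    satfat_pts <- ifelse(products$is_added_fat, ratio_pts, satfat_pts)
  }
  sodium_pts <- .pts_gt(products$sodium_mg, thr_f$sodium_mg)

  n_points <- energy_pts + sugars_pts + satfat_pts + sodium_pts

  fv_pts      <- .fv_points(products$fruit_veg_pct, bev)
  fibre_pts   <- .pts_gt(products$fibre_g, thr_f$fibre_g)
  protein_pts <- .pts_gt(products$protein_g, thr_f$protein_g)

  # protein exclusion: when N >= 11 protein only counts for cheeses or when
  # fruit/veg points are maximal for the branch (5 for foods, reported as
  # >= 5 which also covers the beverage value 10)
  protein_counted <- n_points < 11 | products$is_cheese | fv_pts >= 5
  final_score <- n_points - fv_pts - fibre_pts -
    ifelse(protein_counted, protein_pts, 0L)

  klass <- ifelse(bev,
    ifelse(products$is_water, "A",
      ifelse(final_score <= 1, "B",
        ifelse(final_score <= 5, "C",
          ifelse(final_score <= 9, "D", "E")))),
    ifelse(final_score <= -1, "A",
      ifelse(final_score <= 2, "B",
        ifelse(final_score <= 10, "C",
          ifelse(final_score <= 18, "D", "E")))))

  out <- data.frame(
    energy_pts = as.integer(energy_pts),
    sugars_pts = as.integer(sugars_pts),
    satfat_pts = as.integer(satfat_pts),
    sodium_pts = as.integer(sodium_pts),
    n_points = as.integer(n_points),
    fv_pts = as.integer(fv_pts),
    fibre_pts = as.integer(fibre_pts),
    protein_pts = as.integer(protein_pts),
    protein_counted = protein_counted,
    final_score = as.integer(final_score),
    klass = factor(klass, levels = c("A", "B", "C", "D", "E")),
    stringsAsFactors = FALSE
  )
  if (!is.null(products$product_id)) {
    out <- cbind(product_id = products$product_id, out)
  }
  out
}
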