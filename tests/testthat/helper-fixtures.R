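# Hand-scored Nutri-Score oracle panel.  Every expected value was computed
# by hand from the published 2017 points tables (thresholds strictly
# exceeded; added-fat ratio bands inclusive at the lower bound) and frozen
# here.  Covers: general foods, beverages, water, cheese, added fats, the
# N>=11 protein-exclusion rule on and off, and all five classes.

nutriscore_panel <- function() {
  tab <- read.table(header = TRUE, text = "
name              bev   cheese fat   water  e      s     tf   sf   na    fib  pr   fv   N  score class pc
fv100_food        FALSE FALSE  FALSE FALSE  0      0     0    0    0     0    0    100  0  -5    A     TRUE
water             TRUE  FALSE  FALSE TRUE   0      0     0    0    0     0    0    0    0  0     A     TRUE
worst_food        FALSE FALSE  FALSE FALSE  4000   50    25   20   2000  0    0    0    40 40    E     FALSE
cheese_n15        FALSE TRUE   FALSE FALSE  1600   1     30   12   100   0    25   0    15 10    C     TRUE
noncheese_n15     FALSE FALSE  FALSE FALSE  1600   1     30   12   100   0    25   0    15 15    D     FALSE
fv85_highN        FALSE FALSE  FALSE FALSE  2000   20    6    3    270   2    10   85   13 1     B     TRUE
border_A          FALSE FALSE  FALSE FALSE  300    4.5   1    1    90    1.0  0    0    0  -1    A     TRUE
all_zero          FALSE FALSE  FALSE FALSE  0      0     0    0    0     0    0    0    0  0     B     TRUE
border_C          FALSE FALSE  FALSE FALSE  0      14    0    0    0     0    0    0    3  3     C     TRUE
border_D          FALSE FALSE  FALSE FALSE  3400   5     0    0    0     0    0    0    11 11    D     FALSE
border_E          FALSE FALSE  FALSE FALSE  0      0     11   10   910   0    0    0    19 19    E     FALSE
fibre_protein_A   FALSE FALSE  FALSE FALSE  1010   4.6   0    0    0     5.0  1.7  0    4  -2    A     TRUE
soda_E            TRUE  FALSE  FALSE FALSE  180    8     0    0    0     0    0    0    12 12    E     FALSE
bev_B             TRUE  FALSE  FALSE FALSE  25     0     0    0    0     0    0    0    1  1     B     TRUE
bev_C             TRUE  FALSE  FALSE FALSE  0      3.5   0    0    0     0    0    0    3  3     C     TRUE
bev_D             TRUE  FALSE  FALSE FALSE  0      9.5   0    0    0     0    0    0    7  7     D     TRUE
juice             TRUE  FALSE  FALSE FALSE  190    9     0.1  0    5     0.5  0.5  100  13 3     C     TRUE
butter            FALSE FALSE  TRUE  FALSE  3000   0.6   82   52   20    0    0.5  0    17 17    D     FALSE
olive_oil         FALSE FALSE  TRUE  FALSE  3400   0     100  14   0     0    0    0    11 11    D     FALSE
margarine         FALSE FALSE  TRUE  FALSE  2200   0     60   16   500   0    0    0    14 14    D     FALSE
salmon            FALSE FALSE  FALSE FALSE  900    0     10   3    50    0    20   0    4  -1    A     TRUE
yoghurt_sweet     FALSE FALSE  FALSE FALSE  400    12    3    2    60    0    3.5  0    4  2     B     TRUE
pizza             FALSE FALSE  FALSE FALSE  1000   3     8    5    600   2.5  11   20   12 10    C     FALSE
muesli            FALSE FALSE  FALSE FALSE  1600   16    4    2    10    8    9    45   8  -3    A     TRUE
crisps            FALSE FALSE  FALSE FALSE  2200   0.8   30   4    600   4    6    0    15 11    D     FALSE
soft_cheese       FALSE TRUE   FALSE FALSE  1100   3     15   6    300   0    9    0    11 6     C     TRUE
dark_chocolate    FALSE FALSE  FALSE FALSE  2300   29    30   18   20    7    8    0    22 17    D     FALSE
bev_fv50          TRUE  FALSE  FALSE FALSE  100    4     0    0    0     0    0    50   7  5     C     TRUE
")
  data.frame(
    product_id = tab$name,
    is_beverage = tab$bev, is_cheese = tab$cheese,
    is_added_fat = tab$fat, is_water = tab$water,
    energy_kj = tab$e, sugars_g = tab$s, total_fat_g = tab$tf,
    saturated_fat_g = tab$sf, sodium_mg = tab$na,
    fibre_g = tab$fib, protein_g = tab$pr, fruit_veg_pct = tab$fv,
    exp_N = tab$N, exp_score = tab$score, exp_class = tab$class,
    exp_protein_counted = tab$pc,
    stringsAsFactors = FALSE
  )
}

# toy WHO rule table for boundary tests
toy_who_rules <- function() {
  data.frame(
    who_category = c("catX", "catBan", "catSweet"),
    label = c("toy thresholds", "prohibited", "sweetener rule"),
    always_prohibited = c(FALSE, TRUE, FALSE),
    energy_kj_max = NA_real_,
    total_fat_g_max = NA_real_,
    saturated_fat_g_max = NA_real_,
    total_sugars_g_max = c(10, NA, NA),
    added_sugars_g_max = NA_real_,
    salt_g_max = c(1, NA, NA),
    no_sweeteners = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

toy_product <- function(who_category = "catX", sugars = 0, salt = NA,
                        sodium = 0, markers = "") {
  data.frame(product_id = "p1", who_category = who_category,
             energy_kj = 0, total_fat_g = 0, saturated_fat_g = 0,
             sugars_g = sugars, salt_g = salt, sodium_mg = sodium,
             ingredient_markers = markers, stringsAsFactors = FALSE)
}

# minimal commitment sheet: one company, all six domains
toy_sheet <- function(raw = rep(3, 6), max = rep(5, 6),
                      applicable = rep(TRUE, 6), company_id = "c1",
                      industry = "manufacturer") {
  data.frame(company_id = company_id, industry = industry,
             domain = foodbench::bia_domains,
             indicator_id = paste0(foodbench::bia_domains, "_1"),
             raw = raw, max = max, applicable = applicable,
             stringsAsFactors = FALSE)
}

# random grid geo scene with k outlets / schools, for oracle comparisons
random_grid_scene <- function(rows, cols, n_outlets, n_primary, n_secondary,
                              spacing = 100) {
  nodes <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  nodes <- data.frame(node_id = sprintf("n%d_%d", nodes$r, nodes$c),
                      x = (nodes$c - 1) * spacing, y = (nodes$r - 1) * spacing,
                      stringsAsFactors = FALSE)
  idx <- function(r, c) (c - 1L) * rows + r
  h <- expand.grid(r = seq_len(rows), c = seq_len(cols - 1L))
  v <- expand.grid(r = seq_len(rows - 1L), c = seq_len(cols))
  edges <- rbind(
    data.frame(from = nodes$node_id[idx(h$r, h$c)],
               to = nodes$node_id[idx(h$r, h$c + 1L)]),
    data.frame(from = nodes$node_id[idx(v$r, v$c)],
               to = nodes$node_id[idx(v$r + 1L, v$c)]))
  edges$length_m <- spacing * (1 + stats::runif(nrow(edges), 0, 0.2))
  # randomly drop a few edges so disconnection can occur
  if (nrow(edges) > 8 && stats::runif(1) < 0.3) {
    edges <- edges[-sample(nrow(edges), 3), , drop = FALSE]
  }
  pts <- rbind(
    data.frame(point_id = paste0("o", seq_len(n_outlets)), kind = "outlet",
               company_id = "qs1", level = NA_character_,
               node_id = sample(nodes$node_id, n_outlets, replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(point_id = paste0("sp", seq_len(n_primary)), kind = "school",
               company_id = NA_character_, level = "primary",
               node_id = sample(nodes$node_id, n_primary, replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(point_id = paste0("ss", seq_len(n_secondary)), kind = "school",
               company_id = NA_character_, level = "secondary",
               node_id = sample(nodes$node_id, n_secondary, replace = TRUE),
               stringsAsFactors = FALSE))
  geo_scene(nodes, edges, pts)
}

# one linkage replicate on a fresh synthetic study (products + commitments)
linkage_replicate <- function(seed, coupling, noise_sd = 0.3, ...) {
  cfg <- study_config(coupling = coupling, noise_sd = noise_sd, seed = seed, ...)
  st <- generate_study(cfg, components = c("products", "commitments"))
  prof <- profile_products(st$products)
  summ <- summarize_portfolios(prof)
  summ$industry <- st$truth$industry[match(summ$company_id, st$truth$company_id)]
  bia <- score_commitments(st$commitments, stage = "verified")
  list(linkage = linkage_suite(bia, summ), truth = st$truth,
       summaries = summ, bia = bia)
}
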