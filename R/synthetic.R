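## Synthetic study generator.
##
## Every company gets a latent healthiness theta ~ N(0,1).  A single
## coupling parameter c in [-1,1] ties theta to (a) the company's
## commitment scores and (b) its portfolio composition: both sides receive
## latent value c*theta + sqrt(1-c^2)*noise, so c = 0 makes commitments and
## practices independent (the null world) and |c| = 1 makes them perfectly
## rank-coupled.  The implied population Spearman correlation between a
## domain score and a continuous portfolio indicator is approximately
## (6/pi)*asin(c^2/2) (Gaussian-copula identity), which the generator
## records as `rho_target` in the ground-truth table.
##
## noise_sd scales all idiosyncratic variation below the company latents
## (indicator-level score wobble, company-specific category-mix tilt,
## product-level nutrient draws).  noise_sd = 0 collapses the generator to
## a fully deterministic world: equal portfolio sizes, the global category
## mix, and per-category quantile grids instead of random draws -- so with
## coupling 1 rankings by commitment and by portfolio healthiness agree
## exactly.

# per-category composition model ------------------------------------------

## median per-100g composition, flags and marker probability per category;
## categories are keyed by WHO-model category id (plus bottled water)
.category_params <- function() {
  p <- read.csv(system.file("extdata", "category_params.csv",
                            package = "foodbench"),
                stringsAsFactors = FALSE)
  for (fl in c("is_beverage", "is_cheese", "is_added_fat", "is_water")) {
    p[[fl]] <- as.logical(p[[fl]])
  }
  p
}

.default_category_mix <- function() {
  p <- .category_params()
  w <- p$weight_raw / sum(p$weight_raw)
  names(w) <- p$category
  w
}

#' Study configuration for the synthetic generator
#'
#' @param n_companies named integer vector: companies per industry
#'   (defaults mirror the benchmarked panel: 19 manufacturers, 5
#'   supermarkets, 7 quick-service chains).
#' @param portfolio_size_range integer interval for portfolio sizes
#'   (default 2-300).
#' @param category_mix named weights over generator categories, summing
#'   to 1 (default: the shipped per-category weights).
#' @param coupling rank-coupling parameter in \[-1, 1\] between latent
#'   healthiness and both commitment scores and portfolio composition
#'   (default 0: the null world in which commitments and practices are
#'   unrelated).
#' @param noise_sd non-negative scale of idiosyncratic variation
#'   (default 0.3); 0 gives a deterministic world.
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical output.
#' @param n_flyer_weeks weeks of supermarket flyers (default 52).
#' @param geo list: `rows`, `cols` (grid dimensions), `spacing_m` (edge
#'   length, metres), `outlets_range` (outlets per quick-service company),
#'   `n_primary`, `n_secondary` (school counts).
#' @return validated list of class `study_config`.
#' @export
study_config <- function(n_companies = c(manufacturer = 19L, supermarket = 5L,
                                         quick_service = 7L),
                         portfolio_size_range = c(2L, 300L),
                         category_mix = .default_category_mix(),
                         coupling = 0,
                         noise_sd = 0.3,
                         seed = 1L,
                         n_flyer_weeks = 52L,
                         geo = list(rows = 20L, cols = 20L, spacing_m = 100,
                                    outlets_range = c(3L, 30L),
                                    n_primary = 25L, n_secondary = 15L)) {
  if (is.null(names(n_companies)) ||
      !setequal(names(n_companies), industries) || any(n_companies < 0)) {
    fb_stop("invalid config field 'n_companies': need non-negative counts named %s",
            paste(industries, collapse = ", "))
  }
  if (length(portfolio_size_range) != 2L || portfolio_size_range[1L] < 1L ||
      portfolio_size_range[2L] < portfolio_size_range[1L]) {
    fb_stop("invalid config field 'portfolio_size_range': need lower bound >= 1 and an ordered interval")
  }
  known <- .category_params()$category
  if (is.null(names(category_mix)) || any(!names(category_mix) %in% known)) {
    bad <- setdiff(names(category_mix) %||% "<unnamed>", known)
    fb_stop("invalid config field 'category_mix': unknown category '%s'", bad[[1L]])
  }
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-9) {
    fb_stop("invalid config field 'category_mix': weights must be non-negative and sum to 1")
  }
  if (!is.numeric(coupling) || length(coupling) != 1L ||
      is.na(coupling) || coupling < -1 || coupling > 1) {
    fb_stop("invalid config field 'coupling': must be a number in [-1, 1]")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      is.na(noise_sd) || noise_sd < 0) {
    fb_stop("invalid config field 'noise_sd': must be >= 0")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    fb_stop("invalid config field 'seed': must be a single integer")
  }
  if (n_flyer_weeks < 1L) {
    fb_stop("invalid config field 'n_flyer_weeks': must be >= 1")
  }
  for (fld in c("rows", "cols", "spacing_m", "outlets_range",
                "n_primary", "n_secondary")) {
    if (is.null(geo[[fld]])) fb_stop("invalid config field 'geo$%s': missing", fld)
  }
  structure(list(n_companies = n_companies,
                 portfolio_size_range = as.integer(portfolio_size_range),
                 category_mix = category_mix,
                 coupling = coupling, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 n_flyer_weeks = as.integer(n_flyer_weeks),
                 geo = geo),
            class = "study_config")
}

# companies ------------------------------------------------------------------

## latent companies + the two coupled latents (score side u, portfolio side v)
.generate_companies <- function(config) {
  set.seed(stage_seed(config$seed, "simulate"))
  cn <- config$n_companies
  industry <- rep(names(cn), times = cn)
  n <- length(industry)
  theta <- stats::rnorm(n)
  c_ <- config$coupling
  u <- c_ * theta + sqrt(1 - c_^2) * stats::rnorm(n)
  v <- c_ * theta + sqrt(1 - c_^2) * stats::rnorm(n)
  data.frame(
    company_id = sprintf("%s_%02d", substr(industry, 1, 3), stats::ave(
      seq_len(n), industry, FUN = seq_along)),
    industry = industry,
    theta = theta,
    u = u, v = v,
    participated = stats::runif(n) < 18 / 31,
    stringsAsFactors = FALSE
  )
}

# portfolios ------------------------------------------------------------------

## largest-remainder integer allocation of m products over mix weights
.allocate_counts <- function(m, mix) {
  raw <- m * mix
  base <- floor(raw)
  rem <- m - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate one company's product portfolio
#'
#' Nutrient values are drawn from per-category truncated log-normal
#' distributions whose location is shifted by the company's portfolio
#' latent: healthier companies draw lower energy/sugar/fat/sodium and
#' higher fibre/fruit-veg values, and carry ultra-processed marker tokens
#' less often.  With `noise_sd = 0` draws are replaced by deterministic
#' per-category quantile grids and the portfolio size and mix collapse to
#' their central values.
#'
#' @param company one-row data.frame (or list) with `company_id` and
#'   `theta`; the portfolio latent `v` defaults to `coupling * theta` when
#'   not supplied.
#' @param config a [study_config()].
#' @return product data.frame ready for [profile_products()].
#' @export
generate_portfolio <- function(company, config) {
  stopifnot(inherits(config, "study_config"))
  v <- company$v %||% (config$coupling * company$theta)
  set.seed(stage_seed(config$seed, "portfolio") %% 100000L * 19997L +
             sum(utf8ToInt(company$company_id)))
  pars <- .category_params()
  mix <- config$category_mix[match(pars$category, names(config$category_mix))]
  mix[is.na(mix)] <- 0
  ns <- config$noise_sd
  rng <- config$portfolio_size_range

  if (ns == 0) {
    m <- as.integer(round(mean(rng)))
    mix_i <- mix
  } else {
    m <- if (rng[1L] == rng[2L]) rng[1L] else
      sample(rng[1L]:rng[2L], 1L)
    # company-specific specialisation tilt on the category mix (half the
    # idiosyncratic scale: mild specialisation, so portfolio indicators
    # track the portfolio latent as the coupling contract intends)
    tilt <- exp(0.5 * ns * stats::rnorm(length(mix)))
    mix_i <- mix * tilt / sum(mix * tilt)
  }
  counts <- .allocate_counts(m, mix_i)

  shift <- 1.0 * v  # healthiness shift on the log/z scale
  sig <- 0.4
  tokens <- c("flavouring", "colour", "emulsifier", "sweetener",
              "maltodextrin", "modified_starch")

  keep <- counts > 0L
  kidx <- rep(which(keep), counts[keep])  # category row per product
  mtot <- length(kidx)
  # product-level spread: random draws, or a deterministic per-category
  # quantile grid when noise_sd = 0
  zmat <- if (ns == 0) {
    grid <- unlist(lapply(counts[keep], function(mk)
      stats::qnorm((seq_len(mk) - 0.5) / mk)))
    matrix(grid, nrow = mtot, ncol = 7)
  } else {
    matrix(stats::rnorm(mtot * 7), nrow = mtot, ncol = 7)
  }

  P <- pars[kidx, , drop = FALSE]
  bad  <- function(med, z) ifelse(med > 0, exp(log(pmax(med, 1e-12)) + sig * (z - shift)), 0)
  good <- function(med, z) ifelse(med > 0, exp(log(pmax(med, 1e-12)) + sig * (z + shift)), 0)
  water <- P$is_water
  energy <- ifelse(water, 0, bad(P$energy_med, zmat[, 1]))
  sugars <- ifelse(water, 0, bad(P$sugars_med, zmat[, 2]))
  totfat <- bad(P$totfat_med, zmat[, 3])
  satfat <- totfat * pmin(1, P$satratio * exp(0.15 * zmat[, 4]))
  sodium <- ifelse(water, 0, bad(P$sodium_med, zmat[, 5]))
  fibre  <- good(P$fibre_med, zmat[, 6])
  protein <- ifelse(P$protein_med > 0,
                    exp(log(pmax(P$protein_med, 1e-12)) + 0.25 * zmat[, 7]), 0)
  fv <- pmin(100, pmax(0, P$fv_mean + 12 * (zmat[, 6] + shift) *
                         (P$fv_mean > 0)))

  p_marker <- stats::plogis(stats::qlogis(pmin(0.99, pmax(0.01, P$marker_p))) -
                              1.0 * v)
  has_marker <- if (ns == 0) {
    # deterministic: the p_marker-quantile of the grid carries markers
    stats::pnorm(zmat[, 1]) < p_marker
  } else {
    stats::runif(mtot) < p_marker
  }
  if (ns == 0) {
    # fully deterministic token assignment, identical across companies
    tok1 <- tokens[(seq_len(mtot) - 1L) %% length(tokens) + 1L]
    markers <- ifelse(has_marker, tok1, "")
    displays <- seq_len(mtot) %% 8L == 0L
  } else {
    tok1 <- sample(tokens, mtot, replace = TRUE)
    tok2 <- sample(tokens, mtot, replace = TRUE)
    markers <- ifelse(has_marker,
                      ifelse(tok2 != tok1 & stats::runif(mtot) < 0.5,
                             paste(tok1, tok2, sep = ";"), tok1),
                      "")
    displays <- stats::runif(mtot) < 0.12
  }
  within_idx <- stats::ave(seq_len(mtot), kidx, FUN = seq_along)
  out <- data.frame(
    product_id = sprintf("%s_p%04d", company$company_id, seq_len(mtot)),
    company_id = company$company_id,
    name = paste0(P$category, "_", within_idx),
    who_category = P$who_category,
    category = P$category,
    is_beverage = P$is_beverage,
    is_cheese = P$is_cheese,
    is_added_fat = P$is_added_fat,
    is_water = P$is_water,
    energy_kj = energy,
    sugars_g = sugars,
    total_fat_g = totfat,
    saturated_fat_g = satfat,
    sodium_mg = sodium,
    fibre_g = fibre,
    protein_g = protein,
    fruit_veg_pct = fv,
    ingredient_markers = markers,
    nova_group_override = NA_integer_,
    displays_nutriscore = displays,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# commitments ------------------------------------------------------------------

## domain-specific offsets emulate the observed profile across policy
## domains (corporate strategy strongest, accessibility weakest)
.domain_offsets <- c(corporate_strategy = 0.9, product_formulation = -0.1,
                     nutrition_labelling = -0.3, promotion = -0.2,
                     accessibility = -1.8, relationships = -0.4)

.generate_commitments <- function(companies, config) {
  set.seed(stage_seed(config$seed, "commitments"))
  ns <- config$noise_sd
  n_ind <- 5L
  nc <- nrow(companies)
  # one row per company x stage x domain x indicator, fully vectorised;
  # the domain-level wobble is shared between the two stages of a company
  grid <- expand.grid(indicator = seq_len(n_ind), domain = bia_domains,
                      stage = c("public_only", "verified"),
                      company = seq_len(nc),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # verified sheets carry a uniform information-completion uplift; the
  # participation flag only selects which sheet is used in comparisons
  # (non-participants are assessed on their public_only sheet)
  base <- 1.5 * companies$u[grid$company]
  uplift <- ifelse(grid$stage == "verified", 0.7, 0)
  dom_key <- (grid$company - 1L) * length(bia_domains) +
    match(grid$domain, bia_domains)
  dom_noise <- if (ns > 0) ns * stats::rnorm(nc * length(bia_domains)) else
    numeric(nc * length(bia_domains))
  jit <- if (ns > 0) ns * stats::rnorm(nrow(grid)) else numeric(nrow(grid))
  lat <- base + uplift + .domain_offsets[grid$domain] + dom_noise[dom_key] + jit
  out <- data.frame(
    company_id = companies$company_id[grid$company],
    industry = companies$industry[grid$company],
    stage = grid$stage,
    domain = grid$domain,
    indicator_id = paste0(grid$domain, "_", grid$indicator),
    raw = 5 * stats::plogis(lat),
    max = 5,
    applicable = TRUE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# flyers ------------------------------------------------------------------

.promo_category_mix <- function() {
  # promotion-frequency mix over WHO categories, most-promoted first
  c(processed_meat = 0.118, fresh_fruit_veg = 0.095, soft_drinks = 0.090,
    sweet_bakery = 0.075, confectionery = 0.070, ready_meals = 0.070,
    cheese = 0.065, yoghurts = 0.060, savoury_snacks = 0.055, bread = 0.050,
    milk_drinks = 0.040, juices = 0.040, processed_fruit_veg = 0.040,
    sauces = 0.040, breakfast_cereals = 0.035, edible_ices = 0.025,
    butter_oils = 0.012, pasta_rice_grains = 0.010, energy_drinks = 0.005,
    fresh_meat_fish = 0.005)
}

.generate_flyers <- function(companies, config) {
  set.seed(stage_seed(config$seed, "flyers"))
  sm <- companies[companies$industry == "supermarket", , drop = FALSE]
  if (nrow(sm) == 0L) return(NULL)
  mix <- .promo_category_mix()
  mix <- mix / sum(mix)
  p_upf <- 0.52; p_cover <- 0.08
  rows <- list()
  for (i in seq_len(nrow(sm))) {
    for (w in seq_len(config$n_flyer_weeks)) {
      n_p <- max(1L, stats::rpois(1L, 58))
      cover <- stats::runif(n_p) < p_cover
      cat_w <- sample(names(mix), n_p, replace = TRUE, prob = mix)
      # cover promotions skew healthier
      upf_prob <- ifelse(cover, p_upf * 0.6, p_upf)
      is_upf <- stats::runif(n_p) < upf_prob
      nova <- ifelse(is_upf, 4L, sample(1:3, n_p, replace = TRUE))
      fresh <- cat_w == "fresh_fruit_veg" & stats::runif(n_p) < 0.8
      fresh <- fresh | (cover & stats::runif(n_p) < 0.05)
      kl <- sample(c("A", "B", "C", "D", "E"), n_p, replace = TRUE,
                   prob = c(0.12, 0.18, 0.3, 0.25, 0.15))
      rows[[length(rows) + 1L]] <- data.frame(
        supermarket_id = sm$company_id[i],
        week = w,
        placement = ifelse(cover, "cover", "inside"),
        who_category = cat_w,
        nova = nova,
        klass = kl,
        displays_nutriscore = stats::runif(n_p) < 0.02,
        has_promotional_character = stats::runif(n_p) < 0.05,
        has_premium_offer = stats::runif(n_p) < 0.20,
        is_fresh_fruit_veg = fresh,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# geo scene ------------------------------------------------------------------

.generate_geo <- function(companies, config) {
  set.seed(stage_seed(config$seed, "geo"))
  g <- config$geo
  rows <- g$rows; cols <- g$cols; sp <- g$spacing_m
  nodes <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  nodes <- data.frame(node_id = sprintf("n%03d_%03d", nodes$r, nodes$c),
                      x = (nodes$c - 1) * sp, y = (nodes$r - 1) * sp,
                      r = nodes$r, c = nodes$c, stringsAsFactors = FALSE)
  idx <- function(r, c) (c - 1L) * rows + r
  h <- expand.grid(r = seq_len(rows), c = seq_len(cols - 1L))
  v <- expand.grid(r = seq_len(rows - 1L), c = seq_len(cols))
  edges <- rbind(
    data.frame(from = nodes$node_id[idx(h$r, h$c)],
               to = nodes$node_id[idx(h$r, h$c + 1L)]),
    data.frame(from = nodes$node_id[idx(v$r, v$c)],
               to = nodes$node_id[idx(v$r + 1L, v$c)])
  )
  # road lengths exceed the straight-line spacing by a small curvature factor
  edges$length_m <- sp * (1 + stats::runif(nrow(edges), 0, 0.15))

  qs <- companies[companies$industry == "quick_service", , drop = FALSE]
  pts <- list()
  for (i in seq_len(nrow(qs))) {
    n_out <- sample(g$outlets_range[1L]:g$outlets_range[2L], 1L)
    pts[[length(pts) + 1L]] <- data.frame(
      point_id = sprintf("%s_o%02d", qs$company_id[i], seq_len(n_out)),
      kind = "outlet", company_id = qs$company_id[i], level = NA_character_,
      node_id = sample(nodes$node_id, n_out, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  for (lv in c("primary", "secondary")) {
    n_s <- if (lv == "primary") g$n_primary else g$n_secondary
    pts[[length(pts) + 1L]] <- data.frame(
      point_id = sprintf("sch_%s_%02d", substr(lv, 1, 3), seq_len(n_s)),
      kind = "school", company_id = NA_character_, level = lv,
      node_id = sample(nodes$node_id, n_s, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  points <- do.call(rbind, pts)
  geo_scene(nodes[, c("node_id", "x", "y")], edges, points)
}

# full study ------------------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Produces a bundle of company portfolios, commitment sheets, one year of
#' supermarket flyers, a road-network geo scene and a ground-truth table
#' (latent healthiness, coupling and the implied commitment-practice
#' correlation target `rho_target`).  Identical config implies
#' bit-identical output.
#'
#' @param config a [study_config()].
#' @param components subset of `c("products", "commitments", "flyers",
#'   "geo")` to generate (each component uses its own seed substream, so
#'   skipping one never changes the others).
#' @return list of class `study`: `companies`, `products`, `commitments`,
#'   `flyers`, `scene`, `truth`, `config`.
#' @export
generate_study <- function(config = study_config(),
                           components = c("products", "commitments",
                                          "flyers", "geo")) {
  stopifnot(inherits(config, "study_config"))
  companies <- .generate_companies(config)
  products <- if ("products" %in% components) {
    do.call(rbind, lapply(seq_len(nrow(companies)), function(i)
      generate_portfolio(companies[i, ], config)))
  }
  commitments <- if ("commitments" %in% components)
    .generate_commitments(companies, config)
  flyers <- if ("flyers" %in% components) .generate_flyers(companies, config)
  scene <- if ("geo" %in% components) .generate_geo(companies, config)

  truth <- data.frame(
    company_id = companies$company_id,
    industry = companies$industry,
    theta = companies$theta,
    score_latent = companies$u,
    portfolio_latent = companies$v,
    participated = companies$participated,
    coupling = config$coupling,
    rho_target = (6 / pi) * asin(config$coupling^2 / 2),
    stringsAsFactors = FALSE
  )
  structure(list(companies = companies, products = products,
                 commitments = commitments, flyers = flyers, scene = scene,
                 truth = truth, config = config),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("synthetic study: %d companies, %s products, coupling = %g, seed = %d\n",
              nrow(x$companies),
              if (is.null(x$products)) "no" else nrow(x$products),
              x$config$coupling, x$config$seed))
  invisible(x)
}

#' Write a study bundle to delimited files
#'
#' Writes `products.csv`, `commitments.csv`, `flyers.csv`,
#' `geo_nodes.csv`, `geo_edges.csv`, `geo_points.csv` and `truth.csv`
#' (UTF-8, header row, RFC-4180 quoting) into `dir`.
#'
#' @param study a [generate_study()] bundle.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  files <- character(0)
  if (!is.null(study$products)) files <- c(files, wr(study$products, "products.csv"))
  if (!is.null(study$commitments)) files <- c(files, wr(study$commitments, "commitments.csv"))
  if (!is.null(study$flyers)) files <- c(files, wr(study$flyers, "flyers.csv"))
  if (!is.null(study$scene)) {
    files <- c(files,
               wr(study$scene$nodes, "geo_nodes.csv"),
               wr(study$scene$edges, "geo_edges.csv"),
               wr(study$scene$points, "geo_points.csv"))
  }
  files <- c(files, wr(study$truth, "truth.csv"))
  invisible(files)
}
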