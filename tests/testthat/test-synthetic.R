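test_that("config validation names the offending field", {
  expect_error(study_config(coupling = 2), "coupling")
  expect_error(study_config(noise_sd = -1), "noise_sd")
  expect_error(study_config(portfolio_size_range = c(0, 10)),
               "portfolio_size_range")
  expect_error(study_config(n_companies = c(foo = 3L)), "n_companies")
  mix <- .default_category_mix <- study_config()$category_mix
  names(mix)[1] <- "unobtainium"
  expect_error(study_config(category_mix = mix), "unobtainium")
  mix2 <- study_config()$category_mix
  mix2[1] <- mix2[1] + 0.5
  expect_error(study_config(category_mix = mix2), "sum to 1")
})

test_that("same config and seed reproduce a byte-identical bundle", {
  cfg <- study_config(seed = 99, n_flyer_weeks = 4L,
                      n_companies = c(manufacturer = 3L, supermarket = 2L,
                                      quick_service = 2L),
                      portfolio_size_range = c(2L, 40L))
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(generate_study(cfg), d1)
  write_study(generate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated values respect the domain invariants", {
  st <- generate_study(study_config(seed = 3, portfolio_size_range = c(2L, 60L)))
  p <- st$products
  nutr <- c("energy_kj", "sugars_g", "total_fat_g", "saturated_fat_g",
            "sodium_mg", "fibre_g", "protein_g")
  for (cl in nutr) expect_true(all(p[[cl]] >= 0), label = cl)
  expect_true(all(p$fruit_veg_pct >= 0 & p$fruit_veg_pct <= 100))
  expect_true(all(p$saturated_fat_g <= p$total_fat_g + 1e-9))
  # every company has one sheet per stage with all six domains
  tab <- table(st$commitments$company_id, st$commitments$domain,
               st$commitments$stage)
  expect_true(all(tab > 0))
  # flyers span the configured weeks with >= 1 promotion each
  expect_equal(sort(unique(st$flyers$week)), 1:52)
  wk <- table(st$flyers$supermarket_id, st$flyers$week)
  expect_true(all(wk >= 1))
  # truth table carries the recovery targets
  expect_true(all(c("theta", "coupling", "rho_target") %in% names(st$truth)))
})

test_that("portfolio sizes respect the configured range", {
  cfg <- study_config(seed = 12, portfolio_size_range = c(1L, 1L))
  st <- generate_study(cfg, components = "products")
  expect_true(all(table(st$products$company_id) == 1))
  cfg2 <- study_config(seed = 12, portfolio_size_range = c(5L, 9L))
  st2 <- generate_study(cfg2, components = "products")
  expect_true(all(table(st2$products$company_id) >= 5 &
                    table(st2$products$company_id) <= 9))
})

test_that("theta shifts portfolios in the healthy direction", {
  cfg <- study_config(seed = 8, coupling = 1, noise_sd = 0,
                      portfolio_size_range = c(150L, 150L))
  hi <- generate_portfolio(list(company_id = "hi", theta = 3), cfg)
  lo <- generate_portfolio(list(company_id = "hi", theta = -3), cfg)  # same stream
  s_hi <- summarize_portfolio(profile_products(hi))
  s_lo <- summarize_portfolio(profile_products(lo))
  expect_lt(match(s_hi$median_class, LETTERS), match(s_lo$median_class, LETTERS))
  expect_gt(s_hi$pct_AB, s_lo$pct_AB)
  expect_lt(s_hi$pct_upf, s_lo$pct_upf)
})

test_that("a fruit/vegetable specialist is almost fully permitted", {
  mix <- study_config()$category_mix
  mix[] <- 0; mix["fresh_fruit_veg"] <- 1
  cfg <- study_config(seed = 21, category_mix = mix,
                      n_companies = c(manufacturer = 3L, supermarket = 0L,
                                      quick_service = 0L),
                      portfolio_size_range = c(50L, 50L))
  st <- generate_study(cfg, components = "products")
  prof <- profile_products(st$products)
  # qualitative direction: far fewer not-permitted products than the
  # default mixed portfolio regime (which is majority not-permitted)
  expect_lt(mean(!prof$permitted), 0.1)
  expect_lt(mean(prof$is_upf), 0.2)
})

test_that("perfect coupling with no noise aligns commitment and portfolio rankings", {
  cfg <- study_config(n_companies = c(manufacturer = 10L, supermarket = 0L,
                                      quick_service = 0L),
                      coupling = 1, noise_sd = 0, seed = 7)
  st <- generate_study(cfg, components = c("products", "commitments"))
  bia <- score_commitments(st$commitments, stage = "verified")
  summ <- summarize_portfolios(profile_products(st$products))
  m <- merge(bia, summ, by = "company_id")
  mean_dom <- rowMeans(m[, bia_domains])
  expect_equal(stats::cor(rank(mean_dom), rank(m$pct_AB)), 1)
})

test_that("coupling monotonicity: stronger coupling, stronger recovered correlation", {
  # scaled-down version of the 200-replicate sweep (12 replicates per level)
  mean_rho <- vapply(c(0, 0.4, 0.8), function(coup) {
    mean(vapply(1:12, function(s)
      abs(linkage_replicate(300 + s, coup)$linkage$rho[1]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rho) > 0))
})
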