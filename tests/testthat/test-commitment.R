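test_that("domain score arithmetic and undefined-domain signalling", {
  sheet <- rbind(toy_sheet(),
                 toy_sheet()[2, ] |> transform(indicator_id = "pf_2",
                                               raw = 1, max = 5))
  # product_formulation now has indicators 3/5 and 1/5 -> 100*4/10 = 40
  expect_equal(bia_domain_score(sheet, "product_formulation"), 40)
  full <- toy_sheet(raw = rep(5, 6))
  expect_equal(unname(bia_domain_scores(full)), rep(100, 6))
  zero <- toy_sheet(raw = rep(0, 6))
  expect_equal(unname(bia_domain_scores(zero)), rep(0, 6))
  und <- toy_sheet(applicable = c(FALSE, rep(TRUE, 5)))
  expect_true(is.na(bia_domain_score(und, "corporate_strategy")))
  bad <- toy_sheet(raw = c(9, rep(3, 5)))  # raw > max
  expect_error(bia_domain_score(bad, "promotion"), "raw")
})

test_that("overall score is a weighted convex combination with renormalization", {
  ds <- stats::setNames(rep(60, 6), bia_domains)
  expect_equal(bia_overall_score(ds, "manufacturer"), 60)
  w <- default_domain_weights()
  w <- w[w$industry == "manufacturer", ]
  w$weight <- ifelse(w$domain == "product_formulation", 0.5, 0.1)
  ds2 <- stats::setNames(c(0, 100, 0, 0, 0, 0), bia_domains)
  expect_equal(bia_overall_score(ds2, "manufacturer", w), 50)
  # undefined domain -> renormalize remaining weights
  ds3 <- stats::setNames(c(NA, rep(60, 5)), bia_domains)
  expect_message(ov <- bia_overall_score(ds3, "manufacturer"), "renormalising")
  expect_equal(ov, 60)
  # convexity on random sheets
  set.seed(1)
  for (i in 1:20) {
    ds <- stats::setNames(runif(6, 0, 100), bia_domains)
    ov <- bia_overall_score(ds, "supermarket")
    expect_gte(ov, min(ds)); expect_lte(ov, max(ds))
  }
  wbad <- w; wbad$weight[1] <- wbad$weight[1] + 0.2
  expect_error(bia_overall_score(ds2, "manufacturer", wbad), "sum")
})

test_that("scores are scale invariant and monotone in raw scores", {
  set.seed(2)
  for (i in 1:10) {
    raw <- runif(6, 0, 5)
    s1 <- toy_sheet(raw = raw)
    s2 <- toy_sheet(raw = raw * 7, max = rep(35, 6))
    expect_equal(bia_domain_scores(s1), bia_domain_scores(s2))
  }
  base <- toy_sheet(raw = rep(2, 6))
  up <- toy_sheet(raw = c(2.5, rep(2, 5)))
  expect_gt(bia_overall_score(bia_domain_scores(up), "manufacturer"),
            bia_overall_score(bia_domain_scores(base), "manufacturer"))
})

test_that("engagement effect: exact tail for uniform improvement, refusal on no change", {
  pre <- seq(10, 95, by = 5)  # n = 18
  post <- pre + 5
  res <- engagement_effect(pre, post)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 1 / 2^18)  # all-positive ranks, one-sided
  expect_error(engagement_effect(pre, pre), "non-zero pairs")
  # score vectors aligned by company name
  names(pre) <- names(post) <- paste0("c", 1:18)
  res2 <- engagement_effect(pre, rev(post)[names(pre)])
  expect_equal(res2$p_value, res$p_value)
})

test_that("participation gap: exact two-sided rank-sum conventions", {
  res <- participation_gap(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2 extreme of 20 assignments
  same <- participation_gap(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  swap <- participation_gap(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$p_value, res$p_value)
  expect_error(participation_gap(numeric(0), c(1)), "non-empty")
})
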