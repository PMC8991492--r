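make_profiled <- function(klass, upf = NULL, permitted = NULL, id = "c1") {
  n <- length(klass)
  data.frame(company_id = rep(id, n), klass = klass,
             final_score = match(klass, c("A", "B", "C", "D", "E")),
             is_upf = upf %||% rep(FALSE, n),
             permitted = permitted %||% rep(TRUE, n),
             displays_nutriscore = rep(c(TRUE, FALSE), length.out = n),
             stringsAsFactors = FALSE)
}

test_that("ordinal median class and the round-unhealthy tie rule", {
  s <- summarize_portfolio(make_profiled(c("A", "C", "E")))
  expect_equal(s$median_class, "C")
  expect_equal(s$pct_AB, 100 / 3)
  expect_equal(s$pct_DE, 100 / 3)
  # even n: {B, C} -> C (toward the less healthy class)
  expect_equal(summarize_portfolio(make_profiled(c("B", "C")), min_size = 2)$median_class, "C")
  expect_equal(summarize_portfolio(make_profiled(c("A", "B", "C", "E"), ),
                                   min_size = 2)$median_class, "C")
  # order invariance and duplication invariance
  kl <- c("E", "A", "C", "B", "D", "C", "C")
  s1 <- summarize_portfolio(make_profiled(kl))
  s2 <- summarize_portfolio(make_profiled(sample(kl)))
  s3 <- summarize_portfolio(make_profiled(rep(kl, 2)))
  expect_equal(s1$median_class, s2$median_class)
  expect_equal(s1$median_class, s3$median_class)
  expect_equal(s1$pct_AB, s3$pct_AB)
})

test_that("partition: pct_AB + pct_C + pct_DE = 100 and extremes are reachable", {
  set.seed(11)
  for (i in 1:20) {
    kl <- sample(c("A", "B", "C", "D", "E"), sample(3:40, 1), replace = TRUE)
    s <- summarize_portfolio(make_profiled(kl))
    expect_equal(s$pct_AB + s$pct_C + s$pct_DE, 100)
  }
  all4 <- summarize_portfolio(make_profiled(c("D", "E", "E"),
                                            upf = rep(TRUE, 3),
                                            permitted = rep(FALSE, 3)))
  expect_equal(all4$pct_upf, 100)
  expect_equal(all4$pct_not_permitted, 100)
})

test_that("small portfolios are flagged, empty ones refused", {
  s <- summarize_portfolio(make_profiled(c("A", "B")))
  expect_false(s$reported)
  expect_equal(s$n_products, 2L)
  expect_true(summarize_portfolio(make_profiled(c("A", "B", "C")))$reported)
  expect_error(summarize_portfolio(make_profiled(character(0))), "empty")
})

test_that("industry aggregation: median and range, order invariance, refusals", {
  summ <- rbind(
    cbind(summarize_portfolio(make_profiled(rep("C", 5), upf = rep(TRUE, 5), id = "a")),
          industry = "manufacturer"),
    cbind(summarize_portfolio(make_profiled(rep("C", 4), upf = c(TRUE, TRUE, TRUE, FALSE), id = "b")),
          industry = "manufacturer"),
    cbind(summarize_portfolio(make_profiled(rep("C", 50),
                                            upf = rep(c(TRUE, FALSE), 25), id = "c")),
          industry = "manufacturer"))
  agg <- aggregate_industry(summ, "manufacturer")
  upf <- agg[agg$indicator == "pct_upf", ]
  expect_equal(upf$median, 75)
  expect_equal(upf$min, 50)
  expect_equal(upf$max, 100)
  perm <- aggregate_industry(summ[c(3, 1, 2), ], "manufacturer")
  expect_equal(agg, perm)
  single <- aggregate_industry(summ[1, ], "manufacturer")
  u1 <- single[single$indicator == "pct_upf", ]
  expect_true(u1$median == u1$min && u1$min == u1$max)
  expect_error(aggregate_industry(summ, "quick_service"), "quick_service")
})
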