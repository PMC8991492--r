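test_that("signed-rank exact p matches sign-assignment enumeration (n <= 8)", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    pre <- round(runif(n, 0, 20), 1)
    post <- pre + round(rnorm(n, 0.5, 2), 1)
    if (sum(post - pre != 0) < 2) next
    for (alt in c("greater", "less", "two.sided")) {
      got <- wilcoxon_signed_rank(pre, post, alternative = alt)
      expect_equal(got$p_value, oracle_signrank_p(pre, post, alt),
                   tolerance = 1e-12)
      expect_equal(got$method, "exact")
    }
  }
})

test_that("signed-rank sign-flip symmetry and tie handling", {
  set.seed(5)
  pre <- runif(10); post <- pre + rnorm(10)
  pg <- wilcoxon_signed_rank(pre, post, "greater")
  pl <- wilcoxon_signed_rank(post, pre, "greater")  # flipped differences
  # P(W >= w) + P(W <= w) = 1 + P(W == w)
  expect_gte(pg$p_value + pl$p_value, 1 - 1e-12)
  # with ties in |d| the exact distribution still sums to one
  d <- c(1, 1, -1, 2, 2, -3)
  got <- wilcoxon_signed_rank(rep(0, 6), d, "two.sided")
  expect_true(got$p_value > 0 && got$p_value <= 1)
  expect_equal(got$p_value, oracle_signrank_p(rep(0, 6), d, "two.sided"))
})

test_that("rank-sum exact p matches label-assignment enumeration (N <= 8)", {
  set.seed(102)
  for (i in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:4, 1)
    if (n1 + n2 > 8) next
    x <- sample(1:6, n1, replace = TRUE)  # ties across groups likely
    y <- sample(1:6, n2, replace = TRUE)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_rank_sum(x, y, alternative = alt)
      expect_equal(got$p_value, oracle_ranksum_p(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("large-sample branches report their method and stay near the exact p", {
  set.seed(103)
  pre <- runif(30); post <- pre + rnorm(30, 0.3)
  approx <- wilcoxon_signed_rank(pre, post, exact_limit = 20L)
  exact <- wilcoxon_signed_rank(pre, post, exact_limit = 40L)
  expect_equal(approx$method, "normal_approx")
  expect_equal(exact$method, "exact")
  expect_equal(approx$p_value, exact$p_value, tolerance = 0.01)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  a2 <- wilcoxon_rank_sum(x, y, exact_limit = 20L)
  e2 <- wilcoxon_rank_sum(x, y, exact_limit = 40L)
  expect_equal(a2$method, "normal_approx")
  expect_equal(a2$p_value, e2$p_value, tolerance = 0.02)
})

test_that("spearman: trivial values, exact permutation p, invariances", {
  x <- 1:6
  expect_equal(spearman_test(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_test(x, rev(x))$rho, -1)
  r <- spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  expect_equal(r$method, "exact_permutation")
  expect_equal(r$p_value, oracle_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$p)
  # monotone-transform invariance
  set.seed(7)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(spearman_test(a, b)$rho, spearman_test(exp(a), b^3)$rho)
  # rho equals Pearson on midranks
  expect_equal(spearman_test(a, b)$rho,
               stats::cor(rank(a), rank(b)))
  # constant input -> undefined signal, not an error
  und <- spearman_test(rep(1, 5), 1:5)
  expect_equal(und$method, "undefined")
  expect_true(is.na(und$rho))
})

test_that("spearman exact p matches enumeration on random small cases", {
  set.seed(104)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- spearman_test(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("t-approximation branch for n > exact_limit reports method and flags", {
  set.seed(105)
  x <- rnorm(31); y <- 0.6 * x + rnorm(31, 0, 0.5)
  r <- spearman_test(x, y)
  expect_equal(r$method, "t_approx")
  expect_equal(r$significant, r$p_value < 0.05)
  expect_equal(r$strong, abs(r$rho) > 0.5)
})
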