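## Rank-based tests with exact small-sample p-values.
##
## All three statistics condition on the observed (mid)ranks, so ties are
## handled by the same convention in the point estimate and in the exact
## null distribution.  Midranks are multiples of 1/2; doubling them gives
## integers, so the exact distributions are computed by integer
## generating-function convolutions rather than explicit enumeration.

## distribution of W+ = sum of (doubled) ranks with positive sign over all
## 2^n equiprobable sign assignments; returns probability vector over
## support 0..sum(d)
.signrank_dist <- function(d) {
  f <- 1
  for (di in d) {
    g <- numeric(length(f) + di)
    g[seq_along(f)] <- f / 2
    g[seq_along(f) + di] <- g[seq_along(f) + di] + f / 2
    f <- g
  }
  f
}

## distribution of the (doubled) rank sum of a group of size m drawn without
## replacement from doubled midranks d (length N); conditional permutation
## distribution of the Wilcoxon rank-sum statistic
.ranksum_dist <- function(d, m) {
  total <- sum(d)
  # f[k+1, s+1] = number of k-subsets with sum s
  f <- matrix(0, nrow = m + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (di in d) {
    kmax <- m
    for (k in seq.int(kmax, 1L)) {
      src <- f[k, ]
      if (di > 0) {
        f[k + 1L, (di + 1L):(total + 1L)] <-
          f[k + 1L, (di + 1L):(total + 1L)] + src[1L:(total + 1L - di)]
      } else {
        f[k + 1L, ] <- f[k + 1L, ] + src
      }
    }
  }
  f[m + 1L, ] / choose(length(d), m)
}

#' One- or two-sample Wilcoxon signed-rank test (exact for small n)
#'
#' Tests whether paired differences `post - pre` are shifted in the given
#' direction.  Zero differences are dropped (classic Wilcoxon convention;
#' `zero_method = "pratt"` keeps them for ranking).  For `n <= exact_limit`
#' non-zero pairs the p-value is exact, computed from the conditional
#' distribution of the positive-rank sum over all sign assignments
#' (ties handled via midranks); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param pre,post numeric vectors of equal length (paired observations).
#' @param alternative `"greater"` tests post > pre; also `"less"`,
#'   `"two.sided"`.
#' @param zero_method `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit maximum n for the exact distribution (default 20).
#' @return list with `statistic` (positive-rank sum W+), `p_value`, `n`
#'   (non-zero pairs used), `n_zero` dropped, `method` ("exact" or
#'   "normal_approx"), `median_pre`, `median_post`.
#' @export
wilcoxon_signed_rank <- function(pre, post,
                                 alternative = c("greater", "less", "two.sided"),
                                 zero_method = c("wilcoxon", "pratt"),
                                 exact_limit = 20L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (length(pre) != length(post)) {
    fb_stop("'pre' and 'post' must have equal length (paired data)")
  }
  d <- post - pre
  n_zero <- sum(d == 0)
  if (zero_method == "wilcoxon") {
    d_use <- d[d != 0]
    r <- midrank(abs(d_use))
  } else {
    # Pratt: rank zeros with the rest, then discard their contribution
    r_all <- midrank(abs(d))
    keep <- d != 0
    d_use <- d[keep]
    r <- r_all[keep]
  }
  n <- length(d_use)
  if (n < 2L) {
    fb_stop("signed-rank test refused: fewer than 2 non-zero pairs (n = %d)", n)
  }
  w_plus <- sum(r[d_use > 0])

  if (n <= exact_limit) {
    d2 <- as.integer(round(2 * r))
    dist <- .signrank_dist(d2)
    w2 <- as.integer(round(2 * w_plus))
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p_le <- sum(dist[1L:(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    # variance of W+ under random signs, valid with midranks
    sigma2 <- sum(r^2) / 4
    z_num <- switch(alternative,
                    greater = w_plus - mu - 0.5,
                    less = w_plus - mu + 0.5,
                    two.sided = abs(w_plus - mu) - 0.5)
    z <- z_num / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal_approx"
  }
  list(statistic = w_plus, p_value = p, n = n, n_zero = n_zero,
       method = method,
       median_pre = stats::median(pre), median_post = stats::median(post))
}

#' Two-sample Wilcoxon rank-sum test (exact for small combined n)
#'
#' @param x,y numeric samples.  For combined n up to `exact_limit` the
#'   two-sided p-value is exact (twice the smaller conditional tail of the
#'   rank-sum permutation distribution, capped at 1); beyond that a normal
#'   approximation with tie and continuity correction is used.
#' @param alternative `"two.sided"` (default), `"greater"` (x > y),
#'   `"less"`.
#' @param exact_limit maximum combined sample size for the exact
#'   distribution (default 20).
#' @return list with `statistic` (rank sum of `x`), `p_value`, `n_x`,
#'   `n_y`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_limit = 20L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    fb_stop("rank-sum test refused: both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- midrank(c(x, y))
  w <- sum(r[seq_len(n1)])

  if (N <= exact_limit) {
    d2 <- as.integer(round(2 * r))
    dist <- .ranksum_dist(d2, n1)
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p_le <- sum(dist[1L:(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z_num <- switch(alternative,
                    greater = w - mu - 0.5,
                    less = w - mu + 0.5,
                    two.sided = abs(w - mu) - 0.5)
    z <- z_num / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal_approx"
  }
  list(statistic = w, p_value = p, n_x = n1, n_y = n2, method = method)
}

## all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact permutation p-value for small n
#'
#' Computes rho as the Pearson correlation of midranks.  For
#' `n <= exact_limit` (default 8) the two-sided p-value is the exact
#' permutation probability of `|rho| >= |rho_obs|` over all n! orderings;
#' otherwise the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#' Constant input yields an undefined-rho signal rather than an error, so
#' callers can report "no correlation could be calculated".
#'
#' @param x,y numeric vectors of equal length >= 3; ties allowed.
#' @param exact_limit maximum n for exact permutation enumeration.
#' @return list with `rho`, `p_value`, `n`, `method` ("exact_permutation",
#'   "t_approx" or "undefined"), `strong` (|rho| > 0.5) and `significant`
#'   (p < 0.05); `rho` and `p_value` are NA when undefined.
#' @export
spearman_test <- function(x, y, exact_limit = 8L) {
  if (length(x) != length(y)) fb_stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) fb_stop("spearman_test requires n >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", strong = NA, significant = NA))
  }
  rx <- midrank(x); ry <- midrank(y)
  rho <- stats::cor(rx, ry)

  if (n <= exact_limit) {
    perms <- .all_perms(n)
    cx <- rx - mean(rx)
    cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    # rho for every permutation of y-ranks against fixed x-ranks
    rho_perm <- (matrix(cy[perms], nrow(perms), n) %*% cx) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(1, p)
    method <- "t_approx"
  }
  list(rho = rho, p_value = p, n = n, method = method,
       strong = abs(rho) > 0.5, significant = p < 0.05)
}
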