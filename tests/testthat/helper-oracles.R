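# Independent brute-force oracles.  These deliberately use different
# algorithms from the package implementations (explicit enumeration and
# naive formulas) so the two routes can disagree.

# all 2^n sign assignments: one-sided exact signed-rank p (zeros dropped)
oracle_signrank_p <- function(pre, post, alternative = "greater") {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(w_all >= w_obs - 1e-9),
         less = mean(w_all <= w_obs + 1e-9),
         two.sided = min(1, 2 * min(mean(w_all >= w_obs - 1e-9),
                                    mean(w_all <= w_obs + 1e-9))))
}

# all choose(N, n1) label assignments: two-sided exact rank-sum p
oracle_ranksum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(N, n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# permutations by iterative insertion (distinct from the package's
# recursive first-element expansion)
oracle_perms <- function(n) {
  p <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    out <- matrix(0L, nrow(p) * k, k)
    row <- 0L
    for (pos in seq_len(k)) {
      block <- cbind(p[, seq_len(pos - 1L), drop = FALSE], k,
                     p[, seq.int(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
      out[row + seq_len(nrow(p)), ] <- block
      row <- row + nrow(p)
    }
    p <- out
  }
  p
}

# Spearman rho via the explicit covariance-of-ranks formula, and the exact
# two-sided permutation p by full enumeration
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  perms <- oracle_perms(n)
  cy <- ry - mean(ry)
  rho_all <- (matrix(cy[perms], nrow(perms), n) %*% (rx - mean(rx))) / den
  list(rho = rho, p = mean(abs(rho_all) >= abs(rho) - 1e-12))
}

# Floyd-Warshall all-pairs shortest paths on an undirected weighted graph
oracle_apsp <- function(node_ids, edges) {
  n <- length(node_ids)
  D <- matrix(Inf, n, n, dimnames = list(node_ids, node_ids))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$length_m[i]
    D[a, b] <- min(D[a, b], w)
    D[b, a] <- min(D[b, a], w)
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# naive WHO evaluator: checks every threshold column one by one
oracle_who <- function(product, rule_row) {
  if (isTRUE(as.logical(rule_row$always_prohibited))) return(FALSE)
  ok <- TRUE
  salt <- product$salt_g
  if (is.null(salt) || is.na(salt)) salt <- product$sodium_mg * 2.5 / 1000
  vals <- list(energy_kj_max = product$energy_kj,
               total_fat_g_max = product$total_fat_g,
               saturated_fat_g_max = product$saturated_fat_g,
               total_sugars_g_max = product$sugars_g,
               added_sugars_g_max = product$added_sugars_g,
               salt_g_max = salt)
  for (tc in names(vals)) {
    lim <- rule_row[[tc]]
    if (!is.null(lim) && !is.na(lim)) {
      if (vals[[tc]] > lim) ok <- FALSE
    }
  }
  if (isTRUE(as.logical(rule_row$no_sweeteners))) {
    toks <- strsplit(product$ingredient_markers %||% "", ";")[[1]]
    if ("sweetener" %in% toks) ok <- FALSE
  }
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a
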