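chain_scene <- function(lengths) {
  # straight chain: outlet at one end, school at the other
  n <- length(lengths) + 1
  nodes <- data.frame(node_id = paste0("n", seq_len(n)),
                      x = c(0, cumsum(lengths)), y = 0,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = paste0("n", seq_len(n - 1)),
                      to = paste0("n", 2:n), length_m = lengths,
                      stringsAsFactors = FALSE)
  pts <- data.frame(point_id = c("o1", "s1"), kind = c("outlet", "school"),
                    company_id = c("qs1", NA), level = c(NA, "primary"),
                    node_id = c("n1", paste0("n", n)),
                    stringsAsFactors = FALSE)
  geo_scene(nodes, edges, pts)
}

test_that("coincident and chain scenes give the trivial proportions", {
  sc0 <- chain_scene(c(100))
  sc0$points$node_id <- c("n1", "n1")  # outlet and school on the same node
  sc0 <- geo_scene(sc0$nodes, sc0$edges, sc0$points)
  res0 <- outlets_near_schools(sc0, "qs1", "primary", min_outlets = 1)
  expect_equal(res0$proportion, 1)
  expect_equal(res0$distances$distance_m, 0)
  # 600 m chain: beyond the 500 m radius
  res600 <- outlets_near_schools(chain_scene(c(200, 200, 200)), "qs1",
                                 "primary", min_outlets = 1)
  expect_equal(res600$proportion, 0)
  expect_equal(res600$distances$distance_m, 600)
  # within radius at 400 m
  expect_equal(outlets_near_schools(chain_scene(c(200, 200)), "qs1", "primary",
                                    min_outlets = 1)$proportion, 1)
  expect_error(outlets_near_schools(chain_scene(c(100)), "qs1", "primary",
                                    radius_m = -5), "radius")
  expect_error(outlets_near_schools(chain_scene(c(100)), "other", "primary"),
               "other")
})

test_that("scene validation rejects inconsistent inputs", {
  sc <- chain_scene(c(100, 100))
  bad_edges <- sc$edges; bad_edges$length_m[1] <- 50  # < Euclidean 100
  expect_error(geo_scene(sc$nodes, bad_edges, sc$points), "Euclidean")
  bad_pts <- sc$points; bad_pts$node_id[1] <- "nope"
  expect_error(geo_scene(sc$nodes, sc$edges, bad_pts), "unknown node_id")
  zero_edges <- sc$edges; zero_edges$length_m[1] <- 0
  expect_error(geo_scene(sc$nodes, zero_edges, sc$points), "positive")
})

test_that("proportions match the Floyd-Warshall oracle on random grids", {
  set.seed(31)
  for (i in 1:8) {
    sc <- random_grid_scene(sample(5:8, 1), sample(5:8, 1),
                            n_outlets = 6, n_primary = 4, n_secondary = 3)
    D <- oracle_apsp(sc$nodes$node_id, sc$edges)
    for (lv in c("primary", "secondary")) {
      res <- suppressWarnings(
        outlets_near_schools(sc, "qs1", lv, min_outlets = 1))
      out_nodes <- sc$points$node_id[sc$points$kind == "outlet"]
      sch_nodes <- sc$points$node_id[sc$points$kind == "school" &
                                       sc$points$level == lv]
      want <- apply(D[out_nodes, sch_nodes, drop = FALSE], 1, min)
      expect_equal(unname(res$distances$distance_m), unname(want))
      expect_equal(res$proportion, mean(is.finite(want) & want <= 500))
    }
  }
})

test_that("network distance dominates Euclidean distance", {
  set.seed(32)
  sc <- random_grid_scene(7, 7, n_outlets = 5, n_primary = 5, n_secondary = 2)
  res <- suppressWarnings(outlets_near_schools(sc, "qs1", "primary",
                                               min_outlets = 1))
  xy <- sc$nodes[match(sc$points$node_id, sc$nodes$node_id), c("x", "y")]
  out_i <- which(sc$points$kind == "outlet")
  sch_i <- which(sc$points$kind == "school" & sc$points$level == "primary")
  for (k in seq_along(out_i)) {
    eu <- min(sqrt((xy$x[out_i[k]] - xy$x[sch_i])^2 +
                     (xy$y[out_i[k]] - xy$y[sch_i])^2))
    expect_gte(res$distances$distance_m[k] + 1e-9, eu)
  }
})

test_that("proportion is monotone in radius and ignores farther schools", {
  set.seed(33)
  sc <- random_grid_scene(6, 6, n_outlets = 6, n_primary = 3, n_secondary = 2)
  radii <- c(100, 300, 500, 1000, 5000)
  props <- vapply(radii, function(r)
    suppressWarnings(outlets_near_schools(sc, "qs1", "primary", r,
                                          min_outlets = 1))$proportion,
    numeric(1))
  expect_true(all(diff(props) >= 0))
  # adding a school farther than every current nearest changes nothing
  res <- suppressWarnings(outlets_near_schools(sc, "qs1", "primary",
                                               min_outlets = 1))
  far <- sc$points[1, ]
  far$point_id <- "sp_far"; far$kind <- "school"; far$level <- "primary"
  D <- oracle_apsp(sc$nodes$node_id, sc$edges)
  out_nodes <- sc$points$node_id[sc$points$kind == "outlet"]
  finite_near <- res$distances$distance_m[is.finite(res$distances$distance_m)]
  cand <- names(which(apply(D[out_nodes, , drop = FALSE], 2, min) >
                        max(c(finite_near, 500))))
  if (length(cand) > 0) {
    far$node_id <- cand[1]
    sc2 <- geo_scene(sc$nodes, sc$edges, rbind(sc$points, far))
    res2 <- suppressWarnings(outlets_near_schools(sc2, "qs1", "primary",
                                                  min_outlets = 1))
    expect_equal(res2$proportion, res$proportion)
  }
})
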