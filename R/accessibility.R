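## Outlet accessibility around schools: shortest-path distances on an
## undirected road network, outlets and school entrances snapped to nodes.

#' Construct and validate a geo scene
#'
#' @param nodes data.frame `node_id`, `x`, `y` (metres).
#' @param edges data.frame `from`, `to`, `length_m`; undirected.  Edge
#'   lengths must be positive and at least the Euclidean distance between
#'   their endpoints.
#' @param points data.frame `point_id`, `kind` (`"outlet"` or `"school"`),
#'   `company_id` (outlets), `level` (`"primary"`/`"secondary"`, schools),
#'   `node_id` (snapped location).
#' @return object of class `geo_scene`: the validated tables plus the
#'   igraph road graph and its connected-component labelling.
#' @export
geo_scene <- function(nodes, edges, points) {
  check_columns(nodes, c("node_id", "x", "y"), what = "geo nodes")
  check_columns(edges, c("from", "to", "length_m"), what = "geo edges")
  check_columns(points, c("point_id", "kind", "node_id"), what = "geo points")
  if (anyDuplicated(nodes$node_id)) fb_stop("geo nodes contain duplicated node_id")
  if (any(edges$length_m <= 0)) fb_stop("geo edges must have positive length_m")
  ix <- match(edges$from, nodes$node_id)
  jx <- match(edges$to, nodes$node_id)
  if (any(is.na(ix)) || any(is.na(jx))) {
    fb_stop("geo edges reference unknown node_id")
  }
  eucl <- sqrt((nodes$x[ix] - nodes$x[jx])^2 + (nodes$y[ix] - nodes$y[jx])^2)
  if (any(edges$length_m < eucl - 1e-9)) {
    fb_stop("geo edges shorter than the Euclidean distance between endpoints")
  }
  if (any(!points$node_id %in% nodes$node_id)) {
    fb_stop("geo points reference unknown node_id")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
  igraph::E(g)$weight <- edges$length_m
  comp <- igraph::components(g)
  structure(list(nodes = nodes, edges = edges, points = points,
                 graph = g, components = comp$membership),
            class = "geo_scene")
}

#' @export
print.geo_scene <- function(x, ...) {
  cat(sprintf("geo_scene: %d nodes, %d edges, %d outlets, %d schools, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$points$kind == "outlet"), sum(x$points$kind == "school"),
              max(x$components)))
  invisible(x)
}

#' Proportion of a company's outlets near schools
#'
#' For every outlet of the company, computes the shortest road-network
#' distance to the nearest school entrance of the given level, and the
#' proportion of outlets within `radius_m`.  Outlets that cannot reach any
#' school of the level (disconnected components) count as beyond the
#' radius, with a warning.
#'
#' @param scene a [geo_scene()].
#' @param company_id quick-service company whose outlets to assess.
#' @param level school level, `"primary"` or `"secondary"`.
#' @param radius_m radius in metres (default 500).
#' @param min_outlets minimum outlet count for reporting; companies below
#'   it are still computed but flagged `reported = FALSE` (default 3,
#'   mirroring the exclusion of chains with a marginal outlet presence).
#' @return list: `proportion` (in \[0, 1\]), `n_outlets`, `reported`, and
#'   `distances` (data.frame `point_id`, `distance_m`, `within`).
#' @export
outlets_near_schools <- function(scene, company_id, level, radius_m = 500,
                                 min_outlets = 3L) {
  stopifnot(inherits(scene, "geo_scene"))
  if (radius_m <= 0) fb_stop("'radius_m' must be positive")
  if (!level %in% c("primary", "secondary")) {
    fb_stop("unknown school level '%s'", level)
  }
  pts <- scene$points
  outlets <- pts[pts$kind == "outlet" & pts$company_id == company_id, , drop = FALSE]
  if (nrow(outlets) == 0L) fb_stop("company '%s' has no outlets in the scene", company_id)
  schools <- pts[pts$kind == "school" & pts$level == level, , drop = FALSE]
  if (nrow(schools) == 0L) fb_stop("scene contains no %s schools", level)

  # several points may snap to one node; igraph requires unique vertex lists
  v_nodes <- unique(as.character(outlets$node_id))
  t_nodes <- unique(as.character(schools$node_id))
  d <- igraph::distances(scene$graph, v = v_nodes, to = t_nodes,
                         algorithm = "dijkstra")
  nearest <- apply(d, 1L, min)[match(as.character(outlets$node_id), v_nodes)]
  if (any(!is.finite(nearest))) {
    fb_warn("%d outlet(s) of '%s' cannot reach any %s school; counted as beyond radius",
            sum(!is.finite(nearest)), company_id, level)
  }
  within <- is.finite(nearest) & nearest <= radius_m
  list(
    proportion = sum(within) / nrow(outlets),
    n_outlets = nrow(outlets),
    reported = nrow(outlets) >= min_outlets,
    distances = data.frame(point_id = outlets$point_id,
                           distance_m = nearest, within = within,
                           stringsAsFactors = FALSE)
  )
}

#' Accessibility indicators for every company and school level
#'
#' @param scene a [geo_scene()].
#' @param radius_m radius in metres.
#' @param min_outlets reporting threshold, see [outlets_near_schools()].
#' @return data.frame `company_id`, `level`, `radius_m`, `proportion`,
#'   `n_outlets`, `reported`.
#' @export
accessibility_table <- function(scene, radius_m = 500, min_outlets = 3L) {
  pts <- scene$points
  companies <- sort(unique(pts$company_id[pts$kind == "outlet"]))
  levels <- intersect(c("primary", "secondary"),
                      unique(pts$level[pts$kind == "school"]))
  rows <- list()
  for (cid in companies) {
    for (lv in levels) {
      res <- outlets_near_schools(scene, cid, lv, radius_m, min_outlets)
      rows[[length(rows) + 1L]] <- data.frame(
        company_id = cid, level = lv, radius_m = radius_m,
        proportion = res$proportion, n_outlets = res$n_outlets,
        reported = res$reported, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
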