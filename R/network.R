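#' Construct a planar road network
#'
#' A road network is an undirected planar graph: nodes carry projected
#' (x, y) coordinates in meters, edges carry a polyline geometry, a length,
#' and a full record of street-environment attributes (see
#' [env_attribute_schema()]). Both travel directions share one edge record.
#'
#' @param nodes data.frame with columns `node_id`, `x`, `y` (meters,
#'   projected planar coordinates; no geodesy is performed).
#' @param edges data.frame with columns `edge_id`, `from`, `to` and
#'   optionally `length`; `length` is recomputed from the geometry when
#'   absent and validated against it when present.
#' @param geometry named list (by `edge_id`) of two-column coordinate
#'   matrices tracing each edge from its `from` node to its `to` node.
#'   Missing entries default to the straight chord between the endpoints.
#' @param attributes data.frame with one row per `edge_id` holding every
#'   column of the street-environment schema.
#' @return An object of class `road_network`.
#' @seealso [load_network()], [to_segment_graph()]
#' @export
road_network <- function(nodes, edges, geometry = NULL, attributes = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes$node_id <- as.character(nodes$node_id)
  edges$edge_id <- as.character(edges$edge_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)

  if (is.null(geometry)) geometry <- list()
  node_xy <- function(id) {
    i <- match(id, nodes$node_id)
    c(nodes$x[i], nodes$y[i])
  }
  geom <- vector("list", nrow(edges))
  names(geom) <- edges$edge_id
  for (k in seq_len(nrow(edges))) {
    id <- edges$edge_id[k]
    g <- geometry[[id]]
    if (is.null(g)) g <- rbind(node_xy(edges$from[k]), node_xy(edges$to[k]))
    g <- as.matrix(g)
    dimnames(g) <- NULL
    storage.mode(g) <- "double"
    geom[[id]] <- g
  }
  arc_len <- vapply(geom, polyline_length, numeric(1))
  if (is.null(edges$length)) {
    edges$length <- unname(arc_len)
  }
  net <- structure(
    list(nodes = nodes, edges = edges, geometry = geom,
         attributes = attributes),
    class = "road_network"
  )
  validate_road_network(net)
  net
}

polyline_length <- function(g) {
  if (nrow(g) < 2) return(0)
  d <- diff(g)
  sum(sqrt(rowSums(d^2)))
}

#' Validate a road network
#'
#' Checks the structural invariants: edges reference existing nodes, no
#' self-loops, no parallel edges, positive lengths consistent with the
#' polyline arc length (relative tolerance 1e-6), and — when an attribute
#' table is attached — one complete, range-valid attribute record per edge.
#' Errors name the offending ids.
#'
#' @param net a `road_network`.
#' @return `net`, invisibly, if valid.
#' @export
validate_road_network <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$node_id))
    stop("duplicated node ids: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  if (anyDuplicated(edges$edge_id))
    stop("duplicated edge ids: ",
         paste(unique(edges$edge_id[duplicated(edges$edge_id)]), collapse = ", "))
  dangling <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(dangling))
    stop("edges reference unknown nodes: ", paste(dangling, collapse = ", "))
  loops <- edges$edge_id[edges$from == edges$to]
  if (length(loops))
    stop("self-loop edges not allowed: ", paste(loops, collapse = ", "))
  pair_key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(pair_key)) {
    dup <- edges$edge_id[pair_key %in% pair_key[duplicated(pair_key)]]
    stop("parallel edges between the same node pair: ",
         paste(dup, collapse = ", "))
  }
  arc_len <- vapply(net$geometry[edges$edge_id], polyline_length, numeric(1))
  bad_len <- edges$edge_id[edges$length <= 0]
  if (length(bad_len))
    stop("non-positive edge length: ", paste(bad_len, collapse = ", "))
  rel <- abs(edges$length - arc_len) / pmax(arc_len, .Machine$double.eps)
  mism <- edges$edge_id[rel > 1e-6]
  if (length(mism))
    stop("edge length disagrees with polyline arc length: ",
         paste(mism, collapse = ", "))
  # geometry endpoints must coincide with the node coordinates
  for (k in seq_len(nrow(edges))) {
    g <- net$geometry[[edges$edge_id[k]]]
    a <- match(edges$from[k], nodes$node_id)
    b <- match(edges$to[k], nodes$node_id)
    if (max(abs(g[1, ] - c(nodes$x[a], nodes$y[a]))) > 1e-6 ||
        max(abs(g[nrow(g), ] - c(nodes$x[b], nodes$y[b]))) > 1e-6)
      stop("geometry endpoints do not match node coordinates for edge ",
           edges$edge_id[k])
  }
  if (!is.null(net$attributes)) validate_attributes(net$attributes, edges$edge_id)
  invisible(net)
}

#' @export
print.road_network <- function(x, ...) {
  cat("road_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  total street length:",
      format(round(sum(x$edges$length), 1)), "m\n")
  cat("  attributes:",
      if (is.null(x$attributes)) "none" else "complete", "\n")
  invisible(x)
}

edge_row <- function(net, edge_id) {
  i <- match(edge_id, net$edges$edge_id)
  if (anyNA(i)) stop("unknown edge id: ",
                     paste(edge_id[is.na(i)], collapse = ", "))
  i
}

#' Edges incident to each node
#' @noRd
node_incidence <- function(net) {
  ids <- rep(net$edges$edge_id, 2L)
  at <- c(net$edges$from, net$edges$to)
  split(ids, factor(at, levels = net$nodes$node_id))
}

# Unit direction of travel along edge `eid` when departing from node `nid`,
# taken from the polyline chord incident to that node (robust to curvature).
departure_direction <- function(net, eid, nid) {
  g <- net$geometry[[eid]]
  k <- edge_row(net, eid)
  if (net$edges$from[k] == nid) {
    v <- g[2, ] - g[1, ]
  } else if (net$edges$to[k] == nid) {
    v <- g[nrow(g) - 1, ] - g[nrow(g), ]
  } else {
    stop("edge ", eid, " is not incident to node ", nid)
  }
  v / sqrt(sum(v^2))
}

# Angular turn cost between two distinct edges sharing node `nid`, under the
# theta/90 convention: 0 for straight continuation, 1 for a right angle,
# 2 for a full reversal. Symmetric in its two edges.
angular_turn_cost <- function(net, eid_a, eid_b, nid) {
  ua <- departure_direction(net, eid_a, nid)
  ub <- departure_direction(net, eid_b, nid)
  # travelling a -> nid -> b: arrival direction is -ua, departure is ub
  dot <- max(-1, min(1, sum(-ua * ub)))
  acos(dot) / (pi / 2)
}

#' Convert a road network to its angular segment graph
#'
#' The segment graph is the dual used in space-syntax angular analysis:
#' every street edge becomes a segment node, and every pair of edges sharing
#' an intersection becomes a segment link weighted by the angular deviation
#' a walker incurs turning from one into the other. The weight convention is
#' theta/90 with theta in `[0, 180]` degrees measured against straight-ahead
#' continuation, so collinear continuation costs 0, a right angle costs 1
#' and a reversal costs 2. Bearings come from the polyline chords incident
#' to the shared node, so curved edges are handled by their local tangent.
#'
#' @param net a validated `road_network`.
#' @return An object of class `segment_graph` with elements `segments`
#'   (edge ids) and `links` (data.frame `seg_a`, `seg_b`, `node`,
#'   `angular_cost`).
#' @export
to_segment_graph <- function(net) {
  validate_road_network(net)
  inc <- node_incidence(net)
  rows <- list()
  for (nid in names(inc)) {
    eids <- inc[[nid]]
    if (length(eids) < 2) next
    eids <- sort(eids)
    cmb <- utils::combn(eids, 2)
    cost <- vapply(seq_len(ncol(cmb)), function(j)
      angular_turn_cost(net, cmb[1, j], cmb[2, j], nid), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      seg_a = cmb[1, ], seg_b = cmb[2, ], node = nid,
      angular_cost = cost, stringsAsFactors = FALSE)
  }
  links <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seg_a = character(), seg_b = character(),
               node = character(), angular_cost = numeric())
  rownames(links) <- NULL
  structure(list(segments = net$edges$edge_id, links = links),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat("segment_graph:", length(x$segments), "segments,",
      nrow(x$links), "angular links\n")
  invisible(x)
}

#' Read a road network from GeoJSON and an attribute CSV
#'
#' The GeoJSON must be a FeatureCollection of LineString features, each with
#' an `edge_id` property; nodes are derived from the polyline endpoints with
#' a snapping tolerance of 1e-6 m. The CSV must contain one row per edge id
#' with every street-environment attribute column (see
#' [env_attribute_schema()]).
#'
#' @param network_file path to the GeoJSON network.
#' @param attributes_file path to the attribute CSV; `NULL` to load the
#'   bare network without attributes.
#' @return A validated `road_network`.
#' @export
load_network <- function(network_file, attributes_file = NULL) {
  gj <- jsonlite::fromJSON(network_file, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop("not a GeoJSON FeatureCollection: ", network_file)
  snap <- 1e-6
  node_coords <- matrix(numeric(0), ncol = 2)
  node_ids <- character(0)
  find_node <- function(pt) {
    if (nrow(node_coords)) {
      d <- abs(node_coords[, 1] - pt[1]) + abs(node_coords[, 2] - pt[2])
      hit <- which(d <= snap)
      if (length(hit)) return(node_ids[hit[1]])
    }
    id <- paste0("n", length(node_ids) + 1L)
    node_coords <<- rbind(node_coords, pt)
    node_ids <<- c(node_ids, id)
    id
  }
  edge_id <- character(0); from <- character(0); to <- character(0)
  geometry <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "LineString"))
      stop("feature is not a LineString")
    eid <- f$properties$edge_id
    if (is.null(eid)) stop("feature without an edge_id property")
    eid <- as.character(eid)
    g <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) as.numeric(p[1:2])))
    u <- find_node(g[1, ])
    v <- find_node(g[nrow(g), ])
    edge_id <- c(edge_id, eid); from <- c(from, u); to <- c(to, v)
    geometry[[eid]] <- g
  }
  nodes <- data.frame(node_id = node_ids,
                      x = node_coords[, 1], y = node_coords[, 2],
                      stringsAsFactors = FALSE)
  edges <- data.frame(edge_id = edge_id, from = from, to = to,
                      stringsAsFactors = FALSE)
  attrs <- NULL
  if (!is.null(attributes_file)) {
    attrs <- utils::read.csv(attributes_file, stringsAsFactors = FALSE)
    attrs$edge_id <- as.character(attrs$edge_id)
  }
  road_network(nodes, edges, geometry, attrs)
}

#' Write a road network to GeoJSON and an attribute CSV
#'
#' Inverse of [load_network()]: writing and re-loading reproduces the edge
#' set, lengths and attributes.
#'
#' @param net a `road_network`.
#' @param network_file output GeoJSON path.
#' @param attributes_file output CSV path; `NULL` to skip.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, network_file, attributes_file = NULL) {
  feats <- lapply(net$edges$edge_id, function(eid) {
    g <- net$geometry[[eid]]
    list(type = "Feature",
         properties = list(edge_id = eid),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(i) g[i, ])))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, network_file, auto_unbox = TRUE, digits = NA)
  if (!is.null(attributes_file)) {
    if (is.null(net$attributes)) stop("network has no attribute table")
    utils::write.csv(net$attributes, attributes_file, row.names = FALSE)
  }
  invisible(net)
}
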