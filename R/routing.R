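#' Construct a route on a road network
#'
#' A route is a simple-in-edge-terms path: an ordered edge sequence between
#' an origin and a destination in which consecutive edges share exactly the
#' intermediate node and no edge repeats (nodes may repeat if the path
#' crosses itself).
#'
#' @param net a `road_network`.
#' @param node_ids ordered node sequence from origin to destination.
#' @param edge_ids ordered edge sequence; inferred from `node_ids` when
#'   `NULL`.
#' @return An object of class `route` with elements `origin`, `dest`,
#'   `nodes`, `edges`, `edge_lengths` (named, meters) and `total_length`.
#' @export
route <- function(net, node_ids, edge_ids = NULL) {
  node_ids <- as.character(node_ids)
  if (length(node_ids) < 2) stop("a route needs at least two nodes")
  pair_key <- paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to))
  if (is.null(edge_ids)) {
    want <- paste(pmin(node_ids[-length(node_ids)], node_ids[-1]),
                  pmax(node_ids[-length(node_ids)], node_ids[-1]))
    i <- match(want, pair_key)
    if (anyNA(i))
      stop("no edge between consecutive nodes: ",
           paste(want[is.na(i)], collapse = "; "))
    edge_ids <- net$edges$edge_id[i]
  }
  edge_ids <- as.character(edge_ids)
  if (length(edge_ids) != length(node_ids) - 1)
    stop("edge and node sequences are inconsistent")
  k <- edge_row(net, edge_ids)
  ok <- (net$edges$from[k] == node_ids[-length(node_ids)] &
           net$edges$to[k] == node_ids[-1]) |
        (net$edges$to[k] == node_ids[-length(node_ids)] &
           net$edges$from[k] == node_ids[-1])
  if (!all(ok))
    stop("edge does not connect its consecutive nodes: ",
         paste(edge_ids[!ok], collapse = ", "))
  if (anyDuplicated(edge_ids))
    stop("route repeats an edge: ",
         paste(unique(edge_ids[duplicated(edge_ids)]), collapse = ", "))
  lens <- net$edges$length[k]
  names(lens) <- edge_ids
  structure(list(origin = node_ids[1], dest = node_ids[length(node_ids)],
                 nodes = node_ids, edges = edge_ids,
                 edge_lengths = lens, total_length = sum(lens)),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat("route ", x$origin, " -> ", x$dest, ": ",
      length(x$edges), " edges, ",
      format(round(x$total_length, 1)), " m\n", sep = "")
  invisible(x)
}

# ---- direction-aware routing index -----------------------------------------
#
# Both labeled routes are found by Dijkstra over arcs (directed edge
# traversals), which keeps track of the travel direction so that turn costs
# between consecutive edges are well defined and non-traversable turn
# sequences cannot arise. Immediate reversal onto the same edge is not a
# transition; settled labels are canonical under the tie-break order
# (primary cost, secondary cost, lexicographically smallest edge-id
# sequence).

build_routing_index <- function(net) {
  m <- nrow(net$edges)
  edge_rank <- rank(net$edges$edge_id, ties.method = "first")
  arc_edge <- rep(seq_len(m), 2L)
  fwd <- seq_len(m)
  arc_from <- c(net$edges$from, net$edges$to)
  arc_to <- c(net$edges$to, net$edges$from)
  arc_len <- rep(net$edges$length, 2L)
  dep <- matrix(0, nrow = 2L * m, ncol = 2)   # unit direction leaving arc_from
  arr <- matrix(0, nrow = 2L * m, ncol = 2)   # unit travel direction at arc_to
  for (k in seq_len(m)) {
    g <- net$geometry[[net$edges$edge_id[k]]]
    n <- nrow(g)
    d1 <- g[2, ] - g[1, ]; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- g[n, ] - g[n - 1, ]; d2 <- d2 / sqrt(sum(d2^2))
    dep[k, ] <- d1;      arr[k, ] <- d2        # forward: from -> to
    dep[m + k, ] <- -d2; arr[m + k, ] <- -d1   # reverse: to -> from
  }
  node_levels <- net$nodes$node_id
  out_arcs <- split(seq_len(2L * m), factor(arc_from, levels = node_levels))
  # per-arc transitions: arcs leaving arc_to on a different edge, with the
  # angular deviation cost theta/90 between travel directions
  trans_to <- vector("list", 2L * m)
  trans_cost <- vector("list", 2L * m)
  for (a in seq_len(2L * m)) {
    nxt <- out_arcs[[arc_to[a]]]
    nxt <- nxt[arc_edge[nxt] != arc_edge[a]]
    if (length(nxt)) {
      dots <- dep[nxt, 1, drop = TRUE] * arr[a, 1] +
              dep[nxt, 2, drop = TRUE] * arr[a, 2]
      dots <- pmax(-1, pmin(1, dots))
      trans_cost[[a]] <- acos(dots) / (pi / 2)
    } else {
      trans_cost[[a]] <- numeric(0)
    }
    trans_to[[a]] <- nxt
  }
  list(m = m, edge_rank = edge_rank, edge_id = net$edges$edge_id,
       arc_edge = arc_edge, arc_from = arc_from, arc_to = arc_to,
       arc_len = arc_len, out_arcs = out_arcs,
       trans_to = trans_to, trans_cost = trans_cost)
}

routing_index <- function(net) {
  idx <- attr(net, ".routing_index")
  if (is.null(idx)) idx <- build_routing_index(net)
  idx
}

#' Cache the routing index on a network
#'
#' Precomputes the arc transition structure once so that repeated routing
#' calls (many OD pairs on one network) skip the setup cost.
#'
#' @param net a `road_network`.
#' @return `net` with the index attached.
#' @export
index_network <- function(net) {
  attr(net, ".routing_index") <- build_routing_index(net)
  net
}

# edge-id rank sequence of the label path ending at arc `a`
label_path <- function(pred, arc_edge, edge_rank, a) {
  out <- integer(0)
  while (!is.na(a)) {
    out <- c(edge_rank[arc_edge[a]], out)
    a <- pred[a]
  }
  out
}

lex_less <- function(x, y) {
  n <- min(length(x), length(y))
  if (n > 0) {
    d <- which(x[seq_len(n)] != y[seq_len(n)])
    if (length(d)) return(x[d[1]] < y[d[1]])
  }
  length(x) < length(y)
}

# Single-source label-setting search over arcs.
# mode "distance": primary = length, secondary = turn cost.
# mode "angular":  primary = turn cost, secondary = length.
arc_search <- function(idx, origin, mode = c("distance", "angular")) {
  mode <- match.arg(mode)
  A <- 2L * idx$m
  p <- rep(Inf, A); s <- rep(Inf, A)
  pred <- rep(NA_integer_, A); settled <- rep(FALSE, A)
  start <- idx$out_arcs[[origin]]
  if (is.null(start)) stop("unknown origin node: ", origin)
  if (mode == "distance") {
    p[start] <- idx$arc_len[start]; s[start] <- 0
  } else {
    p[start] <- 0; s[start] <- idx$arc_len[start]
  }
  tol <- function(v) 1e-9 * (1 + abs(v))
  repeat {
    cand <- which(!settled & is.finite(p))
    if (!length(cand)) break
    pm <- min(p[cand])
    cand <- cand[p[cand] <= pm + tol(pm)]
    sm <- min(s[cand])
    cand <- cand[s[cand] <= sm + tol(sm)]
    u <- cand[1]
    if (length(cand) > 1) {
      best <- label_path(pred, idx$arc_edge, idx$edge_rank, u)
      for (v in cand[-1]) {
        pv <- label_path(pred, idx$arc_edge, idx$edge_rank, v)
        if (lex_less(pv, best)) { best <- pv; u <- v }
      }
    }
    settled[u] <- TRUE
    nxt <- idx$trans_to[[u]]
    if (length(nxt)) {
      live <- !settled[nxt]
      nxt <- nxt[live]
      tc <- idx$trans_cost[[u]][live]
      for (j in seq_along(nxt)) {
        b <- nxt[j]
        if (mode == "distance") {
          np <- p[u] + idx$arc_len[b]; ns <- s[u] + tc[j]
        } else {
          np <- p[u] + tc[j]; ns <- s[u] + idx$arc_len[b]
        }
        upd <- if (np < p[b] - tol(np)) TRUE
          else if (np > p[b] + tol(np)) FALSE
          else if (ns < s[b] - tol(ns)) TRUE
          else if (ns > s[b] + tol(ns)) FALSE
          else {
            new_path <- c(label_path(pred, idx$arc_edge, idx$edge_rank, u),
                          idx$edge_rank[idx$arc_edge[b]])
            lex_less(new_path,
                     label_path(pred, idx$arc_edge, idx$edge_rank, b))
          }
        if (upd) { p[b] <- np; s[b] <- ns; pred[b] <- u }
      }
    }
  }
  list(p = p, s = s, pred = pred, origin = origin, mode = mode, idx = idx)
}

# Extract the canonical route to `dest` from a completed arc search.
route_from_search <- function(net, labels, dest) {
  idx <- labels$idx
  arcs_in <- which(idx$arc_to == dest & is.finite(labels$p))
  if (!length(arcs_in))
    stop("no path from ", labels$origin, " to ", dest)
  tol <- function(v) 1e-9 * (1 + abs(v))
  pm <- min(labels$p[arcs_in])
  arcs_in <- arcs_in[labels$p[arcs_in] <= pm + tol(pm)]
  sm <- min(labels$s[arcs_in])
  arcs_in <- arcs_in[labels$s[arcs_in] <= sm + tol(sm)]
  a <- arcs_in[1]
  if (length(arcs_in) > 1) {
    best <- label_path(labels$pred, idx$arc_edge, idx$edge_rank, a)
    for (v in arcs_in[-1]) {
      pv <- label_path(labels$pred, idx$arc_edge, idx$edge_rank, v)
      if (lex_less(pv, best)) { best <- pv; a <- v }
    }
  }
  arcs <- integer(0)
  while (!is.na(a)) { arcs <- c(a, arcs); a <- labels$pred[a] }
  nodes <- c(idx$arc_from[arcs[1]], idx$arc_to[arcs])
  edges <- idx$edge_id[idx$arc_edge[arcs]]
  route(net, nodes, edges)
}

check_od <- function(net, origin, dest) {
  origin <- as.character(origin); dest <- as.character(dest)
  if (!origin %in% net$nodes$node_id) stop("unknown origin node: ", origin)
  if (!dest %in% net$nodes$node_id) stop("unknown destination node: ", dest)
  if (origin == dest) stop("origin and destination coincide: ", origin)
  list(origin = origin, dest = dest)
}

#' Shortest-distance route between two nodes
#'
#' Minimises total length; among equal-length paths prefers the one with
#' the lower total turn cost, then the lexicographically smallest edge-id
#' sequence, so the result is deterministic.
#'
#' @param net a `road_network`.
#' @param origin,dest node ids.
#' @return A `route`.
#' @export
shortest_distance_route <- function(net, origin, dest) {
  od <- check_od(net, origin, dest)
  labels <- arc_search(routing_index(net), od$origin, "distance")
  route_from_search(net, labels, od$dest)
}

#' Least-directional-change route between two nodes
#'
#' Minimises the summed angular turn cost (theta/90 convention) over
#' consecutive edge pairs; among equal-turn-cost paths prefers the shorter,
#' then the lexicographically smallest edge-id sequence.
#'
#' @inheritParams shortest_distance_route
#' @return A `route`.
#' @export
least_angular_route <- function(net, origin, dest) {
  od <- check_od(net, origin, dest)
  labels <- arc_search(routing_index(net), od$origin, "angular")
  route_from_search(net, labels, od$dest)
}

#' Angular step depth of every street segment from an origin
#'
#' Computes the space-syntax angular step depth map: on the segment graph
#' (segments as nodes, links weighted by angular deviation) the cheapest
#' cumulative angular cost from any segment incident to the origin, which
#' sit at depth 0.
#'
#' @param net a `road_network`.
#' @param origin a node id.
#' @return An object of class `angular_depth_map`: list with `origin` and
#'   `depth`, a numeric vector named by edge id (`Inf` for segments not
#'   reachable through any intersection).
#' @export
angular_step_depth <- function(net, origin) {
  origin <- as.character(origin)
  if (!origin %in% net$nodes$node_id) stop("unknown origin node: ", origin)
  sg <- to_segment_graph(net)
  segs <- sg$segments
  n <- length(segs)
  ia <- match(sg$links$seg_a, segs)
  ib <- match(sg$links$seg_b, segs)
  w <- sg$links$angular_cost
  adj_to <- split(c(ib, ia), c(ia, ib))
  adj_w <- split(c(w, w), c(ia, ib))
  depth <- rep(Inf, n)
  incident <- net$edges$from == origin | net$edges$to == origin
  depth[incident] <- 0
  settled <- rep(FALSE, n)
  repeat {
    cand <- which(!settled & is.finite(depth))
    if (!length(cand)) break
    u <- cand[which.min(depth[cand])]
    settled[u] <- TRUE
    key <- as.character(u)
    nb <- adj_to[[key]]
    if (!is.null(nb)) {
      nd <- depth[u] + adj_w[[key]]
      imp <- nd < depth[nb]
      depth[nb[imp]] <- nd[imp]
    }
  }
  names(depth) <- segs
  structure(list(origin = origin, depth = depth),
            class = "angular_depth_map")
}

#' @export
print.angular_depth_map <- function(x, ...) {
  cat("angular_depth_map from node", x$origin, "over",
      length(x$depth), "segments; max finite depth",
      format(round(max(x$depth[is.finite(x$depth)]), 3)), "\n")
  invisible(x)
}

#' Generate both labeled alternative routes for a set of OD pairs
#'
#' The labeling method produces one route per criterion label: the
#' shortest-distance route and the least-directional-change route. Searches
#' are shared across OD pairs with a common origin.
#'
#' @param net a `road_network`.
#' @param od_pairs data.frame with columns `origin` and `dest` (an optional
#'   `od_id` column is carried through; defaults to `od1`, `od2`, ...).
#' @return A list with one element per OD pair, each a list
#'   `(od_id, origin, dest, shortest, least_angular)` where the last two
#'   are `route` objects.
#' @export
generate_alternatives <- function(net, od_pairs) {
  od_pairs <- as.data.frame(od_pairs, stringsAsFactors = FALSE)
  if (is.null(od_pairs$od_id))
    od_pairs$od_id <- paste0("od", seq_len(nrow(od_pairs)))
  od_pairs$origin <- as.character(od_pairs$origin)
  od_pairs$dest <- as.character(od_pairs$dest)
  net <- index_network(net)
  idx <- routing_index(net)
  out <- vector("list", nrow(od_pairs))
  names(out) <- od_pairs$od_id
  for (org in unique(od_pairs$origin)) {
    rows <- which(od_pairs$origin == org)
    lab_d <- arc_search(idx, org, "distance")
    lab_a <- arc_search(idx, org, "angular")
    for (r in rows) {
      check_od(net, org, od_pairs$dest[r])
      out[[r]] <- list(
        od_id = od_pairs$od_id[r], origin = org, dest = od_pairs$dest[r],
        shortest = route_from_search(net, lab_d, od_pairs$dest[r]),
        least_angular = route_from_search(net, lab_a, od_pairs$dest[r]))
    }
  }
  out
}

# plain node-level Dijkstra on edge lengths; distances from `origin` to all
# nodes (used for OD sampling, where only lengths matter)
node_distances <- function(net, origin) {
  n <- nrow(net$nodes)
  io <- match(origin, net$nodes$node_id)
  iu <- match(net$edges$from, net$nodes$node_id)
  iv <- match(net$edges$to, net$nodes$node_id)
  adj_to <- split(c(iv, iu), c(iu, iv))
  adj_w <- split(rep(net$edges$length, 2L), c(iu, iv))
  d <- rep(Inf, n); d[io] <- 0
  settled <- rep(FALSE, n)
  repeat {
    cand <- which(!settled & is.finite(d))
    if (!length(cand)) break
    u <- cand[which.min(d[cand])]
    settled[u] <- TRUE
    key <- as.character(u)
    nb <- adj_to[[key]]
    if (!is.null(nb)) {
      nd <- d[u] + adj_w[[key]]
      imp <- nd < d[nb]
      d[nb[imp]] <- nd[imp]
    }
  }
  names(d) <- net$nodes$node_id
  d
}
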