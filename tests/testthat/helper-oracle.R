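# Independent brute-force routing oracle: enumerate every edge-simple path
# between two nodes and pick the best under the tie-break rule (primary
# cost, then secondary cost, then lexicographically smallest edge-id
# sequence). Deliberately written from the raw network tables, not via the
# package's routing machinery.

oracle_enumerate_paths <- function(net, origin, dest, max_paths = 2e5) {
  ed <- net$edges
  paths <- list()
  walk <- function(node, nodes_so_far, edges_so_far) {
    if (length(paths) >= max_paths) stop("oracle path budget exceeded")
    if (node == dest) {
      paths[[length(paths) + 1L]] <<- list(nodes = nodes_so_far,
                                           edges = edges_so_far)
      return(invisible())
    }
    inc <- which(ed$from == node | ed$to == node)
    for (i in inc) {
      eid <- ed$edge_id[i]
      if (eid %in% edges_so_far) next
      nxt <- if (ed$from[i] == node) ed$to[i] else ed$from[i]
      walk(nxt, c(nodes_so_far, nxt), c(edges_so_far, eid))
    }
    invisible()
  }
  walk(origin, origin, character(0))
  paths
}

# turn angle (in units of 90 degrees) at each interior node of a path,
# recomputed from coordinates alone
oracle_turn_cost <- function(net, nodes) {
  if (length(nodes) < 3) return(0)
  xy <- as.matrix(net$nodes[match(nodes, net$nodes$node_id), c("x", "y")])
  total <- 0
  for (i in 2:(length(nodes) - 1)) {
    v1 <- xy[i, ] - xy[i - 1, ]
    v2 <- xy[i + 1, ] - xy[i, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    total <- total + acos(max(-1, min(1, cosang))) / (pi / 2)
  }
  total
}

oracle_path_length <- function(net, edges) {
  sum(net$edges$length[match(edges, net$edges$edge_id)])
}

# Is candidate label (p1, s1, seq1) strictly better than (p2, s2, seq2)?
oracle_better <- function(p1, s1, seq1, p2, s2, seq2) {
  tol <- function(v) 1e-9 * (1 + abs(v))
  if (p1 < p2 - tol(p2)) return(TRUE)
  if (p1 > p2 + tol(p2)) return(FALSE)
  if (s1 < s2 - tol(s2)) return(TRUE)
  if (s1 > s2 + tol(s2)) return(FALSE)
  n <- min(length(seq1), length(seq2))
  if (n > 0) {
    d <- which(seq1[seq_len(n)] != seq2[seq_len(n)])
    if (length(d)) return(seq1[d[1]] < seq2[d[1]])
  }
  length(seq1) < length(seq2)
}

oracle_best_route <- function(net, origin, dest,
                              mode = c("distance", "angular")) {
  mode <- match.arg(mode)
  paths <- oracle_enumerate_paths(net, origin, dest)
  if (!length(paths)) stop("oracle: no path")
  rank_of <- rank(net$edges$edge_id, ties.method = "first")
  names(rank_of) <- net$edges$edge_id
  best <- NULL
  for (pt in paths) {
    len <- oracle_path_length(net, pt$edges)
    trn <- oracle_turn_cost(net, pt$nodes)
    lab <- if (mode == "distance") c(len, trn) else c(trn, len)
    sq <- unname(rank_of[pt$edges])
    if (is.null(best) ||
        oracle_better(lab[1], lab[2], sq, best$lab[1], best$lab[2],
                      best$sq)) {
      best <- list(nodes = pt$nodes, edges = pt$edges, lab = lab, sq = sq)
    }
  }
  best
}
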