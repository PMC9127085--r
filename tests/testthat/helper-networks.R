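# Toy network builders used across tests. Attributes default to constant,
# in-range values so structural tests need no randomness.

default_test_attrs <- function(edge_ids, overrides = list()) {
  a <- data.frame(edge_id = edge_ids, stringsAsFactors = FALSE)
  defaults <- list(sidewalk_width = 2, on_street_parking = 2,
                   sidewalk_walkability = 2, traffic_signals = 0,
                   driveway_width = 7, dh_ratio = 1, green_spaces = 2,
                   street_walls = 1, garbage_bins = 0, streetlights = 1,
                   benches = 0, shops = 0.1, life_facilities = 0.1,
                   bus_stops = 0.05, leisure_facilities = 0.05)
  for (nm in names(defaults)) {
    v <- rep(defaults[[nm]], length(edge_ids))
    if (nm %in% names(overrides)) v <- overrides[[nm]]
    a[[nm]] <- v
  }
  a
}

# a network from explicit coordinates and edges (straight chords)
make_net <- function(coords, edges, attrs = TRUE, overrides = list()) {
  nodes <- data.frame(node_id = names(coords),
                      x = vapply(coords, `[`, numeric(1), 1),
                      y = vapply(coords, `[`, numeric(1), 2),
                      stringsAsFactors = FALSE)
  ed <- data.frame(edge_id = edges$edge_id, from = edges$from, to = edges$to,
                   stringsAsFactors = FALSE)
  at <- if (isTRUE(attrs)) default_test_attrs(ed$edge_id, overrides) else NULL
  road_network(nodes, ed, attributes = at)
}

# rows x cols rectilinear grid, optional node jitter and block scale
make_grid <- function(rows, cols, block = 100, jitter = 0, seed = NULL,
                      drop_edges = 0) {
  if (!is.null(seed)) set.seed(seed)
  nid <- function(r, c) paste0("g", r, "_", c)
  grid <- expand.grid(c = seq_len(cols), r = seq_len(rows))
  nodes <- data.frame(
    node_id = nid(grid$r, grid$c),
    x = (grid$c - 1) * block + stats::rnorm(nrow(grid), 0, jitter),
    y = (grid$r - 1) * block + stats::rnorm(nrow(grid), 0, jitter),
    stringsAsFactors = FALSE)
  from <- character(0); to <- character(0)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { from <- c(from, nid(r, c)); to <- c(to, nid(r, c + 1)) }
    if (r < rows) { from <- c(from, nid(r, c)); to <- c(to, nid(r + 1, c)) }
  }
  edges <- data.frame(edge_id = sprintf("e%03d", seq_along(from)),
                      from = from, to = to, stringsAsFactors = FALSE)
  if (drop_edges > 0) {
    # drop random edges but keep the graph connected
    for (k in seq_len(drop_edges)) {
      cand <- sample(nrow(edges))
      for (i in cand) {
        trial <- edges[-i, ]
        if (grid_connected(nodes$node_id, trial)) { edges <- trial; break }
      }
    }
  }
  make_net(stats::setNames(
    lapply(seq_len(nrow(nodes)), function(i) c(nodes$x[i], nodes$y[i])),
    nodes$node_id), edges)
}

grid_connected <- function(node_ids, edges) {
  seen <- node_ids[1]
  frontier <- seen
  while (length(frontier)) {
    nb <- unique(c(edges$to[edges$from %in% frontier],
                   edges$from[edges$to %in% frontier]))
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(node_ids)
}

# fixture: chosen route detours around one block of the alternative
one_loop_fixture <- function() {
  #  n3 -- n4
  #   |     |
  #  n1 -- n2 -- n5
  coords <- list(n1 = c(0, 0), n2 = c(100, 0), n5 = c(200, 0),
                 n3 = c(0, 100), n4 = c(100, 100))
  edges <- data.frame(
    edge_id = c("a", "b", "u1", "u2", "u3"),
    from = c("n1", "n2", "n1", "n3", "n4"),
    to = c("n2", "n5", "n3", "n4", "n2"),
    stringsAsFactors = FALSE)
  net <- make_net(coords, edges)
  list(net = net,
       alt = route(net, c("n1", "n2", "n5")),
       chosen = route(net, c("n1", "n3", "n4", "n2", "n5")))
}

# fixture: chosen route deviates around two separate blocks
two_loop_fixture <- function() {
  # alternative runs straight along y = 0 through m0..m4;
  # chosen bumps up around blocks (m0,m1) and (m2,m3)
  coords <- list(m0 = c(0, 0), m1 = c(100, 0), m2 = c(200, 0),
                 m3 = c(300, 0), m4 = c(400, 0),
                 p0 = c(0, 100), p1 = c(100, 100),
                 q2 = c(200, 100), q3 = c(300, 100))
  edges <- data.frame(
    edge_id = c("s1", "s2", "s3", "s4",
                "d1", "d2", "d3", "d4", "d5", "d6"),
    from = c("m0", "m1", "m2", "m3",
             "m0", "p0", "p1", "m2", "q2", "q3"),
    to = c("m1", "m2", "m3", "m4",
           "p0", "p1", "m1", "q2", "q3", "m3"),
    stringsAsFactors = FALSE)
  net <- make_net(coords, edges)
  list(net = net,
       alt = route(net, c("m0", "m1", "m2", "m3", "m4")),
       chosen = route(net, c("m0", "p0", "p1", "m1", "m2",
                             "q2", "q3", "m3", "m4")))
}
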