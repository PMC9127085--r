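# Deterministic child seed for a named stage, so each generator stage draws
# from its own stream under one master seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 100003L)
}

#' Configuration for the synthetic street-network and choice simulator
#'
#' The defaults emulate the study conditions the pipeline is meant for: a
#' dense old-town residential grid (blocks around 100 m with mild length
#' variation and node jitter), audit attributes on the walkability-tool
#' measurement scales, a cohort of 219 short utilitarian walking trips at
#' the ~350 m scale, and utility-maximising route choices with i.i.d.
#' Gumbel(0, 1) noise under known coefficients (which fixes the utility
#' scale on which `beta_true` is read).
#'
#' @param rows,cols grid dimensions (intersections); at least 2 x 2.
#' @param block_length_mean mean block length, meters.
#' @param block_length_cv coefficient of variation of block lengths
#'   (lognormal row/column spacings).
#' @param jitter_sd standard deviation of isotropic node jitter, meters.
#' @param n_od number of origin-destination pairs (trips).
#' @param trip_length_target target shortest-path trip length, meters;
#'   sampled trips fall in `[0.5, 2]` times this scale.
#' @param beta_true named coefficient vector of the data-generating utility
#'   over street-environment attributes.
#' @param seed master seed; fully determines all outputs.
#' @param attribute_params per-attribute sampling parameters; see
#'   [default_attribute_params()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(rows = 8, cols = 8,
                             block_length_mean = 100,
                             block_length_cv = 0.15,
                             jitter_sd = 5,
                             n_od = 219,
                             trip_length_target = 350,
                             beta_true = c(green_spaces = 1.0,
                                           sidewalk_width = -0.5),
                             seed = 1,
                             attribute_params = default_attribute_params()) {
  if (rows < 2 || cols < 2)
    stop("degenerate grid: need at least 2 x 2 intersections")
  if (block_length_mean <= 0 || trip_length_target <= 0)
    stop("lengths must be positive")
  if (is.null(names(beta_true)) ||
      !all(names(beta_true) %in% env_attribute_names()))
    stop("beta_true must be named by street-environment attributes")
  structure(list(rows = rows, cols = cols,
                 block_length_mean = block_length_mean,
                 block_length_cv = block_length_cv,
                 jitter_sd = jitter_sd, n_od = n_od,
                 trip_length_target = trip_length_target,
                 beta_true = beta_true, seed = as.integer(seed),
                 attribute_params = attribute_params),
            class = "synthetic_config")
}

#' Default attribute sampling parameters
#'
#' One entry per street-environment attribute: lognormal for widths and the
#' D/H ratio (realistic medians: sidewalks ~2 m, driveways ~7 m, D/H ~1),
#' categorical over the audit codes for ordinal condition variables,
#' Poisson with a per-meter rate for counts (so longer blocks carry more
#' bins/lights/benches), and Beta for street-front facility proportions.
#' `mean_fn` gives the theoretical edge-level mean (for a 100 m edge in the
#' count case), used by calibration checks.
#'
#' @return Named list of parameter lists.
#' @export
default_attribute_params <- function() {
  list(
    sidewalk_width = list(dist = "lognormal", meanlog = log(2), sdlog = 0.3),
    driveway_width = list(dist = "lognormal", meanlog = log(7), sdlog = 0.25),
    dh_ratio = list(dist = "lognormal", meanlog = log(1), sdlog = 0.4),
    on_street_parking = list(dist = "categorical", values = 1:3,
                             prob = c(0.3, 0.4, 0.3)),
    sidewalk_walkability = list(dist = "categorical", values = 1:3,
                                prob = c(0.2, 0.5, 0.3)),
    green_spaces = list(dist = "categorical", values = 1:3,
                        prob = c(0.4, 0.4, 0.2)),
    street_walls = list(dist = "categorical", values = 0:2,
                        prob = c(0.5, 0.3, 0.2)),
    traffic_signals = list(dist = "poisson", rate_per_m = 1 / 200),
    garbage_bins = list(dist = "poisson", rate_per_m = 1 / 50),
    streetlights = list(dist = "poisson", rate_per_m = 1 / 30),
    benches = list(dist = "poisson", rate_per_m = 1 / 100),
    shops = list(dist = "beta", shape1 = 1.5, shape2 = 6),
    life_facilities = list(dist = "beta", shape1 = 1.5, shape2 = 8),
    bus_stops = list(dist = "beta", shape1 = 1, shape2 = 15),
    leisure_facilities = list(dist = "beta", shape1 = 1, shape2 = 10)
  )
}

#' Theoretical edge-level attribute means implied by a configuration
#'
#' For count attributes the mean refers to an edge of the configured mean
#' block length.
#'
#' @param cfg a `synthetic_config`.
#' @return Named numeric vector.
#' @export
attribute_means <- function(cfg) {
  vapply(cfg$attribute_params, function(p) switch(p$dist,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    categorical = sum(p$values * p$prob),
    poisson = p$rate_per_m * cfg$block_length_mean,
    beta = p$shape1 / (p$shape1 + p$shape2),
    stop("unknown distribution ", p$dist)), numeric(1))
}

draw_attribute <- function(p, n, lengths) {
  switch(p$dist,
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    categorical = sample(p$values, n, replace = TRUE, prob = p$prob),
    poisson = stats::rpois(n, p$rate_per_m * lengths),
    beta = stats::rbeta(n, p$shape1, p$shape2),
    stop("unknown distribution ", p$dist))
}

#' Generate a synthetic street network
#'
#' Builds a `rows x cols` grid of intersections with lognormal row/column
#' spacings around the configured block length, isotropic Gaussian node
#' jitter, straight-chord edge geometry, and per-edge street-environment
#' attributes drawn from the configured distributions. The same seed always
#' yields the same network.
#'
#' @param cfg a `synthetic_config`.
#' @return A validated `road_network` with attributes.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stage_seed(cfg$seed, "network"))
  sdlog <- sqrt(log(1 + cfg$block_length_cv^2))
  meanlog <- log(cfg$block_length_mean) - sdlog^2 / 2
  dx <- if (cfg$cols > 1) stats::rlnorm(cfg$cols - 1, meanlog, sdlog) else numeric(0)
  dy <- if (cfg$rows > 1) stats::rlnorm(cfg$rows - 1, meanlog, sdlog) else numeric(0)
  xs <- c(0, cumsum(dx)); ys <- c(0, cumsum(dy))
  grid <- expand.grid(col = seq_len(cfg$cols), row = seq_len(cfg$rows))
  nid <- function(r, c) paste0("n", r, "_", c)
  nodes <- data.frame(
    node_id = nid(grid$row, grid$col),
    x = xs[grid$col] + stats::rnorm(nrow(grid), 0, cfg$jitter_sd),
    y = ys[grid$row] + stats::rnorm(nrow(grid), 0, cfg$jitter_sd),
    stringsAsFactors = FALSE)
  from <- character(0); to <- character(0)
  for (r in seq_len(cfg$rows)) for (c in seq_len(cfg$cols)) {
    if (c < cfg$cols) { from <- c(from, nid(r, c)); to <- c(to, nid(r, c + 1)) }
    if (r < cfg$rows) { from <- c(from, nid(r, c)); to <- c(to, nid(r + 1, c)) }
  }
  edges <- data.frame(
    edge_id = sprintf("e%03d", seq_along(from)),
    from = from, to = to, stringsAsFactors = FALSE)
  net0 <- road_network(nodes, edges)
  lens <- net0$edges$length
  attrs <- data.frame(edge_id = net0$edges$edge_id,
                      stringsAsFactors = FALSE)
  for (nm in env_attribute_names())
    attrs[[nm]] <- draw_attribute(cfg$attribute_params[[nm]],
                                  nrow(attrs), lens)
  road_network(nodes, edges, attributes = attrs)
}

#' Sample origin-destination pairs at a target trip-length scale
#'
#' Draws OD pairs whose shortest-distance length lies within `[0.5, 2]`
#' times the configured target, preferring lengths near the target via a
#' Gaussian kernel so the empirical mean tracks the target. Emulates short
#' utilitarian walking trips from a residence to a first destination.
#'
#' @param net a `road_network`.
#' @param cfg a `synthetic_config`.
#' @return data.frame with columns `od_id`, `origin`, `dest`,
#'   `shortest_length`.
#' @export
sample_od_pairs <- function(net, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stage_seed(cfg$seed, "od"))
  target <- cfg$trip_length_target
  band <- c(0.5, 2) * target
  kern_sd <- 0.3 * target
  origins <- character(0); dests <- character(0); lens <- numeric(0)
  node_ids <- net$nodes$node_id
  dist_cache <- list()
  attempts <- 0L
  while (length(origins) < cfg$n_od) {
    attempts <- attempts + 1L
    if (attempts > 50L * cfg$n_od)
      stop("no feasible OD pairs at the target trip-length scale")
    o <- sample(node_ids, 1)
    d <- dist_cache[[o]]
    if (is.null(d)) {
      d <- node_distances(net, o)
      dist_cache[[o]] <- d
    }
    ok <- names(d)[is.finite(d) & d >= band[1] & d <= band[2] &
                     names(d) != o]
    if (!length(ok)) next
    w <- exp(-((d[ok] - target)^2) / (2 * kern_sd^2))
    dest <- if (length(ok) == 1) ok else sample(ok, 1, prob = w)
    origins <- c(origins, o); dests <- c(dests, dest)
    lens <- c(lens, unname(d[dest]))
  }
  data.frame(od_id = paste0("od", seq_along(origins)),
             origin = origins, dest = dests, shortest_length = lens,
             stringsAsFactors = FALSE)
}

rgumbel <- function(n) -log(-log(stats::runif(n)))

# k random edge-simple detour paths between o and d (biased random DFS);
# used by the choice-set simulation mode
random_detour <- function(net, origin, dest, rid = NULL) {
  if (is.null(rid)) rid <- routing_index(net)
  nodes <- origin
  edges <- character(0)
  used <- character(0)
  cur <- origin
  xy <- function(n) unlist(net$nodes[match(n, net$nodes$node_id), c("x", "y")])
  for (step in seq_len(4L * nrow(net$edges))) {
    if (cur == dest) break
    inc_idx <- which(net$edges$from == cur | net$edges$to == cur)
    inc <- net$edges$edge_id[inc_idx]
    free <- !(inc %in% used)
    if (!any(free)) return(NULL)
    inc_idx <- inc_idx[free]; inc <- inc[free]
    nxt <- ifelse(net$edges$from[inc_idx] == cur,
                  net$edges$to[inc_idx], net$edges$from[inc_idx])
    # bias toward the destination
    dd <- vapply(nxt, function(n) sqrt(sum((xy(n) - xy(dest))^2)), numeric(1))
    w <- exp(-dd / max(dd + 1))
    pick <- if (length(inc) == 1) 1L else
      sample(seq_along(inc), 1, prob = w + 0.1)
    edges <- c(edges, inc[pick])
    used <- c(used, inc[pick])
    cur <- nxt[pick]
    nodes <- c(nodes, cur)
  }
  if (cur != dest) return(NULL)
  route(net, nodes, edges)
}

#' Simulate utility-maximising route choices
#'
#' For each OD pair the chooser faces a set of alternative routes, derives
#' each alternative's street-environment attribute vector by length-weighted
#' aggregation, and picks the alternative maximising
#' `beta_true' x + Gumbel(0, 1)` noise. In `"pairwise"` mode the choice set
#' is the two labeled routes (shortest distance, least directional change);
#' in `"choice_set"` mode it additionally contains up to `n_detours` random
#' simple-path detours, which demonstrates — without correcting — the
#' misspecification incurred when the estimation choice set is smaller than
#' the true one. When the two labeled routes coincide the trip is marked
#' full-overlap and the common route is chosen.
#'
#' @param net a `road_network` with attributes.
#' @param od_pairs data.frame from [sample_od_pairs()] (columns `od_id`,
#'   `origin`, `dest`).
#' @param beta_true named coefficient vector over street-environment
#'   attributes.
#' @param mode `"pairwise"` or `"choice_set"`.
#' @param seed integer seed for the noise stream.
#' @param n_detours extra random alternatives in `"choice_set"` mode.
#' @return An object of class `choice_cohort`: list with `od_pairs`,
#'   `chosen` (list of `route`), `chosen_label`, `alternatives` (per trip,
#'   named list of routes), `coincident` (logical: labeled routes
#'   identical), and `beta_true`.
#' @export
simulate_choices <- function(net, od_pairs, beta_true,
                             mode = c("pairwise", "choice_set"),
                             seed = 1, n_detours = 3) {
  mode <- match.arg(mode)
  if (is.null(names(beta_true)) ||
      !all(names(beta_true) %in% env_attribute_names()))
    stop("beta_true must be named by street-environment attributes")
  net <- index_network(net)
  alts <- generate_alternatives(net, od_pairs)
  set.seed(stage_seed(seed, paste0("choices_", mode)))
  chosen <- vector("list", length(alts))
  chosen_label <- character(length(alts))
  coincident <- logical(length(alts))
  alternatives <- vector("list", length(alts))
  for (i in seq_along(alts)) {
    a <- alts[[i]]
    alt_list <- list(shortest = a$shortest,
                     least_angular = a$least_angular)
    coincident[i] <- is_full_overlap(a$shortest, a$least_angular)
    if (mode == "choice_set") {
      for (k in seq_len(n_detours)) {
        det <- random_detour(net, a$origin, a$dest)
        if (!is.null(det) &&
            !any(vapply(alt_list, is_full_overlap, logical(1),
                        chosen = det)))
          alt_list[[paste0("detour", k)]] <- det
      }
    }
    if (coincident[i] && length(alt_list) == 2) {
      chosen[[i]] <- a$shortest
      chosen_label[i] <- "coincident"
    } else {
      x <- do.call(rbind, lapply(alt_list, function(r)
        unclass(aggregate_route_environment(net, r))[names(beta_true)]))
      u <- drop(x %*% beta_true) + rgumbel(nrow(x))
      j <- which.max(u)
      chosen[[i]] <- alt_list[[j]]
      chosen_label[i] <- names(alt_list)[j]
    }
    alternatives[[i]] <- alt_list
  }
  structure(list(od_pairs = as.data.frame(od_pairs),
                 chosen = chosen, chosen_label = chosen_label,
                 alternatives = alternatives, coincident = coincident,
                 beta_true = beta_true, mode = mode),
            class = "choice_cohort")
}

#' @export
print.choice_cohort <- function(x, ...) {
  cat("choice_cohort:", length(x$chosen), "trips (mode", x$mode, ")\n")
  cat("  chosen labels:", paste(names(table(x$chosen_label)),
                                table(x$chosen_label), collapse = ", "), "\n")
  invisible(x)
}

#' Choice observations for coefficient recovery from a simulated cohort
#'
#' Packs each simulated trip's full choice set (as generated) into a
#' [choice_observation()], with the chosen alternative marked — the
#' estimation counterpart of the generation step, used for parameter
#' recovery. Coincident-alternative trips carry no preference information
#' and are dropped.
#'
#' @param net the `road_network` the cohort lives on.
#' @param cohort a `choice_cohort`.
#' @param attributes attribute names for the observation matrices
#'   (default: the generator's `beta_true` names).
#' @return List of [choice_observation()]s.
#' @export
cohort_choice_data <- function(net, cohort, attributes = NULL) {
  if (is.null(attributes)) attributes <- names(cohort$beta_true)
  out <- list()
  for (i in seq_along(cohort$chosen)) {
    if (cohort$chosen_label[i] == "coincident") next
    alt_list <- cohort$alternatives[[i]]
    x <- do.call(rbind, lapply(alt_list, function(r)
      unclass(aggregate_route_environment(net, r))[attributes]))
    colnames(x) <- attributes
    j <- match(cohort$chosen_label[i], names(alt_list))
    out[[length(out) + 1L]] <- choice_observation(x, j)
  }
  out
}
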