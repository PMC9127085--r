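#' Overlap ratio between a chosen route and an alternative
#'
#' The overlap ratio is the summed length of edges shared with the
#' alternative divided by the chosen route's total length (chosen-route
#' denominator); `denominator = "symmetric"` divides twice the shared
#' length by the sum of both route lengths instead. Shared means identical
#' edge id — both routes live on the same network — so full overlap is
#' exact edge-set equality.
#'
#' @param chosen,alt `route` objects with the same origin and destination.
#' @param denominator `"chosen"` (default) or `"symmetric"`.
#' @return A proportion in `[0, 1]`.
#' @export
overlap_ratio <- function(chosen, alt, denominator = c("chosen", "symmetric")) {
  denominator <- match.arg(denominator)
  if (chosen$origin != alt$origin || chosen$dest != alt$dest)
    stop("routes do not share an OD pair (",
         chosen$origin, "->", chosen$dest, " vs ",
         alt$origin, "->", alt$dest, ")")
  shared <- intersect(chosen$edges, alt$edges)
  shared_len <- sum(chosen$edge_lengths[shared])
  if (denominator == "chosen") shared_len / chosen$total_length
  else 2 * shared_len / (chosen$total_length + alt$total_length)
}

is_full_overlap <- function(chosen, alt) {
  setequal(chosen$edges, alt$edges)
}

#' Count and percentage of chosen routes fully overlapping an alternative
#'
#' A chosen route fully overlaps its alternative when the two edge sets are
#' identical. The percentage is `round(100 * n_full / n_total)`.
#'
#' @param chosen list of chosen `route`s.
#' @param alts list of alternative `route`s, aligned with `chosen`; or a
#'   list of such lists, in which case a route counts as full overlap only
#'   if it fully overlaps every alternative (the "both alternatives" case).
#' @return list `(n_full, n_total, percentage)`.
#' @export
classify_overlap <- function(chosen, alts) {
  multi <- length(alts) > 0 && !inherits(alts[[1]], "route")
  alt_sets <- if (multi) alts else lapply(alts, list)
  if (length(chosen) != length(alt_sets))
    stop("chosen and alternative lists differ in length (",
         length(chosen), " vs ", length(alt_sets), ")")
  full <- vapply(seq_along(chosen), function(i)
    all(vapply(alt_sets[[i]], is_full_overlap, logical(1),
               chosen = chosen[[i]])), logical(1))
  n_full <- sum(full)
  n_total <- length(chosen)
  list(n_full = n_full, n_total = n_total,
       percentage = round(100 * n_full / n_total),
       is_full = full)
}

#' Share of routes at or above each overlap threshold
#'
#' @param ratios overlap ratios in `[0, 1]`.
#' @param thresholds increasing thresholds in `[0, 1]`.
#' @return Named numeric vector of shares, non-increasing across
#'   increasing thresholds.
#' @export
overlap_distribution <- function(ratios, thresholds) {
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  out <- vapply(thresholds, function(t) mean(ratios >= t), numeric(1))
  names(out) <- paste0(">=", format(thresholds))
  out
}

#' Extract deviated part-routes between a chosen route and an alternative
#'
#' Splits the chosen route into maximal sub-paths absent from the
#' alternative (the deviated part-routes: segments a walker took instead of
#' the alternative) and pairs each with the alternative's sub-path between
#' the same divergence and reconvergence nodes. Pairs are ordered along the
#' chosen route; a fully overlapping pair yields an empty list.
#'
#' @param net the `road_network` both routes live on.
#' @param chosen,alt `route`s over the same OD pair.
#' @return List of pairs, each `(chosen, alt, divergence, reconvergence)`
#'   where `chosen` is a `route` and `alt` is a `route` or `NULL` when the
#'   deviation is a closed loop off a single node of the alternative.
#' @export
extract_deviation_pairs <- function(net, chosen, alt) {
  if (chosen$origin != alt$origin || chosen$dest != alt$dest)
    stop("routes do not share an OD pair")
  off <- !(chosen$edges %in% alt$edges)
  if (!any(off)) return(list())
  runs <- rle(off)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pairs <- list()
  for (j in which(runs$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    div <- chosen$nodes[i0]        # node before the first deviated edge
    rec <- chosen$nodes[i1 + 1L]   # node after the last deviated edge
    sub_chosen <- route(net, chosen$nodes[i0:(i1 + 1L)],
                        chosen$edges[i0:i1])
    sub_alt <- NULL
    if (div != rec) {
      pa <- match(div, alt$nodes)
      pb <- match(rec, alt$nodes)
      if (is.na(pa) || is.na(pb))
        stop("divergence/reconvergence node not on the alternative route")
      lo <- min(pa, pb); hi <- max(pa, pb)
      an <- alt$nodes[lo:hi]
      ae <- alt$edges[lo:(hi - 1L)]
      if (pa > pb) { an <- rev(an); ae <- rev(ae) }
      sub_alt <- route(net, an, ae)
    }
    pairs[[length(pairs) + 1L]] <-
      list(chosen = sub_chosen, alt = sub_alt,
           divergence = div, reconvergence = rec)
  }
  pairs
}

#' Mean route lengths overall and by full-overlap group
#'
#' @param routes list of `route`s.
#' @param full_overlap_flags logical vector aligned with `routes`.
#' @return list `(n, mean_length, mean_length_full, mean_length_partial)`;
#'   group means are `NaN` when a group is empty.
#' @export
summarize_route_lengths <- function(routes, full_overlap_flags) {
  if (length(routes) == 0) stop("no routes to summarize")
  if (length(routes) != length(full_overlap_flags))
    stop("routes and flags differ in length")
  len <- vapply(routes, function(r) r$total_length, numeric(1))
  list(n = length(len),
       mean_length = mean(len),
       mean_length_full = mean(len[full_overlap_flags]),
       mean_length_partial = mean(len[!full_overlap_flags]))
}
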