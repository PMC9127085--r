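#' Street-environment attribute schema
#'
#' The walkability audit records fifteen per-edge attributes in four
#' functional categories. `kind` states how an attribute aggregates from
#' edges to a route: `"mean"` fields (widths, the enclosure D/H ratio,
#' ordinal condition codes, street-front facility proportions) take a
#' length-weighted mean; `"count"` fields (signals, bins, lights, benches)
#' are raw numbers per edge and sum along the route. Ordinal condition
#' codes are coded exactly as audited (poor = 1 ... good = 3; street walls
#' none = 0, railing = 1, solid = 2) and are treated as numeric when
#' length-weighting — an ordinal-as-interval convention, flagged here
#' deliberately.
#'
#' @return data.frame with columns `name`, `kind`, `category`, `lo`, `hi`
#'   (admissible range; `hi = Inf` for unbounded counts/widths) and
#'   `ordinal` (logical; value must lie on the integer codes).
#' @export
env_attribute_schema <- function() {
  data.frame(
    name = c("sidewalk_width", "on_street_parking", "sidewalk_walkability",
             "traffic_signals", "driveway_width",
             "dh_ratio", "green_spaces", "street_walls",
             "garbage_bins", "streetlights", "benches",
             "shops", "life_facilities", "bus_stops", "leisure_facilities"),
    kind = c("mean", "mean", "mean", "count", "mean",
             "mean", "mean", "mean",
             "count", "count", "count",
             "mean", "mean", "mean", "mean"),
    category = c(rep("Roadway features", 5),
                 rep("Streetscape", 3),
                 rep("Pedestrian infrastructure", 3),
                 rep("Facilities", 4)),
    lo = c(0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    hi = c(Inf, 3, 3, Inf, Inf, Inf, 3, 2, Inf, Inf, Inf, 1, 1, 1, 1),
    ordinal = c(FALSE, TRUE, TRUE, FALSE, FALSE,
                FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

env_attribute_names <- function() env_attribute_schema()$name

#' Validate an edge attribute table against the schema
#' @noRd
validate_attributes <- function(attrs, edge_ids) {
  schema <- env_attribute_schema()
  if (is.null(attrs$edge_id)) stop("attribute table lacks an edge_id column")
  missing_cols <- setdiff(schema$name, names(attrs))
  if (length(missing_cols))
    stop("attribute table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  missing_rows <- setdiff(edge_ids, attrs$edge_id)
  if (length(missing_rows))
    stop("attribute rows missing for edges: ",
         paste(missing_rows, collapse = ", "))
  rows <- attrs[match(edge_ids, attrs$edge_id), ]
  for (i in seq_len(nrow(schema))) {
    v <- rows[[schema$name[i]]]
    if (anyNA(v)) stop("NA in attribute ", schema$name[i])
    if (any(v < schema$lo[i] - 1e-12) || any(v > schema$hi[i] + 1e-12))
      stop("attribute ", schema$name[i], " out of range [",
           schema$lo[i], ", ", schema$hi[i], "] for edges: ",
           paste(rows$edge_id[v < schema$lo[i] | v > schema$hi[i]],
                 collapse = ", "))
    if (schema$ordinal[i] && any(v != round(v)))
      stop("attribute ", schema$name[i], " must take integer codes")
  }
  invisible(attrs)
}

# Aggregate an arbitrary edge set to the route level. `lengths` weights the
# mean-type fields; count-type fields are summed (optionally per 100 m).
aggregate_edge_attributes <- function(net, edge_ids, lengths,
                                      counts_per_100m = FALSE) {
  if (is.null(net$attributes)) stop("network has no attribute table")
  schema <- env_attribute_schema()
  rows <- net$attributes[match(edge_ids, net$attributes$edge_id), ]
  total <- sum(lengths)
  out <- numeric(nrow(schema))
  names(out) <- schema$name
  for (i in seq_len(nrow(schema))) {
    v <- rows[[schema$name[i]]]
    out[i] <- if (schema$kind[i] == "mean") {
      sum(v * lengths) / total
    } else if (counts_per_100m) {
      sum(v) * 100 / total
    } else {
      sum(v)
    }
  }
  out
}

#' Aggregate street-environment attributes over a route
#'
#' Widths, the D/H ratio, ordinal condition codes and street-front facility
#' proportions become length-weighted means over the member edges
#' (`sum(value * length) / sum(length)`); signal, bin, light and bench
#' counts are summed. Counts can instead be normalised per 100 m of route
#' with `counts_per_100m = TRUE`.
#'
#' @param net a `road_network` with attributes.
#' @param route a `route` on `net`.
#' @param counts_per_100m normalise count-type attributes by route length.
#' @return An object of class `route_environment`: a named numeric vector of
#'   the fifteen attributes with the route `total_length` (meters) attached
#'   as an attribute of the same name.
#' @export
aggregate_route_environment <- function(net, route, counts_per_100m = FALSE) {
  stopifnot(inherits(route, "route"))
  if (length(route$edges) == 0) stop("cannot aggregate an empty route")
  out <- aggregate_edge_attributes(net, route$edges, route$edge_lengths,
                                   counts_per_100m)
  structure(out, total_length = route$total_length,
            class = c("route_environment", "numeric"))
}

#' Elementwise difference between two route-environment vectors
#'
#' Computes `a - b` attribute by attribute; feeds the conditional-logit
#' choice model, where only within-pair attribute differences matter.
#'
#' @param a,b `route_environment` vectors over the same schema.
#' @param include_length also return the `total_length` difference as an
#'   extra element.
#' @return Named numeric vector of differences.
#' @export
attribute_difference <- function(a, b, include_length = FALSE) {
  if (!identical(names(a), names(b)))
    stop("attribute schemas differ")
  d <- unclass(a) - unclass(b)
  attributes(d) <- list(names = names(a))
  if (include_length)
    d <- c(d, total_length = attr(a, "total_length") - attr(b, "total_length"))
  d
}

#' @export
print.route_environment <- function(x, ...) {
  cat("route_environment (route length",
      format(round(attr(x, "total_length"), 1)), "m):\n")
  print(round(unclass(x), 3))
  invisible(x)
}
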