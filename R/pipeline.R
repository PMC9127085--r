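#' Pipeline configuration
#'
#' @param attributes attribute subset for every model (default: all
#'   fifteen), or a named list with entries `entire_shortest`,
#'   `entire_least_angular`, `part_shortest`, `part_least_angular` to vary
#'   the subset per model (see [attribute_presets()]).
#' @param thresholds overlap thresholds reported in the distribution.
#' @param counts_per_100m normalise count attributes per 100 m when
#'   aggregating.
#' @param min_part_length drop part-route observations whose deviated
#'   chosen sub-route is shorter than this many meters (0 = keep all).
#' @param verbose log stage-level counts to the console.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(attributes = env_attribute_names(),
                            thresholds = c(0.6, 0.7, 0.8, 0.9),
                            counts_per_100m = FALSE,
                            min_part_length = 0,
                            verbose = FALSE) {
  if (!is.list(attributes))
    attributes <- list(entire_shortest = attributes,
                       entire_least_angular = attributes,
                       part_shortest = attributes,
                       part_least_angular = attributes)
  need <- c("entire_shortest", "entire_least_angular",
            "part_shortest", "part_least_angular")
  if (!all(need %in% names(attributes)))
    stop("attributes list must name all four models")
  bad <- setdiff(unique(unlist(attributes)), env_attribute_names())
  if (length(bad))
    stop("unknown attributes: ", paste(bad, collapse = ", "))
  structure(list(attributes = attributes, thresholds = thresholds,
                 counts_per_100m = counts_per_100m,
                 min_part_length = min_part_length, verbose = verbose),
            class = "pipeline_config")
}

# one entire-route observation: {chosen full route, alternative full route},
# chosen first
entire_observation <- function(net, chosen, alt, attributes, per100) {
  x <- rbind(unclass(aggregate_route_environment(net, chosen, per100)),
             unclass(aggregate_route_environment(net, alt, per100)))
  choice_observation(x[, attributes, drop = FALSE], 1L)
}

# one part-route observation: all deviated chosen edges of the trip
# aggregated against the alternative's corresponding sub-routes
part_observation <- function(net, chosen, alt, attributes, per100) {
  pairs <- extract_deviation_pairs(net, chosen, alt)
  if (!length(pairs)) return(NULL)
  ch_edges <- unlist(lapply(pairs, function(p) p$chosen$edges))
  al_edges <- unique(unlist(lapply(pairs, function(p)
    if (is.null(p$alt)) character(0) else p$alt$edges)))
  al_edges <- setdiff(al_edges, ch_edges)
  if (!length(al_edges)) return(NULL)
  ch_len <- net$edges$length[edge_row(net, ch_edges)]
  al_len <- net$edges$length[edge_row(net, al_edges)]
  x <- rbind(aggregate_edge_attributes(net, ch_edges, ch_len, per100),
             aggregate_edge_attributes(net, al_edges, al_len, per100))
  list(obs = choice_observation(x[, attributes, drop = FALSE], 1L),
       part_length = sum(ch_len))
}

fit_or_note <- function(data, attributes, label, verbose) {
  if (length(data) < 2) {
    if (verbose) message(label, ": skipped (", length(data), " observations)")
    return(list(fit = NULL, note = paste0("skipped: only ", length(data),
                                          " observations")))
  }
  fit <- tryCatch(fit_clogit(data, attributes = attributes),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    if (verbose) message(label, ": ", conditionMessage(fit))
    return(list(fit = NULL, note = conditionMessage(fit)))
  }
  if (verbose) message(label, ": fitted on ", length(data), " observations")
  list(fit = fit, note = NULL)
}

#' Run the full route-choice analysis pipeline
#'
#' Orchestrates the analysis end to end: generates the two labeled
#' alternatives per trip, computes overlap statistics (full-overlap counts
#' against each alternative and against both, and the overlap distribution
#' at the configured thresholds), excludes trips whose chosen route fully
#' overlaps the respective alternative, aggregates street-environment
#' attributes over entire routes and over the deviated part-routes, and
#' fits four conditional logit models: {entire, part} x {shortest,
#' least directional change}. The report is deterministic given inputs.
#'
#' @param net a `road_network` with attributes.
#' @param chosen_routes list of chosen `route`s (or a `choice_cohort`).
#' @param config a [pipeline_config()].
#' @param od_ids optional trip identifiers (default `od1`, `od2`, ...).
#' @return An object of class `analysis_report`.
#' @export
run_pipeline <- function(net, chosen_routes, config = pipeline_config(),
                         od_ids = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(chosen_routes, "choice_cohort")) {
    if (is.null(od_ids)) od_ids <- chosen_routes$od_pairs$od_id
    chosen_routes <- chosen_routes$chosen
  }
  n <- length(chosen_routes)
  if (n == 0) stop("no chosen routes")
  if (is.null(od_ids)) od_ids <- paste0("od", seq_len(n))
  # every chosen route must lie on the network
  for (i in seq_len(n)) {
    bad <- setdiff(chosen_routes[[i]]$edges, net$edges$edge_id)
    if (length(bad))
      stop("chosen route ", od_ids[i], " uses unknown edges: ",
           paste(bad, collapse = ", "))
  }
  od <- data.frame(
    od_id = od_ids,
    origin = vapply(chosen_routes, `[[`, character(1), "origin"),
    dest = vapply(chosen_routes, `[[`, character(1), "dest"),
    stringsAsFactors = FALSE)
  if (config$verbose) message("generating alternatives for ", n, " trips")
  alts <- generate_alternatives(net, od)
  shortest <- lapply(alts, `[[`, "shortest")
  least_angular <- lapply(alts, `[[`, "least_angular")

  ratio_s <- vapply(seq_len(n), function(i)
    overlap_ratio(chosen_routes[[i]], shortest[[i]]), numeric(1))
  ratio_a <- vapply(seq_len(n), function(i)
    overlap_ratio(chosen_routes[[i]], least_angular[[i]]), numeric(1))
  cls_s <- classify_overlap(chosen_routes, shortest)
  cls_a <- classify_overlap(chosen_routes, least_angular)
  cls_b <- classify_overlap(chosen_routes,
                            lapply(seq_len(n), function(i)
                              list(shortest[[i]], least_angular[[i]])))
  lengths_summary <- summarize_route_lengths(
    chosen_routes, cls_s$is_full & cls_a$is_full)

  overlap_table <- data.frame(
    od_id = rep(od$od_id, 2L),
    label = rep(c("shortest", "least_angular"), each = n),
    overlap_ratio = c(ratio_s, ratio_a),
    is_full_overlap = c(cls_s$is_full, cls_a$is_full),
    stringsAsFactors = FALSE)

  models <- list(); model_inputs <- list(); notes <- list()
  for (lab in c("shortest", "least_angular")) {
    alt_routes <- if (lab == "shortest") shortest else least_angular
    keep <- which(if (lab == "shortest") !cls_s$is_full else !cls_a$is_full)
    if (config$verbose)
      message(lab, ": ", n - length(keep),
              " full-overlap trips excluded, ", length(keep), " kept")
    entire_data <- lapply(keep, function(i)
      entire_observation(net, chosen_routes[[i]], alt_routes[[i]],
                         config$attributes[[paste0("entire_", lab)]],
                         config$counts_per_100m))
    part_raw <- lapply(keep, function(i)
      part_observation(net, chosen_routes[[i]], alt_routes[[i]],
                       config$attributes[[paste0("part_", lab)]],
                       config$counts_per_100m))
    part_keep <- vapply(part_raw, function(p)
      !is.null(p) && p$part_length >= config$min_part_length, logical(1))
    part_data <- lapply(part_raw[part_keep], `[[`, "obs")
    key_e <- paste0("entire_", lab); key_p <- paste0("part_", lab)
    fe <- fit_or_note(entire_data, NULL, key_e, config$verbose)
    fp <- fit_or_note(part_data, NULL, key_p, config$verbose)
    models[key_e] <- list(fe$fit); notes[key_e] <- list(fe$note)
    models[key_p] <- list(fp$fit); notes[key_p] <- list(fp$note)
    model_inputs[[key_e]] <- od$od_id[keep]
    model_inputs[[key_p]] <- od$od_id[keep][part_keep]
  }

  structure(list(
    n = n,
    mean_trip_length = lengths_summary$mean_length,
    length_summary = lengths_summary,
    full_overlap = list(
      shortest = cls_s[c("n_full", "n_total", "percentage")],
      least_angular = cls_a[c("n_full", "n_total", "percentage")],
      both = cls_b[c("n_full", "n_total", "percentage")]),
    overlap_table = overlap_table,
    overlap_distribution = list(
      shortest = overlap_distribution(ratio_s, config$thresholds),
      least_angular = overlap_distribution(ratio_a, config$thresholds)),
    models = models,
    model_notes = notes,
    model_inputs = model_inputs,
    config = config,
    metadata = list(package_version = as.character(
      utils::packageVersion("routewalk")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Route choice analysis report\n")
  cat(sprintf("  trips: %d, mean length %.1f m\n", x$n, x$mean_trip_length))
  for (lab in names(x$full_overlap)) {
    fo <- x$full_overlap[[lab]]
    cat(sprintf("  full overlap vs %s: %d/%d (%d%%)\n",
                lab, fo$n_full, fo$n_total, fo$percentage))
  }
  for (key in names(x$models)) {
    if (is.null(x$models[[key]])) {
      cat("  model", key, "-", x$model_notes[[key]], "\n")
    } else {
      cat(sprintf("  model %s: n = %d, logLik = %.3f\n",
                  key, x$models[[key]]$n, x$models[[key]]$loglik))
    }
  }
  invisible(x)
}

fmt_num <- function(x, digits = 6) {
  # fixed-format floats so identical runs write byte-identical files
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

#' Write an analysis report to CSV and JSON files
#'
#' Writes `overlap.csv`, one `model_<key>.csv` per fitted model (layout:
#' category, attribute, coef, z, p with a log-likelihood footer row), and
#' `report.json`. Floats are fixed-format so re-running on identical
#' inputs yields byte-identical files.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  ot <- report$overlap_table
  ot$overlap_ratio <- fmt_num(ot$overlap_ratio)
  p <- file.path(dir, "overlap.csv")
  utils::write.csv(ot, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  key_file <- c(entire_shortest = "model_entire_shortest.csv",
                entire_least_angular = "model_entire_angular.csv",
                part_shortest = "model_part_shortest.csv",
                part_least_angular = "model_part_angular.csv")
  for (key in names(report$models)) {
    fit <- report$models[[key]]
    if (is.null(fit)) next
    tab <- model_table(fit)
    out <- data.frame(category = tab$category, attribute = tab$attribute,
                      coef = fmt_num(tab$coef, 3), z = fmt_num(tab$z, 2),
                      p = fmt_num(tab$p, 3), stringsAsFactors = FALSE)
    out <- rbind(out, data.frame(category = "", attribute = "log_likelihood",
                                 coef = fmt_num(fit$loglik, 3), z = "",
                                 p = "", stringsAsFactors = FALSE))
    p <- file.path(dir, key_file[[key]])
    utils::write.csv(out, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  js <- list(
    n = report$n,
    mean_trip_length = round(report$mean_trip_length, 6),
    full_overlap = report$full_overlap,
    overlap_distribution = lapply(report$overlap_distribution,
                                  function(v) round(v, 6)),
    models = lapply(report$models, function(fit) if (is.null(fit)) NULL else
      list(n = fit$n, loglik = round(fit$loglik, 6),
           coefficients = round(fit$coefficients, 6),
           se = round(fit$se, 6))),
    model_notes = report$model_notes,
    metadata = report$metadata)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
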