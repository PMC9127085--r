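#' Build a choice observation
#'
#' One chooser's data: an alternatives-by-attributes matrix and the index
#' of the alternative actually chosen. Utility maximisation with i.i.d.
#' extreme-value noise over these alternatives is the model estimated by
#' [fit_clogit()].
#'
#' @param x numeric matrix, one row per alternative, named attribute
#'   columns; at least two alternatives.
#' @param chosen index of the chosen row.
#' @return An object of class `choice_observation`.
#' @export
choice_observation <- function(x, chosen) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("a choice observation needs at least 2 alternatives")
  if (is.null(colnames(x))) stop("attribute columns must be named")
  chosen <- as.integer(chosen)
  if (chosen < 1 || chosen > nrow(x)) stop("chosen index out of range")
  if (anyNA(x)) stop("NA attribute values in choice observation")
  structure(list(x = x, chosen = chosen), class = "choice_observation")
}

check_choice_data <- function(data) {
  if (!length(data)) stop("empty choice data")
  nm <- colnames(data[[1]]$x)
  for (obs in data) {
    if (!inherits(obs, "choice_observation"))
      stop("choice data must be a list of choice_observation objects")
    if (!identical(colnames(obs$x), nm))
      stop("attribute schemas differ across observations")
  }
  nm
}

subset_attributes <- function(data, attributes) {
  lapply(data, function(obs)
    choice_observation(obs$x[, attributes, drop = FALSE], obs$chosen))
}

#' Conditional logit log-likelihood
#'
#' `sum_n [ beta' x_chosen - log sum_j exp(beta' x_j) ]`, evaluated with
#' log-sum-exp stabilisation so it is finite for any finite input. Only
#' within-observation attribute differences matter: adding a constant to an
#' attribute across all alternatives of an observation leaves the value
#' unchanged.
#'
#' @param beta coefficient vector, one entry per attribute column.
#' @param data list of [choice_observation()]s sharing one schema.
#' @return The log-likelihood (scalar).
#' @export
cl_loglik <- function(beta, data) {
  check_choice_data(data)
  k <- ncol(data[[1]]$x)
  if (length(beta) != k)
    stop("beta has length ", length(beta), " but data has ", k, " attributes")
  ll <- 0
  for (obs in data) {
    u <- drop(obs$x %*% beta)
    m <- max(u)
    ll <- ll + u[obs$chosen] - (m + log(sum(exp(u - m))))
  }
  ll
}

# analytic score and observed information (negative Hessian), accumulated
# across observations; shares the log-sum-exp stabilisation with cl_loglik
cl_score_info <- function(beta, data) {
  k <- length(beta)
  g <- numeric(k)
  info <- matrix(0, k, k)
  ll <- 0
  for (obs in data) {
    u <- drop(obs$x %*% beta)
    m <- max(u)
    w <- exp(u - m)
    pr <- w / sum(w)
    ll <- ll + u[obs$chosen] - (m + log(sum(w)))
    xbar <- drop(pr %*% obs$x)
    g <- g + obs$x[obs$chosen, ] - xbar
    xc <- sweep(obs$x, 2, xbar)
    info <- info + crossprod(xc * sqrt(pr))
  }
  list(ll = ll, score = g, info = info)
}

#' Fit a conditional logit model by maximum likelihood
#'
#' Newton iteration with the analytic score and observed information,
#' started at `beta = 0` (the concave log-likelihood makes this robust),
#' with step halving. Convergence is declared when the score max-norm
#' falls below `grad_tol` or the relative log-likelihood change below
#' `ll_tol`. Standard errors come from the inverse observed information at
#' the optimum; `z = beta/SE` and two-sided normal p values follow.
#'
#' @param data list of [choice_observation()]s.
#' @param attributes character vector naming the attribute subset to fit
#'   (default: all columns). Presets mirroring the four route-choice model
#'   layouts are in [attribute_presets()].
#' @param standardize z-score each attribute (over all alternatives of all
#'   observations) before fitting; coefficients are reported on the
#'   standardized scale.
#' @param max_iter,grad_tol,ll_tol iteration controls.
#' @return An object of class `cl_fit` with `coefficients`, `se`, `z`, `p`,
#'   `vcov`, `loglik`, `loglik_null`, `converged`, `iterations`, `n`.
#' @export
fit_clogit <- function(data, attributes = NULL, standardize = FALSE,
                       max_iter = 100L, grad_tol = 1e-8, ll_tol = 1e-12) {
  check_choice_data(data)
  if (!is.null(attributes)) {
    missing_attr <- setdiff(attributes, colnames(data[[1]]$x))
    if (length(missing_attr))
      stop("unknown attributes: ", paste(missing_attr, collapse = ", "))
    data <- subset_attributes(data, attributes)
  }
  nm <- colnames(data[[1]]$x)
  k <- length(nm)
  # every attribute must vary within at least one choice set
  varies <- rep(FALSE, k)
  for (obs in data)
    varies <- varies | apply(obs$x, 2, function(v) diff(range(v)) > 0)
  if (!all(varies))
    stop("attributes constant within every choice set: ",
         paste(nm[!varies], collapse = ", "))
  if (standardize) {
    allx <- do.call(rbind, lapply(data, `[[`, "x"))
    ctr <- colMeans(allx)
    scl <- apply(allx, 2, stats::sd)
    data <- lapply(data, function(obs)
      choice_observation(scale(obs$x, center = ctr, scale = scl),
                         obs$chosen))
  }
  beta <- numeric(k)
  names(beta) <- nm
  ll0 <- cl_loglik(beta, data)
  ll <- ll0
  converged <- FALSE
  iter <- 0L
  si <- cl_score_info(beta, data)
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(si$info, si$score), error = function(e)
      stop("observed information is singular; attributes may be collinear ",
           "within choice sets"))
    t <- 1
    repeat {
      cand <- beta + t * step
      ll_cand <- cl_loglik(cand, data)
      if (ll_cand >= ll - 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    rel_change <- abs(ll_cand - ll) / (abs(ll) + 1e-12)
    beta <- cand
    ll <- ll_cand
    si <- cl_score_info(beta, data)
    if (max(abs(beta)) > 30)
      stop("likelihood appears unbounded (complete or quasi-complete ",
           "separation): |beta| exceeded 30 for ",
           paste(nm[abs(beta) > 30], collapse = ", "))
    if (max(abs(si$score)) < grad_tol || rel_change < ll_tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  # a perfectly predicted chosen alternative in every choice set means the
  # likelihood supremum (zero) is approached at infinite beta
  if (ll > -1e-6)
    stop("likelihood appears unbounded (complete or quasi-complete ",
         "separation): all chosen alternatives perfectly predicted")
  vcov <- solve(si$info)
  dimnames(vcov) <- list(nm, nm)
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(list(coefficients = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 vcov = vcov, loglik = ll, loglik_null = ll0,
                 converged = converged, iterations = iter,
                 n = length(data), attributes = nm),
            class = "cl_fit")
}

#' @export
print.cl_fit <- function(x, ...) {
  cat("Conditional logit fit:", x$n, "choice sets,",
      length(x$coefficients), "attributes\n")
  print(model_table(x), row.names = FALSE)
  cat(sprintf("Log-likelihood: %.3f (null: %.3f); %s in %d iterations\n",
              x$loglik, x$loglik_null,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Coefficient table grouped by street-environment category
#'
#' Lays out a converged fit as the familiar route-choice results table:
#' rows ordered by the audit tool's functional categories (roadway
#' features, streetscape, pedestrian infrastructure, facilities), with
#' coefficient, z and two-sided p columns. Attributes outside the audit
#' schema are grouped under "Other".
#'
#' @param fit a converged `cl_fit`.
#' @return data.frame with columns `category`, `attribute`, `coef`, `se`,
#'   `z`, `p`.
#' @export
model_table <- function(fit) {
  if (!inherits(fit, "cl_fit")) stop("not a cl_fit object")
  if (!fit$converged)
    stop("model did not converge; refusing to tabulate estimates")
  schema <- env_attribute_schema()
  cat_of <- schema$category[match(fit$attributes, schema$name)]
  cat_of[is.na(cat_of)] <- "Other"
  lev <- c("Roadway features", "Streetscape", "Pedestrian infrastructure",
           "Facilities", "Other")
  ord <- order(match(cat_of, lev), match(fit$attributes, schema$name))
  data.frame(category = cat_of[ord],
             attribute = fit$attributes[ord],
             coef = unname(fit$coefficients[ord]),
             se = unname(fit$se[ord]),
             z = unname(fit$z[ord]),
             p = unname(fit$p[ord]),
             stringsAsFactors = FALSE)
}

#' Attribute subsets mirroring the four route-choice model layouts
#'
#' Named presets for the four models fitted by [run_pipeline()]:
#' entire-route and deviated part-route comparisons against the shortest
#' and the least-directional-change alternative. Each is simply a
#' character vector usable as the `attributes` argument of [fit_clogit()];
#' no automatic selection is performed.
#'
#' @return Named list of character vectors.
#' @export
attribute_presets <- function() {
  list(
    entire_shortest = c("driveway_width", "garbage_bins", "street_walls",
                        "green_spaces", "shops"),
    entire_least_angular = c("sidewalk_width", "benches", "green_spaces",
                             "street_walls", "leisure_facilities",
                             "bus_stops"),
    part_shortest = c("sidewalk_width", "sidewalk_walkability",
                      "driveway_width", "street_walls", "green_spaces",
                      "streetlights"),
    part_least_angular = c("driveway_width", "traffic_signals",
                           "on_street_parking", "street_walls", "dh_ratio",
                           "green_spaces", "leisure_facilities", "shops")
  )
}

#' Build choice observations from a long-format table
#'
#' @param df data.frame with columns `od_id`, `chosen` (0/1, exactly one 1
#'   per `od_id`) and one column per attribute.
#' @param attributes attribute column names; default: every column other
#'   than `od_id`, `chosen` and `alternative_label`.
#' @return List of [choice_observation()]s, ordered by first appearance of
#'   `od_id`.
#' @export
choice_data_from_long <- function(df, attributes = NULL) {
  if (is.null(attributes))
    attributes <- setdiff(names(df), c("od_id", "chosen",
                                       "alternative_label"))
  ids <- unique(df$od_id)
  lapply(ids, function(id) {
    g <- df[df$od_id == id, , drop = FALSE]
    ch <- which(g$chosen == 1)
    if (length(ch) != 1)
      stop("od_id ", id, " must have exactly one chosen alternative")
    choice_observation(as.matrix(g[, attributes, drop = FALSE]), ch)
  })
}
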