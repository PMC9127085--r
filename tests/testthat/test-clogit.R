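# paired observations with attribute matrices drawn once under a seed
sim_paired <- function(n, beta, seed = 1, sd = 1) {
  set.seed(seed)
  k <- length(beta)
  lapply(seq_len(n), function(i) {
    x <- matrix(rnorm(2 * k, sd = sd), nrow = 2,
                dimnames = list(NULL, paste0("a", seq_len(k))))
    u <- drop(x %*% beta) - log(-log(runif(2)))
    choice_observation(x, which.max(u))
  })
}

test_that("the null log-likelihood is -N log(number of alternatives)", {
  data <- sim_paired(37, c(1, -1), seed = 2)
  expect_equal(cl_loglik(c(0, 0), data), -37 * log(2))
  # identical alternatives give -N log(J) for any beta
  x <- matrix(1, nrow = 4, ncol = 2, dimnames = list(NULL, c("a1", "a2")))
  same <- lapply(1:5, function(i) choice_observation(x, 1))
  for (b in list(c(0, 0), c(2, -3), c(-10, 4)))
    expect_equal(cl_loglik(b, same), -5 * log(4))
})

test_that("binary observations follow the closed-form logit identity", {
  x <- matrix(c(1.3, 0), nrow = 2, ncol = 1,
              dimnames = list(NULL, "a1"))
  obs <- list(choice_observation(x, 1))
  for (b in c(-2, -0.5, 0, 1, 3)) {
    dx <- 1.3
    expect_equal(cl_loglik(b, obs), -log(1 + exp(-b * dx)))
  }
})

test_that("adding a constant to an attribute within an observation leaves
           the likelihood unchanged", {
  data <- sim_paired(20, c(0.5, -0.5), seed = 3)
  shifted <- lapply(data, function(obs) {
    x <- obs$x
    x[, 1] <- x[, 1] + 7.5
    choice_observation(x, obs$chosen)
  })
  for (b in list(c(0.3, -1), c(-2, 2)))
    expect_equal(cl_loglik(b, data), cl_loglik(b, shifted))
})

test_that("dimension mismatches and malformed observations error", {
  data <- sim_paired(5, c(1, -1))
  expect_error(cl_loglik(c(1, 2, 3), data), "attributes")
  expect_error(choice_observation(matrix(1, 1, 2,
                                         dimnames = list(NULL, c("a", "b"))),
                                  1), "2 alternatives")
  expect_error(choice_observation(matrix(1, 2, 2,
                                         dimnames = list(NULL, c("a", "b"))),
                                  3), "out of range")
})

test_that("the observed information is positive semi-definite at random
           points (concave log-likelihood)", {
  data <- sim_paired(30, c(1, -0.5), seed = 4)
  set.seed(5)
  for (i in 1:5) {
    b <- rnorm(2)
    info <- routewalk:::cl_score_info(b, data)$info
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-8))
  }
})

test_that("scalar MLE agrees with a one-dimensional brute-force search", {
  data <- sim_paired(200, 0.8, seed = 6)
  data <- lapply(data, function(obs) {
    colnames(obs$x) <- "a1"; obs
  })
  fit <- fit_clogit(data)
  brute <- stats::optimize(function(b) cl_loglik(b, data),
                           interval = c(-10, 10), maximum = TRUE,
                           tol = 1e-10)
  expect_lt(abs(unname(fit$coefficients) - brute$maximum), 1e-6)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("simulated data recover the generating coefficients", {
  beta <- c(1.0, -0.5)
  data <- sim_paired(1000, beta, seed = 7)
  fit <- fit_clogit(data)
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - beta) <= 3 * fit$se))
})

test_that("uniformly random choices give coefficients near zero", {
  set.seed(8)
  data <- lapply(1:2000, function(i) {
    x <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("a1", "a2")))
    choice_observation(x, sample(2, 1))
  })
  fit <- fit_clogit(data)
  expect_true(all(abs(fit$z) < 3))
})

test_that("fit agrees with an independent conditional-logit implementation", {
  data <- sim_paired(300, c(0.7, -0.3), seed = 9)
  fit <- fit_clogit(data)
  df <- do.call(rbind, lapply(seq_along(data), function(i)
    data.frame(id = i, y = as.integer(seq_len(2) == data[[i]]$chosen),
               a1 = data[[i]]$x[, 1], a2 = data[[i]]$x[, 2])))
  suppressPackageStartupMessages(library(survival))
  ref <- clogit(y ~ a1 + a2 + strata(id), data = df)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("a paired fit equals a no-intercept binary logit on differences", {
  data <- sim_paired(400, c(0.5, 0.9), seed = 10)
  fit <- fit_clogit(data)
  dx <- t(vapply(data, function(obs)
    obs$x[obs$chosen, ] - obs$x[3 - obs$chosen, ], numeric(2)))
  glm_fit <- stats::glm(rep(1, nrow(dx)) ~ dx - 1, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(glm_fit)),
               tolerance = 1e-6)
})

test_that("complete separation raises an explicit error", {
  # the chosen alternative always has the strictly larger attribute
  data <- lapply(1:50, function(i) {
    x <- matrix(c(1 + i / 50, 0), 2, 1, dimnames = list(NULL, "a1"))
    choice_observation(x, 1)
  })
  expect_error(fit_clogit(data), "separation")
})

test_that("attributes constant within every choice set are refused", {
  data <- lapply(1:20, function(i) {
    x <- cbind(a1 = rnorm(2), a2 = rep(i, 2))
    choice_observation(x, 1)
  })
  expect_error(fit_clogit(data), "constant within")
})

test_that("95% Wald intervals cover the truth at the nominal rate", {
  beta <- c(1.0, -0.5)
  set.seed(11)
  xs <- lapply(1:500, function(i)
    matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("a1", "a2"))))
  cover <- matrix(FALSE, 200, 2)
  for (r in 1:200) {
    data <- lapply(xs, function(x) {
      u <- drop(x %*% beta) - log(-log(runif(2)))
      choice_observation(x, which.max(u))
    })
    fit <- fit_clogit(data)
    cover[r, ] <- abs(fit$coefficients - beta) <= 1.96 * fit$se
  }
  rate <- colMeans(cover)
  expect_true(all(rate >= 0.93 & rate <= 0.97))
})

test_that("model tables mirror the fit and group by audit category", {
  cfg <- synthetic_config(rows = 5, cols = 5, n_od = 60, seed = 20,
                          beta_true = c(green_spaces = 1,
                                        sidewalk_width = -0.5,
                                        garbage_bins = 0.3))
  net <- generate_network(cfg)
  od <- sample_od_pairs(net, cfg)
  coh <- simulate_choices(net, od, cfg$beta_true, seed = 20)
  fit <- fit_clogit(cohort_choice_data(net, coh))
  tab <- model_table(fit)
  expect_equal(nrow(tab), length(fit$attributes))
  expect_equal(tab$z, tab$coef / tab$se)
  expect_equal(tab$category[tab$attribute == "sidewalk_width"],
               "Roadway features")
  expect_equal(tab$category[tab$attribute == "garbage_bins"],
               "Pedestrian infrastructure")
  # two-sided normal p at z = 1.96 is 0.050 to three decimals
  expect_equal(round(2 * pnorm(-1.96), 3), 0.05)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)))
  bad <- fit; bad$converged <- FALSE
  expect_error(model_table(bad), "converge")
})

test_that("long-format tables build valid choice data", {
  df <- data.frame(od_id = rep(c("t1", "t2"), each = 2),
                   alternative_label = rep(c("chosen", "alt"), 2),
                   chosen = c(1, 0, 0, 1),
                   a1 = c(1, 2, 3, 4), a2 = c(0, 1, 1, 0))
  data <- choice_data_from_long(df)
  expect_length(data, 2)
  expect_equal(data[[1]]$chosen, 1L)
  expect_equal(data[[2]]$chosen, 2L)
  expect_equal(colnames(data[[1]]$x), c("a1", "a2"))
  df_bad <- df; df_bad$chosen[2] <- 1
  expect_error(choice_data_from_long(df_bad), "exactly one")
})
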