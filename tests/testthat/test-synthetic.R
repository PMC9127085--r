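test_that("a zero-jitter 4x4 grid is rectilinear with 24 edges", {
  cfg <- synthetic_config(rows = 4, cols = 4, jitter_sd = 0,
                          block_length_cv = 0, seed = 1)
  net <- generate_network(cfg)
  expect_equal(nrow(net$edges), 24)
  expect_equal(nrow(net$nodes), 16)
  sg <- to_segment_graph(net)
  expect_true(all(abs(sg$links$angular_cost) < 1e-9 |
                    abs(sg$links$angular_cost - 1) < 1e-9))
})

test_that("generation is fully determined by the seed", {
  cfg <- synthetic_config(rows = 5, cols = 5, n_od = 20, seed = 99)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$attributes, n2$attributes)
  od1 <- sample_od_pairs(n1, cfg)
  od2 <- sample_od_pairs(n2, cfg)
  expect_identical(od1, od2)
  c1 <- simulate_choices(n1, od1, cfg$beta_true, seed = cfg$seed)
  c2 <- simulate_choices(n2, od2, cfg$beta_true, seed = cfg$seed)
  expect_identical(lapply(c1$chosen, `[[`, "edges"),
                   lapply(c2$chosen, `[[`, "edges"))
  c3 <- simulate_choices(n1, od1, cfg$beta_true, seed = cfg$seed + 1)
  expect_false(identical(lapply(c1$chosen, `[[`, "edges"),
                         lapply(c3$chosen, `[[`, "edges")))
})

test_that("degenerate grids are rejected", {
  expect_error(synthetic_config(rows = 1, cols = 5), "degenerate")
  expect_error(synthetic_config(beta_true = c(nonsense = 1)), "named")
})

test_that("attribute marginals match their configured means at large n", {
  # ~10,000 edges: a 71 x 71 grid
  cfg <- synthetic_config(rows = 71, cols = 71, jitter_sd = 0,
                          block_length_cv = 0, seed = 13)
  net <- generate_network(cfg)
  expect_gte(nrow(net$edges), 9900)
  mu <- attribute_means(cfg)
  for (nm in names(mu)) {
    v <- net$attributes[[nm]]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - mu[[nm]]), 3 * se + 1e-12,
              label = paste("mean of", nm))
  }
})

test_that("sampled OD pairs respect the trip-length band and target", {
  cfg <- synthetic_config(rows = 8, cols = 8, n_od = 200,
                          trip_length_target = 350, seed = 17)
  net <- generate_network(cfg)
  od <- sample_od_pairs(net, cfg)
  expect_equal(nrow(od), 200)
  expect_true(all(od$shortest_length >= 175 & od$shortest_length <= 700))
  expect_lt(abs(mean(od$shortest_length) - 350), 0.2 * 350)
  # the recorded shortest length is the routed shortest length
  r <- shortest_distance_route(net, od$origin[1], od$dest[1])
  expect_equal(r$total_length, od$shortest_length[1])
})

test_that("zero coefficients give uniform choices between distinct
           alternatives", {
  cfg <- synthetic_config(rows = 6, cols = 6, n_od = 400, seed = 23,
                          beta_true = c(green_spaces = 0))
  net <- generate_network(cfg)
  od <- sample_od_pairs(net, cfg)
  coh <- simulate_choices(net, od, cfg$beta_true, seed = 23)
  informative <- coh$chosen_label != "coincident"
  share <- mean(coh$chosen_label[informative] == "shortest")
  n <- sum(informative)
  expect_gt(n, 50)
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / n))
})

test_that("pairwise choice frequencies follow the logit closed form", {
  cfg <- synthetic_config(rows = 6, cols = 6, n_od = 500, seed = 31)
  net <- generate_network(cfg)
  od <- sample_od_pairs(net, cfg)
  coh <- simulate_choices(net, od, cfg$beta_true, seed = 31)
  keep <- which(coh$chosen_label != "coincident")
  p_short <- vapply(keep, function(i) {
    xs <- aggregate_route_environment(net, coh$alternatives[[i]]$shortest)
    xa <- aggregate_route_environment(net,
                                      coh$alternatives[[i]]$least_angular)
    d <- attribute_difference(xs, xa)[names(cfg$beta_true)]
    stats::plogis(sum(cfg$beta_true * d))
  }, numeric(1))
  y <- as.integer(coh$chosen_label[keep] == "shortest")
  # empirical frequency matches the mean model probability within MC error
  se <- sqrt(sum(p_short * (1 - p_short))) / length(y)
  expect_lt(abs(mean(y) - mean(p_short)), 4 * se)
})

test_that("a strong preference picks the greener alternative when the gap
           is large", {
  cfg <- synthetic_config(rows = 6, cols = 6, n_od = 300, seed = 41,
                          beta_true = c(green_spaces = 5))
  net <- generate_network(cfg)
  od <- sample_od_pairs(net, cfg)
  coh <- simulate_choices(net, od, cfg$beta_true, seed = 41)
  keep <- which(coh$chosen_label != "coincident")
  gap <- vapply(keep, function(i) {
    xs <- aggregate_route_environment(net, coh$alternatives[[i]]$shortest)
    xa <- aggregate_route_environment(net,
                                      coh$alternatives[[i]]$least_angular)
    unname(attribute_difference(xs, xa)["green_spaces"])
  }, numeric(1))
  big <- abs(gap) > 0.5
  expect_gt(sum(big), 10)
  chose_greener <- (coh$chosen_label[keep] == "shortest") == (gap > 0)
  expect_gt(mean(chose_greener[big]), 0.9)
})

test_that("choice-set mode adds detour alternatives on the same OD pair", {
  cfg <- synthetic_config(rows = 5, cols = 5, n_od = 15, seed = 43)
  net <- generate_network(cfg)
  od <- sample_od_pairs(net, cfg)
  coh <- simulate_choices(net, od, cfg$beta_true, mode = "choice_set",
                          seed = 43, n_detours = 3)
  sizes <- vapply(coh$alternatives, length, integer(1))
  expect_true(any(sizes > 2))
  for (i in seq_along(coh$alternatives)) {
    for (alt in coh$alternatives[[i]]) {
      expect_equal(alt$origin, od$origin[i])
      expect_equal(alt$dest, od$dest[i])
    }
  }
})

test_that("end-to-end recovery: fitting simulated choices returns the
           generating coefficients within 3 SEs", {
  for (seed in c(101, 202, 303)) {
    cfg <- synthetic_config(rows = 8, cols = 8, n_od = 500, seed = seed,
                            beta_true = c(green_spaces = 1.0,
                                          sidewalk_width = -0.5))
    net <- generate_network(cfg)
    od <- sample_od_pairs(net, cfg)
    coh <- simulate_choices(net, od, cfg$beta_true, seed = seed)
    fit <- fit_clogit(cohort_choice_data(net, coh))
    expect_true(fit$converged)
    expect_true(all(abs(fit$coefficients - cfg$beta_true) <= 3 * fit$se),
                label = paste("recovery at seed", seed))
  }
})
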