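test_that("effect statistic matches hand computation on a two-channel toy", {
  # cells (more.pre, more.post, less.pre, less.post); only less.post flips
  cells <- cbind(c(1, -1), c(1, -1), c(1, -1), c(-1, 1))
  # double difference / 4 = (c1 - c2 - c3 + c4)/4 = ([-2,2])/4 -> GFP 0.5
  expect_equal(effect_statistic(cells, "interaction"), 0.5)
  # session marginal difference: (c1+c3)/2 - (c2+c4)/2 = ([1,-1]-[0,0]) ->
  # GFP 1... computed by hand: means [1,-1] and [0,0], difference [1,-1]
  expect_equal(effect_statistic(cells, "session"), 1)
  # identical cell maps -> 0 for every effect
  same <- cbind(c(2, -2), c(2, -2), c(2, -2), c(2, -2))
  for (eff in c("session", "side", "interaction"))
    expect_equal(effect_statistic(same, eff), 0)
})

test_that("main-effect statistic ignores relabeling of the other factor", {
  set.seed(55)
  cells <- matrix(rnorm(16 * 4), 16, 4)
  # swapping the side levels permutes columns (1,2,3,4) -> (3,4,1,2)
  expect_equal(effect_statistic(cells, "session"),
               effect_statistic(cells[, c(3, 4, 1, 2)], "session"),
               tolerance = 1e-12)
})

test_that("TANOVA is deterministic given a seed and p-values respect add-one", {
  cfg <- tiny_config()
  sim <- simulate_erp_dataset(cfg, seed = 19)
  a <- tanova(sim$dataset, effect = "interaction", n_permutations = 199,
              seed = 3, window = c(250, 550))
  b <- tanova(sim$dataset, effect = "interaction", n_permutations = 199,
              seed = 3, window = c(250, 550))
  expect_identical(a$table, b$table)
  expect_true(all(a$table$p >= 1 / 200, na.rm = TRUE))
  expect_true(all(a$table$p <= 1, na.rm = TRUE))
  expect_error(tanova(sim$dataset, effect = "interaction",
                      n_permutations = 50, seed = 1), "at least 99")
  expect_error(tanova(sim$dataset, effect = "interaction",
                      n_permutations = 999), "seed")
})

test_that("label-symmetric data never give p = 0 (add-one boundary)", {
  # all cells identical: every permutation ties the observed statistic
  ds <- toy_dataset(n_channels = 6, n_time = 30, n_subjects = 4)
  for (cond in dimnames(ds$data)[[4]]) ds$data[, , , cond] <- ds$data[, , , 1]
  res <- tanova(ds, effect = "interaction", n_permutations = 199, seed = 2,
                window = c(0, 30))
  expect_true(all(res$table$p == 1, na.rm = TRUE))
})

test_that("Monte-Carlo p agrees with full sign-flip enumeration", {
  cfg <- tiny_config(n_subjects = 5)
  sim <- simulate_erp_dataset(cfg, seed = 23)
  ds <- sim$dataset
  res <- tanova(ds, effect = "interaction", n_permutations = 999, seed = 31,
                window = c(300, 310))
  # independent oracle: per-subject interaction contrast of GFP-normalized
  # maps, then exact enumeration of all 2^5 sign patterns
  i <- window_samples(ds, c(300, 310))[1]
  cells <- c("puff.more.pre", "puff.more.post", "puff.less.pre",
             "puff.less.post")
  C <- sapply(erp_subjects(ds), function(s) {
    maps <- sapply(cells, function(cond)
      normalize_gfp(ds$data[, i, s, cond]))
    (maps[, 1] - maps[, 2] - maps[, 3] + maps[, 4]) / 4
  })
  n <- ncol(C)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_stats <- apply(signs, 1, function(sg) gfp(C %*% sg / n))
  obs <- gfp(rowMeans(C))
  p_exact <- mean(null_stats >= obs - 1e-15)
  p_mc <- res$table$p[1]
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 1000)
})

test_that("null p-values are approximately uniform across seeds", {
  cfg <- sim_config(n_channels = 16, scenario = "null")
  ps <- sapply(1:150, function(s) {
    sim <- simulate_erp_dataset(cfg, seed = 7000 + s)
    tanova(sim$dataset, effect = "session", n_permutations = 199,
           seed = 7500 + s, window = c(300, 308))$table$p[1]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted session x side topography swap is detected in-window", {
  cfg <- sim_config()
  found <- sapply(1:15, function(s) {
    sim <- simulate_erp_dataset(cfg, seed = 800 + s)
    res <- tanova(sim$dataset, effect = "interaction",
                  n_permutations = 999, seed = 900 + s)
    any(res$runs$start < 550 & res$runs$end > 250)
  })
  expect_gte(mean(found), 0.9)
  # matched sham analysis stays null most of the time
  null_runs <- sapply(1:15, function(s) {
    sim <- simulate_erp_dataset(cfg, seed = 800 + s)
    res <- tanova(sim$dataset, stimulus = "sham", effect = "interaction",
                  n_permutations = 999, seed = 900 + s)
    nrow(res$runs) > 0
  })
  expect_lte(mean(null_runs), 0.1)
})
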