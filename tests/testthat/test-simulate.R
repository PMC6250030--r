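test_that("configuration invariants are enforced", {
  tls_bad <- default_timelines()
  tls_bad$puff.more.pre <- data.frame(template = 1:2,
                                      fraction = c(0.5, 0.4))
  expect_error(sim_config(timelines = tls_bad), "sum to 1")
  expect_error(sim_config(n_channels = 1), "2 channels")
  expect_error(sim_config(analysis_window = c(250, 800)), "contain")
  cfg <- sim_config()
  # template bank is average-referenced and unit-GFP
  expect_true(all(abs(colMeans(cfg$templates)) < 1e-12))
  expect_equal(apply(cfg$templates, 2, function(v) sqrt(mean(v^2))),
               rep(1, 3), tolerance = 1e-12)
})

test_that("the same seed yields a bit-identical dataset", {
  cfg <- tiny_config()
  a <- simulate_erp_dataset(cfg, seed = 7)
  b <- simulate_erp_dataset(cfg, seed = 7)
  expect_identical(a$dataset$data, b$dataset$data)
  expect_identical(a$truth$durations, b$truth$durations)
  c <- simulate_erp_dataset(cfg, seed = 8)
  expect_false(identical(a$dataset$data, c$dataset$data))
})

test_that("generated ERPs are average-referenced at every time point", {
  sim <- simulate_erp_dataset(tiny_config(), seed = 5)
  expect_true(max(abs(colMeans(sim$dataset$data))) < 1e-12)
})

test_that("with zero noise the GFP time course equals the envelope exactly", {
  cfg <- tiny_config(noise_sd = 0)
  sim <- simulate_erp_dataset(cfg, seed = 2)
  env <- cfg$envelope(erp_times(sim$dataset))
  g <- gfp_series(sim$dataset)
  for (cond in dimnames(g)[[3]])
    expect_equal(unname(g[, , cond]),
                 matrix(env, length(env), cfg$n_subjects),
                 tolerance = 1e-9)
})

test_that("noise-free single-template data correlate 1 with that template", {
  one_map <- timeline(1L, 1)
  tls <- rep(list(one_map), 8)
  names(tls) <- condition_grid()$condition
  cfg <- tiny_config(noise_sd = 0, timelines = tls, kappa = Inf,
                     background_template = 1L)
  sim <- simulate_erp_dataset(cfg, seed = 4)
  idx <- window_samples(sim$dataset, c(250, 550))
  for (s in 1:2) for (cond in c("puff.more.pre", "sham.less.post"))
    for (i in idx[c(1, 10, 30)])
      expect_equal(spatial_correlation(sim$dataset$data[, i, s, cond],
                                       cfg$templates[, 1]), 1,
                   tolerance = 1e-9)
})

test_that("noise-free back-fitting recovers scheduled fractions exactly", {
  tls <- default_timelines("crossover")
  cfg <- tiny_config(noise_sd = 0, kappa = Inf)
  sim <- simulate_erp_dataset(cfg, seed = 6)
  dur <- backfit(sim$dataset, cfg$templates, window = c(250, 550))
  idx_n <- length(window_samples(sim$dataset, c(250, 550)))
  for (cond in names(tls)[1:4]) {
    tl <- tls[[cond]]
    planted <- vapply(1:3, function(m)
      sum(topoplast:::apportion(tl$fraction, idx_n)[tl$template == m]) /
        idx_n, numeric(1))
    got <- dur[dur$condition == cond & dur$subject == "S01", ]
    got <- got$fraction[match(paste0("map", 1:3), got$map)]
    expect_equal(got, planted, tolerance = 1e-12)
  }
})

test_that("occupancy recovery is within 5 points of the schedule over seeds", {
  # moderate noise (SD = half the envelope peak), 10 subjects, 20 seeds
  cfg <- sim_config()
  tls <- default_timelines("crossover")
  err <- sapply(1:20, function(s) {
    sim <- simulate_erp_dataset(cfg, seed = 600 + s)
    dur <- backfit(sim$dataset, cfg$templates)
    mean_rec <- aggregate(fraction ~ condition + map,
                          dur[dur$map != "unlabeled", ], mean)
    sched_of <- function(cond, m) sum(tls[[cond]]$fraction[
      tls[[cond]]$template == as.integer(sub("map", "", m))])
    abs(mapply(sched_of, mean_rec$condition, mean_rec$map) -
        mean_rec$fraction)
  })
  expect_lt(mean(err), 0.05)
})

test_that("trial counts are reproducible and drive the inclusion filter", {
  cfg <- tiny_config()
  a <- simulate_trial_counts(cfg, seed = 1)
  b <- simulate_trial_counts(cfg, seed = 1)
  expect_identical(a, b)
  sim <- simulate_erp_dataset(cfg, seed = 1)
  counts <- simulate_trial_counts(cfg, seed = 1)
  counts[] <- 20
  counts["S03", "puff.less.post"] <- 11
  expect_message(kept <- filter_min_trials(sim$dataset, counts), "S03")
  expect_false("S03" %in% erp_subjects(kept))
})

test_that("behavioral links are monotone: perfect, null and planted cases", {
  cfg <- tiny_config(behavior_links = list(grip = list(map = 1, rho = -1)))
  sim <- simulate_erp_dataset(cfg, seed = 12)
  beh <- simulate_behavior_table(cfg, sim$truth, seed = 13)
  dur <- backfit(sim$dataset, cfg$templates)
  # rho = -1 with zero score noise: sample Spearman is exactly -1
  r <- pooled_hand_correlation(dur, beh, "map1", "grip", "pre")
  expect_equal(r$rho, -1, tolerance = 1e-12)
  # zero link: mean rho near 0 over 50 seeds
  cfg0 <- tiny_config(n_subjects = 10,
                      behavior_links = list(grip = list(map = 1, rho = 0)))
  rhos <- sapply(1:50, function(s) {
    sim <- simulate_erp_dataset(cfg0, seed = 100 + s)
    beh <- simulate_behavior_table(cfg0, sim$truth, seed = 200 + s)
    dur <- backfit(sim$dataset, cfg0$templates)
    pooled_hand_correlation(dur, beh, "map1", "grip", "pre")$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
  expect_error(simulate_behavior_table(cfg, list()), "durations")
})
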