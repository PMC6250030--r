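test_that("sample-wise GFP ANOVA matches the brute-force oracle and aov", {
  cfg <- tiny_config(n_subjects = 3)
  sim <- simulate_erp_dataset(cfg, seed = 41)
  ds <- sim$dataset
  res <- gfp_anova(ds, window = c(-100, 700))
  g <- gfp_series(ds)
  cells <- condition_grid()
  cells <- cells$condition[cells$stimulus == "puff"]
  tt <- erp_times(ds)
  for (i in sample(which(tt >= -100 & tt < 700), 5)) {
    y <- as.vector(g[i, , cells])
    grid <- expand.grid(subject = factor(1:3),
                        session = factor(c("pre", "post")),
                        side = factor(c("more", "less")))
    # cells order: more.pre, more.post, less.pre, less.post; expand.grid
    # varies subject fastest, then session, then side -- matches g[i,,cells]
    br <- brute_rm_anova(y, grid[, c("session", "side")], grid$subject)
    for (eff in c("session", "side")) {
      got <- res$table[res$table$time == tt[i] & res$table$effect == eff, ]
      expect_equal(got$F, br$F[br$effect == eff], tolerance = 1e-8)
    }
    got <- res$table[res$table$time == tt[i] &
                       res$table$effect == "interaction", ]
    expect_equal(got$F, br$F[br$effect == "session:side"], tolerance = 1e-8)
  }
})

test_that("identical data in all cells yield no significant samples", {
  ds <- toy_dataset(n_channels = 6, n_time = 50, n_subjects = 4)
  for (cond in dimnames(ds$data)[[4]]) ds$data[, , , cond] <- ds$data[, , , 1]
  res <- gfp_anova(ds, window = c(0, 50))
  expect_true(all(res$table$F == 0))
  expect_true(all(res$table$p == 1))
  expect_equal(nrow(res$runs), 0)
})

test_that("duration criterion keeps 20 ms runs and rejects 19 ms runs", {
  p <- rep(1, 100)
  p[11:29] <- 0.01                       # 19 samples at 1000 Hz = 19 ms
  expect_equal(nrow(enforce_duration(p, 0.05, 20, 1000)), 0)
  p[11:30] <- 0.01                       # 20 ms: kept, half-open bounds
  runs <- enforce_duration(p, 0.05, 20, 1000)
  expect_equal(runs$start, 10)
  expect_equal(runs$end, 30)
  expect_equal(runs$duration, 20)
  expect_equal(nrow(enforce_duration(rep(1, 50), 0.05, 20, 1000)), 0)
})

test_that("raising the minimum duration never adds runs (monotone filter)", {
  set.seed(77)
  for (i in 1:20) {
    p <- runif(200)
    r20 <- enforce_duration(p, 0.3, 20, 1000)
    r30 <- enforce_duration(p, 0.3, 30, 1000)
    # every run at 30 ms is one of the runs at 20 ms
    if (nrow(r30))
      expect_true(all(r30$start %in% r20$start))
    expect_lte(nrow(r30), nrow(r20))
  }
})

test_that("null GFP data give alpha-level sample significance, rare runs", {
  cfg <- sim_config(n_channels = 16, scenario = "null")
  hits <- numeric(200); fam <- logical(200)
  for (s in 1:200) {
    sim <- simulate_erp_dataset(cfg, seed = 4000 + s)
    res <- gfp_anova(sim$dataset, window = c(0, 700))
    pi <- res$table$p[res$table$effect == "interaction"]
    hits[s] <- mean(pi < 0.05)
    fam[s] <- nrow(res$runs[res$runs$effect == "interaction", ]) > 0
  }
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
  expect_lte(mean(fam), 0.25)            # family-wise rate after the filter
})

test_that("a planted GFP interaction is detected by a run in its window", {
  cfg <- sim_config(n_channels = 16, scenario = "null")
  found <- sapply(1:20, function(s) {
    sim <- simulate_erp_dataset(cfg, seed = 4500 + s)
    ds <- sim$dataset
    idx <- window_samples(ds, c(300, 400))
    ds$data[, idx, , "puff.more.post"] <- 1.5 * ds$data[, idx, , "puff.more.post"]
    res <- gfp_anova(ds, window = c(0, 700))
    runs <- res$runs[res$runs$effect == "interaction", ]
    any(runs$start < 400 & runs$end > 300)
  })
  expect_gte(mean(found), 0.9)
})
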