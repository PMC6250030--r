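test_that("noise-free two-template data are recovered exactly at k = 2", {
  tls <- rep(list(timeline(c(1, 2), c(0.5, 0.5))), 8)
  names(tls) <- condition_grid()$condition
  cfg <- tiny_config(noise_sd = 0, timelines = tls, kappa = Inf)
  sim <- simulate_erp_dataset(cfg, seed = 51)
  seg <- segment_topographies(sim$dataset, k_range = 1:4)
  f2 <- coef(seg, k = 2)
  m <- match_templates(cfg$templates[, 1:2], f2)
  expect_true(all(m$best > 1 - 1e-9))
  expect_equal(seg$gev[["2"]], 1, tolerance = 1e-9)
  # labeling covers half/half in every condition
  lab <- segmentation_labels(seg, k = 2)
  expect_equal(unname(rowMeans(lab == lab[1, 1])), rep(0.5, 4))
})

test_that("single-template data give GEV 1 at k = 1 and a guarded fallback", {
  tls <- rep(list(timeline(1L, 1)), 8)
  names(tls) <- condition_grid()$condition
  cfg <- tiny_config(noise_sd = 0, timelines = tls, kappa = Inf,
                     background_template = 1L)
  sim <- simulate_erp_dataset(cfg, seed = 52)
  expect_warning(seg <- segment_topographies(sim$dataset, k_range = 1:3),
                 "degenerate|falling back")
  expect_equal(seg$k_opt, 1)
  expect_equal(seg$gev[["1"]], 1, tolerance = 1e-9)
})

test_that("GEV is nondecreasing in k and dispersion W nonincreasing", {
  cfg <- tiny_config()
  sim <- simulate_erp_dataset(cfg, seed = 53)
  seg <- segment_topographies(sim$dataset, k_range = 1:6)
  expect_true(all(diff(seg$gev) >= -1e-9))
  expect_true(all(diff(seg$W) <= 1e-9))
})

test_that("sign-flipped input yields sign-flipped maps, same labeling", {
  cfg <- tiny_config()
  sim <- simulate_erp_dataset(cfg, seed = 54)
  seg1 <- segment_topographies(sim$dataset, k_range = 1:4)
  flipped <- sim$dataset
  flipped$data <- -flipped$data
  seg2 <- segment_topographies(flipped, k_range = 1:4)
  expect_equal(coef(seg2, 3), -coef(seg1, 3), tolerance = 1e-9)
  expect_equal(segmentation_labels(seg2, 3), segmentation_labels(seg1, 3))
})

test_that("KL criterion has an interior argmax on a planted-elbow curve and
           is flat on a geometric curve", {
  ks <- 1:8
  # sharp elbow at k = 3
  W <- c(100, 60, 10, 9, 8, 7, 6, 5)
  kl <- topoplast:::kl_index(ks, W, m = 31)
  expect_equal(ks[which.max(kl$index)], 3)
  # strictly geometric dispersion: no pronounced elbow; the documented tie
  # rule (argmax; ties toward smallest k) still returns an interior k
  Wg <- 100 * 0.5^(ks - 1)
  klg <- topoplast:::kl_index(ks, Wg, m = 31)
  expect_equal(klg$index[1], 0)
  expect_equal(klg$index[8], 0)
  expect_equal(ks[which.max(klg$index)], 2)
})

test_that("three planted templates are selected and recovered under noise", {
  cfg <- sim_config()      # moderate noise: SD = half the envelope peak
  hit <- sapply(1:20, function(s) {
    sim <- simulate_erp_dataset(cfg, seed = 1500 + s)
    seg <- segment_topographies(sim$dataset)
    m <- match_templates(cfg$templates, coef(seg, k = 3))
    c(k3 = seg$k_opt == 3, rec = all(m$best >= 0.95))
  })
  expect_gte(mean(hit["k3", ]), 0.9)
  expect_gte(mean(hit["rec", ]), 0.9)
})

test_that("clustering rejects empty windows and degenerate input", {
  cfg <- tiny_config(noise_sd = 0)
  sim <- simulate_erp_dataset(cfg, seed = 55)
  expect_error(segment_topographies(sim$dataset, window = c(900, 950)),
               "outside")
  # pre-stimulus noise-free data are flat everywhere
  expect_error(segment_topographies(sim$dataset, window = c(-200, -100)),
               "degenerate")
})
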