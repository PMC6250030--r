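make_behavior <- function(score_fun) {
  grid <- expand.grid(subject = sprintf("S%02d", 1:10),
                      hand = c("more", "less"), session = c("pre", "post"),
                      test = c("grip", "stereognosis", "two_point"),
                      stringsAsFactors = FALSE)
  grid$score <- mapply(score_fun, grid$subject, grid$hand, grid$session,
                       grid$test)
  class(grid) <- c("behavior_table", "data.frame")
  grid
}

test_that("identical hands give t = 0 and one-tailed p = 0.5", {
  tb <- make_behavior(function(s, h, se, te) match(s, sprintf("S%02d", 1:10)))
  res <- paired_hand_tests(tb, "pre")
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 0.5))
})

test_that("a constant nonzero difference is flagged degenerate", {
  tb <- make_behavior(function(s, h, se, te)
    match(s, sprintf("S%02d", 1:10)) + (h == "less") * 2)
  res <- paired_hand_tests(tb, "pre")
  g <- res[res$test == "grip", ]
  expect_true(g$degenerate)
  expect_equal(g$t, Inf)        # less > more, "greater" direction
  expect_equal(g$p, 0)
  # for two-point distance the direction is reversed (lower is better)
  tp <- res[res$test == "two_point", ]
  expect_equal(tp$p, 1)
})

test_that("one-tailed directions follow the documented better-hand table", {
  set.seed(71)
  # less affected hand clearly better on every test
  tb <- make_behavior(function(s, h, se, te) {
    base <- rnorm(1, 10, 1)
    if (te == "two_point") base - (h == "less") * 4   # smaller is better
    else base + (h == "less") * 4                     # larger is better
  })
  res <- paired_hand_tests(tb, "pre")
  expect_true(all(res$p < 0.05))
  # flip the asymmetry: all one-tailed p near 1
  tb2 <- make_behavior(function(s, h, se, te) {
    base <- rnorm(1, 10, 1)
    if (te == "two_point") base + (h == "less") * 4
    else base - (h == "less") * 4
  })
  res2 <- paired_hand_tests(tb2, "pre")
  expect_true(all(res2$p > 0.95))
})

test_that("pre/post change tests localise a planted grip gain", {
  cfg <- sim_config()
  hits <- sapply(1:15, function(s) {
    set.seed(3100 + s)
    tb <- make_behavior(function(su, h, se, te) {
      gain <- if (te == "grip" && h == "more" && se == "post") 4 else 0
      rnorm(1, 10, 1.5) + gain
    })
    res <- pre_post_change_tests(tb)
    grip_more <- res$p[res$test == "grip" & res$hand == "more"] < 0.05
    others <- res$p[!(res$test == "grip" & res$hand == "more")]
    c(hit = grip_more, fp = mean(others < 0.05))
  })
  expect_gte(mean(hits["hit", ]), 0.8)
  expect_lt(mean(hits["fp", ]), 0.15)
})

test_that("pooled correlation is exact for monotone links and flags
           zero-variance input", {
  dur <- expand.grid(subject = sprintf("S%02d", 1:10),
                     side = c("more", "less"), session = "pre",
                     stringsAsFactors = FALSE)
  dur$condition <- condition_id("puff", dur$side, dur$session)
  dur$map <- "map1"
  dur$fraction <- seq(0.05, 1, length.out = 20)
  class(dur) <- c("fit_durations", "data.frame")
  tb <- data.frame(subject = dur$subject, hand = dur$side, session = "pre",
                   test = "grip", score = 100 - dur$fraction^3)
  class(tb) <- c("behavior_table", "data.frame")
  r <- pooled_hand_correlation(dur, tb, "map1", "grip", "pre")
  expect_equal(r$rho, -1)
  expect_equal(r$n, 20)
  # Spearman is invariant under strictly monotone transforms
  tb$score <- exp(-dur$fraction)
  r2 <- pooled_hand_correlation(dur, tb, "map1", "grip", "pre")
  expect_equal(r2$rho, -1)
  # zero variance -> flagged, not a number
  tb$score <- 5
  r3 <- pooled_hand_correlation(dur, tb, "map1", "grip", "pre")
  expect_true(r3$degenerate)
  expect_true(is.na(r3$rho))
})

test_that("exact-permutation and t-approximation p-values are sensible", {
  st_small <- topoplast:::spearman_test(1:6, c(2, 1, 4, 3, 6, 5))
  # exact enumeration: p is a multiple of 1/720 in (0, 1]
  expect_true(st_small$p > 0 && st_small$p <= 1)
  expect_equal(st_small$p * 720, round(st_small$p * 720), tolerance = 1e-9)
  st_large <- topoplast:::spearman_test(1:20, c(2:20, 1))
  expect_true(st_large$p < 0.05)       # strong monotone association
})
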