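# Behavioral-table statistics: between-hand paired tests, pre/post change
# tests and pooled-hand Spearman correlations against map durations.

# Directional hypothesis per test for the one-tailed between-hand
# comparison: the less affected hand performs better.  "greater" means the
# less affected hand is expected to score higher (counts, forces);
# "less" means lower scores are better (detection-threshold grams,
# two-point distance in mm).
hand_test_direction <- function(test) {
  better_high <- c("localization", "stereognosis", "pinch", "grip")
  better_low <- c("registration", "two_point")
  if (test %in% better_high) "greater"
  else if (test %in% better_low) "less"
  else "two.sided"
}

validate_behavior <- function(table) {
  need <- c("subject", "hand", "session", "test", "score")
  if (!all(need %in% names(table)))
    stop("behavior table needs columns: ", paste(need, collapse = ", "))
  table
}

#' Read / write a behavioral score table
#'
#' Long-format tab-delimited text with columns `subject`, `hand`
#' (`more`/`less` affected), `session` (`pre`/`post`), `test`, `score`.
#'
#' @param path File path.
#' @return A `behavior_table` data frame.
#' @export
read_behavior_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tb <- validate_behavior(tb)
  class(tb) <- c("behavior_table", "data.frame")
  tb
}

#' @rdname read_behavior_table
#' @param table A `behavior_table`.
#' @export
write_behavior_table <- function(table, path) {
  utils::write.table(validate_behavior(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Paired between-hand tests of the sensory measures
#'
#' One paired t test per behavioral test comparing the more and less
#' affected hand within one session.  One-tailed by default, with the
#' directional hypothesis that the less affected hand performs better
#' (direction per test documented in `vignette("topoplast-methods")`).
#' A zero-variance difference is flagged as degenerate (`t` infinite or 0).
#'
#' @param table A `behavior_table`.
#' @param session `"pre"` or `"post"`.
#' @param one_tailed Logical (default `TRUE`).
#' @return Data frame: `test`, `n`, `t`, `df`, `p`, `mean_more`,
#'   `mean_less`, `degenerate`.
#' @export
paired_hand_tests <- function(table, session = "pre", one_tailed = TRUE) {
  table <- validate_behavior(table)
  tb <- table[table$session == session, ]
  out <- lapply(unique(tb$test), function(test) {
    d <- tb[tb$test == test, ]
    wide <- merge(d[d$hand == "more", c("subject", "score")],
                  d[d$hand == "less", c("subject", "score")],
                  by = "subject", suffixes = c("_more", "_less"))
    wide <- wide[stats::complete.cases(wide), ]
    n <- nrow(wide)
    if (n < 3L) stop("fewer than 3 complete pairs for test ", test)
    diffs <- wide$score_less - wide$score_more
    alternative <- if (one_tailed) hand_test_direction(test) else "two.sided"
    degenerate <- stats::sd(diffs) == 0
    if (degenerate) {
      m <- mean(diffs)
      t_stat <- if (m == 0) 0 else sign(m) * Inf
      p <- if (m == 0) {
        if (alternative == "two.sided") 1 else 0.5
      } else if (alternative == "two.sided") 0
      else if ((alternative == "greater") == (m > 0)) 0 else 1
      df <- n - 1
    } else {
      tt <- stats::t.test(wide$score_less, wide$score_more, paired = TRUE,
                          alternative = alternative)
      t_stat <- unname(tt$statistic); p <- tt$p.value
      df <- unname(tt$parameter)
    }
    data.frame(test = test, n = n, t = t_stat, df = df, p = p,
               mean_more = mean(wide$score_more),
               mean_less = mean(wide$score_less),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-hand pre/post change tests
#'
#' Paired two-sided t test of post vs. pre scores, per behavioral test and
#' per hand.
#'
#' @param table A `behavior_table`.
#' @return Data frame: `test`, `hand`, `n`, `t`, `df`, `p`, `mean_change`
#'   (post minus pre), `degenerate`.
#' @export
pre_post_change_tests <- function(table) {
  table <- validate_behavior(table)
  combos <- unique(table[, c("test", "hand")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    test <- combos$test[i]; hand <- combos$hand[i]
    d <- table[table$test == test & table$hand == hand, ]
    wide <- merge(d[d$session == "pre", c("subject", "score")],
                  d[d$session == "post", c("subject", "score")],
                  by = "subject", suffixes = c("_pre", "_post"))
    wide <- wide[stats::complete.cases(wide), ]
    n <- nrow(wide)
    if (n < 3L) stop("fewer than 3 complete pairs for ", test, "/", hand)
    diffs <- wide$score_post - wide$score_pre
    degenerate <- stats::sd(diffs) == 0
    if (degenerate) {
      m <- mean(diffs)
      t_stat <- if (m == 0) 0 else sign(m) * Inf
      p <- if (m == 0) 1 else 0
      df <- n - 1
    } else {
      tt <- stats::t.test(wide$score_post, wide$score_pre, paired = TRUE)
      t_stat <- unname(tt$statistic); p <- tt$p.value
      df <- unname(tt$parameter)
    }
    data.frame(test = test, hand = hand, n = n, t = t_stat, df = df, p = p,
               mean_change = mean(diffs), degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Spearman rho with average ranks; p exact by full permutation for n <= 8
# (enumeration beyond that is disproportionate), t approximation otherwise.
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = min(p, 1), n = n, degenerate = FALSE)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Pooled-hand Spearman correlation of map duration with a score
#'
#' Treats the two hands of each subject as individual data points
#' (2 x n_subjects pairs) and correlates the chosen template map's
#' back-fit duration -- or its pre-to-post change -- with the behavioral
#' score (or its change).  Also reports the between-hand correlation of
#' the scores as an independence diagnostic (reported, never a gate).
#'
#' @param durations A `fit_durations` data frame (from [backfit()]).
#' @param table A `behavior_table`.
#' @param map Template map label (e.g. `"map1"`).
#' @param measure Behavioral test name (e.g. `"grip"`).
#' @param session `"pre"`, `"post"` or `"change"` (post minus pre, both
#'   variables).
#' @return A `correlation_result`: list with `rho`, `p`, `n`, the variable
#'   names and the between-hand diagnostic correlation.
#' @export
pooled_hand_correlation <- function(durations, table, map = "map1",
                                    measure = "grip", session = "pre") {
  table <- validate_behavior(table)
  hands <- c("more", "less")
  get_dur <- function(ses) {
    d <- durations[durations$map == map & durations$session == ses, ]
    stats::setNames(d$fraction, paste(d$subject, d$side))
  }
  get_score <- function(ses) {
    d <- table[table$test == measure & table$session == ses, ]
    stats::setNames(d$score, paste(d$subject, d$hand))
  }
  if (session == "change") {
    keys <- intersect(names(get_dur("pre")), names(get_dur("post")))
    dur <- get_dur("post")[keys] - get_dur("pre")[keys]
    sco <- get_score("post")[keys] - get_score("pre")[keys]
  } else {
    dur <- get_dur(session)
    keys <- intersect(names(dur), names(get_score(session)))
    dur <- dur[keys]
    sco <- get_score(session)[keys]
  }
  st <- spearman_test(dur, sco)
  # independence diagnostic: correlation of the two hands' scores
  ses_diag <- if (session == "change") "pre" else session
  d <- table[table$test == measure & table$session == ses_diag, ]
  wide <- merge(d[d$hand == "more", c("subject", "score")],
                d[d$hand == "less", c("subject", "score")], by = "subject",
                suffixes = c("_more", "_less"))
  between_hand_r <- if (nrow(wide) >= 3L &&
                        stats::sd(wide$score_more) > 0 &&
                        stats::sd(wide$score_less) > 0)
    stats::cor(wide$score_more, wide$score_less, method = "spearman")
  else NA_real_
  structure(list(rho = st$rho, p = st$p, n = st$n,
                 degenerate = st$degenerate,
                 variables = c(paste0(map, " duration"), measure),
                 session = session, between_hand_rho = between_hand_r),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho(%d) = %.3f, p = %.4g  [%s ~ %s, %s]\n",
              x$n - 2L, x$rho, x$p, x$variables[1L], x$variables[2L],
              x$session))
  cat(sprintf("between-hand score correlation (diagnostic): %.3f\n",
              x$between_hand_rho))
  invisible(x)
}
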