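# Time-sample-wise 2x2 repeated-measures ANOVA on GFP with a
# minimum-duration significance criterion.
#
# Both within-subject factors (session, side) have two levels, so each
# effect has 1 numerator df and its repeated-measures F equals the squared
# paired t statistic of the corresponding subject-level contrast; no
# sphericity correction is needed (it is exact at 1 df).

# Subject-level contrast coefficients over the canonical puff cell order
# (more.pre, more.post, less.pre, less.post).
contrast_coef <- function(effect) {
  switch(effect,
    session     = c(0.5, -0.5, 0.5, -0.5),   # pre - post marginal means
    side        = c(0.5, 0.5, -0.5, -0.5),   # more - less marginal means
    interaction = c(0.25, -0.25, -0.25, 0.25),
    stop("unknown effect: ", effect))
}

puff_cells <- function(stimulus = "puff") {
  g <- condition_grid()
  g$condition[g$stimulus == stimulus][c(1L, 2L, 3L, 4L)]
}

# F, p for a subject x cell matrix of responses at one effect.
rm_anova_1df <- function(y, coef) {
  cvals <- as.vector(y %*% coef)
  n <- length(cvals)
  m <- mean(cvals)
  v <- stats::var(cvals)
  if (v <= .Machine$double.eps * max(1, m^2)) {
    if (abs(m) <= sqrt(.Machine$double.eps)) return(c(F = 0, p = 1))
    return(c(F = Inf, p = 0))
  }
  Fv <- n * m^2 / v
  c(F = Fv, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
}

#' Sample-wise Session x Side ANOVA on global field power
#'
#' For every peri-stimulus time sample, computes each subject's GFP in the
#' four session x side cells of the chosen stimulus and runs the 2x2
#' repeated-measures ANOVA (session, side, interaction).  Contiguous runs
#' of sub-alpha samples shorter than `min_duration_ms` are discarded
#' before reporting.
#'
#' @param dataset An `erp_dataset` (>= 2 subjects).
#' @param stimulus `"puff"` or `"sham"`.
#' @param window `c(start, end)` ms analysed (default -100..700).
#' @param alpha Significance level per sample.
#' @param min_duration_ms Minimum duration (ms, inclusive) a sub-alpha run
#'   must last to be reported.
#' @return A `timewise_stats` object: list with `table` (data frame of
#'   `time`, `effect`, `F`, `p`) and `runs` (data frame of significant
#'   runs per effect), plus the analysis parameters.
#' @export
gfp_anova <- function(dataset, stimulus = "puff", window = c(-100, 700),
                      alpha = 0.05, min_duration_ms = 20) {
  stopifnot(inherits(dataset, "erp_dataset"))
  if (dim(dataset$data)[3L] < 2L) stop("need at least 2 subjects")
  cells <- puff_cells(stimulus)
  idx <- window_samples(dataset, window)
  tt <- erp_times(dataset)[idx]
  g <- gfp_series(dataset)                       # [time, subject, condition]
  effects <- c("session", "side", "interaction")
  tab <- vector("list", length(effects))
  names(tab) <- effects
  for (eff in effects) {
    coef <- contrast_coef(eff)
    res <- vapply(idx, function(i)
      rm_anova_1df(g[i, , cells], coef), c(F = 0, p = 0))
    tab[[eff]] <- data.frame(time = tt, effect = eff,
                             F = res["F", ], p = res["p", ])
  }
  table <- do.call(rbind, tab)
  rownames(table) <- NULL
  runs <- do.call(rbind, lapply(effects, function(eff) {
    r <- enforce_duration(tab[[eff]]$p, alpha, min_duration_ms,
                          dataset$sampling_rate, t0 = tt[1L])
    if (nrow(r)) cbind(effect = eff, r) else NULL
  }))
  if (is.null(runs))
    runs <- data.frame(effect = character(), start = numeric(),
                       end = numeric(), duration = numeric())
  structure(list(table = table, runs = runs, alpha = alpha,
                 min_duration_ms = min_duration_ms, window = window,
                 stimulus = stimulus, n_subjects = dim(dataset$data)[3L]),
            class = "timewise_stats")
}

#' @export
print.timewise_stats <- function(x, ...) {
  cat(sprintf(
    "sample-wise GFP ANOVA (%s, %g..%g ms, alpha = %g, >= %g ms)\n",
    x$stimulus, x$window[1L], x$window[2L], x$alpha, x$min_duration_ms))
  if (nrow(x$runs)) {
    cat("significant runs:\n")
    print(x$runs, row.names = FALSE)
  } else cat("no significant runs\n")
  invisible(x)
}

#' Apply the minimum-duration criterion to a p-value series
#'
#' Finds maximal contiguous runs of `p < alpha` on a uniform time grid and
#' keeps those lasting at least `min_duration_ms` (inclusive).  Runs are
#' reported half-open in ms: a run of `n` samples lasts
#' `n * 1000 / sampling_rate` ms.  `NA` p-values break runs.
#'
#' @param p Numeric vector of p-values on a uniform grid.
#' @param alpha Significance level.
#' @param min_duration_ms Minimum run duration in ms.
#' @param sampling_rate Hz.
#' @param t0 Time (ms) of the first sample.
#' @return Data frame with columns `start`, `end` (ms, half-open) and
#'   `duration` (ms).
#' @export
enforce_duration <- function(p, alpha, min_duration_ms, sampling_rate,
                             t0 = 0) {
  dt <- 1000 / sampling_rate
  sig <- !is.na(p) & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * dt >= min_duration_ms - 1e-9
  out <- data.frame(start = t0 + (starts[keep] - 1L) * dt,
                    end = t0 + ends[keep] * dt,
                    duration = r$lengths[keep] * dt)
  rownames(out) <- NULL
  out
}
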