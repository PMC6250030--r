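# Randomization-based topographic ANOVA (TANOVA) for the 2x2
# within-subject design.
#
# Per time sample, each subject-condition map is average-referenced and
# normalized by its instantaneous GFP, so the test is sensitive only to
# map configuration, never to response strength.  The effect statistic is
# the GFP of the relevant contrast of cell-mean maps (a generalized
# dissimilarity: via DISS^2 = 2(1 - r) it is monotone in the dissimilarity
# of the contrasted topographies).  The null is built by within-subject
# rearrangements of condition labels consistent with the tested effect:
# for a main effect the two levels of that factor are exchanged per
# subject, and for the interaction the per-subject double-centered
# residual map has its sign flipped (the subgroup of cell relabelings --
# identity, swap rows, swap columns, swap both -- that commutes with
# double-centering and so leaves main effects untouched).  Both schemes
# flip the sign of the subject-level contrast map, which makes the exact
# randomization a per-subject sign flip of that contrast.

#' Topographic effect statistic from 2x2 cell-mean maps
#'
#' GFP of the contrast of the four average-referenced, unit-GFP cell-mean
#' maps: marginal difference for a main effect, double difference divided
#' by 4 for the interaction.  Zero when the cell topographies are
#' identical.
#'
#' @param cells Channel x 4 matrix of cell maps in the order
#'   `more.pre, more.post, less.pre, less.post` (i.e. factor session
#'   varying fastest within side).
#' @param effect `"session"`, `"side"` or `"interaction"`.
#' @return Non-negative scalar.
#' @export
effect_statistic <- function(cells, effect = c("session", "side",
                                               "interaction")) {
  effect <- match.arg(effect)
  if (ncol(cells) != 4L) stop("`cells` must hold the four 2x2 cell maps")
  cells <- apply(cells, 2L, normalize_gfp)
  gfp(as.vector(cells %*% contrast_coef(effect)))
}

# Per-subject, per-sample contrast maps of GFP-normalized topographies.
# Returns list(C = [channel, sample, subject], degenerate = [sample] flag).
subject_contrast_maps <- function(dataset, stimulus, effect, idx) {
  cells <- puff_cells(stimulus)
  coef <- contrast_coef(effect)
  x <- dataset$data[, idx, , cells, drop = FALSE]
  x <- sweep(x, 2:4, colMeans(x), "-")             # average reference
  g <- sqrt(colMeans(x^2))                         # [sample, subj, cell]
  degen <- apply(g <= .gfp_tol, 1L, any)
  g[g <= .gfp_tol] <- 1                            # avoid 0/0; flagged above
  x <- x / rep(g, each = dim(x)[1L])               # unit GFP per map
  nch <- dim(x)[1L]; nt <- dim(x)[2L]; ns <- dim(x)[3L]
  C <- array(0, dim = c(nch, nt, ns))
  for (j in seq_len(4L))
    C <- C + coef[j] * array(x[, , , j], dim = c(nch, nt, ns))
  list(C = C, degenerate = degen)
}

#' Randomization TANOVA for one effect
#'
#' Tests, at every time sample in `window`, whether the GFP-normalized
#' scalp topography differs across the session x side design of the chosen
#' stimulus, using the permutation scheme described in
#' `vignette("topoplast-methods")`.  P-values follow the add-one rule
#' `(1 + #\{null >= observed\}) / (n_permutations + 1)` and are never zero;
#' significant runs must last at least `min_duration_ms`.
#'
#' @param dataset An `erp_dataset` (>= 2 subjects).
#' @param stimulus `"puff"` or `"sham"`.
#' @param effect `"session"`, `"side"` or `"interaction"`.
#' @param n_permutations Number of random rearrangements (>= 99).
#' @param seed RNG seed (mandatory: permutation results must be
#'   reproducible).
#' @param window `c(start, end)` ms (default -100..700).
#' @param alpha Per-sample significance level.
#' @param min_duration_ms Minimum significant-run duration (ms).
#' @return A `tanova_result`: list with `table` (`time`, `stat`, `p`),
#'   `runs`, and the analysis parameters.  Samples with a degenerate
#'   (flat) map in any cell get `p = NA` and never enter runs.
#' @export
tanova <- function(dataset, stimulus = "puff",
                   effect = c("session", "side", "interaction"),
                   n_permutations = 999, seed, window = c(-100, 700),
                   alpha = 0.05, min_duration_ms = 20) {
  stopifnot(inherits(dataset, "erp_dataset"))
  effect <- match.arg(effect)
  if (missing(seed)) stop("`seed` is required for reproducible permutations")
  if (n_permutations < 99) stop("`n_permutations` must be at least 99")
  ns <- dim(dataset$data)[3L]
  if (ns < 2L) stop("need at least 2 subjects")
  set.seed(seed)

  idx <- window_samples(dataset, window)
  tt <- erp_times(dataset)[idx]
  cm <- subject_contrast_maps(dataset, stimulus, effect, idx)
  nch <- dim(cm$C)[1L]; nt <- dim(cm$C)[2L]

  mean_maps <- rowMeans(cm$C, dims = 2L)           # [channel, sample]
  obs <- sqrt(colMeans(mean_maps^2))               # GFP per sample

  # sign-flip null: [n_perm x n_subj] random +/-1, one draw reused across
  # all time samples (preserves the temporal structure of the null)
  S <- matrix(sample(c(-1, 1), n_permutations * ns, replace = TRUE),
              n_permutations, ns)
  M <- matrix(cm$C, nrow = nch * nt, ncol = ns)
  nullm <- M %*% t(S) / ns                         # [(ch*t), n_perm]
  dim(nullm) <- c(nch, nt * n_permutations)
  nullg <- sqrt(colMeans(nullm^2))
  dim(nullg) <- c(nt, n_permutations)

  exceed <- rowSums(nullg >= obs - 1e-15)
  p <- (exceed + 1) / (n_permutations + 1)
  p[cm$degenerate] <- NA_real_
  obs[cm$degenerate] <- NA_real_

  runs <- enforce_duration(p, alpha, min_duration_ms,
                           dataset$sampling_rate, t0 = tt[1L])
  structure(list(
    table = data.frame(time = tt, stat = obs, p = p),
    runs = runs, effect = effect, stimulus = stimulus,
    n_permutations = n_permutations, seed = seed, alpha = alpha,
    min_duration_ms = min_duration_ms, window = window, n_subjects = ns),
    class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf(
    "TANOVA (%s, %s effect): %d permutations, %g..%g ms, alpha = %g\n",
    x$stimulus, x$effect, x$n_permutations, x$window[1L], x$window[2L],
    x$alpha))
  if (nrow(x$runs)) {
    cat(sprintf("significant runs (>= %g ms):\n", x$min_duration_ms))
    print(x$runs, row.names = FALSE)
  } else cat("no significant runs\n")
  invisible(x)
}
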