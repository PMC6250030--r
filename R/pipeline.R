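# End-to-end orchestration of the five analysis steps.

#' Run the full topographic-plasticity analysis pipeline
#'
#' Executes, in order: the minimum-trial inclusion filter and (optional)
#' laterality relabeling (Step 0-1), the topographic-sequence export
#' (Step 1), the sample-wise GFP ANOVA and the randomization TANOVA of all
#' three effects (Step 2), the spatial-correlation time series against the
#' reference condition (Step 3), topographic clustering with
#' Krzanowski-Lai selection, single-subject back-fitting and the duration
#' ANOVAs (Step 4), and the behavioral tests plus pooled-hand brain-
#' behavior correlations (Step 5).  Every stochastic stage is seeded from
#' `seed`, so a rerun with identical inputs is bit-identical.
#'
#' @param dataset An `erp_dataset`.
#' @param counts Optional usable-trial count matrix for
#'   [filter_min_trials()].
#' @param behavior Optional `behavior_table` for Step 5.
#' @param flip Optional `flip_map`; when given (and the dataset is not
#'   already relabeled) laterality relabeling is applied first.
#' @param reference_side Common laterality anchor for relabeling.
#' @param stimulus Stimulus analysed (`"puff"`; run again with `"sham"`
#'   for the control analysis -- the pipeline makes no special case of it).
#' @param stats_window `c(start, end)` ms for GFP ANOVA / TANOVA.
#' @param cluster_window `c(start, end)` ms for clustering and fitting.
#' @param reference Reference condition for the spatial-correlation series.
#' @param k_range Candidate template-map counts.
#' @param n_permutations TANOVA permutation count.
#' @param alpha,min_duration_ms Significance level and duration criterion.
#' @param min_trials Inclusion threshold for the trial-count filter.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param behavior_measures Tests correlated with map durations in Step 5.
#' @param correlation_map Template map used in Step 5 (default `"map1"`).
#' @return A `topoplast_pipeline` object: named list of stage results
#'   (`filter`, `topo_sequence`, `gfp_anova`, `tanova`, `spatial_correlation`,
#'   `segmentation`, `durations`, `duration_anova`, `behavior`) plus the
#'   configuration in force.
#' @export
run_pipeline <- function(dataset, counts = NULL, behavior = NULL,
                         flip = NULL, reference_side = "left",
                         stimulus = "puff", stats_window = c(-100, 700),
                         cluster_window = c(250, 550),
                         reference = condition_id(stimulus, "less", "pre"),
                         k_range = 1:8, n_permutations = 999, alpha = 0.05,
                         min_duration_ms = 20, min_trials = 12, seed = 1L,
                         behavior_measures = c("grip", "pinch",
                                               "stereognosis"),
                         correlation_map = "map1") {
  stopifnot(inherits(dataset, "erp_dataset"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  excluded <- character()
  if (!is.null(counts)) {
    dataset <- filter_min_trials(dataset, counts, min_trials)
    excluded <- attr(dataset, "excluded")
    note("minimum-trial filter (>= %d): excluded %d subject(s)",
         min_trials, length(excluded))
  }
  if (!is.null(flip) && !dataset$relabeled) {
    dataset <- relabel_laterality(dataset, flip, reference_side)
    note("laterality relabeling applied (reference side: %s)",
         reference_side)
  }
  dataset <- apply_average_reference(dataset)

  topo_seq <- export_topography_sequence(dataset)
  note("topographic sequence exported at 100 ms intervals")

  gfp_res <- gfp_anova(dataset, stimulus, window = stats_window,
                       alpha = alpha, min_duration_ms = min_duration_ms)
  note("GFP ANOVA: %d significant run(s)", nrow(gfp_res$runs))

  tanova_res <- list(
    session = tanova(dataset, stimulus, "session", n_permutations,
                     seed = seed + 11L, window = stats_window,
                     alpha = alpha, min_duration_ms = min_duration_ms),
    side = tanova(dataset, stimulus, "side", n_permutations,
                  seed = seed + 12L, window = stats_window,
                  alpha = alpha, min_duration_ms = min_duration_ms),
    interaction = tanova(dataset, stimulus, "interaction", n_permutations,
                         seed = seed + 13L, window = stats_window,
                         alpha = alpha, min_duration_ms = min_duration_ms))
  note("TANOVA: %d/%d/%d significant run(s) for session/side/interaction",
       nrow(tanova_res$session$runs), nrow(tanova_res$side$runs),
       nrow(tanova_res$interaction$runs))

  sc <- spatial_correlation_series(dataset, reference = reference)
  seg <- segment_topographies(dataset, window = cluster_window,
                              k_range = k_range, stimulus = stimulus)
  note("segmentation: k_opt = %d (GEV %.3f)", seg$k_opt,
       seg$gev[as.character(seg$k_opt)])
  durations <- predict(seg, dataset)
  dur_anova <- duration_anova(durations)

  behav <- NULL
  if (!is.null(behavior)) {
    correlations <- list()
    for (m in behavior_measures) {
      correlations[[paste0(m, ".pre")]] <-
        pooled_hand_correlation(durations, behavior, correlation_map, m,
                                session = "pre")
      correlations[[paste0(m, ".change")]] <-
        pooled_hand_correlation(durations, behavior, correlation_map, m,
                                session = "change")
    }
    behav <- list(hand_tests = paired_hand_tests(behavior, "pre"),
                  change_tests = pre_post_change_tests(behavior),
                  correlations = correlations)
    note("behavior: %d hand tests, %d correlations",
         nrow(behav$hand_tests), length(correlations))
  }

  structure(list(
    filter = list(excluded = excluded, min_trials = min_trials),
    topo_sequence = topo_seq, gfp_anova = gfp_res, tanova = tanova_res,
    spatial_correlation = sc, segmentation = seg, durations = durations,
    duration_anova = dur_anova, behavior = behav,
    config = list(stimulus = stimulus, stats_window = stats_window,
                  cluster_window = cluster_window, reference = reference,
                  k_range = range(k_range), n_permutations = n_permutations,
                  alpha = alpha, min_duration_ms = min_duration_ms,
                  seed = seed, polarity = "signed",
                  permutation_scheme = "within-subject label exchange"),
    log = log), class = "topoplast_pipeline")
}

#' @export
print.topoplast_pipeline <- function(x, ...) {
  cat("topoplast pipeline result\n")
  for (l in x$log) cat(" -", l, "\n")
  cat("configuration:", sprintf("stimulus=%s seed=%d n_perm=%d alpha=%g",
      x$config$stimulus, x$config$seed, x$config$n_permutations,
      x$config$alpha), "\n")
  invisible(x)
}
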