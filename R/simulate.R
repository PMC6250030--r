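# Synthetic ERP generator with known ground truth.
#
# Emulates a 2 (stimulus: puff/sham) x 2 (side: more/less affected) x
# 2 (session: pre/post) within-subject somatosensory ERP design in which
# the conditions differ only in *which* template topographies occupy the
# analysis window, never in field strength: every condition shares one GFP
# envelope, so planted effects are purely topographic.
#
# Each condition owns a template timeline (ordered segments of the analysis
# window) shared by all subjects; per-subject segment durations are
# jittered around the condition schedule with a Dirichlet draw, giving the
# between-subject variance the duration statistics and brain-behavior
# correlations need.  Outside the analysis window all conditions show the
# same background template, and before stimulus onset the envelope is zero.

#' Default synthetic montage
#'
#' `n_channels` must be even and >= 4: `(n-2)/2` homologous left-right
#' pairs (`L01`/`R01`, ...) plus two midline channels (`M01`, `M02`),
#' positioned on concentric rings of a unit head circle.
#'
#' @param n_channels Even channel count >= 4.
#' @return Data frame with columns `channel`, `x`, `y`.
#' @export
default_montage <- function(n_channels = 32) {
  if (n_channels < 4L || n_channels %% 2L != 0L)
    stop("`n_channels` must be even and >= 4")
  n_pairs <- (n_channels - 2L) / 2L
  # pair i at angle theta on left (x<0) and mirrored right
  theta <- seq(0.15 * pi, 1.85 * pi, length.out = n_pairs)
  r <- 0.4 + 0.5 * (seq_len(n_pairs) %% 3L) / 3
  data.frame(
    channel = c(sprintf("L%02d", seq_len(n_pairs)),
                sprintf("R%02d", seq_len(n_pairs)), "M01", "M02"),
    x = c(-abs(r * sin(theta)), abs(r * sin(theta)), 0, 0),
    y = c(r * cos(theta), r * cos(theta), 0.8, -0.8),
    stringsAsFactors = FALSE)
}

#' Flip map for the default synthetic montage
#'
#' @param n_channels Even channel count >= 4.
#' @return A `flip_map` pairing `L..`/`R..` channels, midline self-mapped.
#' @export
default_flip_map <- function(n_channels = 32) {
  n_pairs <- (n_channels - 2L) / 2L
  flip_map(c(sprintf("L%02d", seq_len(n_pairs)), "M01", "M02"),
           c(sprintf("R%02d", seq_len(n_pairs)), "M01", "M02"))
}

#' Default ground-truth template topographies
#'
#' Smooth spatial harmonics over the channel index (cosine/sine of
#' increasing spatial frequency), mutually orthogonal, average-referenced
#' and unit-GFP.  Orthogonality is convenient for recovery tests but is not
#' assumed by any analysis.
#'
#' @param n_channels Channel count.
#' @param k Number of templates (<= 4).
#' @return Matrix `[channel, template]` with unit-GFP, zero-mean columns.
#' @export
default_templates <- function(n_channels = 32, k = 3) {
  stopifnot(k >= 1, k <= 4)
  i <- seq_len(n_channels) - 1L
  basis <- cbind(cos(2 * pi * i / n_channels),
                 sin(2 * pi * i / n_channels),
                 cos(4 * pi * i / n_channels),
                 sin(4 * pi * i / n_channels))[, seq_len(k), drop = FALSE]
  apply(basis, 2L, normalize_gfp)
}

#' Default GFP envelope
#'
#' Zero before stimulus onset, linear rise over 0-100 ms, plateau at
#' `peak` microvolts until 600 ms, linear fall to zero at 700 ms.  Shared
#' by all conditions: the design plants no strength differences.
#'
#' @param peak Plateau amplitude in microvolts.
#' @return Function of time (ms) returning the envelope.
#' @export
default_envelope <- function(peak = 5) {
  force(peak)
  function(t) {
    e <- numeric(length(t))
    up <- t >= 0 & t < 100
    flat <- t >= 100 & t < 600
    down <- t >= 600 & t < 700
    e[up] <- peak * t[up] / 100
    e[flat] <- peak
    e[down] <- peak * (700 - t[down]) / 100
    e
  }
}

#' Define a condition's template timeline
#'
#' An ordered list of (template, fraction) segments filling the analysis
#' window; fractions must sum to 1.  Segment order is part of the design:
#' conditions meant to share topographic dynamics should share a timeline.
#'
#' @param template Integer template indices, one per segment.
#' @param fraction Fraction of the analysis window per segment (sums to 1).
#' @return A timeline data frame.
#' @export
timeline <- function(template, fraction) {
  stopifnot(length(template) == length(fraction))
  if (abs(sum(fraction) - 1) > 1e-8)
    stop("timeline fractions must sum to 1 (got ", sum(fraction), ")")
  data.frame(template = as.integer(template), fraction = as.numeric(fraction))
}

#' Built-in condition timelines
#'
#' In the `"crossover"` scenario the pre-intervention less-affected
#' response (the "functional" timeline, template 2 dominant) is shared by
#' the post-intervention more-affected condition, while the
#' "dysfunctional" timeline (template 1 dominant) characterises pre/more
#' and post/less -- the plasticity signature the analysis pipeline is
#' designed to detect.  In the `"null"` scenario all puff conditions share
#' the functional timeline.  Sham conditions always share a single
#' timeline (no effects).
#'
#' @param scenario `"crossover"` or `"null"`.
#' @return Named list of [timeline()]s, one per condition.
#' @export
default_timelines <- function(scenario = c("crossover", "null")) {
  scenario <- match.arg(scenario)
  functional    <- timeline(c(2, 1, 3), c(0.60, 0.15, 0.25))
  dysfunctional <- timeline(c(1, 3, 2), c(0.60, 0.25, 0.15))
  post_more     <- timeline(c(2, 1, 3), c(0.55, 0.20, 0.25))
  post_less     <- timeline(c(1, 3, 2), c(0.55, 0.25, 0.20))
  sham          <- timeline(c(2, 1, 3), c(0.45, 0.30, 0.25))
  puff <- if (scenario == "crossover")
    list(puff.more.pre = dysfunctional, puff.more.post = post_more,
         puff.less.pre = functional,    puff.less.post = post_less)
  else
    list(puff.more.pre = functional, puff.more.post = functional,
         puff.less.pre = functional, puff.less.post = functional)
  c(puff, list(sham.more.pre = sham, sham.more.post = sham,
               sham.less.pre = sham, sham.less.post = sham))
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic ERP + behavior generator.
#' Defaults give the desk-scale study configuration: 10 subjects,
#' 32 channels at 250 Hz (`n_channels = 128`, `sampling_rate = 1000`
#' reproduces the full-scale recording geometry), epoch -200..700 ms,
#' analysis window 250..550 ms, envelope peak 5 uV, noise SD 2.5 uV
#' (half the envelope peak), Dirichlet concentration 40, and monotone
#' behavior links of grip/pinch (rho -0.6) and stereognosis (rho -0.45)
#' to the duration of template 1.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Even channel count >= 4.
#' @param sampling_rate Hz; `(epoch[2]-epoch[1]) * rate / 1000` must be an
#'   integer.
#' @param epoch `c(start, end)` ms, must contain `analysis_window`.
#' @param analysis_window `c(start, end)` ms where condition timelines act.
#' @param scenario `"crossover"` (plasticity signature planted) or
#'   `"null"` (all puff conditions share one timeline).
#' @param timelines Optional named list of [timeline()]s per condition,
#'   overriding the scenario defaults.
#' @param templates Optional `[channel, template]` matrix of unit-GFP maps.
#' @param envelope Optional envelope function of time (ms).
#' @param envelope_peak Plateau amplitude (uV) for the default envelope.
#' @param noise_sd SD (uV) of the spatially/temporally white Gaussian
#'   channel noise added before re-average-referencing.
#' @param kappa Dirichlet concentration of the per-subject segment-duration
#'   jitter (larger = less between-subject variability); `Inf` disables
#'   jitter.
#' @param background_template Template index shown outside the analysis
#'   window (identical in all conditions).
#' @param behavior_links Named list: per test, `list(map =, rho =)` giving
#'   the planted Spearman link between that test's score and the map's
#'   realized duration.
#' @param trial_shift,trial_lambda Usable-trial counts are drawn as
#'   `trial_shift + Poisson(trial_lambda)`.
#' @param seed Default RNG seed used by the `simulate_*` functions.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 10, n_channels = 32, sampling_rate = 250,
                       epoch = c(-200, 700), analysis_window = c(250, 550),
                       scenario = c("crossover", "null"), timelines = NULL,
                       templates = NULL, envelope = NULL, envelope_peak = 5,
                       noise_sd = 2.5, kappa = 40, background_template = 2L,
                       behavior_links = list(
                         grip = list(map = 1L, rho = -0.6),
                         pinch = list(map = 1L, rho = -0.6),
                         stereognosis = list(map = 1L, rho = -0.45)),
                       trial_shift = 5, trial_lambda = 15, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_channels < 2L) stop("need at least 2 channels")
  if (is.null(templates)) templates <- default_templates(n_channels)
  if (nrow(templates) != n_channels)
    stop("`templates` rows must equal `n_channels`")
  templates <- apply(templates, 2L, normalize_gfp)
  if (is.null(timelines)) timelines <- default_timelines(scenario)
  need <- condition_grid()$condition
  if (!all(need %in% names(timelines)))
    stop("`timelines` must name every condition")
  for (nm in need) {
    tl <- timelines[[nm]]
    if (abs(sum(tl$fraction) - 1) > 1e-8)
      stop("occupancy fractions for ", nm, " do not sum to 1")
    if (any(tl$template < 1L | tl$template > ncol(templates)))
      stop("timeline for ", nm, " references an unknown template")
  }
  if (analysis_window[1L] < epoch[1L] || analysis_window[2L] > epoch[2L])
    stop("`epoch` must contain `analysis_window`")
  n_time <- diff(epoch) * sampling_rate / 1000
  if (abs(n_time - round(n_time)) > 1e-8)
    stop("epoch length x sampling rate must give an integer sample count")
  if (is.null(envelope)) envelope <- default_envelope(envelope_peak)
  structure(list(
    n_subjects = n_subjects, n_channels = n_channels,
    sampling_rate = sampling_rate, epoch = epoch,
    analysis_window = analysis_window, scenario = scenario,
    timelines = timelines[need], templates = templates, envelope = envelope,
    envelope_peak = envelope_peak, noise_sd = noise_sd, kappa = kappa,
    background_template = as.integer(background_template),
    behavior_links = behavior_links, trial_shift = trial_shift,
    trial_lambda = trial_lambda, seed = as.integer(seed)),
    class = "sim_config")
}

#' Read a simulation configuration from JSON
#'
#' Scalar fields of [sim_config()] only (templates and envelope always come
#' from the built-in defaults); unknown keys are an error.
#'
#' @param path JSON file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("n_subjects", "n_channels", "sampling_rate", "epoch",
               "analysis_window", "scenario", "envelope_peak", "noise_sd",
               "kappa", "background_template", "trial_shift", "trial_lambda",
               "seed")
  bad <- setdiff(names(x), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, x)
}

# Integer segment lengths summing exactly to n (largest-remainder method).
apportion <- function(fractions, n) {
  raw <- fractions * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1L
  }
  as.integer(k)
}

# Per-subject Dirichlet jitter of segment fractions.
jitter_fractions <- function(fractions, kappa) {
  if (!is.finite(kappa)) return(fractions)
  g <- stats::rgamma(length(fractions), shape = kappa * fractions)
  g / sum(g)
}

#' Generate a synthetic ERP dataset with ground truth
#'
#' At every post-stimulus time sample each subject x condition ERP equals
#' the scheduled template scaled by the shared GFP envelope, plus
#' independent Gaussian channel noise, re-average-referenced.  With
#' `noise_sd = 0` the GFP time course of every condition equals the
#' envelope exactly and back-fitting recovers the realized occupancy
#' perfectly.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`); the same seed yields a
#'   bit-identical dataset.
#' @return List with elements
#'   \describe{
#'     \item{dataset}{An [erp_dataset()] (montage and affected sides set;
#'       data are generated directly in the common-laterality frame, so
#'       `relabeled = TRUE`).}
#'     \item{truth}{Ground truth: `labels` (`[window sample, subject,
#'       condition]` template indices), `durations` (`[subject, condition,
#'       template]` realized fractions of the analysis window), the
#'       condition `timelines` and the `window` sample indices.}
#'   }
#' @export
simulate_erp_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ns <- config$n_subjects; nc <- config$n_channels
  grid <- condition_grid()
  conds <- grid$condition
  n_time <- round(diff(config$epoch) * config$sampling_rate / 1000)
  tt <- config$epoch[1L] + (seq_len(n_time) - 1L) * 1000 / config$sampling_rate
  env <- config$envelope(tt)
  if (any(env < 0)) stop("the GFP envelope must be nonnegative")
  win <- which(tt >= config$analysis_window[1L] &
               tt < config$analysis_window[2L])
  n_win <- length(win)
  k <- ncol(config$templates)

  subjects <- sprintf("S%02d", seq_len(ns))
  montage <- if (nc >= 4L && nc %% 2L == 0L) default_montage(nc) else NULL
  channels <- if (is.null(montage)) sprintf("ch%02d", seq_len(nc))
              else montage$channel

  labels <- array(NA_integer_, dim = c(n_win, ns, length(conds)),
                  dimnames = list(NULL, subjects, conds))
  durations <- array(0, dim = c(ns, length(conds), k),
                     dimnames = list(subjects, conds,
                                     paste0("map", seq_len(k))))
  data <- array(0, dim = c(nc, n_time, ns, length(conds)),
                dimnames = list(channels, NULL, subjects, conds))

  # background template fills the post-stimulus time outside the window
  bg_seq <- rep(config$background_template, n_time)
  for (ci in seq_along(conds)) {
    tl <- config$timelines[[conds[ci]]]
    for (s in seq_len(ns)) {
      fr <- jitter_fractions(tl$fraction, config$kappa)
      lens <- apportion(fr, n_win)
      lab_win <- rep(tl$template, times = lens)
      labels[, s, ci] <- lab_win
      durations[s, ci, ] <- tabulate(lab_win, nbins = k) / n_win
      lab_full <- bg_seq
      lab_full[win] <- lab_win
      signal <- config$templates[, lab_full, drop = FALSE] *
        rep(env, each = nc)
      signal[, tt < 0] <- 0   # baseline: no evoked field
      if (config$noise_sd > 0)
        signal <- signal + matrix(stats::rnorm(nc * n_time,
                                               sd = config$noise_sd),
                                  nc, n_time)
      data[, , s, ci] <- signal
    }
  }
  # re-average-reference (noise breaks the zero spatial mean)
  data <- sweep(data, 2:4, colMeans(data), "-")

  affected <- stats::setNames(
    sample(c("left", "right"), ns, replace = TRUE), subjects)
  ds <- erp_dataset(data, config$sampling_rate, config$epoch,
                    affected_side = affected, montage = montage,
                    relabeled = TRUE)
  truth <- list(labels = labels, durations = durations,
                timelines = config$timelines, window = win,
                window_ms = config$analysis_window, seed = seed)
  list(dataset = ds, truth = truth)
}

# Table 2/3-style score scales: unit, transform bounds and (for tests
# without a planted link) per-hand location/spread.
behavior_scales <- function() {
  list(
    registration = list(unit = "grams", integer = FALSE, min = 0, max = Inf,
                        mean = c(more = 3.13, less = 2.99),
                        sd = c(more = 0.524, less = 0.329)),
    localization = list(unit = "count (max 4)", integer = FALSE, min = 0,
                        max = 4, mean = c(more = 2.50, less = 2.80),
                        sd = c(more = 0.707, less = 0.422)),
    two_point = list(unit = "mm", integer = FALSE, min = 1, max = 20,
                     mean = c(more = 4.90, less = 3.00),
                     sd = c(more = 2.079, less = 1.886)),
    stereognosis = list(unit = "count (max 9)", integer = TRUE, min = 0,
                        max = 9, center = 6.4, scale = 2.42,
                        mean = c(more = 5.10, less = 7.70),
                        sd = c(more = 2.644, less = 1.160)),
    pinch = list(unit = "psi", integer = FALSE, min = 0, max = Inf,
                 center = 2.6, scale = 1.17,
                 mean = c(more = 1.800, less = 3.400),
                 sd = c(more = 0.9189, less = 0.7746)),
    grip = list(unit = "psi", integer = FALSE, min = 0, max = Inf,
                center = 6.68, scale = 3.75,
                mean = c(more = 4.1, less = 9.25),
                sd = c(more = 2.1187, less = 3.2081))
  )
}

rank_normal_scores <- function(x) stats::qnorm((rank(x) - 0.5) / length(x))

#' Generate a behavioral score table linked to map durations
#'
#' Produces per subject x hand x session scores for six sensory and
#' sensory-motor tests (somatosensory registration, single-point
#' localization, two-point discrimination, stereognosis, pinch, grip).
#' For tests named in `config$behavior_links`, scores are a Gaussian-copula
#' monotone transform of the designated map's realized duration pooled over
#' subject x hand: the sample Spearman correlation approaches the planted
#' `rho` as score noise vanishes, and planted hand asymmetries emerge from
#' the duration asymmetry itself.  Unlinked tests draw around fixed
#' hand-specific locations.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_erp_dataset()].
#' @param seed RNG seed (default `config$seed + 1`).
#' @return A `behavior_table`: data frame with columns `subject`, `hand`
#'   (`"more"`/`"less"` affected), `session`, `test`, `score`.
#' @export
simulate_behavior_table <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$durations)) stop("`truth` must carry realized durations")
  set.seed(seed)
  subjects <- dimnames(truth$durations)[[1L]]
  scales <- behavior_scales()
  rows <- list()
  for (test in names(scales)) {
    sc <- scales[[test]]
    link <- config$behavior_links[[test]]
    for (session in c("pre", "post")) {
      cell <- expand.grid(subject = subjects, hand = c("more", "less"),
                          stringsAsFactors = FALSE)
      if (!is.null(link)) {
        d <- mapply(function(s, h)
          truth$durations[s, condition_id("puff", h, session), link$map],
          cell$subject, cell$hand)
        rho <- link$rho
        z <- rank_normal_scores(d)
        latent <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
        score <- sc$center + sc$scale * latent
      } else {
        score <- sc$mean[cell$hand] +
          sc$sd[cell$hand] * stats::rnorm(nrow(cell))
      }
      score <- pmin(pmax(score, sc$min), sc$max)
      if (sc$integer) score <- round(score)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = cell$subject, hand = cell$hand, session = session,
        test = test, score = as.numeric(score), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Generate usable-trial counts per subject and condition
#'
#' Counts are drawn as `trial_shift + Poisson(trial_lambda)` so the
#' minimum-trial inclusion filter is exercisable; the same seed yields
#' identical counts.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default `config$seed + 2`).
#' @return Integer matrix `[subject, condition]`.
#' @export
simulate_trial_counts <- function(config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  conds <- condition_grid()$condition
  matrix(config$trial_shift +
           stats::rpois(length(subjects) * length(conds),
                        config$trial_lambda),
         nrow = length(subjects), dimnames = list(subjects, conds))
}
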