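# Topographic segmentation: atomize-and-agglomerate hierarchical
# clustering (AAHC) of group-average ERP topographies in a time window,
# Krzanowski-Lai model selection, and single-subject template back-fitting.
#
# Polarity is treated as meaningful: these are evoked responses, so a map
# and its inversion are different brain states, and signed spatial
# correlation drives both cluster reassignment and fitting.

# --- AAHC ------------------------------------------------------------------
# M: channel x n matrix of centered, unit-GFP maps; w: GFP weights of the
# original (unnormalized) maps.  With centered unit-GFP columns, the
# spatial correlation of columns a, b is mean(a * b), so correlations are
# plain cross-products / n_channels.
aahc <- function(M, w, k_range) {
  nch <- nrow(M); n <- ncol(M)
  k_range <- sort(unique(as.integer(k_range)))
  if (k_range[1L] < 1L || k_range[length(k_range)] > n)
    stop("`k_range` must lie within 1..", n)

  members <- as.list(seq_len(n))       # cluster -> map indices
  centroids <- M                       # channel x k
  assign <- seq_len(n)                 # map -> cluster
  mcorr <- rep(1, n)                   # corr of map with own centroid

  centroid_of <- function(ids) {
    v <- rowMeans(M[, ids, drop = FALSE])
    v <- v - mean(v)
    g <- sqrt(mean(v^2))
    if (g <= .gfp_tol) M[, ids[1L]] else v / g
  }

  snapshots <- list()
  take_snapshot <- function() {
    k <- length(members)
    if (!k %in% k_range) return()
    # relabel clusters by first occurrence for stable output
    ord <- unique(assign)
    lab <- match(assign, ord)
    gev <- sum((w * mcorr)^2) / sum(w^2)
    W <- sum(2 * (1 - mcorr))          # within-cluster DISS^2 dispersion
    snapshots[[as.character(k)]] <<- list(
      k = k, templates = centroids[, ord, drop = FALSE],
      labels = lab, gev = gev, W = W)
  }
  take_snapshot()

  while (length(members) > k_range[1L] && length(members) > 1L) {
    # dissolve the cluster contributing least explained variance
    contrib <- vapply(seq_along(members), function(ci)
      sum((w[members[[ci]]] * mcorr[members[[ci]]])^2), numeric(1L))
    kill <- which.min(contrib)
    orphan <- members[[kill]]
    members[[kill]] <- NULL
    centroids <- centroids[, -kill, drop = FALSE]

    # reassign orphans by highest signed spatial correlation
    cc <- crossprod(M[, orphan, drop = FALSE], centroids) / nch
    best <- max.col(cc, ties.method = "first")
    touched <- unique(best)
    for (ci in touched)
      members[[ci]] <- c(members[[ci]], orphan[best == ci])
    # recompute centroids of clusters that received members
    for (ci in touched) {
      centroids[, ci] <- centroid_of(members[[ci]])
      ids <- members[[ci]]
      mcorr[ids] <- crossprod(M[, ids, drop = FALSE],
                              centroids[, ci]) / nch
    }
    for (ci in seq_along(members)) assign[members[[ci]]] <- ci
    take_snapshot()
  }
  snapshots
}

#' Segment ERP topographies into template maps
#'
#' Fits the topographic segmentation model of the electrical-neuroimaging
#' framework to the group-average ERPs of the four session x side
#' conditions of one stimulus: every time-sample topography in the
#' analysis window is average-referenced and GFP-normalized (so the
#' clustering is exclusively sensitive to map configuration), then an
#' atomize-and-agglomerate hierarchical clustering (AAHC) is run from
#' singletons down across `k_range`, and the optimal number of template
#' maps is selected with a modified Krzanowski-Lai criterion.  Flat
#' (zero-GFP) samples are excluded with a warning.
#'
#' @param dataset An `erp_dataset`.
#' @param window `c(start, end)` ms clustering window (default 250..550).
#' @param k_range Candidate numbers of template maps.
#' @param stimulus Conditions entered into the clustering (default
#'   `"puff"`).
#' @return A `topo_segmentation` model object: per-`k` template maps,
#'   labelings, global explained variance (`gev`), dispersion (`W`), the
#'   Krzanowski-Lai index (`kl`) and the selected `k_opt`.  Methods:
#'   [print()], [summary()], [coef()] (templates at `k_opt`), [plot()]
#'   and [predict()] (single-subject back-fit).
#' @export
segment_topographies <- function(dataset, window = c(250, 550),
                                 k_range = 1:8, stimulus = "puff") {
  stopifnot(inherits(dataset, "erp_dataset"))
  idx <- window_samples(dataset, window)
  if (!length(idx)) stop("empty clustering window")
  cells <- puff_cells(stimulus)
  tt <- erp_times(dataset)[idx]

  maps <- do.call(cbind, lapply(cells, function(cond)
    group_average(dataset, cond)[, idx, drop = FALSE]))
  maps <- sweep(maps, 2L, colMeans(maps), "-")
  w <- sqrt(colMeans(maps^2))
  ok <- w > .gfp_tol
  if (!any(ok)) stop("all window topographies are degenerate (flat)")
  if (!all(ok))
    warning(sum(!ok), " flat topograph(ies) excluded from clustering")
  Mn <- sweep(maps[, ok, drop = FALSE], 2L, w[ok], "/")

  k_range <- k_range[k_range <= ncol(Mn)]
  snaps <- aahc(Mn, w[ok], k_range)
  ks <- as.integer(names(snaps))
  ord <- order(ks)
  snaps <- snaps[ord]; ks <- ks[ord]

  kl <- kl_index(ks, vapply(snaps, `[[`, numeric(1L), "W"),
                 m = nrow(Mn) - 1L)
  k_opt <- if (all(kl$index <= 0) || length(ks) < 3L) {
    warning("Krzanowski-Lai criterion degenerate; falling back to k = ",
            ks[1L])
    ks[1L]
  } else ks[which.max(kl$index)]

  structure(list(
    k_range = ks, fits = snaps, kl = kl$index, k_opt = k_opt,
    gev = vapply(snaps, `[[`, numeric(1L), "gev"),
    W = vapply(snaps, `[[`, numeric(1L), "W"),
    window = window, times = tt, stimulus = stimulus, cells = cells,
    kept = ok, channels = erp_channels(dataset)),
    class = "topo_segmentation")
}

# Modified Krzanowski-Lai index on the dispersion curve W(k): the scaled
# second difference of D(k) = k^(2/m) W(k), forced to 0 at the boundary
# k's; the optimum is its interior argmax (elbow of the dispersion curve).
kl_index <- function(ks, W, m) {
  D <- ks^(2 / m) * W
  idx <- rep(0, length(ks))
  if (length(ks) >= 3L) {
    interior <- 2:(length(ks) - 1L)
    d2 <- D[interior - 1L] - 2 * D[interior] + D[interior + 1L]
    idx[interior] <- d2 / max(D[1L], .Machine$double.eps)
  }
  list(index = idx, D = D)
}

#' Winning-map labeling of the clustered group ERPs
#'
#' @param object A `topo_segmentation`.
#' @param k Number of maps (default `k_opt`).
#' @return Integer matrix `[condition, window sample]` of winning template
#'   indices; `NA` where the sample topography was flat and excluded.
#' @export
segmentation_labels <- function(object, k = object$k_opt) {
  f <- segmentation_fit(object, k)
  n_idx <- length(object$times)
  lab_full <- rep(NA_integer_, length(object$kept))
  lab_full[object$kept] <- f$labels
  matrix(lab_full, nrow = length(object$cells), ncol = n_idx, byrow = TRUE,
         dimnames = list(object$cells, NULL))
}

segmentation_fit <- function(object, k = object$k_opt) {
  f <- object$fits[[as.character(k)]]
  if (is.null(f)) stop("no fit stored for k = ", k)
  f
}

#' Template maps of a segmentation
#'
#' @param object A `topo_segmentation`.
#' @param k Number of maps (default: the selected `k_opt`).
#' @param ... Unused.
#' @return Channel x k matrix of unit-GFP template maps
#'   (`map1, map2, ...`).
#' @export
coef.topo_segmentation <- function(object, k = object$k_opt, ...) {
  tm <- segmentation_fit(object, k)$templates
  dimnames(tm) <- list(object$channels, paste0("map", seq_len(ncol(tm))))
  tm
}

#' @export
print.topo_segmentation <- function(x, ...) {
  cat(sprintf(
    "topographic segmentation (%s, %g..%g ms): k = %d template maps\n",
    x$stimulus, x$window[1L], x$window[2L], x$k_opt))
  cat(sprintf("  GEV at k_opt: %.3f; candidates k = %s\n",
              x$gev[as.character(x$k_opt)],
              paste(x$k_range, collapse = ", ")))
  invisible(x)
}

#' @export
summary.topo_segmentation <- function(object, ...) {
  df <- data.frame(k = object$k_range, gev = object$gev, W = object$W,
                   kl = object$kl)
  rownames(df) <- NULL
  structure(list(criteria = df, k_opt = object$k_opt,
                 window = object$window), class = "summary.topo_segmentation")
}

#' @export
print.summary.topo_segmentation <- function(x, ...) {
  cat(sprintf("model selection over k (window %g..%g ms):\n",
              x$window[1L], x$window[2L]))
  print(x$criteria, row.names = FALSE, digits = 4)
  cat("selected k_opt =", x$k_opt, "\n")
  invisible(x)
}

#' Plot a topographic segmentation
#'
#' Left: dispersion and Krzanowski-Lai curves over `k`.  Right: the
#' template maps at `k_opt` as channel profiles.
#'
#' @param x A `topo_segmentation`.
#' @param ... Unused.
#' @export
plot.topo_segmentation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$k_range, x$kl, type = "b", xlab = "k", ylab = "KL index",
       main = "model selection")
  graphics::abline(v = x$k_opt, lty = 2)
  tm <- coef(x)
  graphics::matplot(tm, type = "l", lty = 1, xlab = "channel",
                    ylab = "amplitude (unit GFP)",
                    main = sprintf("templates (k = %d)", x$k_opt))
  graphics::legend("topright", legend = colnames(tm), col = seq_len(ncol(tm)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

# --- back-fitting ----------------------------------------------------------

#' Back-fit template maps to single-subject ERPs
#'
#' Labels every analysis-window time point of every single-subject ERP
#' with the template map of highest signed spatial correlation and returns
#' the fraction of window time each map occupies per subject x condition.
#' Flat samples are left unlabeled; on a correlation tie the previous
#' sample's label is kept if tied, else the lowest map index wins.
#'
#' @param dataset An `erp_dataset`.
#' @param templates Channel x k matrix of unit-GFP template maps (e.g.
#'   `coef()` of a `topo_segmentation`).
#' @param window `c(start, end)` ms (default 250..550).
#' @param stimulus Conditions to fit (default `"puff"`).
#' @return A `fit_durations` data frame: `subject`, `condition`, `side`,
#'   `session`, `map` (including `"unlabeled"`), `fraction`.  Fractions
#'   sum to 1 within subject x condition.
#' @export
backfit <- function(dataset, templates, window = c(250, 550),
                    stimulus = "puff") {
  stopifnot(inherits(dataset, "erp_dataset"))
  if (is.null(templates) || NCOL(templates) < 1L)
    stop("`templates` must hold at least one map")
  templates <- apply(as.matrix(templates), 2L, normalize_gfp)
  k <- ncol(templates)
  nch <- nrow(templates)
  if (nch != dim(dataset$data)[1L])
    stop("template channel count does not match the dataset")
  idx <- window_samples(dataset, window)
  cells <- puff_cells(stimulus)
  subjects <- erp_subjects(dataset)
  map_names <- if (!is.null(colnames(templates))) colnames(templates)
               else paste0("map", seq_len(k))

  rows <- list()
  for (cond in cells) for (s in subjects) {
    x <- dataset$data[, idx, s, cond]
    x <- sweep(x, 2L, colMeans(x), "-")
    g <- sqrt(colMeans(x^2))
    ok <- g > .gfp_tol
    lab <- rep(NA_integer_, length(idx))
    if (any(ok)) {
      cc <- crossprod(templates,
                      sweep(x[, ok, drop = FALSE], 2L, g[ok], "/")) / nch
      win_lab <- integer(ncol(cc))
      prev <- NA_integer_
      for (j in seq_len(ncol(cc))) {
        v <- cc[, j]
        best <- which(v >= max(v) - 1e-12)
        win_lab[j] <- if (length(best) > 1L && !is.na(prev) &&
                          prev %in% best) prev else best[1L]
        prev <- win_lab[j]
      }
      lab[ok] <- win_lab
    }
    counts <- tabulate(lab[!is.na(lab)], nbins = k)
    frac <- c(counts, sum(is.na(lab))) / length(idx)
    info <- strsplit(cond, ".", fixed = TRUE)[[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, condition = cond, side = info[2L], session = info[3L],
      map = c(map_names, "unlabeled"), fraction = frac,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fit_durations", "data.frame")
  out
}

#' Back-fit a segmentation's templates to single-subject ERPs
#'
#' `predict()` for the segmentation model: labels each single-subject
#' time point with the best-correlated template map (see [backfit()]).
#'
#' @param object A `topo_segmentation`.
#' @param dataset An `erp_dataset` (typically the one segmented).
#' @param k Number of maps (default `k_opt`).
#' @param window Fit window; defaults to the segmentation window.
#' @param ... Unused.
#' @return A `fit_durations` data frame.
#' @export
predict.topo_segmentation <- function(object, dataset, k = object$k_opt,
                                      window = object$window, ...) {
  backfit(dataset, coef(object, k), window = window,
          stimulus = object$stimulus)
}

# --- duration statistics ---------------------------------------------------

partial_eta_sq <- function(ss_effect, ss_error) ss_effect /
  (ss_effect + ss_error)

aov_effect_table <- function(fit) {
  sm <- summary(fit)
  # guard against 0/0 strata: sums of squares that are pure rounding dust
  # (identical data in all cells) must give F = 0, not an arbitrary ratio
  total_ss <- sum(vapply(sm, function(s) sum(s[[1L]][, "Sum Sq"]),
                         numeric(1L)))
  eps <- 1e-12 * max(total_ss, 1)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      ss_e <- tab[i, "Sum Sq"]; ss_r <- tab["Residuals", "Sum Sq"]
      dust <- ss_e <= eps
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df = tab[i, "Df"],
        df_error = tab["Residuals", "Df"],
        F = if (dust) 0 else tab[i, "F value"],
        p = if (dust) 1 else tab[i, "Pr(>F)"],
        pes = if (dust) 0 else partial_eta_sq(ss_e, ss_r),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map-duration ANOVAs and paired contrasts
#'
#' Given back-fit durations, runs (i) the 3-way within-subject ANOVA with
#' factors map, session and side, (ii) a 2x2 session x side ANOVA per
#' template map, and (iii) the paired two-sided t contrasts of interest:
#' more vs. less affected before the intervention, and post vs. pre per
#' side.  Partial eta squared is reported for every ANOVA effect.
#'
#' @param durations A `fit_durations` data frame (the `"unlabeled"` rows
#'   are dropped).
#' @return A `duration_anova` object: list with `anova3` (3-way table),
#'   `anova2` (per-map 2x2 tables) and `contrasts` (paired t tests).
#' @export
duration_anova <- function(durations) {
  d <- durations[durations$map != "unlabeled", , drop = FALSE]
  d$subject <- factor(d$subject)
  d$map <- factor(d$map)
  d$session <- factor(d$session, levels = c("pre", "post"))
  d$side <- factor(d$side, levels = c("more", "less"))
  full <- table(d$subject, d$map, d$session, d$side)
  if (any(full != 1L))
    stop("durations must cover every subject x map x session x side cell ",
         "exactly once")
  if (nlevels(d$subject) < 2L) stop("need at least 2 subjects")

  fit3 <- stats::aov(
    fraction ~ map * session * side +
      Error(subject / (map * session * side)), data = d)
  anova3 <- aov_effect_table(fit3)

  anova2 <- lapply(split(d, d$map), function(dm)
    aov_effect_table(stats::aov(
      fraction ~ session * side + Error(subject / (session * side)),
      data = dm)))

  paired_t <- function(x, y, label) {
    diffs <- x - y
    if (stats::sd(diffs) == 0) {
      m <- mean(diffs)
      return(data.frame(contrast = label,
                        t = if (m == 0) 0 else sign(m) * Inf,
                        df = length(diffs) - 1,
                        p = if (m == 0) 1 else 0, mean_diff = m,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(contrast = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = unname(tt$estimate), stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, lapply(levels(d$map), function(mp) {
    dm <- d[d$map == mp, ]
    dm <- dm[order(dm$subject), ]
    cell <- function(se, si) dm$fraction[dm$session == se & dm$side == si]
    rbind(
      paired_t(cell("pre", "more"), cell("pre", "less"),
               paste0(mp, ": pre, more vs less")),
      paired_t(cell("post", "more"), cell("pre", "more"),
               paste0(mp, ": more, post vs pre")),
      paired_t(cell("post", "less"), cell("pre", "less"),
               paste0(mp, ": less, post vs pre")))
  }))
  rownames(contrasts) <- NULL
  structure(list(anova3 = anova3, anova2 = anova2, contrasts = contrasts,
                 n_subjects = nlevels(d$subject)),
            class = "duration_anova")
}

#' @export
print.duration_anova <- function(x, ...) {
  cat("3-way within-subject ANOVA (map x session x side):\n")
  print(x$anova3, row.names = FALSE, digits = 4)
  cat("\nper-map session x side ANOVAs:\n")
  for (mp in names(x$anova2)) {
    cat(" ", mp, "\n")
    print(x$anova2[[mp]], row.names = FALSE, digits = 4)
  }
  cat("\npaired contrasts:\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
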