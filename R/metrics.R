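# Reference-independent field metrics: global field power (GFP), global
# map dissimilarity (DISS) and spatial correlation.
#
# Every metric first subtracts the spatial mean, so results are identical
# whatever recording reference the data arrived with, and the "root mean
# square = standard deviation" reading of GFP holds exactly (RMS about the
# spatial mean, denominator n).

# GFP below this (absolute, in the map's amplitude units) is treated as a
# spatially flat, degenerate map.
.gfp_tol <- 1e-12

avg_ref <- function(x) x - mean(x)

#' Global field power of a scalp map
#'
#' GFP is the spatial standard deviation of an average-referenced
#' topography: `sqrt(mean((x - mean(x))^2))`.  It is a reference-free
#' measure of momentary response strength, invariant to adding any constant
#' to all channels.
#'
#' @param x Numeric vector, one amplitude per channel (>= 2 channels).
#' @return Non-negative scalar; 0 only for a spatially constant map.
#' @export
gfp <- function(x) {
  if (length(x) < 2L) stop("GFP needs at least 2 channels")
  x <- avg_ref(x)
  sqrt(mean(x^2))
}

#' Normalize a scalp map to unit GFP
#'
#' Average-references the map and divides by its instantaneous GFP, leaving
#' topographic shape but not strength.
#'
#' @param x Numeric channel vector with GFP above tolerance.
#' @return Map with GFP exactly 1.
#' @export
normalize_gfp <- function(x) {
  x <- avg_ref(x)
  g <- sqrt(mean(x^2))
  if (g <= .gfp_tol)
    stop("cannot GFP-normalize a (near-)flat map: GFP = ", format(g))
  x / g
}

#' Global map dissimilarity (DISS) between two topographies
#'
#' Root mean square of the channel-wise difference between the two
#' average-referenced, GFP-normalized maps.  DISS ranges from 0 (identical
#' topography) to 2 (polarity inversion) and relates to the spatial
#' correlation `r` by `DISS^2 = 2 * (1 - r)`.
#'
#' @param a,b Numeric channel vectors of equal length, both non-degenerate.
#' @return Scalar in `[0, 2]`.
#' @export
diss <- function(a, b) {
  if (length(a) != length(b)) stop("maps must have the same channel count")
  u <- normalize_gfp(a)
  v <- normalize_gfp(b)
  sqrt(mean((u - v)^2))
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the average-referenced maps;
#' measures topographic similarity independent of response strength.
#'
#' @param a,b Numeric channel vectors of equal length, both non-degenerate.
#' @return Scalar in `[-1, 1]`.
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("maps must have the same channel count")
  if (gfp(a) <= .gfp_tol || gfp(b) <= .gfp_tol)
    stop("spatial correlation is undefined for a (near-)flat map")
  stats::cor(avg_ref(a), avg_ref(b))
}

#' GFP time series of every subject and condition
#'
#' @param dataset An `erp_dataset`.
#' @return Numeric array `[time, subject, condition]` of GFP values.
#' @export
gfp_series <- function(dataset) {
  stopifnot(inherits(dataset, "erp_dataset"))
  x <- dataset$data
  m <- colMeans(x)                               # spatial mean per sample
  x <- sweep(x, 2:4, m, "-")
  sqrt(colMeans(x^2))
}

#' Moment-by-moment spatial correlation against a reference condition
#'
#' For each condition sharing the reference's stimulus, computes the
#' spatial correlation between its group-average topography and the
#' reference condition's, at every time sample.  The reference condition of
#' interest in a plasticity design is typically the pre-intervention
#' less-affected side.
#'
#' @param dataset An `erp_dataset`.
#' @param reference Condition identifier of the reference ERP
#'   (default `"puff.less.pre"`).
#' @param window Optional `c(start, end)` ms restricting the time axis.
#' @return Data frame with columns `time` (ms), `condition`, `r`; `r` is
#'   `NA` where either map is degenerate.
#' @export
spatial_correlation_series <- function(dataset, reference = "puff.less.pre",
                                       window = NULL) {
  stopifnot(inherits(dataset, "erp_dataset"))
  conds <- dimnames(dataset$data)[[4L]]
  if (!reference %in% conds) stop("reference condition not present: ", reference)
  stim <- strsplit(reference, ".", fixed = TRUE)[[1L]][1L]
  targets <- grep(paste0("^", stim, "\\."), conds, value = TRUE)

  idx <- if (is.null(window)) seq_along(erp_times(dataset))
         else window_samples(dataset, window)
  tt <- erp_times(dataset)[idx]

  ref <- group_average(dataset, reference)[, idx, drop = FALSE]
  ref <- sweep(ref, 2L, colMeans(ref), "-")
  ref_g <- sqrt(colMeans(ref^2))

  out <- lapply(targets, function(cond) {
    gm <- group_average(dataset, cond)[, idx, drop = FALSE]
    gm <- sweep(gm, 2L, colMeans(gm), "-")
    g <- sqrt(colMeans(gm^2))
    r <- colMeans(gm * ref) / (g * ref_g)
    r[ref_g <= .gfp_tol | g <= .gfp_tol] <- NA_real_
    data.frame(time = tt, condition = cond, r = r)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
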