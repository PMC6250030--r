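# ERP dataset container and structural operations: average reference,
# laterality relabeling, minimum-trial inclusion filter.

#' The full stimulus x side x session condition crossing
#'
#' Returns the eight-cell factorial design the package analyses:
#' stimulus (puff / sham) x stimulated side (more / less affected) x
#' session (pre / post intervention).
#'
#' @return A data frame with columns `stimulus`, `side`, `session` and the
#'   combined `condition` identifier (`"puff.more.pre"`, ...).
#' @export
condition_grid <- function() {
  g <- expand.grid(
    session  = c("pre", "post"),
    side     = c("more", "less"),
    stimulus = c("puff", "sham"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("stimulus", "side", "session")]
  g$condition <- condition_id(g$stimulus, g$side, g$session)
  g
}

#' Build a condition identifier
#'
#' @param stimulus `"puff"` or `"sham"`.
#' @param side `"more"` or `"less"` (affected side stimulated).
#' @param session `"pre"` or `"post"`.
#' @return Character vector like `"puff.more.pre"`.
#' @export
condition_id <- function(stimulus, side, session) {
  paste(stimulus, side, session, sep = ".")
}

#' Construct an ERP dataset
#'
#' Bundles per-subject, per-condition channel x time ERP averages with their
#' sampling metadata.  The condition dimension must carry the full
#' eight-cell crossing returned by [condition_grid()]; a missing cell is an
#' error (never silently dropped).
#'
#' @param data Numeric 4-d array `[channel, time, subject, condition]`, in
#'   microvolts.  `dimnames` must name subjects (dim 3) and conditions
#'   (dim 4); channel labels (dim 1) are optional and default to
#'   `ch01, ch02, ...`.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch Length-2 numeric, epoch window in ms relative to stimulus
#'   onset, half-open `[start, end)`: sample `i` sits at
#'   `start + (i-1) * 1000 / sampling_rate`.
#' @param affected_side Optional named character vector (per subject),
#'   `"left"` or `"right"`: the side of the body that is more affected.
#' @param montage Optional data frame with columns `channel`, `x`, `y`
#'   giving 2-d sensor positions for plotting.
#' @param relabeled Logical; whether [relabel_laterality()] has been applied.
#' @return An object of class `erp_dataset`.
#' @seealso [simulate_erp_dataset()], [read_erp_dataset()]
#' @export
erp_dataset <- function(data, sampling_rate, epoch, affected_side = NULL,
                        montage = NULL, relabeled = FALSE) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-d array [channel, time, subject, condition]")
  dn <- dimnames(data)
  if (is.null(dn)) dn <- vector("list", 4L)
  if (is.null(dn[[1L]])) dn[[1L]] <- sprintf("ch%02d", seq_len(dim(data)[1L]))
  if (is.null(dn[[3L]])) stop("subject names (dimnames, dim 3) are required")
  if (is.null(dn[[4L]])) stop("condition names (dimnames, dim 4) are required")
  dimnames(data) <- dn

  grid <- condition_grid()
  missing_cells <- setdiff(grid$condition, dn[[4L]])
  if (length(missing_cells))
    stop("dataset is missing condition cell(s): ",
         paste(missing_cells, collapse = ", "))
  extra <- setdiff(dn[[4L]], grid$condition)
  if (length(extra))
    stop("unknown condition name(s): ", paste(extra, collapse = ", "))
  data <- data[, , , grid$condition, drop = FALSE]

  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar (Hz)")
  if (length(epoch) != 2L || epoch[2L] <= epoch[1L])
    stop("`epoch` must be c(start_ms, end_ms) with end > start")
  n_expected <- diff(epoch) * sampling_rate / 1000
  if (abs(n_expected - round(n_expected)) > 1e-8 ||
      round(n_expected) != dim(data)[2L])
    stop(sprintf(
      "epoch %g..%g ms at %g Hz implies %s samples but data has %d",
      epoch[1L], epoch[2L], sampling_rate, format(n_expected), dim(data)[2L]))

  subjects <- dn[[3L]]
  if (!is.null(affected_side)) {
    if (is.null(names(affected_side))) names(affected_side) <- subjects
    affected_side <- affected_side[subjects]
    bad <- !affected_side %in% c("left", "right")
    if (any(bad))
      stop("`affected_side` must be \"left\" or \"right\" for every subject")
  }
  if (!is.null(montage)) {
    if (!all(c("channel", "x", "y") %in% names(montage)))
      stop("`montage` needs columns channel, x, y")
    if (!setequal(montage$channel, dn[[1L]]))
      stop("`montage` channels do not match the data channels")
  }

  structure(
    list(data = data, sampling_rate = sampling_rate, epoch = as.numeric(epoch),
         affected_side = affected_side, montage = montage,
         relabeled = isTRUE(relabeled)),
    class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ERP dataset: %d subjects x %d conditions, %d channels x %d samples\n",
    d[3L], d[4L], d[1L], d[2L]))
  cat(sprintf("  epoch %g..%g ms at %g Hz%s\n", x$epoch[1L], x$epoch[2L],
              x$sampling_rate,
              if (x$relabeled) " (laterality-relabeled)" else ""))
  invisible(x)
}

#' Subject names of an ERP dataset
#' @param x An `erp_dataset`.
#' @return Character vector.
#' @export
erp_subjects <- function(x) dimnames(x$data)[[3L]]

#' Channel labels of an ERP dataset
#' @param x An `erp_dataset`.
#' @return Character vector.
#' @export
erp_channels <- function(x) dimnames(x$data)[[1L]]

#' Time axis of an ERP dataset
#'
#' @param x An `erp_dataset`.
#' @return Numeric vector of sample times in ms (onset at 0; sample `i`
#'   covers `[t_i, t_i + 1000/rate)`).
#' @export
erp_times <- function(x) {
  x$epoch[1L] + (seq_len(dim(x$data)[2L]) - 1L) * 1000 / x$sampling_rate
}

#' Indices of samples inside a time window
#'
#' Half-open window `[start, end)` in ms.
#'
#' @param x An `erp_dataset`.
#' @param window Length-2 numeric in ms.
#' @return Integer vector of sample indices.
#' @export
window_samples <- function(x, window) {
  if (window[1L] < x$epoch[1L] || window[2L] > x$epoch[2L])
    stop(sprintf("window %g..%g ms lies outside the epoch %g..%g ms",
                 window[1L], window[2L], x$epoch[1L], x$epoch[2L]))
  tt <- erp_times(x)
  which(tt >= window[1L] & tt < window[2L])
}

#' Re-reference every topography to the average reference
#'
#' Subtracts, at every time sample of every subject and condition, the mean
#' across channels, so each scalp map has zero spatial mean.  Idempotent.
#'
#' @param dataset An `erp_dataset` (>= 2 channels).
#' @return The re-referenced `erp_dataset`.
#' @export
apply_average_reference <- function(dataset) {
  stopifnot(inherits(dataset, "erp_dataset"))
  if (dim(dataset$data)[1L] < 2L)
    stop("average reference needs at least 2 channels")
  m <- colMeans(dataset$data)           # [time, subject, condition]
  dataset$data <- sweep(dataset$data, 2:4, m, "-")
  dataset
}

#' Read a left-right channel flip map
#'
#' Two-column whitespace-delimited text: left label, right label; midline
#' channels are listed mapped to themselves.
#'
#' @param path File path.
#' @return A `flip_map`: data frame with columns `left`, `right`.
#' @export
read_flip_map <- function(path) {
  fm <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("left", "right"))
  flip_map(fm$left, fm$right)
}

#' Construct a left-right channel flip map
#'
#' @param left,right Character vectors of homologous channel labels; midline
#'   channels appear with `left == right`.
#' @return A `flip_map` data frame.
#' @export
flip_map <- function(left, right) {
  fm <- data.frame(left = as.character(left), right = as.character(right),
                   stringsAsFactors = FALSE)
  all_ch <- c(fm$left, fm$right[fm$left != fm$right])
  if (anyDuplicated(all_ch))
    stop("each channel may appear only once in the flip map")
  class(fm) <- c("flip_map", "data.frame")
  fm
}

# Permutation of channel indices realising one application of the flip map.
flip_permutation <- function(channels, flip) {
  pos <- seq_along(channels)
  names(pos) <- channels
  missing_ch <- setdiff(channels, c(flip$left, flip$right))
  if (length(missing_ch))
    stop("channel(s) absent from flip map: ",
         paste(missing_ch, collapse = ", "))
  perm <- pos
  for (i in seq_len(nrow(flip))) {
    l <- flip$left[i]; r <- flip$right[i]
    if (l == r) next
    perm[l] <- pos[r]
    perm[r] <- pos[l]
  }
  unname(perm)
}

#' Relabel channels to a common laterality map
#'
#' For group analyses of lateralised impairment, the hemisphere
#' contralateral to the more affected hand must be the same for every
#' subject.  Subjects whose affected side equals `reference_side` are left
#' untouched; for all others, homologous left-right channel pairs are
#' swapped.  Applying the same flip twice restores the original data.
#'
#' @param dataset An `erp_dataset` with `affected_side` set.
#' @param flip A `flip_map` covering every channel.
#' @param reference_side `"left"` or `"right"`: the affected side whose
#'   subjects keep their native channel order.
#' @return The relabeled `erp_dataset` (`$relabeled` set to `TRUE`).
#' @export
relabel_laterality <- function(dataset, flip, reference_side = "left") {
  stopifnot(inherits(dataset, "erp_dataset"))
  reference_side <- match.arg(reference_side, c("left", "right"))
  if (is.null(dataset$affected_side))
    stop("`affected_side` must be known for every subject")
  perm <- flip_permutation(erp_channels(dataset), flip)
  to_flip <- which(dataset$affected_side != reference_side)
  for (s in to_flip)
    dataset$data[, , s, ] <- dataset$data[perm, , s, ]
  dataset$relabeled <- TRUE
  dataset
}

#' Exclude subjects with too few usable trials
#'
#' A subject is retained only if every individual condition has at least
#' `min_trials` usable trials; otherwise the subject is removed from all
#' conditions.
#'
#' @param dataset An `erp_dataset`.
#' @param counts Integer matrix `[subject, condition]` of usable-trial
#'   counts, with dimnames matching the dataset.
#' @param min_trials Inclusion threshold (default 12, inclusive: a count of
#'   exactly `min_trials` is kept).
#' @return The filtered `erp_dataset`, with attribute `"excluded"` naming
#'   removed subjects.
#' @export
filter_min_trials <- function(dataset, counts, min_trials = 12) {
  stopifnot(inherits(dataset, "erp_dataset"))
  subjects <- erp_subjects(dataset)
  conds <- dimnames(dataset$data)[[4L]]
  if (!all(subjects %in% rownames(counts)) ||
      !all(conds %in% colnames(counts)))
    stop("`counts` must cover every subject and condition of the dataset")
  counts <- counts[subjects, conds, drop = FALSE]
  keep <- apply(counts >= min_trials, 1L, all)
  excluded <- subjects[!keep]
  if (length(excluded))
    message("excluding subject(s) below ", min_trials, " trials: ",
            paste(excluded, collapse = ", "))
  if (!any(keep))
    warning("no subjects remain after the minimum-trial filter")
  dataset$data <- dataset$data[, , keep, , drop = FALSE]
  if (!is.null(dataset$affected_side))
    dataset$affected_side <- dataset$affected_side[keep]
  attr(dataset, "excluded") <- excluded
  dataset
}

#' Group-average ERP of one condition
#'
#' @param dataset An `erp_dataset`.
#' @param condition Condition identifier (see [condition_id()]).
#' @return Channel x time matrix of the across-subject mean.
#' @export
group_average <- function(dataset, condition) {
  stopifnot(inherits(dataset, "erp_dataset"))
  if (!condition %in% dimnames(dataset$data)[[4L]])
    stop("unknown condition: ", condition)
  x <- dataset$data[, , , condition, drop = FALSE]
  rowMeans(x, dims = 2L)
}
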