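# Plain-text dataset serialization: one delimited channels x time matrix
# per subject x condition plus a JSON sidecar for metadata.  Transparent,
# diffable and language-neutral.

erp_file_name <- function(subject, condition)
  sprintf("erp_%s_%s.tsv", subject, condition)

#' Write an ERP dataset to a directory
#'
#' Serializes the dataset as one tab-delimited channels x time matrix per
#' subject x condition (`erp_<subject>_<condition>.tsv`, channel labels in
#' the first column) and a JSON sidecar `metadata.json` holding sampling
#' rate, epoch, subjects, conditions, affected sides and montage.
#'
#' @param dataset An `erp_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_erp_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "erp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- erp_subjects(dataset)
  conds <- dimnames(dataset$data)[[4L]]
  meta <- list(
    format_version = "1.0",
    sampling_rate = dataset$sampling_rate,
    epoch = dataset$epoch,
    channels = erp_channels(dataset),
    subjects = subjects,
    conditions = conds,
    affected_side = as.list(dataset$affected_side),
    relabeled = dataset$relabeled,
    montage = dataset$montage
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (s in subjects) for (cond in conds) {
    m <- dataset$data[, , s, cond]
    df <- data.frame(channel = erp_channels(dataset), m,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("channel", sprintf("t%04d", seq_len(ncol(m))))
    utils::write.table(df, file.path(dir, erp_file_name(s, cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an ERP dataset written by [write_erp_dataset()]
#'
#' @param dir Directory containing `metadata.json` and the per-cell
#'   matrices.
#' @return An `erp_dataset`.  Errors name any missing subject x condition
#'   cell or any file whose channel set disagrees with the sidecar.
#' @export
read_erp_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("no metadata.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- meta$channels
  subjects <- meta$subjects
  conds <- meta$conditions
  n_time <- round(diff(meta$epoch) * meta$sampling_rate / 1000)

  data <- array(NA_real_,
                dim = c(length(channels), n_time, length(subjects),
                        length(conds)),
                dimnames = list(channels, NULL, subjects, conds))
  for (s in subjects) for (cond in conds) {
    f <- file.path(dir, erp_file_name(s, cond))
    if (!file.exists(f))
      stop(sprintf("missing cell: subject %s, condition %s (%s)",
                   s, cond, basename(f)))
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!identical(as.character(df$channel), as.character(channels)))
      stop(sprintf("channel labels in %s disagree with metadata.json",
                   basename(f)))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (ncol(m) != n_time)
      stop(sprintf("subject %s, condition %s: expected %d samples, found %d",
                   s, cond, n_time, ncol(m)))
    data[, , s, cond] <- m
  }
  affected <- unlist(meta$affected_side)
  montage <- meta$montage
  if (!is.null(montage) && !is.data.frame(montage)) montage <- NULL
  erp_dataset(data, meta$sampling_rate, meta$epoch,
              affected_side = if (length(affected)) affected else NULL,
              montage = montage, relabeled = isTRUE(meta$relabeled))
}

#' Export group-average topographies at regular intervals
#'
#' Takes the group-average scalp map of every condition at each interval
#' boundary over the post-stimulus period (e.g. 0, 100, ..., 700 ms) for
#' visual inspection of the topographic sequence.
#'
#' @param dataset An `erp_dataset`.
#' @param interval_ms Spacing of the boundaries in ms (default 100).
#' @param window `c(start, end)` ms; defaults to onset .. epoch end.
#' @return An object of class `topo_sequence`: list with `maps` (array
#'   `[channel, boundary, condition]`), `times` (ms) and the montage.
#'   `plot()` renders it when sensor positions are available; without a
#'   montage the numeric tables remain usable and plotting warns.
#' @export
export_topography_sequence <- function(dataset, interval_ms = 100,
                                       window = NULL) {
  stopifnot(inherits(dataset, "erp_dataset"))
  if (is.null(window)) window <- c(0, dataset$epoch[2L])
  bounds <- seq(window[1L], window[2L], by = interval_ms)
  tt <- erp_times(dataset)
  idx <- vapply(bounds, function(b) which.min(abs(tt - b)), integer(1L))
  conds <- dimnames(dataset$data)[[4L]]
  maps <- array(NA_real_,
                dim = c(dim(dataset$data)[1L], length(bounds), length(conds)),
                dimnames = list(erp_channels(dataset),
                                sprintf("%gms", bounds), conds))
  for (cond in conds)
    maps[, , cond] <- group_average(dataset, cond)[, idx, drop = FALSE]
  structure(list(maps = maps, times = bounds, montage = dataset$montage),
            class = "topo_sequence")
}

#' @export
print.topo_sequence <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("topographic sequence: %d maps (%g..%g ms) x %d conditions\n",
              d[2L], x$times[1L], x$times[length(x$times)], d[3L]))
  invisible(x)
}

#' Plot a topographic map sequence
#'
#' One row per condition, one column per interval boundary; each map is
#' drawn as colour-coded sensor disks at the montage positions (no spatial
#' interpolation).  Requires a montage; without one a warning is issued and
#' nothing is drawn.
#'
#' @param x A `topo_sequence`.
#' @param conditions Conditions to draw (default: all).
#' @param ... Unused.
#' @export
plot.topo_sequence <- function(x, conditions = dimnames(x$maps)[[3L]], ...) {
  if (is.null(x$montage)) {
    warning("no montage positions available; rendering skipped")
    return(invisible(x))
  }
  mon <- x$montage[match(dimnames(x$maps)[[1L]], x$montage$channel), ]
  nb <- dim(x$maps)[2L]
  op <- graphics::par(mfrow = c(length(conditions), nb),
                      mar = c(0.3, 0.3, 1.2, 0.3))
  on.exit(graphics::par(op))
  lim <- max(abs(x$maps[, , conditions]), na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (cond in conditions) for (b in seq_len(nb)) {
    v <- x$maps[, b, cond]
    col <- pal[pmax(1L, pmin(64L, round((v + lim) / (2 * lim) * 63) + 1L))]
    plot(mon$x, mon$y, pch = 21, bg = col, cex = 1.6, axes = FALSE,
         xlab = "", ylab = "", asp = 1,
         main = sprintf("%s %s", cond, dimnames(x$maps)[[2L]][b]),
         cex.main = 0.6)
  }
  invisible(x)
}
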