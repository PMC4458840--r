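#' Temporal high-pass filter by discrete-cosine drift regression
#'
#' Removes slow drift by regressing out a discrete-cosine basis spanning all
#' periods longer than `cutoff_s` (the classic 128-s default), plus an
#' intercept and a linear trend so polynomial drift is annihilated exactly.
#' Deterministic and idempotent, unlike recursive filters.
#'
#' @param mat time-by-voxel matrix.
#' @param cutoff_s high-pass cutoff in seconds; must exceed `2 * tr`.
#' @param tr repetition time in seconds.
#' @return Filtered matrix; columns have zero projection onto the drift basis.
#' @export
highpass_filter <- function(mat, cutoff_s = 128, tr) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  stopifnot(n >= 2, tr > 0)
  if (cutoff_s <= 2 * tr)
    stop("cutoff must exceed twice the repetition time", call. = FALSE)
  k_max <- floor(2 * n * tr / cutoff_s)
  if (k_max < 1) {
    warning("run shorter than the cutoff period: returning demeaned data",
            call. = FALSE)
    return(sweep(mat, 2, colMeans(mat)))
  }
  t0 <- seq_len(n) - 0.5
  dct <- vapply(seq_len(k_max),
                function(k) cos(pi * k * t0 / n), numeric(n))
  basis <- cbind(1, t0 - mean(t0), dct)
  # orthonormalize then project out
  q <- qr.Q(qr(basis))
  mat - q %*% crossprod(q, mat)
}

#' Convert to percent signal change
#'
#' Per voxel: `100 * (x - mean) / mean`, mirroring the standard conversion of
#' raw BOLD amplitude into percent units before connectivity analysis. Voxels
#' whose temporal mean is (near) zero cannot be scaled and raise an error.
#'
#' @param mat time-by-voxel matrix with nonzero column means.
#' @return Matrix of percent-signal-change values; each column has zero mean.
#' @export
to_percent_signal_change <- function(mat) {
  mat <- as.matrix(mat)
  mu <- colMeans(mat)
  bad <- abs(mu) < .Machine$double.eps * 1e3
  if (any(bad))
    stop(sum(bad), " voxel(s) have zero temporal mean: cannot scale",
         call. = FALSE)
  100 * sweep(sweep(mat, 2, mu), 2, mu, "/")
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum(|d translations|) + 50 mm * sum(|d rotations|)` over backward
#' differences, the rotation terms converted to arc length on a 50 mm head
#' radius; the first volume has FD 0.
#'
#' @param trace motion trace: a data frame or matrix with 6 columns, the
#'   first three translations in mm, the last three rotations in radians, one
#'   row per volume.
#' @return Tibble with `volume` (1-based) and `fd` (mm).
#' @export
framewise_displacement <- function(trace) {
  m <- as.matrix(as.data.frame(trace))
  if (ncol(m) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 volumes", call. = FALSE)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            50 * rowSums(d[, 4:6, drop = FALSE]))
  tibble::tibble(volume = seq_len(nrow(m)), fd = fd)
}

#' Scrub volumes around supra-threshold movements
#'
#' For every volume whose framewise displacement exceeds the threshold, the
#' volume itself, the one preceding and the two following are censored
#' (clipped at the run boundaries); removal sets from multiple events are
#' unioned. An isolated interior event therefore removes exactly 4 volumes.
#'
#' @param fd framewise-displacement series: the tibble from
#'   [framewise_displacement()] or a bare numeric vector (mm).
#' @param threshold_mm censoring threshold, default 0.5 mm.
#' @return A `scrub_report`: list with `fd`, `threshold_mm`, `events`
#'   (1-based indices of supra-threshold volumes), `removed`, `kept` and
#'   `n_removed`.
#' @export
scrub <- function(fd, threshold_mm = 0.5) {
  stopifnot(threshold_mm > 0)
  fd_vec <- if (is.data.frame(fd)) fd$fd else as.numeric(fd)
  n <- length(fd_vec)
  events <- which(fd_vec > threshold_mm)
  removed <- sort(unique(unlist(lapply(events, function(t)
    intersect((t - 1L):(t + 2L), seq_len(n))))))
  removed <- as.integer(removed)
  structure(list(fd = fd_vec, threshold_mm = threshold_mm,
                 events = events, removed = removed,
                 kept = setdiff(seq_len(n), removed),
                 n_removed = length(removed)),
            class = "scrub_report")
}

#' @export
print.scrub_report <- function(x, ...) {
  cat(sprintf("<scrub_report> %d/%d volumes removed (%d events > %g mm)\n",
              x$n_removed, length(x$fd), length(x$events), x$threshold_mm))
  invisible(x)
}

#' @rdname scrub
#' @param x a `scrub_report`.
#' @param ... unused.
#' @export
tidy.scrub_report <- function(x, ...) {
  tibble::tibble(volume = seq_along(x$fd), fd = x$fd,
                 event = seq_along(x$fd) %in% x$events,
                 removed = seq_along(x$fd) %in% x$removed)
}

#' @rdname scrub
#' @export
glance.scrub_report <- function(x, ...) {
  tibble::tibble(n_volumes = length(x$fd), n_events = length(x$events),
                 n_removed = x$n_removed, threshold_mm = x$threshold_mm)
}

#' Participant exclusion by movement-event count
#'
#' A subject is excluded when their count of supra-threshold instantaneous
#' movements exceeds the cohort mean plus one sample (n-1) standard
#' deviation.
#'
#' @param event_counts per-subject counts, or a data frame with columns
#'   `subject` and `n_events`.
#' @return Tibble with `subject`, `n_events`, `cutoff` and `excluded`.
#' @export
exclusion_rule <- function(event_counts) {
  if (is.data.frame(event_counts)) {
    subj <- event_counts$subject
    counts <- event_counts$n_events
  } else {
    counts <- as.numeric(event_counts)
    subj <- names(event_counts) %||% seq_along(counts)
  }
  if (length(counts) < 2L) stop("need at least 2 subjects", call. = FALSE)
  cutoff <- mean(counts) + stats::sd(counts)
  tibble::tibble(subject = subj, n_events = counts, cutoff = cutoff,
                 excluded = counts > cutoff)
}

#' Temporal and spatial signal-to-noise ratio
#'
#' Temporal SNR divides mean signal by the standard deviation of the signal
#' over time; by default the per-voxel ratio is averaged over the region
#' (`method = "voxelwise"`); `method = "roi_mean"` instead forms the
#' region-mean series first. Spatial SNR divides the mean signal by the
#' standard deviation across voxels at each time point, then averages over
#' time. Sample (n-1) standard deviations throughout.
#'
#' @param mat time-by-voxel matrix (at least 2 volumes and 2 voxels).
#' @param method aggregation for [temporal_snr()].
#' @return A single SNR value.
#' @export
temporal_snr <- function(mat, method = c("voxelwise", "roi_mean")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  if (method == "roi_mean") {
    s <- rowMeans(mat)
    sdv <- stats::sd(s)
    if (sdv == 0) stop("degenerate region: zero temporal variance", call. = FALSE)
    return(mean(s) / sdv)
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate region: voxel with zero temporal variance", call. = FALSE)
  mean(colMeans(mat) / sds)
}

#' @rdname temporal_snr
#' @export
spatial_snr <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    stop("degenerate region: time point with zero spatial variance",
         call. = FALSE)
  mean(rowMeans(mat) / sds)
}

#' FD trace plot with the scrubbing threshold
#'
#' @param object a `scrub_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scrub_report <- function(object, ...) {
  df <- tidy.scrub_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, y = .data$fd)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = df[df$removed, ], colour = "firebrick",
                        size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold_mm,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "volume", y = "framewise displacement (mm)",
                  title = sprintf("%d volumes censored", object$n_removed)) +
    ggplot2::theme_minimal()
}
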