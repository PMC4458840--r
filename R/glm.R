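#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a response gamma peaking near 5-6 s minus a
#' 1/6-weighted undershoot gamma peaking near 15-16 s, sampled at `dt` and
#' normalized to unit peak.
#'
#' @param dt sampling interval in seconds (typically the TR, or a finer grid
#'   for convolution).
#' @param length_s kernel duration in seconds; must cover the response peak.
#' @param peak,undershoot gamma shape parameters (s, with unit rate).
#' @param ratio undershoot amplitude relative to the response.
#' @return Numeric kernel sampled at `0, dt, 2 dt, ...`; value 0 at t = 0.
#' @export
canonical_hrf <- function(dt, length_s = 32, peak = 6, undershoot = 16,
                          ratio = 1 / 6) {
  stopifnot(dt > 0)
  if (length_s < peak)
    stop("truncated kernel: length shorter than the response peak",
         call. = FALSE)
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(h)
}

#' Build a GLM design matrix from events and motion parameters
#'
#' One HRF-convolved indicator column per condition (boxcars built on a fine
#' grid of `oversample` points per TR, convolved, then sampled at volume
#' acquisition times), six demeaned motion regressors, intercept last.
#'
#' @param events tibble with `onset` (s), `duration` (s), `condition`.
#' @param motion motion trace (volumes x 6) or `NULL` to omit.
#' @param tr repetition time (s).
#' @param n_volumes number of volumes.
#' @param oversample fine-grid factor for the convolution.
#' @return Design matrix (volumes x regressors) with named columns, class
#'   `design_matrix`; attribute `"conditions"` lists the condition columns.
#' @export
build_design <- function(events, motion, tr, n_volumes, oversample = 16) {
  stopifnot(tr > 0, n_volumes >= 2)
  conds <- if (nrow(events) > 0) sort(unique(events$condition)) else character()
  if (nrow(events) > 0 && any(events$onset + events$duration > n_volumes * tr))
    stop("event extends beyond the run", call. = FALSE)
  dt <- tr / oversample
  fine_n <- n_volumes * oversample
  hrf <- canonical_hrf(dt)
  cols <- lapply(conds, function(cc) {
    box <- numeric(fine_n)
    ev <- events[events$condition == cc, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      a <- floor(ev$onset[r] / dt) + 1
      b <- min(fine_n, ceiling((ev$onset[r] + ev$duration[r]) / dt))
      box[a:b] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(fine_n)]
    conv[1 + (seq_len(n_volumes) - 1) * oversample]
  })
  x <- if (length(cols) > 0) do.call(cbind, cols) else
    matrix(numeric(0), n_volumes, 0)
  if (length(conds) > 0) colnames(x) <- conds
  if (!is.null(motion)) {
    m <- as.matrix(as.data.frame(motion))
    stopifnot(nrow(m) == n_volumes, ncol(m) == 6)
    m <- sweep(m, 2, colMeans(m))
    colnames(m) <- paste0("motion", 1:6)
    x <- cbind(x, m)
  }
  x <- cbind(x, intercept = 1)
  if (qr(x)$rank < ncol(x))
    stop("collinear design: rank deficient", call. = FALSE)
  structure(x, class = c("design_matrix", "matrix", "array"),
            conditions = conds)
}

#' Fit a massively univariate GLM
#'
#' Ordinary least squares of every in-mask voxel's time series on the design.
#'
#' @param run a `bold_run` (or a time-by-voxel matrix).
#' @param design design matrix from [build_design()].
#' @param mask `roi_mask` restricting the fit (required when `run` is a
#'   `bold_run`).
#' @return A `glm_fit`: list with `beta` (regressors x voxels), `design`,
#'   `coordinates` (when available) and `sigma2` (residual variance per
#'   voxel).
#' @export
fit_glm <- function(run, design, mask = NULL) {
  y <- if (inherits(run, "bold_run")) {
    stopifnot(!is.null(mask))
    extract_timeseries(run, mask)
  } else as.matrix(run)
  x <- unclass(design)
  stopifnot(nrow(y) == nrow(x))
  if (qr(x)$rank < ncol(x)) stop("collinear design: rank deficient",
                                 call. = FALSE)
  beta <- solve(crossprod(x), crossprod(x, y))
  res <- y - x %*% beta
  sigma2 <- colSums(res^2) / (nrow(x) - ncol(x))
  structure(list(beta = beta, design = design,
                 coordinates = attr(y, "coordinates"), sigma2 = sigma2,
                 residuals = res),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors x %d voxels\n", nrow(x$beta),
              ncol(x$beta)))
  invisible(x)
}

#' @rdname fit_glm
#' @param x a `glm_fit`.
#' @param ... unused.
#' @export
tidy.glm_fit <- function(x, ...) {
  out <- tibble::as_tibble(t(x$beta))
  out <- tibble::add_column(out, voxel = seq_len(ncol(x$beta)), .before = 1)
  tidyr::pivot_longer(out, -"voxel", names_to = "term", values_to = "estimate")
}

#' Contrast of GLM betas
#'
#' @param fit a `glm_fit`.
#' @param weights named numeric vector of contrast weights over regressor
#'   names (unnamed regressors get weight 0).
#' @return Numeric per-voxel contrast values, in the fit's voxel order.
#' @export
glm_contrast <- function(fit, weights) {
  w <- numeric(nrow(fit$beta))
  names(w) <- rownames(fit$beta)
  if (is.null(names(weights)))
    stop("contrast weights must be named after regressors", call. = FALSE)
  missing <- setdiff(names(weights), names(w))
  if (length(missing) > 0)
    stop("unknown regressors in contrast: ", paste(missing, collapse = ", "),
         call. = FALSE)
  w[names(weights)] <- weights
  drop(w %*% fit$beta)
}

#' ROI beta summary over connectopic clusters
#'
#' Averages a per-voxel contrast within each median-split cluster for every
#' subject and runs a paired t test across subjects on the two cluster
#' means — the ROI-level summary of whether a stimulus contrast follows the
#' connectopic parcellation.
#'
#' @param contrast_maps list (one per subject) of per-voxel contrast values
#'   in canonical ROI voxel order.
#' @param clusters integer cluster labels (1/2) in the same voxel order, from
#'   [median_split()].
#' @return List with `subject_means` (tibble: `subject`, `cluster_1`,
#'   `cluster_2`, `difference`) and `test` (the [paired_t()] row).
#' @export
roi_beta_summary <- function(contrast_maps, clusters) {
  stopifnot(length(contrast_maps) >= 2)
  if (!all(c(1L, 2L) %in% clusters))
    stop("invalid parcellation: a cluster is empty", call. = FALSE)
  sm <- purrr::imap_dfr(contrast_maps, function(cm, s) {
    stopifnot(length(cm) == length(clusters))
    tibble::tibble(subject = s,
                   cluster_1 = mean(cm[clusters == 1L]),
                   cluster_2 = mean(cm[clusters == 2L]))
  })
  sm$difference <- sm$cluster_1 - sm$cluster_2
  list(subject_means = sm, test = paired_t(sm$cluster_1, sm$cluster_2))
}
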