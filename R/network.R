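#' SVD representative time series of an ROI
#'
#' Demeans each voxel and returns the first left singular time course scaled
#' by its singular value — the dominant shared signal of the region — with
#' the sign fixed so its mean correlation with the voxel series is positive.
#'
#' @param roi_mat time-by-voxel matrix (at least 2 voxels, 3 volumes).
#' @param standardize return a zero-mean, unit-variance series.
#' @return Numeric time course of length `nrow(roi_mat)`.
#' @export
representative_timeseries <- function(roi_mat, standardize = TRUE) {
  roi_mat <- as.matrix(roi_mat)
  stopifnot(nrow(roi_mat) >= 3, ncol(roi_mat) >= 2)
  roi_mat <- sweep(roi_mat, 2, colMeans(roi_mat))
  if (all(roi_mat == 0))
    stop("degenerate ROI: zero variance everywhere", call. = FALSE)
  s <- svd(roi_mat, nu = 1, nv = 0)
  ts <- s$u[, 1] * s$d[1]
  r <- suppressWarnings(stats::cor(ts, roi_mat))
  if (mean(r, na.rm = TRUE) < 0) ts <- -ts
  if (standardize) ts <- as.numeric(scale(ts))
  ts
}

#' Partial correlation between two series given a control set
#'
#' Pearson correlation of the residuals of both targets after least-squares
#' regression on all control series (plus an intercept); identical to the
#' precision-matrix partial correlation. An empty control set reduces to the
#' plain Pearson correlation.
#'
#' @param x,y target time series.
#' @param controls list (possibly empty) of control time series, or a matrix
#'   with one control per column.
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, controls = list()) {
  cm <- if (is.matrix(controls)) controls
        else if (length(controls) > 0) do.call(cbind, controls)
        else NULL
  n <- length(x)
  stopifnot(length(y) == n)
  if (!is.null(cm)) {
    stopifnot(nrow(cm) == n)
    if (n <= ncol(cm) + 2)
      stop("too few volumes for the number of controls", call. = FALSE)
    z <- cbind(1, cm)
    if (qr(z)$rank < ncol(z))
      stop("rank deficiency: collinear controls", call. = FALSE)
    q <- qr.Q(qr(z))
    x <- x - q %*% crossprod(q, x)
    y <- y - q %*% crossprod(q, y)
  }
  stats::cor(as.numeric(x), as.numeric(y))
}

#' Fisher-Z transform of a correlation
#'
#' `Z = atanh(r)`, the variance-stabilizing transform used before
#' across-subject comparisons of correlation coefficients.
#'
#' @param r correlation in (-1, 1).
#' @return Z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop("|r| >= 1: Fisher Z undefined at the boundary", call. = FALSE)
  atanh(r)
}

#' Seed-pair dual-regression connectivity maps
#'
#' Regresses every gray-matter voxel's time series on both seed series plus
#' an intercept and returns the two beta maps and their difference — the
#' dual-regression estimate of differential connectivity to the two seeds.
#'
#' @param seed_a,seed_b standardized seed time courses.
#' @param run a `bold_run`.
#' @param gray gray-matter `roi_mask`.
#' @return Tibble with the gray-matter voxel coordinates, `beta_a`, `beta_b`
#'   and `contrast` (`beta_a - beta_b`).
#' @export
seed_pair_maps <- function(seed_a, seed_b, run, gray) {
  stopifnot(inherits(run, "bold_run"), inherits(gray, "roi_mask"))
  if (abs(stats::cor(seed_a, seed_b)) > 0.999)
    stop("seeds (near-)collinear: unidentifiable model", call. = FALSE)
  y <- extract_timeseries(run, gray)
  coords <- attr(y, "coordinates")
  x <- cbind(intercept = 1, a = seed_a, b = seed_b)
  beta <- solve(crossprod(x), crossprod(x, y))
  dplyr::mutate(coords, beta_a = beta["a", ], beta_b = beta["b", ],
                contrast = .data$beta_a - .data$beta_b)
}

#' Network-contrast table for one subject
#'
#' Builds each network's representative series from the pooled voxels of all
#' its seed spheres, each ROI half's representative series, and returns the
#' Fisher-Z partial correlation of every half with every network while
#' controlling for the other network — the 2 x 2 interaction behind
#' anterior/posterior (or medial/lateral) by network comparisons.
#'
#' @param half_mats named list of two time-by-voxel matrices, one per ROI
#'   half.
#' @param network_mats named list of two time-by-voxel matrices, one per
#'   network (pooled sphere voxels).
#' @return Tibble with `half`, `network`, `r` and `z`, 4 rows.
#' @export
network_contrast <- function(half_mats, network_mats) {
  stopifnot(length(half_mats) == 2, length(network_mats) == 2)
  halves <- lapply(half_mats, representative_timeseries)
  nets <- lapply(network_mats, representative_timeseries)
  if (abs(stats::cor(nets[[1]], nets[[2]])) > 0.999)
    stop("identical networks: collinear representative series", call. = FALSE)
  grid <- tidyr::expand_grid(half = names(halves), network = names(nets))
  grid$r <- purrr::map2_dbl(grid$half, grid$network, function(h, nw) {
    other <- setdiff(names(nets), nw)
    partial_correlation(halves[[h]], nets[[nw]], list(nets[[other]]))
  })
  grid$z <- fisher_z(grid$r)
  grid
}

#' Homologous vs non-homologous connectivity of four ROI quarters
#'
#' Takes the four anterior-lateral / posterior-medial quarters across both
#' hemispheres, computes the Fisher-Z partial correlation of every pair
#' (controlling for the remaining two regions), and groups the six pairs into
#' homologous (same region, across hemispheres), contralateral
#' non-homologous and ipsilateral non-homologous conditions.
#'
#' @param quarter_mats named list of four time-by-voxel matrices with names
#'   `alEC_left`, `alEC_right`, `pmEC_left`, `pmEC_right`.
#' @return List with `pairs` (tibble: `roi_a`, `roi_b`, `condition`, `r`,
#'   `z`) and `condition_means` (tibble: `condition`, `mean_z`).
#' @export
homologous_contrast <- function(quarter_mats) {
  need <- c("alEC_left", "alEC_right", "pmEC_left", "pmEC_right")
  if (!setequal(names(quarter_mats), need))
    stop("quarter_mats must be named ", paste(need, collapse = ", "),
         call. = FALSE)
  ts <- lapply(quarter_mats[need], representative_timeseries)
  pairs <- utils::combn(need, 2, simplify = FALSE)
  classify <- function(a, b) {
    ra <- sub("_(left|right)$", "", a); rb <- sub("_(left|right)$", "", b)
    ha <- sub("^.*_", "", a); hb <- sub("^.*_", "", b)
    if (ra == rb) "homologous"
    else if (ha == hb) "ipsilateral_nonhomologous"
    else "contralateral_nonhomologous"
  }
  tab <- purrr::map_dfr(pairs, function(p) {
    ctrl <- ts[setdiff(need, p)]
    r <- partial_correlation(ts[[p[1]]], ts[[p[2]]], unname(ctrl))
    tibble::tibble(roi_a = p[1], roi_b = p[2],
                   condition = classify(p[1], p[2]), r = r, z = fisher_z(r))
  })
  means <- dplyr::summarise(dplyr::group_by(tab, .data$condition),
                            mean_z = mean(.data$z), .groups = "drop")
  list(pairs = tab, condition_means = means)
}

#' Paired t test on per-subject values
#'
#' Thin wrapper around [stats::t.test()] with `paired = TRUE`, returning a
#' tidy row; zero-variance differences are rejected rather than reported as
#' an infinite statistic.
#'
#' @param values_a,values_b per-subject paired values.
#' @return Tibble with `estimate` (mean difference), `statistic` (T), `df`
#'   and `p.value` (two-sided).
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(tibble::tibble(estimate = 0, statistic = 0,
                            df = length(d) - 1, p.value = 1))
    stop("degenerate test: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value)
}

#' One-sample sign-flip permutation test with max-statistic FWE correction
#'
#' Tests per-voxel one-sample t statistics of subject contrast maps against
#' the null distribution of the maximum absolute t over voxels under random
#' sign flips of whole subject maps. The returned familywise-error-corrected
#' p per voxel is the proportion of permutations (always including the
#' identity flip) whose max |t| is at least the observed |t|.
#'
#' @param maps subjects x voxels matrix of contrast values.
#' @param n_perm requested number of permutations; capped at the full
#'   enumeration `2^n_subjects` when that is smaller, in which case all flips
#'   are enumerated exactly.
#' @param seed RNG seed for the sampled flips.
#' @return Tibble with `voxel`, `t`, `p_fwe`; attribute `"max_t_null"` holds
#'   the null distribution.
#' @export
sign_flip_test <- function(maps, n_perm = 1000, seed = 1) {
  maps <- as.matrix(maps)
  n <- nrow(maps); v <- ncol(maps)
  stopifnot(n >= 2, n_perm >= 1)
  tstat <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, stats::sd) / sqrt(n)
    ifelse(se == 0, 0, mu / se)
  }
  t_obs <- tstat(maps)
  if (n_perm >= 2^n) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE),
                    ncol = n)
    flips <- rbind(rep(1, n), flips)    # identity flip always included
  }
  max_null <- apply(flips, 1, function(f) max(abs(tstat(f * maps))))
  p <- vapply(abs(t_obs), function(t0) mean(max_null >= t0 - 1e-12),
              numeric(1))
  out <- tibble::tibble(voxel = seq_len(v), t = t_obs, p_fwe = p)
  attr(out, "max_t_null") <- max_null
  out
}
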