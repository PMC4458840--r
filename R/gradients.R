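#' Lossless SVD reduction of the data outside the ROI
#'
#' Replaces the (huge) time-by-voxel matrix of gray matter outside the ROI by
#' its left singular time courses scaled by the singular values (`U %*% S`),
#' truncated only at numerical rank, so the column space — and hence every
#' correlation computed against it — is preserved exactly.
#'
#' @param mat time-by-voxel matrix with demeaned columns (columns are
#'   demeaned internally if not already).
#' @return Time-by-component matrix; at most `min(dim(mat))` columns.
#' @export
svd_reduce <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2)
  mat <- sweep(mat, 2, colMeans(mat))
  if (all(mat == 0)) stop("all-zero matrix: no data to reduce", call. = FALSE)
  s <- svd(mat, nu = min(dim(mat)), nv = 0)
  keep <- s$d > max(dim(mat)) * .Machine$double.eps * s$d[1]
  s$u[, keep, drop = FALSE] %*% diag(s$d[keep], sum(keep))
}

#' Voxel-wise connectivity fingerprints
#'
#' Each ROI voxel's fingerprint is its vector of Pearson correlations with
#' the SVD-reduced time courses of gray matter outside the ROI. Constant
#' (zero-variance) ROI voxels have no defined correlation; they are dropped
#' and recorded in the `"dropped_voxels"` attribute.
#'
#' @param roi_mat time-by-voxel matrix of ROI voxels (canonical order).
#' @param components time-by-component matrix from [svd_reduce()].
#' @return ROI-voxels x components matrix of correlations in `[-1, 1]`.
#' @export
fingerprints <- function(roi_mat, components) {
  roi_mat <- as.matrix(roi_mat); components <- as.matrix(components)
  if (nrow(roi_mat) != nrow(components))
    stop("ROI and component matrices must have equal volume counts",
         call. = FALSE)
  sds <- apply(roi_mat, 2, stats::sd)
  dropped <- which(sds == 0)
  if (length(dropped) > 0) {
    warning(length(dropped), " constant ROI voxel(s) dropped from fingerprints",
            call. = FALSE)
    roi_mat <- roi_mat[, -dropped, drop = FALSE]
  }
  if (any(apply(components, 2, stats::sd) == 0))
    stop("constant component column", call. = FALSE)
  out <- stats::cor(roi_mat, components)
  attr(out, "dropped_voxels") <- dropped
  out
}

#' Eta-squared similarity between two profiles
#'
#' A bounded similarity in `[0, 1]` that penalizes pointwise discrepancy
#' between two connectivity fingerprints relative to their total variance
#' about the grand mean:
#' \deqn{\eta^2 = 1 - \frac{\sum_i (a_i-m_i)^2 + (b_i-m_i)^2}
#'                         {\sum_i (a_i-\bar M)^2 + (b_i-\bar M)^2}}
#' with \eqn{m_i = (a_i+b_i)/2} and \eqn{\bar M} the grand mean of both
#' vectors. Identical profiles score 1; a profile and its negation (about a
#' zero grand mean) score 0.
#'
#' @param a,b numeric vectors of equal length (at least 2).
#' @return Scalar similarity in `[0, 1]`.
#' @export
eta2 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  m <- (a + b) / 2
  gm <- mean(m)
  den <- sum((a - gm)^2 + (b - gm)^2)
  if (den < .Machine$double.eps * 64)
    stop("degenerate pair: both profiles constant at the grand mean",
         call. = FALSE)
  1 - sum((a - m)^2 + (b - m)^2) / den
}

#' Eta-squared similarity matrix over all fingerprint pairs
#'
#' Vectorized pairwise [eta2()] over the rows of a fingerprint matrix. The
#' numerator reduces to half the squared Euclidean row distance and the
#' denominator to row sums of squares about the pair grand mean, so the whole
#' matrix is a few rank-one updates on the Gram matrix.
#'
#' @param fp ROI-voxels x components fingerprint matrix (at least 2 rows).
#' @return Symmetric ROI-voxels x ROI-voxels matrix with unit diagonal,
#'   values in `[0, 1]`, class `similarity_matrix`.
#' @export
similarity_matrix <- function(fp) {
  fp <- as.matrix(fp)
  n <- nrow(fp); p <- ncol(fp)
  stopifnot(n >= 2)
  g <- tcrossprod(fp)                       # G_ij = sum_c a_ic b_jc
  ss <- rowSums(fp^2)                       # S2_i
  rs <- rowSums(fp)                         # s_i
  num <- (outer(ss, ss, "+") - 2 * g) / 2   # sum (a-b)^2 / 2
  gm <- outer(rs, rs, "+") / (2 * p)        # pair grand mean
  den <- outer(ss, ss, "+") - 2 * gm * outer(rs, rs, "+") + 2 * p * gm^2
  if (any(den < .Machine$double.eps * 64))
    stop("degenerate fingerprint pair: zero variance about the grand mean",
         call. = FALSE)
  sim <- 1 - num / den
  sim <- (sim + t(sim)) / 2                 # enforce exact symmetry
  sim[sim < 0] <- 0; sim[sim > 1] <- 1
  diag(sim) <- 1
  structure(sim, class = c("similarity_matrix", "matrix", "array"))
}

#' Laplacian Eigenmaps of a similarity graph
#'
#' Treats the eta-squared similarity matrix (diagonal zeroed) as edge weights
#' `W`, forms the graph Laplacian `L = D - W` with `D = diag(rowSums(W))`,
#' and solves the generalized eigenproblem `L v = lambda D v` via the
#' symmetric normalized Laplacian. The constant lambda = 0 mode is discarded;
#' the next `n_modes` eigenvectors, in ascending eigenvalue order, are the
#' modes of functional-connectivity change. Each mode is scaled to unit
#' D-norm and sign-oriented: positively correlated with the first spatial
#' principal axis of `coords` when given, otherwise with canonical voxel
#' order.
#'
#' @param sim symmetric similarity matrix (e.g. from [similarity_matrix()]).
#' @param n_modes number of nontrivial modes to return.
#' @param coords optional tibble/matrix of voxel coordinates (columns x,y,z
#'   or a plain matrix), used for the deterministic sign convention and kept
#'   for downstream plotting.
#' @return A `gradient_set`: list with `modes` (voxels x n_modes matrix),
#'   `eigenvalues`, `topology` (Spearman rho per mode, see
#'   [topology_preservation()]), and `coordinates`.
#' @export
laplacian_eigenmaps <- function(sim, n_modes = 2, coords = NULL) {
  sim <- unclass(sim)
  n <- nrow(sim)
  stopifnot(n_modes >= 1, n >= 3)
  if (!isSymmetric(sim, tol = 1e-8))
    stop("invalid similarity: matrix not symmetric", call. = FALSE)
  w <- sim; diag(w) <- 0
  d <- rowSums(w)
  if (any(d <= 0))
    stop("disconnected ROI: voxel with zero total similarity", call. = FALSE)
  dis <- 1 / sqrt(d)
  lsym <- diag(n) - outer(dis, dis) * w     # D^-1/2 L D^-1/2, symmetric
  lsym <- (lsym + t(lsym)) / 2
  e <- eigen(lsym, symmetric = TRUE)
  ord <- order(e$values)                    # ascending
  lam <- pmax(e$values[ord], 0)
  vecs <- e$vectors[, ord, drop = FALSE]
  # the lambda ~ 0 constant mode is the first; flag disconnection if the
  # second eigenvalue is also numerically zero
  if (n_modes + 1 > n)
    stop("n_modes too large for ROI size", call. = FALSE)
  if (lam[2] < 1e-10)
    stop("disconnected ROI: repeated zero eigenvalue", call. = FALSE)
  sel <- 2:(n_modes + 1)
  modes <- dis * vecs[, sel, drop = FALSE]  # generalized eigenvectors
  # unit D-norm: v' D v = 1 (already, since w columns are unit norm)
  modes <- sweep(modes, 2, sqrt(colSums(modes^2 * d)), "/")
  ref <- sign_reference(coords, n)
  for (m in seq_len(ncol(modes))) {
    r <- suppressWarnings(stats::cor(modes[, m], ref))
    if (!is.na(r) && r < 0) modes[, m] <- -modes[, m]
  }
  # degenerate similarity structure (e.g. all pairs equal) has no rank
  # order to preserve; report NA rather than fail
  topo <- vapply(seq_len(ncol(modes)), function(m)
    tryCatch(suppressWarnings(topology_preservation(sim, modes[, m])),
             error = function(e) NA_real_),
    numeric(1))
  structure(list(modes = modes, eigenvalues = lam[sel], topology = topo,
                 coordinates = coords),
            class = "gradient_set")
}

sign_reference <- function(coords, n) {
  if (is.null(coords)) return(seq_len(n))
  xyz <- if (is.data.frame(coords)) as.matrix(coords[, c("x", "y", "z")])
         else as.matrix(coords)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  pc1 <- svd(xyz, nu = 0, nv = 1)$v[, 1]
  pc1 <- pc1 * sign(pc1[which.max(abs(pc1))])   # canonical PC sign
  ref <- drop(xyz %*% pc1)
  if (stats::sd(ref) == 0) seq_len(n) else ref
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d voxels, %d mode(s)\n", nrow(x$modes),
              ncol(x$modes)))
  for (m in seq_len(ncol(x$modes)))
    cat(sprintf("  mode %d: lambda = %.4g, topology rho = %.3f\n",
                m, x$eigenvalues[m], x$topology[m]))
  invisible(x)
}

#' @rdname laplacian_eigenmaps
#' @param x a `gradient_set`.
#' @param ... unused.
#' @export
tidy.gradient_set <- function(x, ...) {
  out <- tibble::as_tibble(x$modes, .name_repair = ~ paste0("mode", seq_along(.x)))
  out <- tibble::add_column(out, voxel = seq_len(nrow(x$modes)), .before = 1)
  if (!is.null(x$coordinates))
    out <- dplyr::bind_cols(tibble::as_tibble(x$coordinates), out)
  tidyr::pivot_longer(out, dplyr::starts_with("mode"),
                      names_to = "mode", values_to = "value",
                      names_prefix = "mode", names_transform = as.integer)
}

#' @rdname laplacian_eigenmaps
#' @export
glance.gradient_set <- function(x, ...) {
  tibble::tibble(mode = seq_len(ncol(x$modes)),
                 eigenvalue = x$eigenvalues,
                 topology_rho = x$topology,
                 n_voxels = nrow(x$modes))
}

#' Group-level gradients from averaged similarity matrices
#'
#' Group modes are the Laplacian Eigenmaps of the element-wise mean of the
#' per-subject similarity matrices, which presumes voxel-wise ROI
#' correspondence across subjects.
#'
#' @param sims list of similarity matrices with identical dimensions and
#'   voxel order.
#' @inheritParams laplacian_eigenmaps
#' @return A `gradient_set` (see [laplacian_eigenmaps()]).
#' @export
group_gradient <- function(sims, n_modes = 2, coords = NULL) {
  stopifnot(length(sims) >= 1)
  dims <- vapply(sims, function(s) nrow(s), integer(1))
  if (length(unique(dims)) != 1L)
    stop("misaligned cohort: similarity matrices differ in size", call. = FALSE)
  avg <- Reduce(`+`, lapply(sims, unclass)) / length(sims)
  laplacian_eigenmaps(structure(avg, class = c("similarity_matrix", "matrix",
                                               "array")),
                      n_modes = n_modes, coords = coords)
}

#' Topology preservation of a mode
#'
#' Spearman rank correlation between the high-dimensional pairwise
#' eta-squared similarities and proximity along the one-dimensional mode
#' (`-|mode_i - mode_j|`), over all unordered voxel pairs. Reported without a
#' p-value, since the embedding maximizes this quantity by construction.
#'
#' @param sim similarity matrix.
#' @param mode per-voxel mode values.
#' @return Spearman's rho.
#' @export
topology_preservation <- function(sim, mode) {
  sim <- unclass(sim)
  n <- length(mode)
  stopifnot(nrow(sim) == n, n >= 3)
  if (stats::sd(mode) == 0)
    stop("degenerate mode: constant values have no rank order", call. = FALSE)
  lower <- lower.tri(sim)
  prox <- -abs(outer(mode, mode, "-"))
  stats::cor(sim[lower], prox[lower], method = "spearman")
}

#' Median split of a mode into two equal clusters
#'
#' Voxels below the mode's median form cluster A and voxels above it cluster
#' B; voxels exactly at the median are assigned to A in canonical voxel order
#' until A holds `ceiling(n/2)` voxels, then to B. For an even number of
#' distinct values the split is exactly 50/50.
#'
#' @param mode per-voxel mode values (at least 2, not all identical).
#' @return Integer vector of cluster labels (1 = below-median cluster A,
#'   2 = above-median cluster B).
#' @export
median_split <- function(mode) {
  n <- length(mode)
  stopifnot(n >= 2)
  if (length(unique(mode)) == 1L)
    stop("degenerate mode: all values identical", call. = FALSE)
  med <- stats::median(mode)
  lab <- integer(n)
  lab[mode < med] <- 1L
  lab[mode > med] <- 2L
  at <- which(mode == med)
  if (length(at) > 0) {
    room_a <- max(0L, ceiling(n / 2) - sum(lab == 1L))
    take <- seq_len(min(room_a, length(at)))
    lab[at[take]] <- 1L
    lab[at[-take]] <- 2L
  }
  lab
}

#' Align the sign of a mode to a reference
#'
#' Eigenvector signs are arbitrary; for cross-session or cross-subject
#' comparison a mode is flipped when its Pearson correlation with the
#' reference (a coordinate or a reference mode) is negative. A mode with zero
#' correlation is left unflipped and flagged via attribute `"ambiguous"`.
#'
#' @param mode per-voxel mode values.
#' @param reference nonconstant numeric vector of the same length.
#' @return The (possibly sign-flipped) mode.
#' @export
align_sign <- function(mode, reference) {
  stopifnot(length(mode) == length(reference))
  if (stats::sd(reference) == 0)
    stop("reference must be nonconstant", call. = FALSE)
  r <- suppressWarnings(stats::cor(mode, reference))
  if (is.na(r) || abs(r) < 1e-12) {
    attr(mode, "ambiguous") <- TRUE
    return(mode)
  }
  if (r < 0) -mode else mode
}

#' Connectopic gradients for one subject
#'
#' The full per-subject chain: extract ROI and outside-ROI gray-matter time
#' series, percent-signal-change and high-pass filter both, SVD-reduce the
#' outside data, correlate to get fingerprints, build the eta-squared
#' similarity matrix and embed it with Laplacian Eigenmaps. Gray-matter
#' restriction is applied by mask intersection before any correlation.
#'
#' @param run a `bold_run`.
#' @param roi ROI `roi_mask`.
#' @param gray gray-matter `roi_mask` (must contain the ROI).
#' @param n_modes number of modes.
#' @param hp_cutoff_s high-pass cutoff (s); `NULL` to skip filtering.
#' @param psc convert to percent signal change first.
#' @return List with the `gradient_set` (`gradients`), the `similarity`
#'   matrix, the `fingerprints` matrix, and the ROI `coordinates` tibble.
#' @export
connectopic_gradients <- function(run, roi, gray, n_modes = 2,
                                  hp_cutoff_s = 128, psc = TRUE) {
  stop_if_grid_mismatch(run, roi); stop_if_grid_mismatch(run, gray)
  outside <- roi_mask(gray$mask & !roi$mask, gray$affine,
                      name = paste0(gray$name, "_minus_", roi$name))
  roi_mat <- extract_timeseries(run, roi)
  out_mat <- extract_timeseries(run, outside)
  coords <- attr(roi_mat, "coordinates")
  prep <- function(m) {
    if (psc) m <- to_percent_signal_change(m)
    if (!is.null(hp_cutoff_s)) m <- highpass_filter(m, hp_cutoff_s, run$tr)
    m
  }
  roi_mat <- prep(roi_mat); out_mat <- prep(out_mat)
  comp <- svd_reduce(out_mat)
  fp <- fingerprints(roi_mat, comp)
  dropped <- attr(fp, "dropped_voxels")
  if (length(dropped) > 0) coords <- coords[-dropped, ]
  sim <- similarity_matrix(fp)
  gs <- laplacian_eigenmaps(sim, n_modes = n_modes, coords = coords)
  list(gradients = gs, similarity = sim, fingerprints = fp,
       coordinates = coords)
}

#' Plot gradient modes along a spatial axis
#'
#' Scatter of mode values against a voxel coordinate, faceted by mode — the
#' quickest visual check that a gradient runs along an anatomical axis.
#'
#' @param object a `gradient_set` with coordinates.
#' @param axis coordinate to plot against ("x", "y" or "z").
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gradient_set <- function(object, axis = "y", ...) {
  if (is.null(object$coordinates))
    stop("gradient_set has no coordinates to plot against", call. = FALSE)
  df <- tidy.gradient_set(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[axis]], y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~mode, labeller = ggplot2::label_both) +
    ggplot2::labs(x = paste0("world ", axis, " (mm)"), y = "mode value") +
    ggplot2::theme_minimal()
}
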