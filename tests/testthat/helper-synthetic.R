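# Shared fixtures, generated in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# Small desk-scale configuration for fast unit tests.
small_config <- function(...) {
  defaults <- list(grid_dim = c(16, 16, 16), roi_corner = c(5, 5, 5),
                   roi_dim = c(6, 6, 6), network_a_corner = c(5, 1, 5),
                   network_b_corner = c(5, 12, 5), network_dim = c(4, 4, 4),
                   gray_extra_corner = c(1, 5, 5),
                   gray_extra_dim = c(4, 6, 6),
                   n_volumes = 120, n_subjects = 2, seed = 7)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# The default study-condition cohort: 10 subjects, 8x8x8 ROI, noise sd 0.5,
# seed 7. Cached because several acceptance properties reuse it.
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$config <- synth_config(seed = 7)
    .fixtures$cohort <- make_cohort(.fixtures$config)
  }
  .fixtures$cohort
}

default_config <- function() {
  default_cohort()
  .fixtures$config
}

default_group_gradient <- function() {
  if (is.null(.fixtures$group)) {
    cohort <- default_cohort()
    subj <- lapply(cohort, function(s)
      connectopic_gradients(s$run, s$roi, s$gray))
    .fixtures$subject_gradients <- subj
    .fixtures$group <- group_gradient(
      lapply(subj, function(x) x$similarity), n_modes = 2,
      coords = subj[[1]]$coordinates)
  }
  .fixtures$group
}

# Independent brute-force eta-squared, the oracle for the vectorized matrix.
eta2_brute <- function(a, b) {
  m <- (a + b) / 2
  gm <- mean(c(a, b))
  1 - sum((a - m)^2 + (b - m)^2) / sum((a - gm)^2 + (b - gm)^2)
}

similarity_brute <- function(fp) {
  n <- nrow(fp)
  out <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out[i, j] <- out[j, i] <- eta2_brute(fp[i, ], fp[j, ])
  out
}

# Dense generalized eigendecomposition oracle for Laplacian Eigenmaps,
# solved as a plain (non-symmetric) eigenproblem of D^-1 L.
le_brute <- function(sim, n_modes) {
  w <- unclass(sim); diag(w) <- 0
  d <- rowSums(w)
  l <- diag(d) - w
  e <- eigen(diag(1 / d) %*% l)
  ord <- order(Re(e$values))
  vals <- Re(e$values[ord]); vecs <- Re(e$vectors[, ord, drop = FALSE])
  sel <- 2:(n_modes + 1)
  list(values = vals[sel], vectors = vecs[, sel, drop = FALSE], d = d)
}
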