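test_that("svd_reduce is lossless up to numerical rank", {
  set.seed(5)
  tc <- rnorm(40)
  rank1 <- outer(tc, runif(30, 0.5, 2))
  comp <- svd_reduce(rank1)
  expect_equal(ncol(comp), 1)
  expect_equal(abs(cor(comp[, 1], tc)), 1, tolerance = 1e-10)

  x <- matrix(rnorm(40 * 200), 40, 200)     # V >> T: at most T components
  comp2 <- svd_reduce(x)
  expect_lte(ncol(comp2), 40)
  # spans the column space: projecting the input onto the components is lossless
  xc <- sweep(x, 2, colMeans(x))
  q <- qr.Q(qr(comp2))
  expect_lt(max(abs(xc - q %*% crossprod(q, xc))), 1e-8)

  expect_error(svd_reduce(matrix(0, 10, 4)), "all-zero")
})

test_that("fingerprints are correlations with the component series", {
  set.seed(6)
  comp <- matrix(rnorm(200), 50, 4)
  roi <- cbind(comp[, 2], rnorm(50))
  fp <- fingerprints(roi, comp)
  expect_equal(fp[1, 2], 1, tolerance = 1e-12)
  expect_true(all(fp >= -1 & fp <= 1))
  # component sign flip flips that fingerprint column
  comp2 <- comp; comp2[, 3] <- -comp2[, 3]
  fp2 <- fingerprints(roi, comp2)
  expect_equal(fp2[, 3], -fp[, 3])
  expect_equal(fp2[, -3], fp[, -3])
  # constant voxels are dropped with a warning and recorded
  expect_warning(fp3 <- fingerprints(cbind(roi, 1), comp), "constant")
  expect_identical(attr(fp3, "dropped_voxels"), 3L)
  expect_equal(nrow(fp3), 2)
})

test_that("eta2 matches hand computations and its stated identities", {
  expect_equal(eta2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(eta2(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_equal(eta2(c(1, 2, 3), c(1, 2, 4)), 0.9268, tolerance = 1e-3)
  # self-similarity 1; similarity with the negation (zero grand mean) 0
  set.seed(7)
  a <- rnorm(20)
  expect_equal(eta2(a, a), 1)
  expect_equal(eta2(a, -a), 0)
  b <- rnorm(20)
  expect_equal(eta2(a, b), eta2(b, a))  # symmetry
  expect_error(eta2(c(2, 2, 2), c(2, 2, 2)), "degenerate")
})

test_that("vectorized similarity matrix equals the brute-force double loop", {
  set.seed(8)
  fp <- matrix(rnorm(35 * 12), 35, 12)
  sim <- similarity_matrix(fp)
  expect_lt(max(abs(unclass(sim) - similarity_brute(fp))), 1e-12)
  expect_true(isSymmetric(unclass(sim), tol = 1e-12))
  expect_true(all(diag(sim) == 1))
  expect_true(all(sim >= 0 & sim <= 1))
  # duplicated rows give off-diagonal similarity 1
  sim2 <- similarity_matrix(rbind(fp, fp[3, ]))
  expect_equal(sim2[3, 36], 1, tolerance = 1e-12)
})

test_that("Laplacian Eigenmaps solve the generalized eigenproblem", {
  # 3-node path: first nontrivial mode is monotone across the path
  sim_path <- diag(3)
  sim_path[1, 2] <- sim_path[2, 1] <- 1
  sim_path[2, 3] <- sim_path[3, 2] <- 1
  sim_path[1, 3] <- sim_path[3, 1] <- 1e-6
  gs <- laplacian_eigenmaps(sim_path, 1)
  m <- gs$modes[, 1]
  expect_true(all(diff(m) > 0) || all(diff(m) < 0))
  expect_gt(min(m[2] - min(m), max(m) - m[2]), 0)
  # agrees with the dense generalized eigendecomposition oracle
  br <- le_brute(sim_path, 1)
  expect_equal(gs$eigenvalues[1], br$values[1], tolerance = 1e-10)
  expect_equal(abs(cor(m, br$vectors[, 1])), 1, tolerance = 1e-10)

  # complete graph: all nontrivial eigenvalues equal, zero D-weighted mean
  n <- 8
  simc <- matrix(0.5, n, n); diag(simc) <- 1
  gsc <- laplacian_eigenmaps(simc, n - 1)
  expect_equal(gsc$eigenvalues, rep(gsc$eigenvalues[1], n - 1),
               tolerance = 1e-10)
  w <- simc; diag(w) <- 0
  d <- rowSums(w)
  for (k in seq_len(n - 1))
    expect_equal(sum(gsc$modes[, k] * d), 0, tolerance = 1e-8)

  # eigen-residual ||L v - lambda D v|| <= 1e-8 ||v|| on random similarity
  set.seed(9)
  fp <- matrix(rnorm(40 * 8), 40, 8)
  sim <- similarity_matrix(fp)
  g <- laplacian_eigenmaps(sim, 3)
  wl <- unclass(sim); diag(wl) <- 0
  l <- diag(rowSums(wl)) - wl
  for (k in 1:3) {
    v <- g$modes[, k]
    expect_lt(sqrt(sum((l %*% v - g$eigenvalues[k] * rowSums(wl) * v)^2)),
              1e-8 * sqrt(sum(v^2)))
  }

  # permuting voxel order permutes mode values identically
  perm <- sample(nrow(sim))
  coords <- matrix(rnorm(nrow(sim) * 3), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  g1 <- laplacian_eigenmaps(sim, 1, coords = coords)
  g2 <- laplacian_eigenmaps(unclass(sim)[perm, perm], 1,
                            coords = coords[perm, ])
  expect_equal(g2$modes[, 1], g1$modes[perm, 1], tolerance = 1e-8)

  expect_error(laplacian_eigenmaps(matrix(rnorm(9), 3, 3), 1),
               "not symmetric")
  disc <- diag(4); disc[1, 2] <- disc[2, 1] <- 1; disc[3, 4] <- disc[4, 3] <- 1
  expect_error(laplacian_eigenmaps(disc, 1), "disconnected")
})

test_that("group gradients equal the embedding of the averaged similarity", {
  set.seed(10)
  sims <- lapply(1:3, function(i) similarity_matrix(matrix(rnorm(25 * 6), 25)))
  grp <- group_gradient(sims, 1)
  avg <- (unclass(sims[[1]]) + unclass(sims[[2]]) + unclass(sims[[3]])) / 3
  direct <- laplacian_eigenmaps(avg, 1)
  expect_equal(grp$modes, direct$modes, tolerance = 1e-10)
  expect_true(isSymmetric(avg, tol = 1e-12))
  expect_true(all(diag(avg) == 1))
  # identical subjects reduce to the single-subject result
  same <- group_gradient(list(sims[[1]], sims[[1]]), 1)
  single <- laplacian_eigenmaps(sims[[1]], 1)
  expect_equal(same$modes, single$modes, tolerance = 1e-10)
  expect_error(group_gradient(list(sims[[1]],
                                   similarity_matrix(matrix(rnorm(80), 20)))),
               "misaligned")
})

test_that("topology preservation ranks mode proximity against similarity", {
  n <- 30
  sim <- outer(1:n, 1:n, function(i, j) exp(-abs(i - j) / n))
  diag(sim) <- 1
  expect_equal(topology_preservation(sim, as.numeric(1:n)), 1)
  expect_equal(topology_preservation(sim, -as.numeric(1:n)), 1)
  set.seed(11)
  shuffled <- sample(n)
  expect_lt(abs(topology_preservation(sim, as.numeric(shuffled))), 0.2)
  expect_error(topology_preservation(sim, rep(1, n)), "degenerate")
})

test_that("median split halves the ROI with the stated tie rule", {
  expect_identical(median_split(c(0.1, 0.2, 0.3, 0.4)), c(1L, 1L, 2L, 2L))
  set.seed(12)
  v <- rnorm(100)
  lab <- median_split(v)
  expect_equal(sum(lab == 1), 50)
  expect_equal(sum(lab == 2), 50)
  expect_true(all(v[lab == 1] <= min(v[lab == 2])))
  expect_identical(median_split(c(1, 1, 2, 2)), c(1L, 1L, 2L, 2L))
  expect_error(median_split(rep(3, 10)), "degenerate")
})

test_that("sign alignment flips only anticorrelated modes", {
  set.seed(13)
  ref <- rnorm(40)
  m <- ref + rnorm(40, sd = 0.2)
  expect_identical(align_sign(m, ref), m)
  expect_identical(align_sign(-m, ref), m)
  expect_identical(align_sign(m, m), m)
  orth <- residuals(lm(rnorm(40) ~ ref))
  flagged <- align_sign(orth, ref)
  expect_equal(as.numeric(flagged), as.numeric(orth))
  expect_error(align_sign(m, rep(1, 40)), "nonconstant")
})

test_that("tidiers and plots expose gradient results", {
  sim <- similarity_matrix(matrix(rnorm(20 * 5), 20, 5))
  coords <- tibble::tibble(i = 1:20, j = 1, k = 1, x = rnorm(20),
                           y = rnorm(20), z = rnorm(20))
  gs <- laplacian_eigenmaps(sim, 2, coords = coords)
  td <- tidy(gs)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  expect_true(all(c("voxel", "mode", "value", "x") %in% names(td)))
  gl <- glance(gs)
  expect_equal(gl$topology_rho, gs$topology)
  p <- autoplot(gs)
  expect_s3_class(p, "ggplot")
})
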