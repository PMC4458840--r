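test_that("representative time series is the dominant SVD time course", {
  set.seed(14)
  tc <- rnorm(60)
  roi <- outer(tc, runif(12, 0.8, 1.2)) + matrix(rnorm(60 * 12, sd = 0.01),
                                                 60, 12)
  rep_ts <- representative_timeseries(roi)
  expect_gt(cor(rep_ts, tc), 0.99)
  expect_equal(mean(rep_ts), 0, tolerance = 1e-12)
  expect_equal(sd(rep_ts), 1, tolerance = 1e-12)
  # sign stable under voxel duplication
  expect_gt(cor(representative_timeseries(cbind(roi, roi)), rep_ts), 0.999)
  # matches the dominant eigenvector time course of the voxel covariance
  rc <- sweep(roi, 2, colMeans(roi))
  ev <- eigen(crossprod(rc))$vectors[, 1]
  oracle <- as.numeric(rc %*% ev)
  expect_equal(abs(cor(rep_ts, oracle)), 1, tolerance = 1e-10)
  expect_error(representative_timeseries(matrix(5, 10, 3)), "degenerate")
})

test_that("partial correlation equals the precision-matrix formula", {
  set.seed(15)
  n <- 80
  # empty control set: plain Pearson
  x <- rnorm(n); y <- x + rnorm(n, sd = 0.5)
  expect_equal(partial_correlation(x, y), cor(x, y))
  # y = x + c with independent control c: partial correlation ~ 1
  c1 <- rnorm(n)
  expect_equal(partial_correlation(x, x + c1, list(c1)), 1, tolerance = 1e-10)
  # precision-matrix oracle on random data, several control-set sizes
  for (k in 1:3) {
    dat <- matrix(rnorm(n * (2 + k)), n)
    p <- solve(cov(dat))
    oracle <- -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
    mine <- partial_correlation(dat[, 1], dat[, 2],
                                lapply(seq_len(k) + 2, function(j) dat[, j]))
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
  expect_error(partial_correlation(x, y, list(c1, 2 * c1)), "rank")
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   list(rnorm(4), rnorm(4))), "too few")
})

test_that("fisher_z is the odd, increasing atanh with exact inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "boundary")
})

test_that("seed-pair maps recover exact regressors and the gradient contrast", {
  cfg <- small_config(n_volumes = 100)
  sub <- make_subject_run(cfg, 5)
  tc <- sub$truth$timecourses
  sa <- as.numeric(scale(tc$A)); sb <- as.numeric(scale(tc$B))
  maps <- seed_pair_maps(sa, sb, sub$run, sub$gray)
  expect_true(all(c("beta_a", "beta_b", "contrast") %in% names(maps)))
  # ROI contrast tracks the ground-truth gradient (A-weighted end positive)
  coords <- mask_coordinates(sub$roi)
  roi_rows <- dplyr::inner_join(dplyr::mutate(coords, u = sub$truth$u),
                                maps, by = c("i", "j", "k", "x", "y", "z"))
  expect_lt(cor(roi_rows$contrast, roi_rows$u), -0.8)

  # a voxel equal to seed_a gets beta_a ~ 1, beta_b ~ 0
  one <- array(FALSE, cfg$grid_dim); one[6, 6, 6] <- TRUE
  run2 <- sub$run
  run2$data[6, 6, 6, ] <- sa
  m2 <- seed_pair_maps(sa, sb, run2, roi_mask(one, sub$run$affine))
  expect_equal(unname(m2$beta_a), 1, tolerance = 1e-6)
  expect_equal(unname(m2$beta_b), 0, tolerance = 1e-6)

  # orthogonal seeds: multiple regression equals simple regressions
  set.seed(16)
  s1 <- rnorm(100); s2 <- residuals(lm(rnorm(100) ~ s1))
  y <- extract_timeseries(run2, sub$gray)
  mo <- seed_pair_maps(s1, s2, run2, sub$gray)
  simple_a <- apply(y, 2, function(v) coef(lm(v ~ s1))[2])
  expect_equal(mo$beta_a, unname(simple_a), tolerance = 1e-8)

  expect_error(seed_pair_maps(sa, sa, sub$run, sub$gray), "collinear")
})

test_that("network contrast recovers the built-in mixing direction", {
  cfg <- small_config(n_volumes = 150)
  sub <- make_subject_run(cfg, 21)
  halves <- split_roi_axis(sub$roi, "anterior-posterior")
  hm <- lapply(halves, function(h) extract_timeseries(sub$run, h))
  gd <- cfg$grid_dim
  nm <- list(
    A = extract_timeseries(sub$run, roi_mask(
      connectograd:::block_mask(gd, cfg$network_a_corner, cfg$network_dim),
      sub$run$affine)),
    B = extract_timeseries(sub$run, roi_mask(
      connectograd:::block_mask(gd, cfg$network_b_corner, cfg$network_dim),
      sub$run$affine)))
  tab <- network_contrast(hm, nm)
  expect_equal(nrow(tab), 4)
  z <- function(h, nw) tab$z[tab$half == h & tab$network == nw]
  # anterior (large world y) mixes network B more
  expect_gt(z("anterior", "B"), z("anterior", "A"))
  expect_gt(z("posterior", "A"), z("posterior", "B"))
  # swapping network labels swaps the columns
  tab_sw <- network_contrast(hm, list(A = nm$B, B = nm$A))
  expect_equal(tab_sw$z[tab_sw$network == "A"], tab$z[tab$network == "B"],
               tolerance = 1e-10)
  expect_error(network_contrast(hm, list(A = nm$A, B = nm$A)), "collinear")
})

test_that("homologous connectivity separates the three pair conditions", {
  set.seed(17)
  n <- 200
  base_al <- rnorm(n); base_pm <- rnorm(n)
  mk <- function(shared, own_sd = 0.6, nv = 10)
    outer(shared, rep(1, nv)) + matrix(rnorm(n * nv, sd = own_sd), n, nv)
  quarters <- list(alEC_left = mk(base_al), alEC_right = mk(base_al),
                   pmEC_left = mk(base_pm), pmEC_right = mk(base_pm))
  res <- homologous_contrast(quarters)
  expect_equal(nrow(res$pairs), 6)
  expect_equal(sort(table(res$pairs$condition))[["homologous"]], 2)
  m <- res$condition_means
  get <- function(cond) m$mean_z[m$condition == cond]
  expect_gt(get("homologous"), get("ipsilateral_nonhomologous"))
  expect_gt(get("homologous"), get("contralateral_nonhomologous"))
  # mirrored hemispheres: left/right values of each condition pair agree
  hom <- res$pairs[res$pairs$condition == "homologous", ]
  expect_equal(hom$z[1], hom$z[2], tolerance = 0.5)
  expect_error(homologous_contrast(quarters[1:3]), "must be named")
})

test_that("paired t matches the long-hand computation", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})

test_that("sign-flip permutation test matches exhaustive enumeration", {
  # all-zero maps: nothing to detect, p = 1 everywhere
  res0 <- sign_flip_test(matrix(0, 6, 5), 200, seed = 1)
  expect_true(all(res0$p_fwe == 1))

  # a strong consistent effect in one voxel is detected
  maps <- matrix(rnorm(10 * 30), 10, 30)
  maps[, 7] <- 5 + rnorm(10)
  res <- sign_flip_test(maps, 1000, seed = 2)
  expect_lte(res$p_fwe[7], 0.01)

  # full enumeration at n = 4 equals the brute-force 16-flip computation
  m4 <- matrix(rnorm(4 * 6), 4, 6)
  res4 <- sign_flip_test(m4, 1e6, seed = 3)
  tval <- function(mm) colMeans(mm) / (apply(mm, 2, sd) / 2)
  flips <- expand.grid(rep(list(c(1, -1)), 4))
  max_null <- apply(flips, 1, function(f)
    max(abs(tval(as.numeric(f) * m4))))
  p_brute <- vapply(abs(tval(m4)), function(t0)
    mean(max_null >= t0 - 1e-12), numeric(1))
  expect_equal(res4$p_fwe, p_brute, tolerance = 1e-12)
  expect_length(attr(res4, "max_t_null"), 16)
})
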