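test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.1)
  expect_equal(h[1], 0)
  peak_t <- (which.max(h) - 1) * 0.1
  expect_gte(peak_t, 4.5); expect_lte(peak_t, 6.5)
  expect_equal(max(h), 1)
  late <- h[seq_along(h) * 0.1 > 10]
  expect_lt(min(late), 0)                 # negative undershoot after ~10 s
  expect_error(canonical_hrf(0.5, length_s = 4), "truncated")
})

test_that("design matrices convolve events and carry motion plus intercept", {
  tr <- 2; n_vol <- 150
  ev <- tibble::tibble(onset = 30, duration = 2, condition = "scene")
  motion <- matrix(rnorm(n_vol * 6, sd = 0.01), n_vol, 6)
  x <- build_design(ev, motion, tr, n_vol)
  expect_equal(ncol(x), 1 + 6 + 1)
  expect_equal(colnames(x)[ncol(x)], "intercept")
  expect_true(all(abs(colMeans(x[, paste0("motion", 1:6)])) < 1e-12))
  # the single-event column is a shifted, scaled HRF: peak ~ onset + 6 s
  sc <- x[, "scene"]
  expect_equal((which.max(sc) - 1) * tr, 36, tolerance = 2)
  expect_true(all(abs(sc[1:15]) < 1e-10)) # nothing before the onset
  # two conditions -> conditions + 6 + 1 columns
  ev2 <- make_event_table(small_config(), run_duration_s = n_vol * tr)
  x2 <- build_design(ev2, motion, tr, n_vol)
  expect_equal(ncol(x2), 2 + 6 + 1)
  # no events: flagged absence of condition columns
  x0 <- build_design(ev[0, ], motion, tr, n_vol)
  expect_equal(attr(x0, "conditions"), character())
  expect_error(build_design(tibble::tibble(onset = 1e5, duration = 2,
                                           condition = "scene"),
                            motion, tr, n_vol), "beyond the run")
})

test_that("GLM fits recover constructed betas and orthogonal residuals", {
  tr <- 2; n_vol <- 200
  ev <- make_event_table(small_config(n_events_per_condition = 10),
                         run_duration_s = n_vol * tr)
  x <- build_design(ev, NULL, tr, n_vol)
  # noise-free voxel equal to 2 * scene column
  y <- cbind(2 * x[, "scene"] + 5, rnorm(n_vol))
  fit <- fit_glm(y, x)
  expect_equal(unname(fit$beta["scene", 1]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$beta["object", 1]), 0, tolerance = 1e-10)
  expect_equal(unname(glm_contrast(fit, c(scene = 1, object = -1))[1]), 2,
               tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(unclass(x), fit$residuals))), 1e-8)
  expect_error(glm_contrast(fit, c(1, -1)), "named")
  expect_error(glm_contrast(fit, c(banana = 1)), "unknown")

  # parameter recovery at noise sd 0.1, 400 volumes
  n_vol <- 400
  ev4 <- make_event_table(small_config(n_events_per_condition = 20, seed = 41),
                          run_duration_s = n_vol * tr)
  x4 <- build_design(ev4, NULL, tr, n_vol)
  set.seed(42)
  b_true <- c(object = 0.4, scene = 0.9, intercept = 100)
  nv <- 60
  y4 <- matrix(unclass(x4) %*% b_true, n_vol, nv) +
    matrix(rnorm(n_vol * nv, sd = 0.1), n_vol, nv)
  fit4 <- fit_glm(y4, x4)
  rmse <- sqrt(mean((fit4$beta["scene", ] - 0.9)^2 +
                      (fit4$beta["object", ] - 0.4)^2))
  expect_lte(rmse, 0.05)
})

test_that("beta recovery is unbiased over repeated simulations", {
  tr <- 2; n_vol <- 120
  ev <- make_event_table(small_config(n_events_per_condition = 8, seed = 5),
                         run_duration_s = n_vol * tr)
  x <- build_design(ev, NULL, tr, n_vol)
  errs <- vapply(1:50, function(s) {
    set.seed(100 + s)
    y <- matrix(unclass(x) %*% c(0.5, 0.5, 10) +
                  rnorm(n_vol, sd = 0.3), n_vol, 1)
    fit_glm(y, x)$beta["scene", 1] - 0.5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("cluster beta summaries follow the built-in gradient effect", {
  cfg <- small_config(n_volumes = 150, n_events_per_condition = 8,
                      noise_sd = 0.3)
  u <- ground_truth_u(cfg)
  clusters <- ifelse(u <= median(u), 1L, 2L)
  maps <- lapply(1:6, function(s) {
    sub <- make_task_run(cfg, subject_seed = 300 + s, effect_size = 1)
    x <- build_design(sub$truth$events, sub$truth$motion, cfg$tr,
                      cfg$n_volumes)
    roi_mat <- to_percent_signal_change(extract_timeseries(sub$run, sub$roi))
    glm_contrast(fit_glm(roi_mat, x), c(scene = 1, object = -1))
  })
  res <- roi_beta_summary(maps, clusters)
  # cluster 2 (high u) has the larger scene > object contrast
  expect_true(all(res$subject_means$difference < 0))
  expect_lt(res$test$statistic, 0)
  expect_lt(res$test$p.value, 0.05)
  # label swap flips the sign of the difference
  res_sw <- roi_beta_summary(maps, 3L - clusters)
  expect_equal(res_sw$subject_means$difference,
               -res$subject_means$difference)
  # identical clusters cannot happen; empty cluster is an error
  expect_error(roi_beta_summary(maps, rep(1L, length(clusters))),
               "empty")
  # spatially flat maps: both cluster means equal, T = 0
  flat <- lapply(1:4, function(s) rep(s, length(clusters)))
  expect_equal(roi_beta_summary(flat, clusters)$test$statistic, 0)
})
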