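#' Configuration for the synthetic fMRI generator
#'
#' Defines a desk-scale acquisition with the statistical structure the
#' connectopic analyses assume: two "network" blocks of gray matter driven by
#' their own autocorrelated time courses, an ROI whose voxels mix the two
#' network courses with weights varying linearly along one spatial axis (the
#' ground-truth gradient), a block of plain gray matter, multiplicative
#' baseline, additive Gaussian noise, smooth motion drift with injectable
#' displacement spikes, and a balanced two-condition event schedule.
#'
#' @param grid_dim voxels per axis (default 24^3).
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param tr repetition time (s).
#' @param n_volumes volumes per run.
#' @param n_subjects cohort size.
#' @param roi_corner,roi_dim 1-based corner and size of the ROI block.
#' @param gradient_axis axis along which the mixing weight varies
#'   (1 = x, 2 = y, 3 = z).
#' @param network_a_corner,network_b_corner,network_dim corners/size of the
#'   two network blocks (disjoint from the ROI).
#' @param gray_extra_corner,gray_extra_dim a block of plain gray matter with
#'   noise only.
#' @param baseline positive baseline signal level.
#' @param mixing_amplitude amplitude of the network signal relative to
#'   baseline.
#' @param noise_sd additive noise standard deviation as a fraction of the
#'   signal amplitude.
#' @param smooth_window moving-average window (volumes) for network time
#'   courses.
#' @param max_network_cor admissible absolute correlation between network
#'   courses; redrawn until satisfied.
#' @param drift_amplitude_mm amplitude of the smooth motion drift.
#' @param motion_spikes list of `list(volume =, magnitude_mm =)` entries.
#' @param n_events_per_condition events per condition for the task schedule.
#' @param event_duration_s stimulus duration (s).
#' @param iti_range_s inter-trial-interval range (s), uniform with mean 5.
#' @param seed base random seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid_dim = c(24, 24, 24), voxel_size_mm = 2,
                         tr = 2.7, n_volumes = 200, n_subjects = 10,
                         roi_corner = c(9, 9, 9), roi_dim = c(8, 8, 8),
                         gradient_axis = 2,
                         network_a_corner = c(9, 1, 9),
                         network_b_corner = c(9, 19, 9),
                         network_dim = c(6, 6, 6),
                         gray_extra_corner = c(1, 9, 9),
                         gray_extra_dim = c(6, 8, 8),
                         baseline = 100, mixing_amplitude = 1,
                         noise_sd = 0.5, smooth_window = 5,
                         max_network_cor = 0.2, drift_amplitude_mm = 0.01,
                         motion_spikes = list(),
                         n_events_per_condition = 12,
                         event_duration_s = 2, iti_range_s = c(1.5, 8.5),
                         seed = 1) {
  cfg <- list(grid_dim = as.integer(grid_dim), voxel_size_mm = voxel_size_mm,
              tr = tr, n_volumes = as.integer(n_volumes),
              n_subjects = as.integer(n_subjects),
              roi_corner = as.integer(roi_corner),
              roi_dim = as.integer(roi_dim),
              gradient_axis = as.integer(gradient_axis),
              network_a_corner = as.integer(network_a_corner),
              network_b_corner = as.integer(network_b_corner),
              network_dim = as.integer(network_dim),
              gray_extra_corner = as.integer(gray_extra_corner),
              gray_extra_dim = as.integer(gray_extra_dim),
              baseline = baseline, mixing_amplitude = mixing_amplitude,
              noise_sd = noise_sd, smooth_window = as.integer(smooth_window),
              max_network_cor = max_network_cor,
              drift_amplitude_mm = drift_amplitude_mm,
              motion_spikes = motion_spikes,
              n_events_per_condition = as.integer(n_events_per_condition),
              event_duration_s = event_duration_s,
              iti_range_s = iti_range_s, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(all(cfg$grid_dim > 0), cfg$voxel_size_mm > 0, cfg$tr > 0,
            cfg$n_volumes >= 2, cfg$n_subjects >= 1, cfg$noise_sd >= 0,
            cfg$baseline > 0, cfg$gradient_axis %in% 1:3)
  if (prod(cfg$roi_dim) < 8) stop("degenerate ROI: fewer than 8 voxels",
                                  call. = FALSE)
  blocks <- list(roi = block_voxels(cfg$roi_corner, cfg$roi_dim),
                 a = block_voxels(cfg$network_a_corner, cfg$network_dim),
                 b = block_voxels(cfg$network_b_corner, cfg$network_dim))
  for (bl in blocks)
    if (any(bl$hi > cfg$grid_dim)) stop("block exceeds grid", call. = FALSE)
  if (blocks_overlap(blocks$roi, blocks$a) ||
      blocks_overlap(blocks$roi, blocks$b) ||
      blocks_overlap(blocks$a, blocks$b))
    stop("ROI and network blocks must be disjoint", call. = FALSE)
  for (sp in cfg$motion_spikes) {
    if (sp$magnitude_mm < 0)
      stop("invalid schedule: negative spike magnitude", call. = FALSE)
    if (sp$volume < 2 || sp$volume > cfg$n_volumes)
      stop("spike index outside the run", call. = FALSE)
  }
  invisible(cfg)
}

block_voxels <- function(corner, dim) list(lo = corner, hi = corner + dim - 1L)

synth_config_zero_events <- function(config) {
  config$n_events_per_condition <- 0L
  config
}

blocks_overlap <- function(a, b)
  all(a$lo <= b$hi) && all(b$lo <= a$hi)

block_mask <- function(grid_dim, corner, dim) {
  m <- array(FALSE, grid_dim)
  m[corner[1]:(corner[1] + dim[1] - 1), corner[2]:(corner[2] + dim[2] - 1),
    corner[3]:(corner[3] + dim[3] - 1)] <- TRUE
  m
}

synth_affine <- function(cfg) {
  # MNI-like: center the grid on the world origin, 1 mm = 1 unit
  v <- cfg$voxel_size_mm
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (cfg$grid_dim - 1) / 2
  aff
}

#' Generate mutually decorrelated network time courses
#'
#' Smoothed Gaussian noise (moving average of window `smooth_window`),
#' standardized to zero mean and unit variance — resting-state-like
#' autocorrelated signals. Draws are repeated until all pairwise absolute
#' correlations fall below `max_network_cor`; an unsatisfiable bound raises a
#' generation failure.
#'
#' @param config a [synth_config()].
#' @param n_networks number of courses.
#' @param max_tries redraw budget.
#' @return Named list (`A`, `B`, ...) of time courses of length `n_volumes`.
#' @export
make_network_timecourses <- function(config, n_networks = 2, max_tries = 100) {
  stopifnot(config$n_volumes >= 2)
  set.seed(config$seed)
  nm <- LETTERS[seq_len(n_networks)]
  for (try in seq_len(max_tries)) {
    tc <- lapply(seq_len(n_networks), function(i)
      smooth_standardize(stats::rnorm(config$n_volumes),
                         config$smooth_window))
    cm <- stats::cor(do.call(cbind, tc))
    if (max(abs(cm[upper.tri(cm)])) < config$max_network_cor)
      return(stats::setNames(tc, nm))
  }
  stop("generation failure: correlation bound ", config$max_network_cor,
       " unsatisfied after ", max_tries, " draws", call. = FALSE)
}

smooth_standardize <- function(x, window) {
  if (window > 1) {
    k <- rep(1 / window, window)
    x <- stats::filter(x, k, sides = 2, circular = TRUE)
  }
  as.numeric(scale(as.numeric(x)))
}

#' Ground-truth gradient coordinate of the ROI voxels
#'
#' Linear in the voxel index along the configured axis, rescaled to `[0, 1]`,
#' in canonical voxel order.
#'
#' @param config a [synth_config()].
#' @return Numeric vector `u`, one value per ROI voxel.
#' @export
ground_truth_u <- function(config) {
  m <- block_mask(config$grid_dim, config$roi_corner, config$roi_dim)
  idx <- order_mask_indices(m)
  a <- config$gradient_axis
  (idx[, a] - min(idx[, a])) / (max(idx[, a]) - min(idx[, a]))
}

#' Generate a synthetic subject run
#'
#' ROI voxel v gets `baseline * (1 + amp * ((1 - u_v) s_A + u_v s_B) +
#' noise)`; each network block gets `baseline * (1 + amp * s_net + noise)`;
#' the plain gray block gets `baseline * (1 + noise)`; everything outside
#' gray matter is zero. Fixing the seeds makes the run bit-reproducible.
#'
#' @param config a [synth_config()].
#' @param subject_seed per-subject RNG seed for noise and motion.
#' @param timecourses optionally reuse network courses (e.g. shared across a
#'   cohort); default draws them from `config$seed`.
#' @return List with `run` (`bold_run`), `roi`, `gray` (`roi_mask`), and
#'   `truth` (list: `u`, `weights`, `timecourses`, `motion`, `events`).
#' @export
make_subject_run <- function(config, subject_seed,
                             timecourses = NULL) {
  validate_synth_config(config)
  if (is.null(timecourses)) timecourses <- make_network_timecourses(config)
  sA <- timecourses$A; sB <- timecourses$B
  aff <- synth_affine(config)
  gd <- config$grid_dim; nt <- config$n_volumes
  roi_m <- block_mask(gd, config$roi_corner, config$roi_dim)
  a_m <- block_mask(gd, config$network_a_corner, config$network_dim)
  b_m <- block_mask(gd, config$network_b_corner, config$network_dim)
  extra_m <- block_mask(gd, config$gray_extra_corner, config$gray_extra_dim)
  extra_m <- extra_m & !(roi_m | a_m | b_m)
  gray_m <- roi_m | a_m | b_m | extra_m
  u <- ground_truth_u(config)

  set.seed(subject_seed)
  dat <- array(0, c(gd, nt))
  flat <- matrix(dat, prod(gd), nt)
  amp <- config$mixing_amplitude
  put <- function(mask, signal_mat) {
    ord <- order_mask_indices(mask)
    lin <- ord[, 1] + gd[1] * (ord[, 2] - 1L) + gd[1] * gd[2] * (ord[, 3] - 1L)
    nv <- length(lin)
    noise <- matrix(stats::rnorm(nv * nt, sd = config$noise_sd), nv, nt)
    flat[lin, ] <<- config$baseline * (1 + signal_mat + noise)
  }
  put(roi_m, outer(1 - u, sA * amp) + outer(u, sB * amp))
  put(a_m, matrix(sA * amp, sum(a_m), nt, byrow = TRUE))
  put(b_m, matrix(sB * amp, sum(b_m), nt, byrow = TRUE))
  if (any(extra_m)) put(extra_m, matrix(0, sum(extra_m), nt))
  motion <- make_motion_trace(config, seed = subject_seed + 1L)
  # resting-type runs may be shorter than the configured task schedule; the
  # ground truth then carries no events (make_task_run still requires them)
  events <- tryCatch(make_event_table(config, seed = subject_seed + 2L),
                     error = function(e) make_event_table(
                       synth_config_zero_events(config),
                       seed = subject_seed + 2L))
  list(run = bold_run(array(flat, c(gd, nt)), aff, config$tr),
       roi = roi_mask(roi_m, aff, "roi"),
       gray = roi_mask(gray_m, aff, "gray_matter"),
       truth = list(u = u, weights = cbind(A = 1 - u, B = u),
                    timecourses = timecourses, motion = motion,
                    events = events))
}

#' Generate a rigid-body motion trace with scheduled displacement spikes
#'
#' The baseline is a low-amplitude smooth sinusoidal drift on all six
#' parameters. Each scheduled spike is a persistent translation step on the
#' first axis; the spiked volume's parameters are set to exactly the previous
#' volume's plus the step, so the framewise displacement at that index equals
#' the scheduled magnitude to within 1e-9 even with nonzero drift.
#'
#' @param config a [synth_config()] (fields `n_volumes`,
#'   `drift_amplitude_mm`, `motion_spikes`).
#' @param seed RNG seed for drift phases.
#' @return Tibble, volumes x 6: `trans_x/y/z` (mm), `rot_x/y/z` (radians).
#' @export
make_motion_trace <- function(config, seed = config$seed) {
  n <- config$n_volumes
  for (sp in config$motion_spikes) {
    if (sp$magnitude_mm < 0)
      stop("invalid schedule: negative spike magnitude", call. = FALSE)
    if (sp$volume < 2 || sp$volume > n)
      stop("spike index outside the run", call. = FALSE)
  }
  set.seed(seed)
  t0 <- seq_len(n)
  m <- vapply(seq_len(6), function(j) {
    ph <- stats::runif(1, 0, 2 * pi)
    per <- stats::runif(1, 40, 80)
    config$drift_amplitude_mm * sin(2 * pi * t0 / per + ph)
  }, numeric(n))
  for (sp in config$motion_spikes) {
    i <- sp$volume
    step <- c(sp$magnitude_mm, 0, 0, 0, 0, 0)
    prev <- m[i - 1, ]
    if (i < n) {
      off <- sweep(m[(i + 1):n, , drop = FALSE], 2, step, "+")
      m[(i + 1):n, ] <- off
    }
    m[i, ] <- prev + step
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tibble::as_tibble(m)
}

#' Generate a balanced two-condition event table
#'
#' Stimuli of fixed duration separated by inter-trial intervals drawn
#' uniformly from `iti_range_s` (default mean 5 s, within the 1.5-10 s
#' range); the two condition labels are balanced and shuffled.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param run_duration_s override the run duration (defaults to
#'   `n_volumes * tr`).
#' @return Tibble with `onset` (s), `duration` (s), `condition`
#'   ("scene"/"object").
#' @export
make_event_table <- function(config, seed = config$seed,
                             run_duration_s = config$n_volumes * config$tr) {
  n_per <- config$n_events_per_condition
  if (n_per == 0)
    return(tibble::tibble(onset = numeric(0), duration = numeric(0),
                          condition = character(0)))
  set.seed(seed)
  n_ev <- 2L * n_per
  cond <- sample(rep(c("scene", "object"), n_per))
  itis <- stats::runif(n_ev, config$iti_range_s[1], config$iti_range_s[2])
  onsets <- cumsum(c(itis[1], rep(config$event_duration_s, n_ev - 1) +
                       itis[-1]))
  if (max(onsets) + config$event_duration_s > run_duration_s)
    stop("overflow: events do not fit in the run", call. = FALSE)
  tibble::tibble(onset = onsets, duration = config$event_duration_s,
                 condition = cond)
}

#' Generate a synthetic cohort
#'
#' One run per subject with subject-specific noise and motion but shared
#' network time courses and ground truth, emulating template-space
#' correspondence across subjects.
#'
#' @param config a [synth_config()].
#' @return List of [make_subject_run()] results, length `n_subjects`.
#' @export
make_cohort <- function(config) {
  tc <- make_network_timecourses(config)
  lapply(seq_len(config$n_subjects), function(s)
    make_subject_run(config, subject_seed = config$seed + 1000L * s,
                     timecourses = tc))
}

#' Generate a task run with condition effects tracking the gradient
#'
#' Adds HRF-convolved condition signal to the resting structure of
#' [make_subject_run()]: the "scene" response amplitude scales with the
#' ground-truth gradient coordinate `u` and the "object" response with
#' `1 - u`, so the scene-minus-object contrast has a known spatial form
#' inside the ROI.
#'
#' @param config a [synth_config()].
#' @param subject_seed per-subject seed.
#' @param effect_size peak condition amplitude (signal fraction).
#' @return As [make_subject_run()]; `truth` additionally holds
#'   `scene_amplitude` and `object_amplitude` per ROI voxel.
#' @export
make_task_run <- function(config, subject_seed, effect_size = 1) {
  sub <- make_subject_run(config, subject_seed)
  ev <- sub$truth$events
  if (nrow(ev) == 0)
    stop("run too short for the configured event schedule", call. = FALSE)
  x <- build_design(ev, motion = NULL, tr = config$tr,
                    n_volumes = config$n_volumes)
  u <- sub$truth$u
  scene_amp <- effect_size * u
  object_amp <- effect_size * (1 - u)
  task <- outer(scene_amp, x[, "scene"]) + outer(object_amp, x[, "object"])
  roi_lin <- {
    ord <- order_mask_indices(sub$roi$mask)
    gd <- config$grid_dim
    ord[, 1] + gd[1] * (ord[, 2] - 1L) + gd[1] * gd[2] * (ord[, 3] - 1L)
  }
  d <- dim(sub$run$data)
  flat <- matrix(sub$run$data, prod(d[1:3]), d[4])
  flat[roi_lin, ] <- flat[roi_lin, ] + config$baseline * task
  sub$run <- bold_run(array(flat, d), sub$run$affine, config$tr)
  sub$truth$scene_amplitude <- scene_amp
  sub$truth$object_amplitude <- object_amp
  sub
}
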