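# Shared fixtures: all built in code at test time.

# A sensor recording holding a pure sinusoid (or silence).
make_sine_sensor <- function(label, freq_hz = 10, duration_s = 10, fs = 512,
                             amp_uv = 1, start_time = 0) {
  t <- seq_len(duration_s * fs) / fs
  sensor_recording(amp_uv * sin(2 * pi * freq_hz * t), label,
    sampling_rate = fs, start_time = start_time
  )
}

# Four identical-frequency sensors (independent phases optional).
make_sine_quad <- function(duration_s = 10, fs = 512, amp_uv = 1) {
  lapply(c("LF", "RF", "LE", "RE"), make_sine_sensor,
    freq_hz = 10, duration_s = duration_s, fs = fs, amp_uv = amp_uv
  )
}

# A minimal segment grid starting at time 0.
make_grid <- function(n_segments, window_s = 2) {
  structure(
    list(
      window_s = window_s, hop_s = window_s, n_segments = n_segments,
      start_s = (seq_len(n_segments) - 1) * window_s
    ),
    class = "segment_grid"
  )
}

# Synthetic labeled_features for detector-mechanics tests: `n_seg` segments
# whose feature vectors are Gaussian with the ictal block mean-shifted, so
# the classes are separable without any signal processing.  Ground truth and
# labels are mutually consistent on a 2-s grid.
make_toy_featset <- function(subject_id, n_seg = 300, ictal_from = 120,
                             ictal_len = 15, n_feat = 12, shift = 4,
                             near_margin_seg = 30, seed = 1) {
  grid <- make_grid(n_seg)
  x <- with_seed_test(seed, {
    m <- matrix(rnorm(n_seg * n_feat), n_seg, n_feat)
    m[ictal_from:(ictal_from + ictal_len - 1), ] <-
      m[ictal_from:(ictal_from + ictal_len - 1), ] + shift
    m
  })
  colnames(x) <- paste0("f", seq_len(n_feat))
  labels <- rep("non_ictal", n_seg)
  near <- max(1, ictal_from - near_margin_seg):min(n_seg, ictal_from + ictal_len - 1 + near_margin_seg)
  labels[near] <- "near_ictal"
  labels[ictal_from:(ictal_from + ictal_len - 1)] <- "ictal"
  truth <- annotation_set(
    (ictal_from - 1) * 2, (ictal_from - 1 + ictal_len) * 2,
    source = "ground_truth", subject_id = subject_id
  )
  structure(
    list(
      x = x, labels = factor(labels, levels = c("ictal", "near_ictal", "non_ictal")),
      grid = grid, truth = truth, subject_id = subject_id,
      record_hours = n_seg * 2 / 3600
    ),
    class = "labeled_features"
  )
}

# Seed helper independent of the package internals.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Random non-degenerate event set on a 0.5-s grid (so the raster oracle at
# 0.25 s resolution is exact).
random_events <- function(n, t_max = 1000) {
  if (n == 0) {
    return(data.frame(start_s = numeric(), stop_s = numeric()))
  }
  start <- sort(sample(seq(0, t_max - 2, by = 0.5), n))
  stop <- start + sample(seq(0.5, 30, by = 0.5), n, replace = TRUE)
  data.frame(start_s = start, stop_s = pmin(stop, t_max))
}

# Brute-force any-overlap oracle by rasterization: a truth event is TP iff
# its rasterized support intersects some detection's support.
raster_match_oracle <- function(truth, det, res = 0.25, t_max = 1100) {
  bins <- seq(0, t_max, by = res)
  cover <- function(ev) {
    hit <- logical(length(bins))
    for (i in seq_len(nrow(ev))) {
      hit <- hit | (bins >= ev$start_s[i] & bins < ev$stop_s[i])
    }
    hit
  }
  det_cov <- cover(det)
  tp <- vapply(seq_len(nrow(truth)), function(i) {
    any(det_cov & bins >= truth$start_s[i] & bins < truth$stop_s[i])
  }, logical(1))
  truth_cov <- cover(truth)
  fp <- vapply(seq_len(nrow(det)), function(j) {
    !any(truth_cov & bins >= det$start_s[j] & bins < det$stop_s[j])
  }, logical(1))
  list(n_tp = sum(tp), n_fn = sum(!tp), n_fp = sum(fp))
}

# Independent first-principles kappa oracles (explicit count loops).
cohen_oracle <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  n00 <- sum(a == 0 & b == 0)
  po <- (n11 + n00) / n
  pe <- (sum(a == 1) / n) * (sum(b == 1) / n) +
    (sum(a == 0) / n) * (sum(b == 0) / n)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

fleiss_oracle <- function(tab) {
  N <- nrow(tab)
  n <- ncol(tab)
  nij <- cbind(rowSums(tab == 0), rowSums(tab == 1))
  Pi <- (rowSums(nij^2) - n) / (n * (n - 1))
  pj <- colSums(nij) / (N * n)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-12) return(1)
  (Pbar - Pe) / (1 - Pe)
}

# Reduced-scale end-to-end configuration shared by the CLI and determinism
# tests: 128 Hz, two ~45-min subjects with one seizure each, 4-min
# near-ictal margin, 60-tree forest.
tiny_config <- function(seed = 3) {
  run_config(
    cohort = cohort_spec(
      n_subjects = 2, n_with_seizures = 2, seizures_per_subject = c("1" = 1),
      stay_hours = c(0.75, 0.8), sampling_rate = 128,
      seizure_duration_s = c(40, 60), seed = seed
    ),
    features = feature_config(near_ictal_margin_s = 240),
    integrator = integrator_config(),
    n_trees = 60, seed = seed
  )
}

# Labeled feature sets for a seeded synthetic cohort (used by the
# acceptance suite).
cohort_featsets <- function(spec, cfg = feature_config()) {
  lapply(generate_cohort(spec), function(s) {
    m <- build_remi_montage(s$sensors)
    compute_features(m, s$ground_truth, s$subject_id, cfg)
  })
}

# Train-on-all-subjects calibration experiment: fit the 500-tree forest on
# the balanced pool from every subject, calibrate the threshold on the
# out-of-bag-corrected training traces, and measure pooled any-overlap
# event sensitivity of the post-processed detections on those same
# training subjects at the operating threshold.
training_sensitivity_experiment <- function(featsets, seed,
                                            cfg = integrator_config(),
                                            n_trees = 500) {
  ts <- assemble_training(featsets, held_out = NULL,
    seed = derive_seed(seed, "balance"))
  model <- train_detector(ts, n_trees = n_trees,
    seed = derive_seed(seed, "forest"))
  traces <- calibration_traces(model, ts, featsets, cfg$alpha)
  truths <- lapply(featsets, `[[`, "truth")
  grids <- lapply(featsets, `[[`, "grid")
  names(truths) <- names(grids) <- vapply(featsets, `[[`, character(1), "subject_id")
  theta_crit <- suppressWarnings(
    calibrate_threshold(traces, truths[names(traces)], grids[names(traces)], cfg)
  )
  cfg_op <- cfg
  cfg_op$theta <- theta_crit * cfg$theta_safety
  tp <- 0; fn <- 0; fp <- 0
  for (id in names(traces)) {
    ev <- postprocess_events(detect_events(traces[[id]], cfg_op, grids[[id]]), cfg_op)
    mr <- match_events(truths[[id]], ev)
    tp <- tp + mr$n_tp; fn <- fn + mr$n_fn; fp <- fp + mr$n_fp
  }
  list(sensitivity_pct = 100 * tp / (tp + fn), n_events = tp + fn,
    n_fp = fp, theta_crit = theta_crit, theta_op = cfg_op$theta)
}
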