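test_that("training assembly enforces the 3:1 balance and exclusions", {
  # pool: 40 ictal + 1000 non-ictal -> keep 40 + 120
  fs1 <- make_toy_featset("A", n_seg = 1040, ictal_from = 500, ictal_len = 40,
    near_margin_seg = 0, seed = 1)
  fs2 <- make_toy_featset("B", n_seg = 300, ictal_from = 100, ictal_len = 10, seed = 2)
  ts <- assemble_training(list(fs1, fs2), held_out = "B", seed = 3)
  expect_equal(ts$n_ictal, 40)
  expect_equal(ts$n_non_ictal, 120)
  expect_equal(sum(ts$y == 0) / sum(ts$y == 1), 3)
  expect_false("B" %in% ts$rows$subject_id)
  expect_identical(ts$provenance, "A")

  # near-ictal rows are excluded entirely
  fs3 <- make_toy_featset("C", n_seg = 300, ictal_from = 100, ictal_len = 10,
    near_margin_seg = 50, seed = 4)
  ts3 <- assemble_training(list(fs3, fs2), held_out = "B", seed = 3)
  near_segs <- which(fs3$labels == "near_ictal")
  expect_length(intersect(ts3$rows$segment[ts3$rows$subject_id == "C"], near_segs), 0)

  # shortfall: fewer than 3x non-ictal available -> keep all of them
  fs4 <- make_toy_featset("D", n_seg = 130, ictal_from = 50, ictal_len = 40,
    near_margin_seg = 0, seed = 5)
  ts4 <- assemble_training(list(fs4), held_out = NULL, seed = 3)
  expect_equal(ts4$n_ictal, 40)
  expect_equal(ts4$n_non_ictal, 90)

  # all-non-ictal pool is a training error
  fs5 <- make_toy_featset("E", n_seg = 100, ictal_from = 40, ictal_len = 5, seed = 6)
  fs5$labels[] <- "non_ictal"
  expect_error(assemble_training(list(fs5)), "training error")
})

test_that("forest separates a two-cluster toy problem deterministically", {
  x <- with_seed_test(1, rbind(
    matrix(rnorm(200 * 5), 200, 5),
    matrix(rnorm(80 * 5, mean = 4), 80, 5)
  ))
  colnames(x) <- paste0("f", 1:5)
  y <- c(rep(0, 200), rep(1, 80))
  model <- rf_train(x, y, n_trees = 100, seed = 2)
  p <- rf_predict(model, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p[y == 1] > 0.5))
  expect_true(all(p[y == 0] < 0.5))

  # same seed -> identical probe predictions; different seed -> a different forest
  probe <- with_seed_test(3, matrix(rnorm(50 * 5, mean = 2), 50, 5,
    dimnames = list(NULL, paste0("f", 1:5))))
  expect_identical(p, rf_predict(rf_train(x, y, n_trees = 100, seed = 2), x))
  expect_false(identical(
    rf_predict(model, probe),
    rf_predict(rf_train(x, y, n_trees = 100, seed = 9), probe)
  ))

  # schema-keyed scoring: permuting named columns changes nothing
  perm <- probe[, c(4, 2, 5, 1, 3)]
  expect_identical(rf_predict(model, probe), rf_predict(model, perm))
  expect_error(rf_predict(model, probe[, 1:3]), "missing features")
  expect_error(rf_train(x, rep(1, nrow(x))), "training error")

  # out-of-bag votes are defined for every training row and less extreme
  oob <- rf_predict_oob(model, x)
  expect_true(all(is.finite(oob)))
  expect_true(all(oob >= 0 & oob <= 1))
})

test_that("leaky integrator follows its recursion and fixed point", {
  expect_equal(integrate_likelihood(c(1, 1, 1), 0.5), c(0.5, 0.75, 0.875))
  expect_true(all(integrate_likelihood(rep(0, 10), 0.8) == 0))
  y <- integrate_likelihood(rep(0.6, 50), 0.8)
  expect_true(all(diff(y) > 0)) # approaches the fixed point from below
  expect_lt(max(y), 0.6 + 1e-9)
  expect_equal(y[50], 0.6, tolerance = 1e-4)
  # convex combination: never exceeds the largest input
  p <- with_seed_test(1, runif(100))
  expect_lte(max(integrate_likelihood(p, 0.8)), max(p))
  expect_error(integrate_likelihood(p, 1.2), "config error")
})

test_that("event formation applies trigger runs and latency correction", {
  grid <- make_grid(30)
  cfg <- integrator_config(alpha = 0.5, theta = 0.5)

  # never above threshold -> nothing
  expect_equal(nrow(detect_events(rep(0.2, 30), cfg, grid)), 0)

  # a 4-segment run is one short of the 5-segment trigger
  y4 <- rep(0.1, 30); y4[11:14] <- 0.9
  expect_equal(nrow(detect_events(y4, cfg, grid)), 0)

  # supra-threshold segments 11..20 (1-based), alpha = 0.5 -> L = 1 segment:
  # start = 20 s - 2 s = 18 s, stop = end of segment 20 = 40 s
  y10 <- rep(0.1, 30); y10[11:20] <- 0.9
  ev <- detect_events(y10, cfg, grid)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 18)
  expect_equal(ev$stop_s, 40)
  expect_equal(ev$peak, 0.9)

  # a sub-threshold dip shorter than 5 segments does not close the event
  ydip <- rep(0.1, 30); ydip[6:12] <- 0.9; ydip[13:14] <- 0.2; ydip[15:20] <- 0.9
  expect_equal(nrow(detect_events(ydip, cfg, grid)), 1)

  # an event still open at record end closes there
  yopen <- rep(0.1, 30); yopen[25:30] <- 0.9
  evo <- detect_events(yopen, cfg, grid)
  expect_equal(evo$stop_s, 60)

  # latency correction is floored at the record start
  ystart <- rep(0.1, 30); ystart[1:6] <- 0.9
  cfg8 <- integrator_config(alpha = 0.8, theta = 0.5) # L = 4 segments
  expect_equal(detect_events(ystart, cfg8, grid)$start_s, 0)
})

test_that("post-processing merges within 2 min then discards > 15 min", {
  cfg <- integrator_config()
  ev <- data.frame(start_s = c(0, 90), stop_s = c(30, 120), peak = c(0.8, 0.9))
  out <- postprocess_events(ev, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$start_s, 0)
  expect_equal(out$stop_s, 120)
  expect_equal(out$peak, 0.9)

  # merging can chain and the merged result is then length-filtered
  chain <- data.frame(
    start_s = seq(0, 900, by = 100),
    stop_s = seq(0, 900, by = 100) + 50
  )
  expect_equal(nrow(postprocess_events(chain, cfg)), 0) # 950 s > 900 s
  # a gap of exactly 2 min does not merge
  apart <- data.frame(start_s = c(0, 150), stop_s = c(30, 180))
  expect_equal(nrow(postprocess_events(apart, cfg)), 2)
  expect_equal(nrow(postprocess_events(chain[0, ], cfg)), 0)
})

test_that("threshold calibration meets the training sensitivity target", {
  grid <- make_grid(400)
  truth <- annotation_set(200, 260, subject_id = "T")
  # perfectly separating trace: 1 inside the seizure, 0 outside
  y <- rep(0, 400); y[101:130] <- 1
  cfg <- integrator_config()
  theta <- calibrate_threshold(list(y), list(truth), list(grid), cfg)
  expect_equal(theta, 0.95) # the largest grid candidate qualifies

  # sensitivity is non-increasing in theta on a fixed graded trace
  y2 <- rep(0, 400); y2[101:110] <- 0.5; y2[201:215] <- 0.9
  truth2 <- annotation_set(c(200, 400), c(220, 430), subject_id = "T")
  sens_at <- function(theta) {
    cfg_t <- integrator_config(theta = theta)
    ev <- postprocess_events(detect_events(y2, cfg_t, grid), cfg_t)
    match_events(truth2, ev)$n_tp / 2
  }
  sweep <- vapply(seq(0.05, 0.95, 0.05), sens_at, numeric(1))
  expect_true(all(diff(sweep) <= 0))

  # the returned threshold honors the >= 90% training target
  theta2 <- calibrate_threshold(list(y2), list(truth2), list(grid), cfg,
    target_sens = 0.5)
  expect_gte(sens_at(theta2), 0.5)
  expect_error(calibrate_threshold(list(y), list(truth), list(grid), cfg,
    grid_theta = numeric()), "config error")
  expect_warning(
    calibrate_threshold(list(rep(0, 400)), list(truth), list(grid), cfg),
    "grid minimum"
  )
})

test_that("LOSO pipeline is seeded, isolated and event-valid", {
  featsets <- list(
    make_toy_featset("A", seed = 1), make_toy_featset("B", seed = 2),
    make_toy_featset("C", seed = 3)
  )
  res <- run_loso(featsets, integrator_config(), seed = 7, n_trees = 60)
  expect_named(res, c("A", "B", "C"))

  res2 <- run_loso(featsets, integrator_config(), seed = 7, n_trees = 60)
  expect_identical(
    lapply(res, function(r) r$events$start_s),
    lapply(res2, function(r) r$events$start_s)
  )

  for (id in names(res)) {
    ev <- res[[id]]$events
    expect_length(res[[id]]$trace, 300)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$start_s) > 0))
      expect_true(all(ev$start_s[-1] - ev$stop_s[-nrow(ev)] >= 120))
    }
    if (nrow(ev)) expect_true(all(ev$stop_s - ev$start_s <= 900))
  }
  # the separable toy seizures are recovered out of sample
  hits <- vapply(names(res), function(id) {
    fs <- featsets[[match(id, c("A", "B", "C"))]]
    match_events(fs$truth, res[[id]]$events)$n_tp
  }, integer(1))
  expect_true(all(hits == 1))
  expect_error(run_loso(featsets[1]), "at least 2")
})
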