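#' Event-former configuration
#'
#' Parameters of the leaky weighted integrator and the event post-processor:
#' integrator leak `alpha`, fixed detection threshold `theta` (calibrated on
#' training data when `NULL`), the 5-segment (10-s) trigger run, the 2-min
#' merge gap and the 15-min maximum event duration.
#'
#' @param alpha Integrator leak in (0, 1).
#' @param theta Fixed threshold in (0, 1), or `NULL` to calibrate.
#' @param trigger_run Consecutive segments above/below threshold required to
#'   open/close an event.
#' @param merge_gap_s Events closer than this are concatenated.
#' @param max_event_s Events longer than this are discarded (after merging).
#' @param theta_safety Factor in (0, 1] applied to the calibrated critical
#'   threshold to obtain the operating threshold.  Calibration finds the
#'   largest threshold still meeting the target training sensitivity; the
#'   operating point is deliberately set below it (threshold "set low", at
#'   the expense of a possibly higher false-detection rate) because
#'   training-side traces are optimistic for unseen subjects even when
#'   out-of-bag corrected.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(alpha = 0.8, theta = NULL, trigger_run = 5,
                              merge_gap_s = 120, max_event_s = 900,
                              theta_safety = 0.8) {
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must lie in (0, 1)")
  if (!is.null(theta) && (theta <= 0 || theta >= 1)) {
    stop("config error: theta must lie in (0, 1)")
  }
  if (trigger_run < 1) stop("config error: trigger_run must be >= 1")
  if (merge_gap_s <= 0 || max_event_s <= 0) {
    stop("config error: merge_gap_s and max_event_s must be positive")
  }
  if (theta_safety <= 0 || theta_safety > 1) {
    stop("config error: theta_safety must lie in (0, 1]")
  }
  structure(
    list(
      alpha = alpha, theta = theta, trigger_run = as.integer(trigger_run),
      merge_gap_s = merge_gap_s, max_event_s = max_event_s,
      theta_safety = theta_safety
    ),
    class = "integrator_config"
  )
}

#' Assemble a balanced leave-one-subject-out training set
#'
#' Pools segments from every subject except the held-out one, keeps all
#' ictal segments, excludes near-ictal segments entirely, and samples
#' non-ictal segments without replacement down to a 3:1 non-ictal:ictal
#' ratio (all available non-ictal rows are kept when fewer).
#'
#' @param featsets List of `labeled_features`, one per subject.
#' @param held_out Subject id to exclude, or `NULL` to train on all.
#' @param seed Integer seed for the non-ictal subsample.
#' @param balance_ratio Non-ictal:ictal ratio (3 by default).
#' @return List with `x`, `y` (1 = ictal), `provenance` (included subject
#'   ids) and counts.
#' @export
assemble_training <- function(featsets, held_out = NULL, seed = 1L,
                              balance_ratio = 3) {
  ids <- vapply(featsets, `[[`, character(1), "subject_id")
  keep <- if (is.null(held_out)) rep(TRUE, length(ids)) else ids != held_out
  if (!any(keep)) stop("training error: no subjects left after hold-out")
  xs <- list()
  ys <- list()
  rows <- list()
  for (fs in featsets[keep]) {
    sel <- which(fs$labels != "near_ictal")
    xs[[fs$subject_id]] <- fs$x[sel, , drop = FALSE]
    ys[[fs$subject_id]] <- as.integer(fs$labels[sel] == "ictal")
    rows[[fs$subject_id]] <- data.frame(
      subject_id = fs$subject_id, segment = sel,
      stringsAsFactors = FALSE
    )
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys, use.names = FALSE)
  rows <- do.call(rbind, rows)
  n_ictal <- sum(y == 1)
  if (n_ictal == 0) {
    stop("training error: no ictal segments in the training pool")
  }
  non_idx <- which(y == 0)
  n_keep <- min(length(non_idx), balance_ratio * n_ictal)
  non_keep <- with_seed(seed, sample(non_idx, n_keep))
  idx <- sort(c(which(y == 1), non_keep))
  rows <- rows[idx, , drop = FALSE]
  rownames(rows) <- NULL
  list(
    x = x[idx, , drop = FALSE], y = y[idx], rows = rows,
    provenance = ids[keep], n_ictal = n_ictal, n_non_ictal = n_keep,
    balance_ratio = balance_ratio, seed = seed
  )
}

#' Train the seizure segment classifier
#'
#' @param ts Training set from [assemble_training()].
#' @param n_trees Number of trees (500 by default).
#' @param seed Integer training seed.
#' @return A [rf_train()] forest.
#' @export
train_detector <- function(ts, n_trees = 500, seed = 1L) {
  rf_train(ts$x, ts$y, n_trees = n_trees, seed = seed)
}

#' Score a subject's segments
#'
#' @param model A trained forest.
#' @param featset `labeled_features` of one subject (including its
#'   near-ictal segments).
#' @return Ictal likelihood per 2-s segment, in temporal order.
#' @export
score_segments <- function(model, featset) {
  rf_predict(model, featset$x)
}

#' Leaky weighted integrator
#'
#' Smooths the per-segment likelihood trace:
#' `y_t = alpha * y_(t-1) + (1 - alpha) * p_t`, `y_0 = 0`.  The output is a
#' convex combination of past likelihoods, so it stays within `[0, 1]`.
#'
#' @param p Likelihood sequence in `[0, 1]`.
#' @param alpha Leak parameter in (0, 1).
#' @return Integrated sequence of the same length.
#' @export
integrate_likelihood <- function(p, alpha = 0.8) {
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must lie in (0, 1)")
  as.numeric(stats::filter((1 - alpha) * p, alpha, method = "recursive"))
}

#' Form detection events from an integrated likelihood trace
#'
#' A seizure start marker is set when the integrated likelihood exceeds the
#' threshold for `trigger_run` (5) consecutive segments; the start time is
#' the start of the first supra-threshold segment minus the integrator
#' latency `L = round(alpha / (1 - alpha))` segments (floored at time 0),
#' accounting for the integrator's ramp-up.  A stop marker is set when the
#' trace falls below threshold for 5 consecutive segments; the stop time is
#' the end of the last supra-threshold segment.  An event still open at the
#' record end is closed there.
#'
#' @param y Integrated likelihood trace.
#' @param cfg An [integrator_config()] with a non-`NULL` `theta`.
#' @param grid The subject's [segment()] grid (aligned with `y`).
#' @return Data frame of events with `start_s`, `stop_s`, `peak`.
#' @export
detect_events <- function(y, cfg, grid) {
  stopifnot(inherits(cfg, "integrator_config"), inherits(grid, "segment_grid"))
  if (is.null(cfg$theta)) stop("config error: theta must be set (calibrate first)")
  if (length(y) != grid$n_segments) stop("y is not aligned with the segment grid")
  supra <- y > cfg$theta
  L <- round(cfg$alpha / (1 - cfg$alpha))
  run <- cfg$trigger_run
  w <- grid$window_s
  rec_start <- grid$start_s[1]
  rec_end <- grid$start_s[grid$n_segments] + w

  events <- list()
  open <- FALSE
  first_supra <- NA_integer_
  last_supra <- NA_integer_
  r <- rle(supra)
  idx <- cumsum(r$lengths) - r$lengths + 1 # run start indices
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) {
      if (!open && r$lengths[k] >= run) {
        open <- TRUE
        first_supra <- idx[k]
      }
      if (open) last_supra <- idx[k] + r$lengths[k] - 1
    } else if (open && r$lengths[k] >= run) {
      events[[length(events) + 1]] <- c(first_supra, last_supra)
      open <- FALSE
    }
  }
  if (open) events[[length(events) + 1]] <- c(first_supra, last_supra)
  if (!length(events)) {
    return(data.frame(start_s = numeric(), stop_s = numeric(), peak = numeric()))
  }
  ev <- do.call(rbind, events)
  start_s <- pmax(rec_start, grid$start_s[ev[, 1]] - L * w)
  stop_s <- pmin(rec_end, grid$start_s[ev[, 2]] + w)
  peak <- vapply(
    seq_len(nrow(ev)),
    function(i) max(y[ev[i, 1]:ev[i, 2]]), numeric(1)
  )
  data.frame(start_s = start_s, stop_s = stop_s, peak = peak)
}

#' Post-process detection events
#'
#' (1) Events within 2 min of each other are concatenated into a single
#' event; (2) after concatenation, any event longer than 15 min is
#' discarded.  Merging strictly precedes the duration filter.
#'
#' @param events Data frame of sorted events (`start_s`, `stop_s`, optional
#'   `peak`).
#' @param cfg An [integrator_config()].
#' @return Post-processed event data frame.
#' @export
postprocess_events <- function(events, cfg = integrator_config()) {
  if (nrow(events) == 0) return(events)
  events <- events[order(events$start_s), , drop = FALSE]
  has_peak <- "peak" %in% names(events)
  out <- events[1, , drop = FALSE]
  for (i in seq_len(nrow(events))[-1]) {
    j <- nrow(out)
    if (events$start_s[i] - out$stop_s[j] < cfg$merge_gap_s) {
      out$stop_s[j] <- max(out$stop_s[j], events$stop_s[i])
      if (has_peak) out$peak[j] <- max(out$peak[j], events$peak[i])
    } else {
      out <- rbind(out, events[i, , drop = FALSE])
    }
  }
  out <- out[out$stop_s - out$start_s <= cfg$max_event_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the fixed detection threshold on training subjects
#'
#' Sweeps a descending threshold grid; for each candidate it forms
#' post-processed events from every training subject's integrated trace and
#' pools any-overlap event sensitivity over their ground truth.  Returns the
#' largest threshold achieving the target sensitivity (>= 90% by default),
#' i.e. the threshold is "set low so sensitivity is high" while keeping the
#' false-detection rate as low as the target allows.  When no candidate
#' reaches the target the grid minimum is returned with a warning.
#'
#' @param traces List of integrated likelihood traces (training subjects).
#' @param truths List of ground-truth [annotation_set()]s, aligned.
#' @param grids List of [segment()] grids, aligned.
#' @param cfg An [integrator_config()] (its `theta` is ignored).
#' @param grid_theta Candidate thresholds; default `seq(0.05, 0.95, 0.01)`.
#' @param target_sens Target training event sensitivity (0.90).
#' @return The calibrated threshold.
#' @export
calibrate_threshold <- function(traces, truths, grids, cfg = integrator_config(),
                                grid_theta = seq(0.05, 0.95, by = 0.01),
                                target_sens = 0.90) {
  if (!length(grid_theta)) stop("config error: empty threshold grid")
  n_truth <- sum(vapply(truths, nrow, integer(1)))
  if (n_truth == 0) stop("training error: no ground-truth events to calibrate on")
  for (theta in sort(grid_theta, decreasing = TRUE)) {
    cfg_t <- cfg
    cfg_t$theta <- theta
    tp <- 0
    for (i in seq_along(traces)) {
      ev <- postprocess_events(detect_events(traces[[i]], cfg_t, grids[[i]]), cfg_t)
      mr <- match_events(truths[[i]], ev)
      tp <- tp + mr$n_tp
    }
    if (tp / n_truth >= target_sens) {
      return(theta)
    }
  }
  warning("no threshold reached the target training sensitivity; using grid minimum")
  min(grid_theta)
}

#' Integrated likelihood traces of training subjects for calibration
#'
#' Scores each training subject's complete segment sequence with the fitted
#' forest, but substitutes out-of-bag likelihoods ([rf_predict_oob()]) at
#' the segments that entered the training set, so the calibration traces are
#' not inflated by in-sample (near-perfect) votes; the remaining segments
#' (near-ictal and unsampled non-ictal) are genuinely out-of-sample already.
#'
#' @param model A trained [rf_train()] forest.
#' @param ts The [assemble_training()] set the model was fitted on.
#' @param featsets List of `labeled_features` containing the training
#'   subjects.
#' @param alpha Integrator leak.
#' @return Named list of integrated likelihood traces, one per training
#'   subject.
#' @export
calibration_traces <- function(model, ts, featsets, alpha = 0.8) {
  ids <- vapply(featsets, `[[`, character(1), "subject_id")
  names(featsets) <- ids
  oob <- rf_predict_oob(model, ts$x)
  traces <- list()
  for (id in intersect(ts$provenance, ids)) {
    fs <- featsets[[id]]
    p <- score_segments(model, fs)
    in_train <- ts$rows$subject_id == id
    p[ts$rows$segment[in_train]] <- oob[in_train]
    traces[[id]] <- integrate_likelihood(p, alpha)
  }
  traces
}

#' Run the full leave-one-subject-out detection pipeline
#'
#' For each subject: assemble the balanced training set from all other
#' subjects, train the 500-tree forest, calibrate the threshold on the
#' training subjects' integrated traces, then score, integrate, detect and
#' post-process the held-out subject's complete feature set (near-ictal
#' segments included).  Fully seeded.
#'
#' @param featsets List of `labeled_features`, one per subject (>= 2).
#' @param cfg An [integrator_config()]; a non-`NULL` `theta` skips
#'   calibration.
#' @param seed Master seed.
#' @param n_trees Trees per forest.
#' @return An object of class `loso_result`: per-subject list with
#'   `events` ([annotation_set()], source `"algorithm"`), `trace`, `theta`.
#' @export
run_loso <- function(featsets, cfg = integrator_config(), seed = 1L,
                     n_trees = 500) {
  if (length(featsets) < 2) stop("LOSO requires at least 2 subjects")
  ids <- vapply(featsets, `[[`, character(1), "subject_id")
  names(featsets) <- ids
  out <- list()
  for (id in ids) {
    ts <- assemble_training(featsets,
      held_out = id,
      seed = derive_seed(seed, paste0("balance.", id))
    )
    model <- train_detector(ts,
      n_trees = n_trees,
      seed = derive_seed(seed, paste0("forest.", id))
    )
    train_ids <- setdiff(ids, id)
    cfg_fold <- cfg
    if (is.null(cfg$theta)) {
      traces <- calibration_traces(model, ts, featsets[train_ids], cfg$alpha)
      theta_crit <- calibrate_threshold(
        traces,
        lapply(featsets[names(traces)], `[[`, "truth"),
        lapply(featsets[names(traces)], `[[`, "grid"),
        cfg
      )
      cfg_fold$theta <- theta_crit * cfg$theta_safety
    }
    fs <- featsets[[id]]
    trace <- integrate_likelihood(score_segments(model, fs), cfg$alpha)
    ev <- postprocess_events(detect_events(trace, cfg_fold, fs$grid), cfg_fold)
    out[[id]] <- list(
      events = annotation_set(ev$start_s, ev$stop_s,
        label = "detection",
        source = "algorithm", subject_id = id
      ),
      trace = trace, theta = cfg_fold$theta
    )
  }
  structure(out, class = "loso_result")
}
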