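#' Segment a montage into non-overlapping scoring windows
#'
#' The montage is cut into contiguous, non-overlapping 2-s windows (hop =
#' window); a trailing partial window is dropped.
#'
#' @param m A `remi_montage`.
#' @param window_s Window length in seconds (2 by default).
#' @return An object of class `segment_grid`: list with `window_s`, `hop_s`,
#'   `n_segments` and `start_s` (absolute window start times).
#' @export
segment <- function(m, window_s = 2) {
  stopifnot(inherits(m, "remi_montage"))
  if (m$duration < window_s) {
    stop("recording too short to segment: ", m$duration, " s < ", window_s, " s")
  }
  n <- as.integer(floor(m$duration / window_s))
  structure(
    list(
      window_s = window_s, hop_s = window_s, n_segments = n,
      start_s = m$start_time + (seq_len(n) - 1) * window_s
    ),
    class = "segment_grid"
  )
}

#' Label segments as ictal, near-ictal or non-ictal
#'
#' A segment overlapping a known seizure by any amount is `ictal`; a
#' non-ictal segment within the margin (15 min by default) before or after
#' any known seizure is `near_ictal`; all others are `non_ictal`.
#'
#' @param grid A [segment()] grid.
#' @param truth Ground-truth [annotation_set()] on the same time base.
#' @param margin_s Near-ictal margin in seconds (default 900 = 15 min).
#' @return Factor of length `n_segments` with levels
#'   `ictal`, `near_ictal`, `non_ictal`.
#' @export
label_segments <- function(grid, truth, margin_s = 900) {
  stopifnot(inherits(grid, "segment_grid"))
  s0 <- grid$start_s
  s1 <- s0 + grid$window_s
  ictal <- rep(FALSE, grid$n_segments)
  near <- rep(FALSE, grid$n_segments)
  for (i in seq_len(nrow(truth))) {
    ictal <- ictal | (s0 < truth$stop_s[i] & s1 > truth$start_s[i])
    near <- near | (s0 < truth$stop_s[i] + margin_s & s1 > truth$start_s[i] - margin_s)
  }
  out <- rep("non_ictal", grid$n_segments)
  out[near] <- "near_ictal"
  out[ictal] <- "ictal"
  factor(out, levels = c("ictal", "near_ictal", "non_ictal"))
}

#' Feature-extraction configuration
#'
#' @param band_edges_hz Named list of frequency-band edges (Hz); defaults to
#'   the clinical delta/theta/alpha/beta/gamma bands, all inside the 0.8--92
#'   Hz passband.
#' @param wavelet_levels Number of Haar wavelet decomposition levels.
#' @param entropy_embedding Sample-entropy embedding dimension m.
#' @param entropy_tolerance Sample-entropy tolerance as a fraction of the
#'   segment SD.
#' @param sampen_decimation Keep every k-th sample for sample entropy (the
#'   quadratic-cost estimator runs on the decimated segment).
#' @param history_decay Exponential history weight `alpha_h` in (0,1);
#'   0.8 gives roughly a 10-segment (20 s) memory.
#' @param near_ictal_margin_s Near-ictal labeling margin in seconds.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(band_edges_hz = list(
                             delta = c(0.8, 4), theta = c(4, 8),
                             alpha = c(8, 13), beta = c(13, 30),
                             gamma = c(30, 70)
                           ),
                           wavelet_levels = 6,
                           entropy_embedding = 2,
                           entropy_tolerance = 0.2,
                           sampen_decimation = 8,
                           history_decay = 0.8,
                           near_ictal_margin_s = 900) {
  edges <- unlist(band_edges_hz)
  if (any(edges < DEVICE_PASSBAND_HZ[1] - 1e-9) || any(edges > DEVICE_PASSBAND_HZ[2] + 1e-9)) {
    stop("band edges must lie within the ", DEVICE_PASSBAND_HZ[1], "-",
      DEVICE_PASSBAND_HZ[2], " Hz passband")
  }
  if (history_decay <= 0 || history_decay >= 1) {
    stop("history_decay must lie strictly inside (0, 1)")
  }
  structure(
    list(
      band_edges_hz = band_edges_hz, wavelet_levels = as.integer(wavelet_levels),
      entropy_embedding = as.integer(entropy_embedding),
      entropy_tolerance = entropy_tolerance,
      sampen_decimation = as.integer(sampen_decimation),
      history_decay = history_decay,
      near_ictal_margin_s = near_ictal_margin_s
    ),
    class = "feature_config"
  )
}

# Names of the per-channel base features for a given config.
base_feature_names <- function(cfg) {
  c(
    "variance", "line_length", "rms",
    paste0("bp_", names(cfg$band_edges_hz)),
    paste0("relbp_", names(cfg$band_edges_hz)),
    paste0("wavelet_e", seq_len(cfg$wavelet_levels)),
    "spectral_entropy", "sample_entropy"
  )
}

# Haar DWT detail energies per level for each column of S (samples x segments).
haar_level_energies <- function(S, levels) {
  n_seg <- ncol(S)
  out <- matrix(0, n_seg, levels)
  A <- S
  for (lev in seq_len(levels)) {
    m <- nrow(A)
    if (m < 2) break
    if (m %% 2 == 1) A <- A[-m, , drop = FALSE]
    odd <- A[seq(1, nrow(A), by = 2), , drop = FALSE]
    evn <- A[seq(2, nrow(A), by = 2), , drop = FALSE]
    D <- (odd - evn) / sqrt(2)
    A <- (odd + evn) / sqrt(2)
    out[, lev] <- colSums(D^2) / nrow(S)
  }
  out
}

# Features for one channel: samples reshaped as (window x segments) matrix.
channel_features <- function(S, fs, cfg) {
  w <- nrow(S)
  n_seg <- ncol(S)
  mu <- colMeans(S)
  ss <- colSums(S^2)
  variance <- (ss - w * mu^2) / (w - 1)
  variance[variance < 0] <- 0
  line_length <- colSums(abs(S[-1, , drop = FALSE] - S[-w, , drop = FALSE]))
  rms <- sqrt(ss / w)

  # Hann-windowed periodogram (power spectral density up to Nyquist)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / w)
  Fm <- mvfft(S * hann)
  nb <- floor(w / 2)
  P <- (Mod(Fm[2:(nb + 1), , drop = FALSE])^2) / (sum(hann^2) * fs)
  fbin <- seq_len(nb) * fs / w

  lo <- DEVICE_PASSBAND_HZ[1]
  hi <- min(DEVICE_PASSBAND_HZ[2], fs / 2)
  inband <- fbin >= lo & fbin <= hi
  total <- colSums(P[inband, , drop = FALSE])
  bp <- vapply(cfg$band_edges_hz, function(e) {
    sel <- fbin >= e[1] & fbin < min(e[2], fs / 2)
    if (!any(sel)) return(rep(0, n_seg))
    colSums(P[sel, , drop = FALSE])
  }, numeric(n_seg))
  bp <- matrix(bp, nrow = n_seg,
    dimnames = list(NULL, names(cfg$band_edges_hz)))
  relbp <- bp / ifelse(total > 0, total, 1)
  relbp[total == 0, ] <- 0

  we <- haar_level_energies(S, cfg$wavelet_levels)

  # spectral entropy over the in-band normalized periodogram, in [0, 1]
  Pb <- P[inband, , drop = FALSE]
  pn <- sweep(Pb, 2, ifelse(total > 0, total, 1), "/")
  plogp <- pn * log(pn)
  plogp[!is.finite(plogp)] <- 0
  spec_ent <- -colSums(plogp) / log(nrow(Pb))
  spec_ent[total == 0] <- 0

  dec <- S[seq(1, w, by = cfg$sampen_decimation), , drop = FALSE]
  samp_ent <- sampen_cols(dec, cfg$entropy_embedding, cfg$entropy_tolerance)

  out <- cbind(variance, line_length, rms, bp, relbp, we, spec_ent, samp_ent)
  colnames(out) <- base_feature_names(cfg)
  out
}

#' Extract per-segment, per-channel features
#'
#' For every segment and each of the 10 montage channels: variance, line
#' length and RMS (time domain); absolute and relative band power in the
#' configured bands from a Hann-windowed periodogram (frequency domain);
#' Haar wavelet detail energy per level (time-frequency domain); spectral
#' entropy and sample entropy (complexity domain).  All values are finite;
#' degenerate flat segments yield zero entropies by convention.
#'
#' @param m A `remi_montage`.
#' @param grid Its [segment()] grid.
#' @param cfg A [feature_config()].
#' @return Numeric matrix `n_segments x (10 * n_base_features)` with columns
#'   named `<channel>.<feature>` (differential channels use `_`, e.g.
#'   `LF_RF.variance`).
#' @export
extract_segment_features <- function(m, grid, cfg = feature_config()) {
  stopifnot(inherits(m, "remi_montage"), inherits(grid, "segment_grid"))
  w <- as.integer(round(grid$window_s * m$sampling_rate))
  n_seg <- grid$n_segments
  blocks <- lapply(MONTAGE_CHANNELS, function(ch) {
    S <- matrix(m$channels[seq_len(w * n_seg), ch], nrow = w)
    fe <- channel_features(S, m$sampling_rate, cfg)
    colnames(fe) <- paste(gsub("-", "_", ch), colnames(fe), sep = ".")
    fe
  })
  out <- do.call(cbind, blocks)
  stopifnot(all(is.finite(out)))
  out
}

#' Append exponentially weighted feature history
#'
#' Seizures evolve over time, so each feature is augmented with a weighted
#' average of its past values: `h_t = alpha_h * h_(t-1) + (1 - alpha_h) *
#' f_t` with `h_1 = f_1`.  Doubles the per-channel feature count.
#'
#' @param features Feature matrix with rows in temporal order.
#' @param alpha_h History decay in (0, 1).
#' @return The input with `hist.`-prefixed history columns appended.
#' @export
add_history <- function(features, alpha_h = 0.8) {
  if (!is.numeric(alpha_h) || alpha_h <= 0 || alpha_h >= 1) {
    stop("config error: alpha_h must lie strictly inside (0, 1)")
  }
  h <- matrix(0, nrow(features), ncol(features))
  h[1, ] <- features[1, ]
  if (nrow(features) > 1) {
    for (t in 2:nrow(features)) {
      h[t, ] <- alpha_h * h[t - 1, ] + (1 - alpha_h) * features[t, ]
    }
  }
  colnames(h) <- paste0("hist.", colnames(features))
  cbind(features, h)
}

#' Append cross-channel summaries and sensor-pair correlations
#'
#' Adds, for every base feature, the across-channel mean, SD, max and min of
#' the 10 per-channel values, and, per segment, the six zero-lag Pearson
#' correlations of the broadband sensor-pair signals (LF-RF, LF-LE, LF-RE,
#' RF-LE, RF-RE, LE-RE).  A zero-variance channel in a segment contributes a
#' correlation of 0 by convention.
#'
#' @param features Matrix from [add_history()] (or
#'   [extract_segment_features()]).
#' @param m The `remi_montage` the features came from.
#' @param grid Its [segment()] grid.
#' @param cfg The [feature_config()] used.
#' @return The feature matrix with `xmean./xsd./xmax./xmin.` and
#'   `corr.` columns appended.
#' @export
add_cross_channel <- function(features, m, grid, cfg = feature_config()) {
  base <- base_feature_names(cfg)
  chans <- gsub("-", "_", MONTAGE_CHANNELS)
  stats_blocks <- lapply(base, function(f) {
    M <- features[, paste(chans, f, sep = "."), drop = FALSE]
    cbind(
      rowMeans(M),
      apply(M, 1, sd),
      apply(M, 1, max),
      apply(M, 1, min)
    )
  })
  xs <- do.call(cbind, stats_blocks)
  colnames(xs) <- as.vector(t(outer(base, c("xmean", "xsd", "xmax", "xmin"),
    function(f, s) paste(s, f, sep = ".")
  )))

  w <- as.integer(round(grid$window_s * m$sampling_rate))
  n_seg <- grid$n_segments
  seg_mat <- lapply(SENSOR_PLACEMENTS, function(ch) {
    S <- matrix(m$channels[seq_len(w * n_seg), ch], nrow = w)
    sweep(S, 2, colMeans(S))
  })
  names(seg_mat) <- SENSOR_PLACEMENTS
  cors <- vapply(seq_len(nrow(DIFF_PAIRS)), function(k) {
    A <- seg_mat[[DIFF_PAIRS[k, "a"]]]
    B <- seg_mat[[DIFF_PAIRS[k, "b"]]]
    num <- colSums(A * B)
    den <- sqrt(colSums(A^2) * colSums(B^2))
    r <- ifelse(den > 0, num / den, 0)
    pmax(-1, pmin(1, r))
  }, numeric(n_seg))
  cors <- matrix(cors, nrow = n_seg)
  colnames(cors) <- paste0("corr.", DIFF_PAIRS[, "a"], "_", DIFF_PAIRS[, "b"])
  cbind(features, xs, cors)
}

#' Compute the full labeled feature set for one subject
#'
#' Convenience wrapper running segmentation, labeling, per-channel feature
#' extraction, history augmentation and cross-channel augmentation.
#'
#' @param m A `remi_montage`.
#' @param truth Ground-truth [annotation_set()].
#' @param subject_id Subject identifier.
#' @param cfg A [feature_config()].
#' @return An object of class `labeled_features`: list with `x` (feature
#'   matrix), `labels`, `grid`, `truth`, `subject_id` and `record_hours`.
#' @export
compute_features <- function(m, truth, subject_id, cfg = feature_config()) {
  grid <- segment(m)
  labels <- label_segments(grid, truth, cfg$near_ictal_margin_s)
  x <- extract_segment_features(m, grid, cfg)
  x <- add_history(x, cfg$history_decay)
  x <- add_cross_channel(x, m, grid, cfg)
  structure(
    list(
      x = x, labels = labels, grid = grid, truth = truth,
      subject_id = subject_id, record_hours = m$duration / 3600
    ),
    class = "labeled_features"
  )
}

#' @export
print.labeled_features <- function(x, ...) {
  cat(sprintf(
    "<labeled_features> %s: %d segments x %d features (%d ictal, %d near-ictal)\n",
    x$subject_id, nrow(x$x), ncol(x$x),
    sum(x$labels == "ictal"), sum(x$labels == "near_ictal")
  ))
  invisible(x)
}
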