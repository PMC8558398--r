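#' Specification of a synthetic EEG cohort
#'
#' Describes the cohort emulated by the generator: number of subjects, how
#' many experience seizures, the per-subject seizure-count distribution
#' (clinical cohort: min 1, mean 2.4, median 2, max 6), stay length, focal
#' seizure duration and the ictal signal-to-background ratio.  Default stays
#' are scaled down (2--6 h) so desk-scale runs are tractable; the clinical
#' 0.5--5 day stays are available via `stay_hours = c(12, 120)`.
#'
#' @param n_subjects Number of subjects.
#' @param n_with_seizures Number of subjects with at least one seizure.
#' @param seizures_per_subject Probability weights over counts 1..6.
#' @param stay_hours Length-2 range of stay durations (hours).
#' @param seizure_duration_s Length-2 range of seizure durations, within
#'   the 10 s -- 15 min envelope of complete focal seizures.
#' @param ictal_snr Ratio of ictal waveform RMS (on the onset sensor) to the
#'   background RMS; detectability scales monotonically with it.
#' @param sampling_rate Sensor sampling rate in Hz.
#' @param seed Master cohort seed; all per-subject randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_with_seizures = 10,
                        seizures_per_subject = c(
                          "1" = 0.30, "2" = 0.35, "3" = 0.15,
                          "4" = 0.10, "5" = 0.05, "6" = 0.05
                        ),
                        stay_hours = c(2, 6),
                        seizure_duration_s = c(30, 180),
                        ictal_snr = 3,
                        sampling_rate = DEVICE_SAMPLING_RATE,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_with_seizures < 0 || n_with_seizures > n_subjects) {
    stop("n_with_seizures must be between 0 and n_subjects")
  }
  if (length(stay_hours) != 2 || any(stay_hours <= 0) || stay_hours[1] > stay_hours[2]) {
    stop("stay_hours must be an increasing positive range")
  }
  if (length(seizure_duration_s) != 2 ||
    seizure_duration_s[1] < 10 || seizure_duration_s[2] > 900 ||
    seizure_duration_s[1] > seizure_duration_s[2]) {
    stop("seizure_duration_s must be a range within [10, 900] seconds")
  }
  if (ictal_snr < 0) stop("ictal_snr must be non-negative")
  if (is.null(names(seizures_per_subject)) ||
    !all(names(seizures_per_subject) %in% as.character(1:6)) ||
    any(seizures_per_subject < 0) || sum(seizures_per_subject) <= 0) {
    stop("seizures_per_subject must be non-negative weights named over 1..6")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_with_seizures = as.integer(n_with_seizures),
      seizures_per_subject = seizures_per_subject / sum(seizures_per_subject),
      stay_hours = as.numeric(stay_hours),
      seizure_duration_s = as.numeric(seizure_duration_s),
      ictal_snr = ictal_snr,
      sampling_rate = sampling_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Background generator calibration: RMS of resting scalp EEG under the
# hairline sensors, and the posterior-alpha bump on the 1/f spectrum.
BACKGROUND_RMS_UV <- 12
ALPHA_PEAK_HZ <- 10
ALPHA_PEAK_GAIN <- 1.5
ALPHA_PEAK_WIDTH_HZ <- 1.5

# Round to the sensor's 10-bit amplitude grid over +/- full scale and clip.
quantize_adc <- function(x, full_scale = DEVICE_FULL_SCALE_UV,
                         bits = DEVICE_ADC_BITS) {
  step <- 2 * full_scale / (2^bits - 1)
  pmax(-full_scale, pmin(full_scale, round(x / step) * step))
}

#' Generate background EEG
#'
#' Seeded 1/f-weighted Gaussian noise with a band-limited alpha-rhythm bump,
#' band-limited to the amplifier passband (0.8--92 Hz) by frequency-domain
#' masking, scaled to a 12 uV RMS, then quantized to the sensor's 10-bit
#' amplitude grid over +/-175 uV and clipped to full scale.
#'
#' @param duration_s Positive duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param rms_uv Target RMS before quantization, in uV.
#' @return Numeric vector of `duration_s * sampling_rate` samples (uV).
#' @export
generate_background <- function(duration_s, sampling_rate = DEVICE_SAMPLING_RATE,
                                seed = 1L, rms_uv = BACKGROUND_RMS_UV) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  n <- as.integer(round(duration_s * sampling_rate))
  w <- with_seed(seed, rnorm(n))
  f <- c(0, seq_len(n - 1)) * sampling_rate / n
  f <- pmin(f, sampling_rate - f) # fold to physical frequency of each bin
  shape <- 1 / sqrt(pmax(f, DEVICE_PASSBAND_HZ[1]))
  shape <- shape * (1 + ALPHA_PEAK_GAIN *
    exp(-(f - ALPHA_PEAK_HZ)^2 / (2 * ALPHA_PEAK_WIDTH_HZ^2)))
  lo <- DEVICE_PASSBAND_HZ[1]
  hi <- min(DEVICE_PASSBAND_HZ[2], sampling_rate / 2)
  shape[f < lo | f > hi] <- 0
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  x <- x * rms_uv / sqrt(mean(x^2))
  quantize_adc(x)
}

# Volume-conduction surrogate: relative gain of a focal discharge at each
# sensor, by onset placement.  Forehead pair is closest (0.5), same-side
# forehead/ear 0.4, ear pair 0.3, diagonals 0.25.
MIXING_GAINS <- rbind(
  LF = c(LF = 1, RF = 0.50, LE = 0.40, RE = 0.25),
  RF = c(LF = 0.50, RF = 1, LE = 0.25, RE = 0.40),
  LE = c(LF = 0.40, RF = 0.25, LE = 1, RE = 0.30),
  RE = c(LF = 0.25, RF = 0.40, LE = 0.30, RE = 1)
)

# Cosine-tapered (Tukey) envelope: ramp up, plateau, ramp down.
tukey_window <- function(n, taper = 0.4) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a <- taper / 2
  up <- t < a
  dn <- t > 1 - a
  w[up] <- 0.5 * (1 + cos(pi * (t[up] / a - 1)))
  w[dn] <- 0.5 * (1 + cos(pi * ((t[dn] - 1 + a) / a)))
  w
}

#' Generate a focal ictal waveform for the four sensors
#'
#' Emulates a focal-onset electrographic seizure as an evolving oscillation:
#' a frequency glide from 8 to 3 Hz with a spiky harmonic, slow amplitude
#' modulation and a cosine ramp-up/ramp-down envelope.  The waveform appears
#' at full gain on the onset sensor and attenuated on the other three
#' (volume-conduction surrogate).  RMS on the onset sensor equals
#' `ictal_snr` times the 12 uV background reference, so waveform energy
#' scales monotonically (linearly in RMS) with `ictal_snr`.
#'
#' @param duration_s Seizure duration in seconds, within `[10, 900]`.
#' @param onset_sensor Placement of the seizure focus (`"LF"`, `"RF"`,
#'   `"LE"`, `"RE"`).
#' @param ictal_snr Non-negative ratio of onset-sensor ictal RMS to
#'   background RMS; 0 yields silence.
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate in Hz.
#' @param freq_glide_hz Start/end oscillation frequency of the chirp.
#' @return Named list of four numeric vectors (uV), one per placement, to be
#'   added to the background.
#' @export
generate_seizure_waveform <- function(duration_s, onset_sensor, ictal_snr,
                                      seed = 1L,
                                      sampling_rate = DEVICE_SAMPLING_RATE,
                                      freq_glide_hz = c(8, 3)) {
  if (!is.numeric(duration_s) || duration_s < 10 || duration_s > 900) {
    stop("duration_s must lie in [10, 900] seconds")
  }
  if (!onset_sensor %in% SENSOR_PLACEMENTS) {
    stop("onset_sensor must be one of ", paste(SENSOR_PLACEMENTS, collapse = ", "))
  }
  if (ictal_snr < 0) stop("ictal_snr must be non-negative")
  n <- as.integer(round(duration_s * sampling_rate))
  inst_f <- seq(freq_glide_hz[1], freq_glide_hz[2], length.out = n)
  phase <- 2 * pi * cumsum(inst_f) / sampling_rate
  core <- with_seed(seed, {
    phi2 <- runif(1, 0, 2 * pi)
    # slow multiplicative amplitude modulation (~0.3 Hz), band-limited noise
    am_n <- max(4L, as.integer(round(duration_s * 0.3)))
    am <- approx(seq(0, 1, length.out = am_n), rnorm(am_n, 1, 0.2),
      xout = seq(0, 1, length.out = n)
    )$y
    (sin(phase) + 0.35 * sin(2 * phase + phi2)) * pmax(0.3, am)
  })
  wave <- core * tukey_window(n)
  rms <- sqrt(mean(wave^2))
  wave <- if (rms > 0) wave / rms * (ictal_snr * BACKGROUND_RMS_UV) else wave * 0
  gains <- MIXING_GAINS[onset_sensor, ]
  out <- lapply(gains, function(g) g * wave)
  names(out) <- names(gains)
  out[SENSOR_PLACEMENTS]
}

#' @importFrom stats approx
NULL

# Draw k seizure onset times in a stay of `duration_s` seconds such that
# onsets are > sep_s apart and every event keeps >= edge_s from both record
# edges (including its own duration at the tail).  Uses the spacing
# transform (sorted uniforms plus mandatory gaps), which is uniform under
# the separation constraint and never fails when placement is feasible.
draw_seizure_times <- function(duration_s, k, durations_s,
                               sep_s = 1800, edge_s = 960) {
  if (k == 0) return(numeric(0))
  lo <- edge_s
  hi <- duration_s - edge_s - max(durations_s)
  slack <- (hi - lo) - (k - 1) * sep_s
  if (hi < lo || slack < 0) {
    stop(
      "placement error: stay of ", round(duration_s), " s too short for ",
      k, " seizure(s) with >", sep_s, " s separation"
    )
  }
  lo + sort(runif(k, 0, slack)) + (seq_len(k) - 1) * sep_s
}

max_feasible_seizures <- function(duration_s, max_dur_s,
                                  sep_s = 1800, edge_s = 960) {
  span <- duration_s - 2 * edge_s - max_dur_s
  if (span < 0) return(0L)
  as.integer(floor(span / sep_s) + 1)
}

#' Generate one synthetic subject
#'
#' Draws a stay length, generates independent background EEG on the four
#' sensors, and (for seizure subjects) injects focal ictal waveforms with a
#' per-subject onset focus, onsets separated by more than 30 min and at
#' least 16 min from the record edges.  The final trace is re-quantized to
#' the 10-bit grid and clipped to full scale.  Ground truth holds the exact
#' injected start/stop times.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier string.
#' @param with_seizures Logical; generate ictal events?
#' @param seed Integer seed for this subject.
#' @param n_seizures Optional explicit seizure count.  When supplied and the
#'   drawn stay cannot host it, a placement error is raised; when drawn from
#'   the spec distribution the count is truncated to the feasible maximum for
#'   the stay (documented generator behavior, so cohorts of short stays
#'   remain generable).
#' @return An object of class `subject_record`: list with `subject_id`,
#'   `sensors` (named list of four [sensor_recording()]), `ground_truth`
#'   ([annotation_set()]), `has_seizures` and `stay_hours`.
#' @export
generate_subject <- function(spec, subject_id, with_seizures, seed,
                             n_seizures = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  fs <- spec$sampling_rate
  stay_s <- with_seed(
    derive_seed(seed, "stay"),
    round(runif(1, spec$stay_hours[1], spec$stay_hours[2]) * 3600)
  )
  onsets <- numeric(0)
  durs <- numeric(0)
  onset_sensor <- NA_character_
  if (with_seizures) {
    counts <- as.integer(names(spec$seizures_per_subject))
    k_max <- max_feasible_seizures(stay_s, spec$seizure_duration_s[2])
    if (is.null(n_seizures)) {
      if (k_max < 1) {
        stop("placement error: stay of ", stay_s, " s too short for any seizure")
      }
      ok <- counts <= k_max
      if (!any(ok)) {
        k <- k_max # every configured count infeasible: truncate to the stay
      } else {
        cand <- counts[ok]
        wts <- spec$seizures_per_subject[ok]
        k <- with_seed(
          derive_seed(seed, "count"),
          if (length(cand) == 1) cand else sample(cand, 1, prob = wts)
        )
      }
    } else {
      k <- as.integer(n_seizures)
    }
    drawn <- with_seed(derive_seed(seed, "times"), {
      d <- runif(k, spec$seizure_duration_s[1], spec$seizure_duration_s[2])
      list(durs = d, onsets = draw_seizure_times(stay_s, k, d))
    })
    onsets <- drawn$onsets
    durs <- drawn$durs
    onset_sensor <- with_seed(
      derive_seed(seed, "focus"),
      sample(SENSOR_PLACEMENTS, 1)
    )
  }
  sensors <- list()
  for (lab in SENSOR_PLACEMENTS) {
    x <- generate_background(stay_s, fs, seed = derive_seed(seed, paste0("bg.", lab)))
    sensors[[lab]] <- x
  }
  for (i in seq_along(onsets)) {
    wf <- generate_seizure_waveform(durs[i], onset_sensor, spec$ictal_snr,
      seed = derive_seed(seed, paste0("sz.", i)), sampling_rate = fs
    )
    i0 <- as.integer(round(onsets[i] * fs))
    idx <- (i0 + 1):(i0 + length(wf[[1]]))
    for (lab in SENSOR_PLACEMENTS) {
      sensors[[lab]][idx] <- sensors[[lab]][idx] + wf[[lab]]
    }
  }
  sensors <- lapply(SENSOR_PLACEMENTS, function(lab) {
    sensor_recording(quantize_adc(sensors[[lab]]), lab,
      sampling_rate = fs, start_time = 0
    )
  })
  names(sensors) <- SENSOR_PLACEMENTS
  truth <- annotation_set(onsets, onsets + durs,
    label = "seizure",
    source = "ground_truth", subject_id = subject_id
  )
  structure(
    list(
      subject_id = subject_id, sensors = sensors, ground_truth = truth,
      has_seizures = with_seizures, stay_hours = stay_s / 3600,
      onset_sensor = onset_sensor
    ),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "<subject_record> %s: %.2f h stay, %d seizure(s)%s\n",
    x$subject_id, x$stay_hours, nrow(x$ground_truth),
    if (x$has_seizures) paste0(" (focus ", x$onset_sensor, ")") else ""
  ))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' The first `n_with_seizures` subjects carry seizures, the remainder are
#' seizure-free; per-subject seeds are derived deterministically from the
#' spec seed, so a fixed spec regenerates the cohort bit-identically.
#'
#' @param spec A [cohort_spec()].
#' @return List of [generate_subject()] records, named by subject id.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  out <- lapply(seq_along(ids), function(i) {
    generate_subject(
      spec, ids[i],
      with_seizures = i <= spec$n_with_seizures,
      seed = derive_seed(spec$seed, paste0("subject.", ids[i]))
    )
  })
  names(out) <- ids
  out
}

#' Simulate a reviewer's seizure marks
#'
#' Fixture generator for the inter-rater machinery: each ground-truth event
#' is reproduced independently with probability `hit_rate` with boundaries
#' jittered by up to `boundary_jitter_s`; spurious marks arrive as a Poisson
#' process with rate `fp_per_hour`, placed clear of true events.
#'
#' @param truth Ground-truth [annotation_set()].
#' @param hit_rate Probability in `[0, 1]` of reproducing each true event.
#' @param fp_per_hour Expected spurious marks per hour.
#' @param boundary_jitter_s Uniform boundary jitter half-width (s).
#' @param record_hours Record length in hours.
#' @param seed Integer seed.
#' @param source Source tag for the returned set.
#' @return An [annotation_set()] of reviewer marks.
#' @export
simulate_reviewer_marks <- function(truth, hit_rate, fp_per_hour,
                                    boundary_jitter_s, record_hours, seed,
                                    source = "reviewer_1") {
  if (hit_rate < 0 || hit_rate > 1) stop("hit_rate must lie in [0, 1]")
  if (fp_per_hour < 0 || boundary_jitter_s < 0 || record_hours <= 0) {
    stop("rates must be non-negative and record_hours positive")
  }
  record_s <- record_hours * 3600
  with_seed(seed, {
    start <- stop <- numeric(0)
    if (nrow(truth)) {
      hit <- runif(nrow(truth)) < hit_rate
      if (any(hit)) {
        j1 <- runif(sum(hit), -boundary_jitter_s, boundary_jitter_s)
        j2 <- runif(sum(hit), -boundary_jitter_s, boundary_jitter_s)
        s <- pmax(0, truth$start_s[hit] + j1)
        e <- pmin(record_s, truth$stop_s[hit] + j2)
        e <- pmax(e, s + 1) # keep marks at least 1 s long
        start <- s
        stop <- e
      }
    }
    n_fp <- rpois(1, fp_per_hour * record_hours)
    placed <- 0
    tries <- 0
    while (placed < n_fp && tries < 50 * n_fp + 100) {
      tries <- tries + 1
      dur <- runif(1, 10, 60)
      s <- runif(1, 0, max(record_s - dur, 1))
      clear <- !nrow(truth) ||
        all(interval_overlap(s - 60, s + dur + 60, truth$start_s, truth$stop_s) == 0)
      overlap_own <- length(start) &&
        any(interval_overlap(s, s + dur, start, stop) > 0)
      if (clear && !overlap_own) {
        start <- c(start, s)
        stop <- c(stop, s + dur)
        placed <- placed + 1
      }
    }
    annotation_set(start, stop,
      label = "mark", source = source,
      subject_id = attr(truth, "subject_id")
    )
  })
}
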