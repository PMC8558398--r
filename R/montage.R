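#' Build the 10-channel montage from four sensor recordings
#'
#' Combines the four single-channel sensors (LF, RF, LE, RE) into the
#' 10-channel reduced-montage used for review and detection: the four
#' referential sensor channels followed by the six sensor-to-sensor
#' differential channels LF-RF, LF-LE, LF-RE, RF-LE, RF-RE, LE-RE (fixed
#' lexicographic pair order).  Recordings are aligned by their start times
#' and trimmed to the common temporal overlap.
#'
#' @param recs List of exactly four [sensor_recording()] objects, one per
#'   placement, in any order.
#' @return An object of class `remi_montage` with elements `channels`
#'   (numeric matrix, one column per channel, in the fixed order),
#'   `sampling_rate`, `start_time` and `duration`.
#' @export
build_remi_montage <- function(recs) {
  if (!is.list(recs) || length(recs) != 4 ||
    !all(vapply(recs, inherits, logical(1), "sensor_recording"))) {
    stop("montage error: recs must be a list of exactly four sensor_recording objects")
  }
  labels <- vapply(recs, `[[`, character(1), "sensor_label")
  if (!setequal(labels, SENSOR_PLACEMENTS) || anyDuplicated(labels)) {
    stop(
      "montage error: need each placement exactly once; got ",
      paste(labels, collapse = ", ")
    )
  }
  names(recs) <- labels
  recs <- recs[SENSOR_PLACEMENTS]
  fs <- vapply(recs, `[[`, numeric(1), "sampling_rate")
  if (length(unique(fs)) != 1) {
    stop("montage error: sampling rates differ (", paste(fs, collapse = ", "), ")")
  }
  fs <- unname(fs[1])
  starts <- vapply(recs, `[[`, numeric(1), "start_time")
  ends <- starts + vapply(recs, duration, numeric(1))
  t0 <- max(starts)
  t1 <- min(ends)
  n <- floor((t1 - t0) * fs + 1e-9)
  if (n < 1) stop("overlap error: recordings share no temporal overlap")
  ref <- vapply(seq_along(recs), function(i) {
    off <- as.integer(round((t0 - starts[i]) * fs))
    recs[[i]]$samples[(off + 1):(off + n)]
  }, numeric(n))
  colnames(ref) <- SENSOR_PLACEMENTS
  diffs <- ref[, DIFF_PAIRS[, "a"], drop = FALSE] - ref[, DIFF_PAIRS[, "b"], drop = FALSE]
  channels <- cbind(ref, diffs)
  colnames(channels) <- MONTAGE_CHANNELS
  structure(
    list(
      channels = channels, sampling_rate = fs,
      start_time = t0, duration = n / fs
    ),
    class = "remi_montage"
  )
}

#' @export
duration.remi_montage <- function(x) x$duration

#' @export
print.remi_montage <- function(x, ...) {
  cat(sprintf(
    "<remi_montage> 10 channels, %.1f s @ %g Hz, start %.1f s\n",
    x$duration, x$sampling_rate, x$start_time
  ))
  invisible(x)
}
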