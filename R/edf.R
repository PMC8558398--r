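#' Single-sensor EEG recording
#'
#' Container for one wearable sensor's single-channel EEG trace.  The device
#' records at 512 Hz with a 10-bit ADC, a full-scale amplitude of +/-175 uV
#' and an amplifier passband of 0.8--92 Hz; those are the defaults here.
#'
#' @param samples Numeric vector of EEG samples in microvolts.
#' @param sensor_label Placement label, one of `"LF"`, `"RF"`, `"LE"`, `"RE"`
#'   (left/right forehead, left/right behind-ear).
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Recording start in seconds since the cohort epoch.
#' @param full_scale Full-scale amplitude in uV; samples must not exceed it.
#' @param passband Amplifier passband in Hz, length-2 numeric.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(samples, sensor_label,
                             sampling_rate = DEVICE_SAMPLING_RATE,
                             start_time = 0,
                             full_scale = DEVICE_FULL_SCALE_UV,
                             passband = DEVICE_PASSBAND_HZ) {
  if (!is.character(sensor_label) || length(sensor_label) != 1 ||
    !sensor_label %in% SENSOR_PLACEMENTS) {
    stop("sensor_label must be one of ", paste(SENSOR_PLACEMENTS, collapse = ", "))
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("samples must not contain NA")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(samples) && max(abs(samples)) > full_scale + 1e-9) {
    stop(
      "samples exceed the +/-", full_scale, " uV full scale (max |x| = ",
      signif(max(abs(samples)), 5), ")"
    )
  }
  structure(
    list(
      samples = samples,
      sensor_label = sensor_label,
      sampling_rate = sampling_rate,
      start_time = start_time,
      full_scale = full_scale,
      passband = as.numeric(passband)
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %s: %.1f s @ %g Hz, start %.1f s, +/-%g uV\n",
    x$sensor_label, duration.sensor_recording(x), x$sampling_rate,
    x$start_time, x$full_scale
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param x A `sensor_recording` or `remi_montage`.
#' @return Duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.sensor_recording <- function(x) length(x$samples) / x$sampling_rate

EDF_EPOCH <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

fixed_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# Format a number into an 8-char ASCII EDF header field.
edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  fixed_field(s, width)
}

#' Write a sensor recording to an EDF file
#'
#' Writes one signal in the classic EDF container (16-bit samples, physical
#' range +/- the recording's full scale).  The placement label is embedded in
#' the signal label (`"EEG LF"` etc.) and the start time is encoded in the
#' header date/time relative to the cohort epoch (2000-01-01 UTC), so a
#' round trip through [read_sensor_edf()] recovers timing to the second.
#'
#' @param rec A [sensor_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_edf <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  n <- length(rec$samples)
  if (n == 0) stop("cannot write an empty recording")
  if (max(abs(rec$samples)) > rec$full_scale + 1e-9) {
    stop("samples exceed the +/-", rec$full_scale, " uV full scale")
  }
  fs <- rec$sampling_rate
  if (n %% fs == 0 && abs(fs - round(fs)) < 1e-9) {
    n_rec <- n %/% fs
    spr <- as.integer(round(fs))
    rec_dur <- "1"
  } else {
    n_rec <- 1L
    spr <- n
    rec_dur <- formatC(n / fs, format = "g", digits = 7)
  }
  start <- EDF_EPOCH + round(rec$start_time)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fixed_field("0", 8),
    fixed_field("X", 80),
    fixed_field(sprintf("Startdate 01-JAN-2000 X X %s", rec$sensor_label), 80),
    fixed_field(format(start, "%d.%m.%y"), 8),
    fixed_field(format(start, "%H.%M.%S"), 8),
    fixed_field(256 + 256, 8),
    fixed_field("", 44),
    fixed_field(n_rec, 8),
    fixed_field(rec_dur, 8),
    fixed_field(1, 4),
    # per-signal fields
    fixed_field(paste("EEG", rec$sensor_label), 16),
    fixed_field("AgAgCl electrode", 80),
    fixed_field("uV", 8),
    edf_num(-rec$full_scale),
    edf_num(rec$full_scale),
    edf_num(-32767),
    edf_num(32767),
    fixed_field(
      sprintf("HP:%gHz LP:%gHz", rec$passband[1], rec$passband[2]), 80
    ),
    fixed_field(spr, 8),
    fixed_field("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  dig <- as.integer(round(rec$samples / rec$full_scale * 32767))
  dig <- pmax(-32767L, pmin(32767L, dig))
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < w) {
      stop("unreadable EDF header: file truncated")
    }
    trimws(raw)
  }
  version <- rd(8)
  if (version != "0") stop("unreadable EDF header: bad version field '", version, "'")
  patient <- rd(80)
  recording <- rd(80)
  startdate <- rd(8)
  starttime <- rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  reserved <- rd(44)
  n_records <- suppressWarnings(as.integer(rd(8)))
  record_dur <- suppressWarnings(as.numeric(rd(8)))
  n_signals <- suppressWarnings(as.integer(rd(4)))
  if (is.na(n_signals) || is.na(n_records) || is.na(record_dur)) {
    stop("unreadable EDF header: malformed numeric fields")
  }
  if (n_signals < 1) stop("EDF file contains zero signals")
  per <- function(w) vapply(seq_len(n_signals), function(i) rd(w), character(1))
  sig <- list(
    label = per(16), transducer = per(80), dim = per(8),
    phys_min = as.numeric(per(8)), phys_max = as.numeric(per(8)),
    dig_min = as.numeric(per(8)), dig_max = as.numeric(per(8)),
    prefilter = per(80), spr = as.integer(per(8))
  )
  per(32) # per-signal reserved
  list(
    recording = recording, startdate = startdate, starttime = starttime,
    header_bytes = header_bytes, reserved = reserved,
    n_records = n_records, record_dur = record_dur,
    n_signals = n_signals, sig = sig
  )
}

#' Read a sensor recording from an EDF/EDF+ file
#'
#' Reads the first data signal.  The placement label is parsed from the EDF
#' signal label, falling back to the file name; the sampling rate is taken
#' from the header (samples per record / record duration).
#'
#' @param path Path to an EDF or EDF+ file whose first signal is EEG in uV.
#' @return A [sensor_recording()].
#' @export
read_sensor_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  dim1 <- h$sig$dim[1]
  if (!dim1 %in% c("uV", "µV")) {
    stop("first signal has unit '", dim1, "'; expected uV")
  }
  spr <- h$sig$spr
  dat <- readBin(con, "integer",
    n = h$n_records * sum(spr), size = 2,
    endian = "little", signed = TRUE
  )
  if (length(dat) < h$n_records * sum(spr)) stop("unreadable EDF: data truncated")
  # slice out signal 1 from the interleaved records
  if (h$n_signals == 1) {
    dig <- dat
  } else {
    rec_len <- sum(spr)
    offs <- 0
    keep <- logical(rec_len)
    keep[seq_len(spr[1])] <- TRUE
    dig <- dat[rep(keep, h$n_records)]
  }
  s1 <- h$sig
  gain <- (s1$phys_max[1] - s1$phys_min[1]) / (s1$dig_max[1] - s1$dig_min[1])
  phys <- (dig - s1$dig_min[1]) * gain + s1$phys_min[1]
  fs <- spr[1] / h$record_dur
  label <- h$sig$label[1]
  m <- regmatches(label, regexpr("\\b(LF|RF|LE|RE)\\b", label))
  if (!length(m)) {
    m <- regmatches(basename(path), regexpr("LF|RF|LE|RE", basename(path)))
  }
  if (!length(m)) stop("cannot determine sensor placement from label '", label, "'")
  start <- tryCatch(
    as.numeric(difftime(
      as.POSIXct(paste(h$startdate, h$starttime), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
      EDF_EPOCH,
      units = "secs"
    )),
    error = function(e) 0
  )
  if (is.na(start)) start <- 0
  full_scale <- max(abs(c(s1$phys_min[1], s1$phys_max[1])))
  sensor_recording(phys, m[1],
    sampling_rate = round(fs, 6), start_time = start,
    full_scale = full_scale
  )
}
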