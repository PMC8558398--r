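#' Match detections to ground truth with the any-overlap rule
#'
#' A truth event is a true positive iff at least one detection overlaps it
#' by any positive amount; a detection is a false positive iff it overlaps
#' no truth event.  One detection may validate multiple truth events and
#' vice versa (standard any-overlap bookkeeping); a matched detection is
#' never also a false positive.
#'
#' @param truth Ground-truth [annotation_set()] (or data frame with
#'   `start_s`, `stop_s`).
#' @param detected Detections on the same time base.
#' @return An object of class `match_result`: list with `n_tp`, `n_fn`,
#'   `n_fp`, `n_detections`, index vectors `tp_idx`/`fn_idx`/`fp_idx` and
#'   `overlap_pct` (per-TP percent of the truth event covered by the union
#'   of its matched detections).
#' @export
match_events <- function(truth, detected) {
  nt <- nrow(truth)
  nd <- nrow(detected)
  O <- matrix(0, nt, nd)
  if (nt && nd) {
    for (i in seq_len(nt)) {
      O[i, ] <- interval_overlap(
        truth$start_s[i], truth$stop_s[i],
        detected$start_s, detected$stop_s
      )
    }
  }
  tp_idx <- which(rowSums(O > 0) > 0)
  fn_idx <- setdiff(seq_len(nt), tp_idx)
  fp_idx <- which(colSums(matrix(O > 0, nt, nd)) == 0)
  overlap_pct <- vapply(tp_idx, function(i) {
    percent_overlap(truth[i, , drop = FALSE], detected[O[i, ] > 0, , drop = FALSE])
  }, numeric(1))
  structure(
    list(
      n_tp = length(tp_idx), n_fn = length(fn_idx), n_fp = length(fp_idx),
      n_detections = nd, tp_idx = tp_idx, fn_idx = fn_idx, fp_idx = fp_idx,
      overlap_pct = overlap_pct
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FN %d, FP %d (of %d detections)\n",
    x$n_tp, x$n_fn, x$n_fp, x$n_detections
  ))
  invisible(x)
}

#' Percent of a truth event covered by its matched detections
#'
#' The amount of time of the known seizure event that the detection
#' event(s) encompassed: `|union(detections) intersect truth| / |truth|`,
#' as a percentage.
#'
#' @param truth_event One-row data frame (`start_s`, `stop_s`).
#' @param detections Data frame of detections overlapping the event.
#' @return Percentage in `(0, 100]`.
#' @export
percent_overlap <- function(truth_event, detections) {
  ov_s <- pmax(truth_event$start_s, detections$start_s)
  ov_e <- pmin(truth_event$stop_s, detections$stop_s)
  keep <- ov_e > ov_s
  if (!any(keep)) {
    stop("percent_overlap is undefined when no detection overlaps the event")
  }
  100 * interval_union_length(ov_s[keep], ov_e[keep]) /
    (truth_event$stop_s - truth_event$start_s)
}

#' Per-subject detection metrics
#'
#' Sensitivity `TP/(TP+FN)` and precision `TP/(TP+FP)` in percent, and the
#' false detection rate in false positives per hour of recording.
#' Conventions for degenerate subjects: sensitivity is `NA` (excluded from
#' cohort means) when the subject has no truth events; precision is 100 when
#' there are neither detections nor truth events, `NA` when there are truth
#' events but no detections, and computable (0) when detections exist for a
#' truth-free subject.
#'
#' @param match A [match_events()] result.
#' @param record_hours Recording duration in hours (> 0).
#' @return One-row data frame: `sensitivity`, `precision`, `fdr`,
#'   `record_hours`.
#' @export
subject_metrics <- function(match, record_hours) {
  if (!is.numeric(record_hours) || record_hours <= 0) {
    stop("record_hours must be positive")
  }
  n_truth <- match$n_tp + match$n_fn
  sens <- if (n_truth > 0) 100 * match$n_tp / n_truth else NA_real_
  prec <- if (match$n_tp + match$n_fp > 0) {
    100 * match$n_tp / (match$n_tp + match$n_fp)
  } else if (n_truth == 0) {
    100
  } else {
    NA_real_
  }
  data.frame(
    sensitivity = sens, precision = prec,
    fdr = match$n_fp / record_hours, record_hours = record_hours
  )
}

#' Cohort summary: mean, SD and range per metric
#'
#' Unweighted across-subject summaries in the `% +/- SD [range]` style;
#' subjects with undefined (NA) values are excluded per metric.
#'
#' @param metrics Data frame of per-subject [subject_metrics()] rows.
#' @return Data frame with one row per metric: `mean`, `sd`, `min`, `max`,
#'   `n`.
#' @export
cohort_summary <- function(metrics) {
  if (!nrow(metrics)) stop("cohort_summary requires at least one subject")
  cols <- c("sensitivity", "precision", "fdr")
  out <- do.call(rbind, lapply(cols, function(cn) {
    v <- metrics[[cn]]
    v <- v[!is.na(v)]
    data.frame(
      metric = cn,
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else 0,
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_,
      n = length(v)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Patient-level rule-in sensitivity and specificity
#'
#' Rule-in sensitivity is the fraction of seizure subjects for whom at least
#' one true-positive event was detected; rule-in specificity is the fraction
#' of seizure-free subjects with no detections at all.
#'
#' @param matches List of [match_events()] results, one per subject.
#' @param has_seizures Logical vector aligned with `matches`.
#' @return List with `sensitivity` and `specificity` (percent; `NA` when a
#'   group is empty).
#' @export
rule_in_metrics <- function(matches, has_seizures) {
  stopifnot(length(matches) == length(has_seizures))
  tp_any <- vapply(matches, function(m) m$n_tp > 0, logical(1))
  no_det <- vapply(matches, function(m) m$n_detections == 0, logical(1))
  sens <- if (any(has_seizures)) 100 * mean(tp_any[has_seizures]) else NA_real_
  spec <- if (any(!has_seizures)) 100 * mean(no_det[!has_seizures]) else NA_real_
  list(sensitivity = sens, specificity = spec)
}

#' Majority (2-of-3) consensus of reviewer marks
#'
#' Each reviewer's events are rasterized at the given resolution; time
#' points marked by at least two of the three reviewers are kept, contiguous
#' kept points become consensus events, and events shorter than 2 s are
#' discarded.
#'
#' @param marks List of exactly three [annotation_set()]s.
#' @param resolution_s Raster resolution in seconds (1 by default).
#' @param min_duration_s Minimum consensus event duration (2 s).
#' @return A consensus [annotation_set()].
#' @export
consensus <- function(marks, resolution_s = 1, min_duration_s = 2) {
  if (!is.list(marks) || length(marks) != 3) {
    stop("consensus requires exactly 3 mark sets")
  }
  t_max <- max(0, vapply(marks, function(a) if (nrow(a)) max(a$stop_s) else 0, numeric(1)))
  n_bins <- ceiling(t_max / resolution_s)
  sid <- attr(marks[[1]], "subject_id")
  if (n_bins == 0) {
    return(annotation_set(source = "consensus", subject_id = sid))
  }
  votes <- integer(n_bins)
  bin_s <- (seq_len(n_bins) - 1) * resolution_s
  for (a in marks) {
    hit <- logical(n_bins)
    for (i in seq_len(nrow(a))) {
      hit <- hit | (bin_s < a$stop_s[i] & bin_s + resolution_s > a$start_s[i])
    }
    votes <- votes + hit
  }
  keep <- votes >= 2
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  ev_start <- bin_s[starts[sel]]
  ev_stop <- bin_s[ends[sel]] + resolution_s
  dur_ok <- (ev_stop - ev_start) >= min_duration_s
  annotation_set(ev_start[dur_ok], ev_stop[dur_ok],
    label = "consensus",
    source = "consensus", subject_id = sid
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` from the 2x2
#' agreement table of two binary rating vectors.  Degenerate unanimity
#' (`p_o = p_e = 1`) returns 1 by convention.
#'
#' @param a,b Binary (0/1) rating vectors of equal length (>= 1).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b) || !length(a)) stop("a and b must be equal-length, non-empty")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("ratings must be binary 0/1")
  }
  n <- length(a)
  po <- mean(a == b)
  pa1 <- mean(a == 1)
  pb1 <- mean(b == 1)
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (abs(1 - pe) < 1e-12) {
    return(if (po >= 1 - 1e-12) 1 else (po - pe) / .Machine$double.eps)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for a fixed group of raters
#'
#' Standard Fleiss formula over the two binary categories of an items x
#' raters table with an equal number of raters per item.  A degenerate table
#' where every rating falls in one category returns 1 by convention.
#'
#' @param table Binary matrix, rows = items (known seizures), columns =
#'   raters (>= 2).
#' @return Kappa.
#' @export
fleiss_kappa <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("ragged rater table: NA cells")
  if (ncol(table) < 2) stop("fleiss_kappa requires >= 2 raters")
  if (!all(table %in% c(0, 1))) stop("ratings must be binary 0/1")
  n <- ncol(table) # raters per item
  n1 <- rowSums(table)
  n0 <- n - n1
  P_i <- (n1^2 + n0^2 - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  p1 <- sum(n1) / (n * nrow(table))
  P_e <- p1^2 + (1 - p1)^2
  if (abs(1 - P_e) < 1e-12) {
    return(1)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Build the known-seizure x rater detection table
#'
#' One row per known seizure event (across subjects); a cell is 1 iff that
#' rater has at least one mark overlapping the seizure (any-overlap rule).
#'
#' @param truths List of ground-truth [annotation_set()]s, one per subject.
#' @param raters List of raters; each rater is a list of [annotation_set()]s
#'   aligned with `truths`.
#' @return Binary matrix with one column per rater.
#' @export
build_rater_table <- function(truths, raters) {
  n_events <- sum(vapply(truths, nrow, integer(1)))
  out <- matrix(0L, n_events, length(raters))
  colnames(out) <- names(raters)
  row <- 0
  for (s in seq_along(truths)) {
    tr <- truths[[s]]
    for (i in seq_len(nrow(tr))) {
      row <- row + 1
      for (r in seq_along(raters)) {
        mk <- raters[[r]][[s]]
        if (nrow(mk) && any(interval_overlap(
          tr$start_s[i], tr$stop_s[i],
          mk$start_s, mk$stop_s
        ) > 0)) {
          out[row, r] <- 1L
        }
      }
    }
  }
  out
}
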