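#' Timed seizure annotations
#'
#' A set of timed events (seizures, detections or reviewer marks) for one
#' subject from one source.  Events are half-open intervals `[start_s,
#' stop_s)` in seconds since the cohort epoch.  On construction events are
#' validated (`stop_s > start_s`), sorted by start time and overlapping
#' events are merged, so a valid set is always sorted and non-overlapping.
#'
#' @param start_s,stop_s Numeric vectors of event start/stop times (s).
#' @param label Optional event labels (recycled).
#' @param source One of `"ground_truth"`, `"algorithm"`, `"reviewer_1"`,
#'   `"reviewer_2"`, `"reviewer_3"`, `"consensus"`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `annotation_set`: a data frame with columns
#'   `start_s`, `stop_s`, `label` and attributes `source` and `subject_id`.
#' @export
annotation_set <- function(start_s = numeric(), stop_s = numeric(),
                           label = "seizure", source = "ground_truth",
                           subject_id = NA_character_) {
  sources <- c(
    "ground_truth", "algorithm", "reviewer_1", "reviewer_2",
    "reviewer_3", "consensus"
  )
  if (!source %in% sources) {
    stop("source must be one of ", paste(sources, collapse = ", "))
  }
  start_s <- as.numeric(start_s)
  stop_s <- as.numeric(stop_s)
  if (length(start_s) != length(stop_s)) stop("start_s and stop_s lengths differ")
  bad <- which(!(stop_s > start_s))
  if (length(bad)) {
    stop("event ", bad[1], " has stop_s <= start_s (", stop_s[bad[1]],
      " <= ", start_s[bad[1]], ")")
  }
  label <- rep_len(as.character(label), length(start_s))
  o <- order(start_s, stop_s)
  start_s <- start_s[o]
  stop_s <- stop_s[o]
  label <- label[o]
  # merge overlapping events within the set
  if (length(start_s) > 1) {
    ks <- numeric(0)
    ke <- numeric(0)
    kl <- character(0)
    cs <- start_s[1]
    ce <- stop_s[1]
    cl <- label[1]
    for (i in seq_along(start_s)[-1]) {
      if (start_s[i] < ce) {
        ce <- max(ce, stop_s[i])
        if (!identical(label[i], cl)) cl <- paste(unique(c(cl, label[i])), collapse = "+")
      } else {
        ks <- c(ks, cs); ke <- c(ke, ce); kl <- c(kl, cl)
        cs <- start_s[i]; ce <- stop_s[i]; cl <- label[i]
      }
    }
    start_s <- c(ks, cs); stop_s <- c(ke, ce); label <- c(kl, cl)
  }
  structure(
    data.frame(start_s = start_s, stop_s = stop_s, label = label,
               stringsAsFactors = FALSE),
    source = source, subject_id = subject_id,
    class = c("annotation_set", "data.frame")
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> source=%s subject=%s, %d event(s)\n",
    attr(x, "source"), attr(x, "subject_id"), nrow(x)
  ))
  if (nrow(x)) print(as.data.frame(x), ...)
  invisible(x)
}

n_events <- function(a) nrow(a)

#' Read annotations from CSV
#'
#' The CSV schema is `subject_id, source, start_s, stop_s, label` with a
#' header row; times are seconds as decimals.  Rows are validated (stop must
#' exceed start, naming the offending row) and returned per subject/source
#' as sorted [annotation_set()] objects.
#'
#' @param path CSV file path.
#' @return A nested list: `x[[subject_id]][[source]]` is an `annotation_set`.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "source", "start_s", "stop_s", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$stop_s > df$start_s))
  if (length(bad)) {
    stop("annotation row ", bad[1], " has stop_s <= start_s (",
      df$stop_s[bad[1]], " <= ", df$start_s[bad[1]], ")")
  }
  out <- list()
  if (nrow(df) == 0) return(out)
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, , drop = FALSE]
    out[[sid]] <- lapply(split(sub, sub$source), function(g) {
      annotation_set(g$start_s, g$stop_s, g$label,
        source = g$source[1], subject_id = sid
      )
    })
  }
  out
}

#' Write annotations to CSV
#'
#' @param x An [annotation_set()], or a list of them (optionally nested per
#'   subject as produced by [read_annotations()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  flatten <- function(x) {
    if (inherits(x, "annotation_set")) return(list(x))
    unlist(lapply(x, flatten), recursive = FALSE)
  }
  sets <- flatten(x)
  rows <- lapply(sets, function(a) {
    if (nrow(a) == 0) return(NULL)
    data.frame(
      subject_id = attr(a, "subject_id"), source = attr(a, "source"),
      start_s = a$start_s, stop_s = a$stop_s, label = a$label,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(
      subject_id = character(), source = character(),
      start_s = numeric(), stop_s = numeric(), label = character()
    )
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
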