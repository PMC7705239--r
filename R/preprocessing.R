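# Signal normalization, segmentation and task construction.

#' Z-score normalize a signal
#'
#' Centers and scales a signal to zero mean and unit standard deviation,
#' `s* = (s - mu) / theta`. The standard deviation is the population
#' estimator (divide by n). A constant signal (theta = 0) maps to the zero
#' vector rather than dividing by zero.
#'
#' @param s Numeric vector, non-empty and finite.
#' @return A list with `values` (the normalized vector) and `stats`, itself
#'   a list with `mu` and `theta`.
#' @examples
#' zscore_normalize(c(1, 2, 3))$stats$theta  # 0.8164966
#' @export
zscore_normalize <- function(s) {
  if (length(s) == 0L) stop("empty input: cannot normalize a zero-length signal")
  if (!is.numeric(s) || !all(is.finite(s))) stop("signal must be finite numeric")
  mu <- mean(s)
  theta <- sqrt(mean((s - mu)^2))
  values <- if (theta > 0) (s - mu) / theta else rep(0, length(s))
  list(values = values, stats = list(mu = mu, theta = theta))
}

#' Construct an EEG record object
#'
#' @param samples Numeric sample vector (arbitrary amplitude units).
#' @param set_id One of "A".."E".
#' @param record_index Non-negative integer record number within its set.
#' @param sampling_rate_hz Sampling rate; the Bonn recordings use 173.61 Hz.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, set_id, record_index,
                       sampling_rate_hz = 173.61) {
  if (length(samples) == 0L || !all(is.finite(samples)))
    stop("samples must be non-empty and finite")
  if (!is.character(set_id) || length(set_id) != 1L || !(set_id %in% SET_IDS))
    stop("set_id must be one of ", paste(SET_IDS, collapse = ", "))
  if (record_index < 0) stop("record_index must be >= 0")
  structure(
    list(samples = as.numeric(samples), set_id = set_id,
         record_index = as.integer(record_index),
         sampling_rate_hz = sampling_rate_hz),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> set %s #%d: %d samples @ %.2f Hz (%.1f s)\n",
              x$set_id, x$record_index, length(x$samples),
              x$sampling_rate_hz, length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Construct a segment table
#'
#' A segment table is the dataset unit of the pipeline: a matrix of
#' fixed-length segments, one integer label per segment (consecutive,
#' starting at 0), and per-segment provenance (set id, record index, chunk
#' index).
#'
#' @param segments Numeric matrix, one segment per row.
#' @param labels Integer label vector, one per row.
#' @param provenance Data frame with columns `set_id`, `record_index`,
#'   `chunk_index`, one row per segment.
#' @return An object of class `segment_table`.
#' @export
segment_table <- function(segments, labels, provenance) {
  segments <- as.matrix(segments)
  labels <- as.integer(labels)
  if (nrow(segments) != length(labels))
    stop("labels length must match number of segments")
  if (nrow(segments) != nrow(provenance))
    stop("provenance must have one row per segment")
  stopifnot(all(c("set_id", "record_index", "chunk_index") %in%
                  names(provenance)))
  dimnames(segments) <- NULL
  rownames(provenance) <- NULL
  structure(
    list(segments = segments, labels = labels, provenance = provenance,
         segment_length = ncol(segments)),
    class = "segment_table")
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %d segments x %d samples, %d class(es)\n",
              nrow(x$segments), x$segment_length,
              length(unique(x$labels))))
  tab <- table(x$labels)
  cat("  label counts:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of segments in a table
#' @param x A `segment_table`.
#' @return Integer count.
#' @export
n_segments <- function(x) nrow(x$segments)

#' Split one record into fixed-length chunks
#'
#' Divides a record into `n_chunks` contiguous, non-overlapping segments of
#' length `floor(length / n_chunks)`; trailing remainder samples are
#' discarded. A 4097-sample Bonn record with the default 23 chunks yields
#' 23 segments of 178 samples (3 samples dropped).
#'
#' The raw set identity is carried both in `provenance$set_id` and as the
#' table label (A=0 .. E=4) so downstream task construction can relabel.
#'
#' @param record An [eeg_record()].
#' @param n_chunks Number of chunks (default 23).
#' @return A [segment_table()] with `n_chunks` rows.
#' @export
segment_record <- function(record, n_chunks = 23L) {
  stopifnot(inherits(record, "eeg_record"))
  len <- length(record$samples)
  if (len < n_chunks)
    stop(sprintf("record of length %d is shorter than n_chunks = %d",
                 len, n_chunks))
  chunk_len <- len %/% n_chunks
  used <- chunk_len * n_chunks
  seg <- matrix(record$samples[seq_len(used)], nrow = n_chunks,
                ncol = chunk_len, byrow = TRUE)
  prov <- data.frame(set_id = record$set_id,
                     record_index = record$record_index,
                     chunk_index = 0:(n_chunks - 1L))
  segment_table(seg, rep(match(record$set_id, SET_IDS) - 1L, n_chunks), prov)
}

#' Segment a list of records into one table
#'
#' @param records List of [eeg_record()] objects.
#' @param n_chunks Chunks per record (default 23).
#' @return A single [segment_table()]; all records must share a length
#'   compatible with one common chunk length.
#' @export
segment_records <- function(records, n_chunks = 23L) {
  tabs <- lapply(records, segment_record, n_chunks = n_chunks)
  lens <- vapply(tabs, function(t) t$segment_length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("records produce differing segment lengths; cannot combine")
  segment_table(do.call(rbind, lapply(tabs, function(t) t$segments)),
                unlist(lapply(tabs, function(t) t$labels)),
                do.call(rbind, lapply(tabs, function(t) t$provenance)))
}

#' Parse a class-combination scheme string
#'
#' Task schemes merge the five canonical sets into classifier classes using
#' the hyphen grammar of the experimental tables: `"A-E"` is healthy (A)
#' versus seizure (E); `"AB-E"` merges A and B into one class against E;
#' `"A-B-C-D-E"` keeps all five separate. Group i (left to right) becomes
#' task class i.
#'
#' @param scheme_string Groups of letters from A-E joined by `-`.
#' @return An object of class `task_scheme` with elements `scheme_string`,
#'   `groups` (list of character vectors) and `n_classes`.
#' @examples
#' parse_scheme("AB-E")$n_classes  # 2
#' @export
parse_scheme <- function(scheme_string) {
  if (!is.character(scheme_string) || length(scheme_string) != 1L ||
      !nzchar(scheme_string))
    stop("scheme must be a single non-empty string")
  parts <- strsplit(scheme_string, "-", fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    stop(sprintf("scheme '%s' must have at least 2 groups", scheme_string))
  if (any(!nzchar(parts)))
    stop(sprintf("scheme '%s' contains an empty group", scheme_string))
  groups <- lapply(parts, function(p) strsplit(p, "")[[1]])
  letters_all <- unlist(groups)
  bad <- setdiff(letters_all, SET_IDS)
  if (length(bad) > 0L)
    stop(sprintf("scheme '%s' contains unknown set id '%s'",
                 scheme_string, bad[1]))
  if (anyDuplicated(letters_all))
    stop(sprintf("scheme '%s' uses set '%s' more than once", scheme_string,
                 letters_all[duplicated(letters_all)][1]))
  structure(
    list(scheme_string = scheme_string, groups = groups,
         n_classes = length(groups)),
    class = "task_scheme")
}

#' @export
print.task_scheme <- function(x, ...) {
  cat(sprintf("<task_scheme> %s: %d classes (%s)\n", x$scheme_string,
              x$n_classes,
              paste(vapply(x$groups, paste, "", collapse = ""),
                    collapse = " vs ")))
  invisible(x)
}

#' Index of the "abnormal" (positive) class under a scheme
#'
#' For binary and one-vs-seizure tasks the positive class is the group that
#' is exactly the seizure set E; otherwise the last group is used.
#'
#' @param scheme A `task_scheme`.
#' @return 0-based class index of the positive class.
#' @export
positive_class <- function(scheme) {
  is_e <- vapply(scheme$groups, function(g) identical(g, "E"), logical(1))
  if (any(is_e)) which(is_e)[1] - 1L else scheme$n_classes - 1L
}

#' Build a labeled task dataset from raw segments
#'
#' Keeps exactly the segments whose set appears in some group of the
#' scheme, relabels them to the group index (0-based), and z-score
#' normalizes each retained segment independently with its own mean and
#' population standard deviation.
#'
#' @param segments A [segment_table()] whose provenance carries raw set ids.
#' @param scheme A [parse_scheme()] result (or a scheme string).
#' @return A [segment_table()] with task labels 0..n_classes-1.
#' @export
build_task_dataset <- function(segments, scheme) {
  if (is.character(scheme)) scheme <- parse_scheme(scheme)
  stopifnot(inherits(segments, "segment_table"),
            inherits(scheme, "task_scheme"))
  set_ids <- segments$provenance$set_id
  new_label <- rep(NA_integer_, n_segments(segments))
  for (i in seq_along(scheme$groups)) {
    in_group <- set_ids %in% scheme$groups[[i]]
    if (!any(in_group))
      stop(sprintf("scheme group '%s' matches no segments",
                   paste(scheme$groups[[i]], collapse = "")))
    new_label[in_group] <- i - 1L
  }
  keep <- which(!is.na(new_label))
  seg <- segments$segments[keep, , drop = FALSE]
  seg <- t(apply(seg, 1L, function(row) zscore_normalize(row)$values))
  segment_table(seg, new_label[keep],
                segments$provenance[keep, , drop = FALSE])
}
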