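# Readers and writers: Bonn-style ASCII records, UCI-style segment CSV,
# evaluation reports (CSV + JSON sidecar).

#' Read one Bonn-style ASCII record
#'
#' Bonn-distribution record files hold one sample value per line (4097
#' lines for the original recordings). Blank lines and surrounding
#' whitespace are skipped; any other non-numeric content is an error naming
#' the offending line.
#'
#' @param path Path to the ASCII file.
#' @param set_id Set identifier A..E for the record.
#' @param record_index Non-negative integer index of the record.
#' @param sampling_rate_hz Sampling rate (default 173.61).
#' @return An [eeg_record()]; sample order matches file line order.
#' @export
read_bonn_record <- function(path, set_id, record_index,
                             sampling_rate_hz = 173.61) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- which(nzchar(trimmed))
  if (length(keep) == 0L) stop("empty record file: ", path)
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1]]
    stop(sprintf("format error in %s at line %d: '%s' is not a number",
                 path, bad, trimmed[bad]))
  }
  eeg_record(vals, set_id, record_index, sampling_rate_hz)
}

#' Read a directory tree of Bonn-style records
#'
#' Expects one subdirectory per set (named A..E), each containing ASCII
#' record files; files are read in sorted order and indexed 0, 1, ...
#'
#' @param dir Root directory.
#' @param sets Which sets to read (default all five).
#' @inheritParams read_bonn_record
#' @return List of [eeg_record()] objects.
#' @export
read_bonn_dir <- function(dir, sets = SET_IDS, sampling_rate_hz = 173.61) {
  records <- list()
  for (s in sets) {
    sub <- file.path(dir, s)
    if (!dir.exists(sub)) stop("missing set directory: ", sub)
    files <- sort(list.files(sub, full.names = TRUE))
    if (length(files) == 0L) stop("no record files in ", sub)
    for (i in seq_along(files)) {
      records[[length(records) + 1L]] <-
        read_bonn_record(files[i], s, i - 1L, sampling_rate_hz)
    }
  }
  records
}

#' Read a UCI-style segment CSV
#'
#' The UCI "Epileptic Seizure Recognition" layout: a header row, an
#' optional leading ID column, then `segment_length` numeric sample
#' columns, and a final integer label column named `y` with values 1..5.
#' Labels are remapped to the canonical A-E vocabulary (UCI 1 = seizure set
#' E, 2 = D, 3 = C, 4 = B, 5 = A); table labels are set indices (A=0 ..
#' E=4) so task construction works identically to segmented raw records.
#'
#' Provenance is parsed from ID strings of the form `S.<set>.<record>.<chunk>`
#' when present, otherwise synthesized as consecutive chunk indices per set.
#'
#' @param path CSV path.
#' @return A [segment_table()].
#' @export
read_uci_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(segment_table(matrix(numeric(0), 0, max(ncol(df) - 1L, 0L)),
                         integer(0),
                         data.frame(set_id = character(0),
                                    record_index = integer(0),
                                    chunk_index = integer(0))))
  }
  has_id <- is.character(df[[1]])
  ids <- if (has_id) df[[1]] else NULL
  if (has_id) df <- df[, -1L, drop = FALSE]
  ycol <- ncol(df)
  if (!identical(names(df)[ycol], "y"))
    stop("format error: last column must be the label column 'y'")
  y <- df[[ycol]]
  if (!all(y == as.integer(y)) || any(y < 1L) || any(y > 5L))
    stop("label error: labels must be integers in 1..5")
  seg <- as.matrix(df[, -ycol, drop = FALSE])
  if (!is.numeric(seg) || anyNA(seg))
    stop("format error: non-numeric sample values")
  set_id <- UCI_LABEL_TO_SET[as.integer(y)]
  prov <- parse_uci_ids(ids, set_id)
  segment_table(seg, match(set_id, SET_IDS) - 1L, prov)
}

# Provenance from UCI id strings ("S.<set>.<record>.<chunk>"); falls back to
# consecutive numbering within each set when ids are absent or unparseable.
parse_uci_ids <- function(ids, set_id) {
  n <- length(set_id)
  rec <- rep(NA_integer_, n)
  chunk <- rep(NA_integer_, n)
  if (!is.null(ids)) {
    m <- regmatches(ids, regexec("^S\\.([A-E])\\.([0-9]+)\\.([0-9]+)$", ids))
    ok <- lengths(m) == 4L
    rec[ok] <- as.integer(vapply(m[ok], `[`, "", 3L))
    chunk[ok] <- as.integer(vapply(m[ok], `[`, "", 4L))
  }
  if (anyNA(rec)) {
    for (s in unique(set_id)) {
      idx <- which(set_id == s & is.na(rec))
      if (length(idx) > 0L) {
        # assume 23 chunks per record, UCI convention
        rec[idx] <- (seq_along(idx) - 1L) %/% 23L
        chunk[idx] <- (seq_along(idx) - 1L) %% 23L
      }
    }
  }
  data.frame(set_id = set_id, record_index = rec, chunk_index = chunk)
}

#' Write an evaluation report (CSV plus JSON sidecar)
#'
#' The CSV mirrors the k-fold result tables: columns
#' `task,metric,k1..kK,mean` with metric values as percentages rounded to
#' two decimals. A JSON sidecar (same path, `.json` extension) stores the
#' raw fractions at full precision for programmatic use; [read_report()]
#' reads it back bit-exactly.
#'
#' @param report An `eval_report` from [cross_validate()].
#' @param path Output CSV path; the sidecar replaces its extension with
#'   `.json`.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  validate_report(report)
  k <- report$k
  fold_cols <- paste0("k", seq_len(k))
  df <- data.frame(task = report$scheme_string,
                   metric = rownames(report$folds),
                   round(report$folds * 100, 2),
                   mean = round(report$mean * 100, 2),
                   check.names = FALSE)
  names(df)[3:(2 + k)] <- fold_cols
  json_path <- sub("\\.[A-Za-z0-9]+$", "", path)
  json_path <- paste0(json_path, ".json")
  tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(task = report$scheme_string, k = k,
           metrics = unname(report$folds),     # matrix: one array per metric
           metric_names = rownames(report$folds),
           mean = as.list(report$mean)),
      json_path, auto_unbox = TRUE, digits = I(17))
  }, error = function(e) stop("I/O error writing report: ",
                              conditionMessage(e)))
  invisible(c(csv = path, json = json_path))
}

#' Read back a report's JSON sidecar
#'
#' @param path Either the CSV path passed to [write_report()] or the
#'   sidecar path itself.
#' @return An `eval_report` with fold and mean values restored at full
#'   precision.
#' @export
read_report <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path
               else paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")
  if (!file.exists(json_path)) stop("report sidecar not found: ", json_path)
  obj <- jsonlite::fromJSON(json_path)
  folds <- matrix(as.numeric(obj$metrics), nrow = length(obj$metric_names))
  rownames(folds) <- obj$metric_names
  colnames(folds) <- paste0("k", seq_len(obj$k))
  eval_report(obj$task, folds)
}

#' Construct an evaluation report
#'
#' @param scheme_string The task scheme the report describes.
#' @param folds Numeric matrix of per-fold metric values (rows = metrics,
#'   columns = folds), as raw fractions in `[0, 1]`.
#' @return An object of class `eval_report` with the per-metric fold values
#'   and their arithmetic means.
#' @export
eval_report <- function(scheme_string, folds) {
  folds <- as.matrix(folds)
  if (is.null(rownames(folds))) stop("folds matrix must have metric rownames")
  colnames(folds) <- paste0("k", seq_len(ncol(folds)))
  structure(
    list(scheme_string = scheme_string, k = ncol(folds), folds = folds,
         mean = rowMeans(folds)),
    class = "eval_report")
}

validate_report <- function(report) {
  if (anyNA(report$folds))
    stop("incomplete report: missing fold values")
  if (ncol(report$folds) != report$k)
    stop(sprintf("incomplete report: expected %d folds, found %d",
                 report$k, ncol(report$folds)))
  invisible(TRUE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold cross-validation (%%)\n",
              x$scheme_string, x$k))
  out <- cbind(round(x$folds * 100, 2), mean = round(x$mean * 100, 2))
  print(out)
  invisible(x)
}
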