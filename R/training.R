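# Stratified k-fold cross-validation around mnlnet().

#' Stratified k-fold split
#'
#' Randomly partitions each class into k non-overlapping folds of equal
#' size (within one segment when a class count is not divisible by k).
#' Deterministic given the seed.
#'
#' @param x A [segment_table()] or an integer label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_split`: `assignment` (fold id 1..k per
#'   segment) and `test_indices` (list of k index vectors).
#' @export
make_folds <- function(x, k = 10L, seed = 1L) {
  y <- if (inherits(x, "segment_table")) x$labels else as.integer(x)
  k <- as.integer(k)
  set.seed(seed)
  assignment <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop(sprintf("class %d has %d segments, fewer than k = %d",
                   cl, length(idx), k))
    idx <- sample(idx)
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    assignment[idx] <- rep(seq_len(k), times = sizes)
  }
  structure(
    list(k = k, assignment = assignment,
         test_indices = lapply(seq_len(k), function(f) which(assignment == f))),
    class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> k = %d, %d segments (fold sizes %s)\n", x$k,
              length(x$assignment),
              paste(lengths(x$test_indices), collapse = ", ")))
  invisible(x)
}

#' k-fold cross-validation of the network on a task scheme
#'
#' Builds the task dataset for the scheme (selection, relabeling,
#' per-segment z-scoring), splits it into stratified folds, and for each
#' fold trains a fresh network on the other folds (with an internal
#' stratified validation slice for the learning-rate schedule and
#' checkpoint selection) and evaluates the best checkpoint on the held-out
#' fold. Test segments of a fold are never seen during that fold's
#' training or validation.
#'
#' Binary tasks are scored one-vs-rest against the seizure class; tasks
#' with three or more classes are macro-averaged (see
#' [multiclass_score()]).
#'
#' @param segments A raw [segment_table()] (set-labeled, e.g. from
#'   [segment_records()] or [read_uci_csv()]).
#' @param scheme A scheme string (`"A-E"`, `"AB-CD-E"`, ...) or a
#'   [parse_scheme()] result.
#' @param k Number of folds (default 10).
#' @param config A [train_config()]; its seed drives the fold split and
#'   per-fold training seeds.
#' @param keep_models Keep the k fitted models in the result (default
#'   FALSE; they are large).
#' @param ... Architecture arguments forwarded to [mnlnet()].
#' @return An `eval_report` (see [eval_report()]) with one row per metric;
#'   attribute `"details"` carries per-fold sizes and best epochs.
#' @export
cross_validate <- function(segments, scheme, k = 10L,
                           config = train_config(), keep_models = FALSE,
                           ...) {
  if (is.character(scheme)) scheme <- parse_scheme(scheme)
  task <- build_task_dataset(segments, scheme)
  folds <- make_folds(task, k = k, seed = config$seed)
  metrics <- matrix(NA_real_, 5L, k,
                    dimnames = list(c("accuracy", "precision", "sensitivity",
                                      "specificity", "f1"), NULL))
  details <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  pos <- positive_class(scheme)
  for (f in seq_len(k)) {
    test_idx <- folds$test_indices[[f]]
    stopifnot(length(intersect(test_idx,
                               setdiff(seq_len(n_segments(task)), test_idx)))
              == 0L)
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    fit <- mnlnet(task$segments[-test_idx, , drop = FALSE],
                  task$labels[-test_idx], n_classes = scheme$n_classes,
                  config = fold_cfg, ...)
    y_pred <- predict(fit, task$segments[test_idx, , drop = FALSE])
    y_true <- task$labels[test_idx]
    sc <- multiclass_score(y_true, y_pred, scheme$n_classes, positive = pos)
    metrics[, f] <- sc[rownames(metrics)]
    details[[f]] <- list(n_test = length(test_idx),
                         best_epoch = fit$best_epoch,
                         best_val_accuracy = fit$best_val_accuracy)
    if (keep_models) models[[f]] <- fit
  }
  report <- eval_report(scheme$scheme_string, metrics)
  attr(report, "details") <- details
  if (keep_models) attr(report, "models") <- models
  report
}

#' Evaluate a fitted model on a labeled dataset
#'
#' @param model A fitted [mnlnet()] model.
#' @param segments Segment matrix or [segment_table()] (already
#'   task-labeled and normalized).
#' @param labels Integer labels (taken from the table when omitted).
#' @param positive Positive class for binary scoring (default: last
#'   class).
#' @return Named metric vector as in [multiclass_score()].
#' @export
evaluate_model <- function(model, segments, labels = NULL,
                           positive = model$arch$n_classes - 1L) {
  if (inherits(segments, "segment_table")) {
    labels <- segments$labels
    segments <- segments$segments
  }
  n_cl <- model$arch$n_classes
  if (max(labels) >= n_cl)
    stop(sprintf("label %d outside the model's %d classes: checkpoint/task mismatch",
                 max(labels), n_cl))
  y_pred <- predict(model, segments)
  multiclass_score(as.integer(labels), y_pred, n_cl, positive = positive)
}
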