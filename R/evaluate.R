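# Evaluation: projection of segment predictions back onto the 5-s grid,
# one-vs-rest confusion counts per activity, the standard derived metrics,
# Table-style reports, and leave-one-home-out cross-validation.

#' Project segment predictions onto 5-s time slices
#'
#' Every 5-s slice inherits the label and visitor flag of the segment
#' covering it; the segments must partition the grid.
#'
#' @param predictions A prediction table (`start_s`, `end_s`, `label`,
#'   `visitor`), ordered or orderable by `start_s`.
#' @param grid_times Ascending slice times (multiples of 5 s).
#' @return data.frame with `time_s`, `label`, `visitor`.
#' @export
segments_to_slices <- function(predictions, grid_times) {
  p <- predictions[order(predictions$start_s), , drop = FALSE]
  idx <- findInterval(grid_times, p$start_s)
  if (any(idx == 0L) || any(grid_times >= p$end_s[idx]))
    stop("some time slices are not covered by any segment")
  data.frame(time_s = grid_times, label = p$label[idx],
             visitor = p$visitor[idx], stringsAsFactors = FALSE)
}

#' One-vs-rest confusion counts for one activity
#'
#' @param pred,truth Equal-length label vectors (one entry per time slice).
#' @param activity The positive class.
#' @return List with integer `tp`, `fp`, `tn`, `fn` (summing to the number
#'   of slices).
#' @export
confusion <- function(pred, truth, activity) {
  if (length(pred) != length(truth))
    stop("prediction and truth vectors differ in length")
  p <- pred == activity
  t <- truth == activity
  list(tp = sum(p & t), fp = sum(p & !t),
       tn = sum(!p & !t), fn = sum(!p & t))
}

#' Sensitivity, specificity, precision and F-measure
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `precision = tp/(tp+fp)`,
#' `F = 2 * precision * sensitivity / (precision + sensitivity)`; any 0/0 is
#' 0 by convention.
#'
#' @param counts Confusion counts from [confusion()].
#' @return Named numeric vector of the four metrics, each in `[0, 1]`.
#' @export
confusion_metrics <- function(counts) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  sens <- safe(counts$tp, counts$tp + counts$fn)
  spec <- safe(counts$tn, counts$tn + counts$fp)
  prec <- safe(counts$tp, counts$tp + counts$fp)
  f <- safe(2 * prec * sens, prec + sens)
  c(sensitivity = sens, specificity = spec, precision = prec,
    f_measure = f)
}

metric_names <- c("sensitivity", "specificity", "precision", "f_measure")

# per-activity metric data.frame from a named list of count lists
counts_to_metrics <- function(counts_by_activity) {
  rows <- lapply(names(counts_by_activity), function(a) {
    m <- confusion_metrics(counts_by_activity[[a]])
    data.frame(activity = a, t(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a per-activity performance report
#'
#' @param metrics data.frame with columns `classifier`, `activity`,
#'   `sensitivity`, `specificity`, `precision`, `f_measure`; every
#'   classifier must cover every activity in `activities`.
#' @param activities Report row order; defaults to [adl_labels()].
#' @return data.frame in report order with an appended unweighted `Mean` row
#'   per classifier.
#' @export
build_report <- function(metrics, activities = adl_labels()) {
  stopifnot(all(c("classifier", "activity", metric_names) %in%
                  names(metrics)))
  out <- list()
  for (cl in unique(metrics$classifier)) {
    m <- metrics[metrics$classifier == cl, , drop = FALSE]
    missing_acts <- setdiff(activities, m$activity)
    if (length(missing_acts) > 0L)
      stop("classifier '", cl, "' is missing activities: ",
           paste(missing_acts, collapse = ", "))
    m <- m[match(activities, m$activity), , drop = FALSE]
    mean_row <- data.frame(classifier = cl, activity = "Mean",
                           t(colMeans(m[, metric_names])),
                           stringsAsFactors = FALSE)
    out[[cl]] <- rbind(m[, c("classifier", "activity", metric_names)],
                       mean_row)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a report as percentages
#'
#' @param report A report from [build_report()].
#' @param digits Decimal places (default 2, e.g. `0.6666 -> "66.67"`).
#' @return The report with metric columns formatted as percentage strings.
#' @export
format_report <- function(report, digits = 2) {
  for (col in intersect(metric_names, names(report))) {
    report[[col]] <- formatC(round(report[[col]] * 100, digits),
                             format = "f", digits = digits)
  }
  report
}

#' Overlay detected no-activity periods onto slice predictions
#'
#' Periods without any activity in the flat are detected directly from the
#' PIR stream -- maximal runs of 5-s slices in which no room fires, lasting
#' at least `min_gap_s` -- and relabelled `"AWAY"`, independently of (and
#' uniformly across) the segmentation method that produced the predictions.
#' Visitor flags are left untouched.
#'
#' @param slices Slice predictions from [segments_to_slices()].
#' @param grid The feature grid the slices refer to.
#' @param min_gap_s Minimum zero-motion run length to count as absence.
#' @return The slice table with `label` overwritten inside absence periods.
#' @export
away_slice_overlay <- function(slices, grid, min_gap_s = 300) {
  any_pir <- as.integer(rowSums(room_pir_matrix(grid)) > 0)
  r <- rle(any_pir == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- r$values & r$lengths * TICK_S >= min_gap_s
  for (j in which(long)) slices$label[starts[j]:ends[j]] <- AWAY_LABEL
  slices
}

# Segment a preprocessed grid by the requested method.
segment_grid <- function(grid, segmentation = c("room", "token", "slots60"),
                         cfg = room_filter_config(), slot_s = 60) {
  segmentation <- match.arg(segmentation)
  switch(segmentation,
         room = segment_rooms(grid, cfg),
         token = segment_tokens(grid),
         slots60 = slice_fixed_windows(grid, slot_s))
}

#' Leave-one-home-out cross-validation
#'
#' For each home, trains on the pooled segments of all other homes, predicts
#' the held-out home, projects predictions onto 5-s slices and accumulates
#' one-vs-rest confusion counts per activity across folds. Metrics are
#' computed once on the pooled counts (micro over folds, macro over
#' activities); per-fold metrics are also reported. Slices whose truth is
#' `NONE`/`AWAY` enter every activity's counts as negatives.
#'
#' @param datasets List of at least two homes, each either a `home_dataset`
#'   or an already-preprocessed feature grid from [preprocess_home()]
#'   (passing grids lets several evaluation runs share the preprocessing).
#' @param spec A [classifier_spec()] for the ADL classifier.
#' @param segmentation `"room"`, `"token"` or `"slots60"`.
#' @param cfg A [room_filter_config()] (room segmentation only).
#' @param slot_s Baseline slot length (slots60 only).
#' @param visitor Also train/evaluate the parallel visitor classifier?
#' @param visitor_rooms Optional room restriction for the visitor
#'   classifier.
#' @param activities Activities to report.
#' @return List with `report` (pooled per-activity metrics + Mean row),
#'   `macro` (named vector, the Mean row), `counts` (pooled per-activity
#'   confusion counts), `per_fold` (per-home metric data.frame),
#'   `n_slices`, and `visitor` (counts + metrics, when requested).
#' @export
leave_one_home_out <- function(datasets, spec = classifier_spec("rf"),
                               segmentation = c("room", "token", "slots60"),
                               cfg = room_filter_config(), slot_s = 60,
                               visitor = FALSE, visitor_rooms = NULL,
                               activities = adl_labels()) {
  stopifnot(length(datasets) >= 2L)
  segmentation <- match.arg(segmentation)

  prep <- lapply(datasets, function(d) {
    grid <- if (inherits(d, "home_dataset")) preprocess_home(d) else d
    list(segments = segment_grid(grid, segmentation, cfg, slot_s),
         truth = grid[, c("time_s", "truth_label", "truth_visitor")],
         grid = grid)
  })

  # cross-home comparability: pool only the feature columns shared by all
  # homes (identical layouts share everything)
  common <- Reduce(intersect, lapply(prep, function(p) names(p$segments)))
  prep <- lapply(prep, function(p) {
    p$segments <- p$segments[, common, drop = FALSE]
    p
  })

  zero <- function() list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  pooled <- stats::setNames(replicate(length(activities), zero(),
                                      simplify = FALSE), activities)
  vis_pooled <- zero()
  per_fold <- list()
  n_slices <- 0L

  for (h in seq_along(prep)) {
    train_segs <- do.call(rbind, lapply(prep[-h], `[[`, "segments"))
    n_classes <- length(unique(
      train_segs$truth_label[train_segs$truth_label != AWAY_LABEL]))
    if (n_classes < 2L) {
      warning("fold ", h, " skipped: training pool has fewer than 2 classes")
      next
    }
    model <- train_adl(train_segs, spec)
    pred <- predict_adl(model, prep[[h]]$segments)
    if (visitor) {
      vis_model <- train_visitor(train_segs, classifier_spec(
        "rf", n_trees = spec$n_trees, seed = spec$seed), visitor_rooms)
      pred <- merge_predictions(pred,
                                predict_visitor(vis_model,
                                                prep[[h]]$segments))
    }
    slices <- segments_to_slices(pred, prep[[h]]$truth$time_s)
    slices <- away_slice_overlay(slices, prep[[h]]$grid, cfg$min_gap_s)
    truth <- prep[[h]]$truth
    n_slices <- n_slices + nrow(truth)

    fold_metrics <- list()
    for (a in activities) {
      cts <- confusion(slices$label, truth$truth_label, a)
      for (nm in names(cts)) pooled[[a]][[nm]] <- pooled[[a]][[nm]] + cts[[nm]]
      fold_metrics[[a]] <- cts
    }
    fm <- counts_to_metrics(fold_metrics)
    fm$home <- h
    per_fold[[length(per_fold) + 1L]] <- fm

    if (visitor) {
      vc <- confusion(as.character(slices$visitor),
                      as.character(as.integer(truth$truth_visitor > 0)), "1")
      for (nm in names(vc)) vis_pooled[[nm]] <- vis_pooled[[nm]] + vc[[nm]]
    }
  }
  if (length(per_fold) == 0L) stop("no usable folds")

  metrics <- counts_to_metrics(pooled)
  metrics$classifier <- spec$algorithm
  report <- build_report(metrics, activities)
  macro <- unlist(report[report$activity == "Mean", metric_names])
  res <- list(report = report, macro = macro, counts = pooled,
              per_fold = do.call(rbind, per_fold), n_slices = n_slices)
  if (visitor)
    res$visitor <- list(counts = vis_pooled,
                        metrics = confusion_metrics(vis_pooled))
  res
}
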