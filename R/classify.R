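# Episode classification: ADL classifiers (naive Bayes, SVM, random
# forest) over segment features, the parallel visitor classifier, merging
# of the two prediction streams, and the fixed 60-s time-slot baseline.

#' Specify a classifier
#'
#' @param algorithm `"rf"` (random forest), `"svm"` (support vector
#'   machine, radial-basis kernel) or `"nb"` (Gaussian naive Bayes).
#' @param n_trees Number of trees for the random forest.
#' @param mtry Features per split for the random forest; default
#'   `floor(sqrt(p))`.
#' @param cost SVM regularisation constant.
#' @param kernel SVM kernel.
#' @param seed Random seed used when fitting.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("rf", "svm", "nb"),
                            n_trees = 100L, mtry = NULL, cost = 1,
                            kernel = "radial", seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_trees >= 1L, cost > 0)
  structure(list(algorithm = algorithm, n_trees = as.integer(n_trees),
                 mtry = mtry, cost = cost, kernel = kernel,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Columns of a segment table that enter the models: the compressed sensor
# features plus duration, activity degree, weekday and the token/room
# context. Clock time itself is deliberately not a feature -- the daily
# rhythm reaches the classifier only through what the sensors see (daylight
# in the lux channel) and the weekday, mirroring the measured feature set.
segment_feature_columns <- function(segments) {
  stat_cols <- grep("_(mean|var|min|max|first|last)$", names(segments),
                    value = TRUE)
  c(stat_cols, "duration_s", "activity_degree",
    "weekday", "token", "prev_token", "next_token", "room")
}

# Rooms appearing in a segment table's feature columns, in column order.
segment_rooms_of <- function(segments) {
  pir_means <- grep("_pir_mean$", names(segments), value = TRUE)
  unique(sub("(_[a-z])?_pir_mean$", "", pir_means))
}

# Numeric design frame. Categorical features (token context, room, weekday)
# are integer codes for rf/nb and one-hot factors for svm; unseen
# categorical levels at prediction time map to an "unknown" code rather
# than failing. `meta` carries the encoding fitted at training time.
build_design <- function(segments, algorithm, meta = NULL,
                         feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- segment_feature_columns(segments)
  missing_cols <- setdiff(feature_cols, names(segments))
  if (length(missing_cols) > 0L)
    stop("segment table lacks feature column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- segments[, feature_cols, drop = FALSE]

  if (is.null(meta)) {
    meta <- list(feature_cols = feature_cols,
                 room_levels = sort(unique(x$room[!is.na(x$room)])))
  }
  if ("room" %in% names(x)) {
    code <- match(x$room, meta$room_levels)
    code[is.na(x$room)] <- 0L          # segmentation without room estimates
    code[is.na(code)] <- -1L           # unseen room level
    x$room <- code
  }
  for (col in feature_cols) {
    if (anyNA(x[[col]]) || any(is.nan(x[[col]])))
      stop("feature column contains missing values: ", col)
  }

  if (algorithm == "svm") {
    for (col in intersect(c("token", "prev_token", "next_token", "room",
                            "weekday"), names(x))) {
      lev_key <- paste0(col, "_levels")
      if (is.null(meta[[lev_key]]))
        meta[[lev_key]] <- sort(unique(x[[col]]))
      # one-hot; an unseen level yields an all-zero block (the "unknown"
      # encoding) instead of failing
      mm <- outer(x[[col]], meta[[lev_key]], `==`) * 1
      colnames(mm) <- paste0(col, "_", meta[[lev_key]])
      x[[col]] <- NULL
      x <- cbind(x, as.data.frame(mm))
    }
  }
  list(x = x, meta = meta)
}

# Fit / predict over the three algorithm families. Shared by the ADL and
# visitor classifiers.
fit_classifier <- function(x, y, spec) {
  y <- factor(y)
  set.seed(spec$seed)
  if (spec$algorithm == "rf") {
    mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(x)))) else
      spec$mtry
    fit <- ranger::ranger(x = x, y = y, num.trees = spec$n_trees,
                          mtry = min(mtry, ncol(x)), seed = spec$seed,
                          num.threads = 1L)
  } else if (spec$algorithm == "nb") {
    fit <- e1071::naiveBayes(x = x, y = y)
    # guard degenerate zero-variance features
    fit$tables <- lapply(fit$tables, function(tb) {
      tb[, 2][!is.finite(tb[, 2]) | tb[, 2] < 1e-6] <- 1e-6
      tb
    })
  } else {
    keep <- vapply(x, function(v) stats::sd(v) > 0, TRUE)
    if (!any(keep)) stop("all features are constant; cannot fit an SVM")
    fit <- e1071::svm(x = as.matrix(x[, keep, drop = FALSE]), y = y,
                      kernel = spec$kernel, cost = spec$cost, scale = TRUE)
    attr(fit, "kept_cols") <- names(x)[keep]
  }
  list(fit = fit, levels = levels(y))
}

predict_classifier <- function(model, x, spec) {
  if (spec$algorithm == "rf") {
    as.character(predict(model$fit, data = x,
                         num.threads = 1L)$predictions)
  } else if (spec$algorithm == "nb") {
    as.character(predict(model$fit, newdata = x, type = "class"))
  } else {
    kept <- attr(model$fit, "kept_cols")
    as.character(predict(model$fit,
                         newdata = as.matrix(x[, kept, drop = FALSE])))
  }
}

#' Train the ADL classifier
#'
#' Fits the requested classifier on segment features. Away segments (truth
#' `"AWAY"`) are excluded: absence from the flat is detected from the PIR
#' signal by rule, not learned. Deterministic given `spec$seed`.
#'
#' @param segments A segment table with `truth_label`.
#' @param spec A [classifier_spec()].
#' @return An object of class `adl_model`.
#' @export
train_adl <- function(segments, spec = classifier_spec("rf")) {
  stopifnot(inherits(spec, "classifier_spec"),
            "truth_label" %in% names(segments))
  train <- segments[segments$truth_label != AWAY_LABEL, , drop = FALSE]
  labels <- train$truth_label
  if (length(unique(labels)) < 2L)
    stop("training set must contain at least two distinct labels")
  d <- build_design(train, spec$algorithm)
  model <- fit_classifier(d$x, labels, spec)
  structure(list(spec = spec, fit = model$fit,
                 label_levels = model$levels, meta = d$meta),
            class = "adl_model")
}

#' Predict ADL labels for segments
#'
#' Away segments are labelled by rule first -- a segment assigned no room by
#' the room-based clustering, or containing no PIR firing at all, is
#' `"AWAY"` -- and all remaining segments get the classifier's label.
#'
#' @param model An `adl_model` from [train_adl()].
#' @param segments A segment table carrying the training feature columns.
#' @return A prediction table: `segment_id`, `start_s`, `end_s`, `label`,
#'   `visitor` (NA; filled by [merge_predictions()]).
#' @export
predict_adl <- function(model, segments) {
  stopifnot(inherits(model, "adl_model"))
  out <- data.frame(segment_id = segments$segment_id,
                    start_s = segments$start_s, end_s = segments$end_s,
                    label = character(nrow(segments)),
                    visitor = rep(NA_integer_, nrow(segments)),
                    stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(out)
  is_away <- (!is.na(segments$room) & segments$room == NO_ROOM) |
    segments$activity_degree == 0
  out$label[is_away] <- AWAY_LABEL
  if (any(!is_away)) {
    d <- build_design(segments[!is_away, , drop = FALSE],
                      model$spec$algorithm, meta = model$meta,
                      feature_cols = model$meta$feature_cols)
    out$label[!is_away] <- predict_classifier(model, d$x, model$spec)
  }
  out
}

#' Train the visitor classifier
#'
#' A random forest, fully independent of the ADL classifier, predicting the
#' binary visitor flag of each segment. When `room_subset` is given, only
#' the feature columns of those rooms (plus the room-independent features:
#' duration, activity degree, weekday) are used -- the regime in
#' which restricting to e.g. bathroom, TV room and living room sharpened
#' visitor precision.
#'
#' @param segments A segment table with `truth_visitor`.
#' @param spec A [classifier_spec()]; must have `algorithm = "rf"`.
#' @param room_subset Optional character vector of room codes.
#' @return An object of class `visitor_model`.
#' @export
train_visitor <- function(segments, spec = classifier_spec("rf"),
                          room_subset = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$algorithm != "rf")
    stop("the visitor classifier uses the random forest only")
  y <- segments$truth_visitor
  if (length(unique(y)) < 2L)
    stop("visitor labels are single-class; cannot train")
  feature_cols <- visitor_feature_columns(segments, room_subset)
  d <- build_design(segments, "rf", feature_cols = feature_cols)
  model <- fit_classifier(d$x, y, spec)
  structure(list(spec = spec, fit = model$fit, meta = d$meta,
                 room_subset = room_subset),
            class = "visitor_model")
}

visitor_feature_columns <- function(segments, room_subset = NULL) {
  stat_cols <- grep("_(mean|var|min|max|first|last)$", names(segments),
                    value = TRUE)
  if (!is.null(room_subset)) {
    rooms <- segment_rooms_of(segments)
    col_room <- rep(NA_character_, length(stat_cols))
    for (r in rooms[order(-nchar(rooms))]) {
      hit <- is.na(col_room) & startsWith(stat_cols, paste0(r, "_"))
      col_room[hit] <- r
    }
    stat_cols <- stat_cols[!is.na(col_room) & col_room %in% room_subset]
  }
  c(stat_cols, "duration_s", "activity_degree", "weekday")
}

#' Predict visitor flags for segments
#'
#' @param model A `visitor_model` from [train_visitor()].
#' @param segments A segment table.
#' @return A prediction table: `segment_id`, `start_s`, `end_s`, `label`
#'   (NA), `visitor` (0/1).
#' @export
predict_visitor <- function(model, segments) {
  stopifnot(inherits(model, "visitor_model"))
  out <- data.frame(segment_id = segments$segment_id,
                    start_s = segments$start_s, end_s = segments$end_s,
                    label = rep(NA_character_, nrow(segments)),
                    visitor = integer(nrow(segments)),
                    stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(out)
  d <- build_design(segments, "rf", meta = model$meta,
                    feature_cols = model$meta$feature_cols)
  out$visitor <- as.integer(predict_classifier(model, d$x, model$spec))
  out
}

#' Merge ADL and visitor predictions
#'
#' The merged table carries the ADL label from the ADL classifier and the
#' visitor flag from the visitor classifier; neither overrides the other.
#'
#' @param adl,visitor Prediction tables over the same segments.
#' @return A merged prediction table.
#' @export
merge_predictions <- function(adl, visitor) {
  if (nrow(adl) != nrow(visitor) ||
      !identical(adl$segment_id, visitor$segment_id))
    stop("prediction tables refer to different segments")
  out <- adl
  if (any(!is.na(visitor$visitor))) out$visitor <- visitor$visitor
  out
}

#' Fixed-length time-slot baseline segmentation
#'
#' Partitions the grid into consecutive `slot_s` windows (trailing partial
#' window kept as a short final segment) and compresses each exactly as
#' [compress_segments()] does, with tokens recomputed per slot. This is the
#' conventional fixed-window baseline against which the clustering-based
#' segmentations are compared.
#'
#' @param grid A feature grid.
#' @param slot_s Slot length in seconds (multiple of 5).
#' @return A segment table.
#' @export
slice_fixed_windows <- function(grid, slot_s = 60) {
  if (slot_s %% TICK_S != 0 || slot_s < TICK_S)
    stop("slot_s must be a positive multiple of the 5-s grid step")
  rows_per <- slot_s / TICK_S
  seg_id <- ((seq_len(nrow(grid)) - 1L) %/% rows_per) + 1L
  compress_rows(grid, seg_id)
}
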