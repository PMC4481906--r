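# Refined room-based clustering: weighted moving-average PIR filters,
# activity/no-activity periods with raw-PIR edge preservation, room change
# points, merged change-point lists, and the short-activity filter.

#' Configuration of the room-based clustering
#'
#' @param short_window_s,long_window_s Centered moving-average windows
#'   (seconds; must convert to whole numbers of 5-s rows;
#'   `short_window_s < long_window_s`). The short filter reacts to brief
#'   room visits, the long filter to sustained occupancy.
#' @param room_weights Named list mapping room codes to
#'   `c(short_weight, long_weight)`. Rooms not listed use `default_weights`.
#'   The default up-weights short-term bathroom movement (brief toileting
#'   visits must not be smoothed away) while other rooms depend more on
#'   long-term activity.
#' @param default_weights `c(short_weight, long_weight)` for unlisted rooms.
#' @param activity_threshold Minimum filtered any-room score for a row to
#'   count as active.
#' @param min_gap_s No-activity runs shorter than this are absorbed into the
#'   surrounding activity period.
#' @param edge_keep_s Span at each activity-period boundary within which the
#'   raw (unfiltered) PIR refines the boundary to the first/last raw firing,
#'   preserving short information peaks at the edges.
#' @param min_activity_s Active segments shorter than this are excluded
#'   (strictly shorter: a segment of exactly this duration is kept).
#' @return An object of class `room_filter_config`.
#' @export
room_filter_config <- function(short_window_s = 15, long_window_s = 300,
                               room_weights = list(BATHROOM = c(2, 1)),
                               default_weights = c(1, 1),
                               activity_threshold = 0.05,
                               min_gap_s = 300, edge_keep_s = 10,
                               min_activity_s = 20) {
  if (short_window_s < TICK_S || long_window_s < TICK_S)
    stop("filter windows must span at least one 5-s grid step")
  if (short_window_s %% TICK_S != 0 || long_window_s %% TICK_S != 0)
    stop("filter windows must be whole multiples of the 5-s grid step")
  weight_ok <- function(w) length(w) == 2L && all(w >= 0) && sum(w) > 0
  stopifnot(short_window_s < long_window_s,
            all(vapply(room_weights, weight_ok, TRUE)),
            weight_ok(default_weights),
            activity_threshold >= 0, min_gap_s >= 0, edge_keep_s >= 0,
            min_activity_s >= 0)
  structure(list(short_window_s = short_window_s,
                 long_window_s = long_window_s,
                 room_weights = room_weights,
                 default_weights = default_weights,
                 activity_threshold = activity_threshold,
                 min_gap_s = min_gap_s, edge_keep_s = edge_keep_s,
                 min_activity_s = min_activity_s),
            class = "room_filter_config")
}

#' Load a room-clustering configuration from YAML
#'
#' Reads the `room_clustering:` block of a YAML file; fields absent from the
#' file keep their [room_filter_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `room_filter_config`.
#' @export
room_filter_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  if (!is.null(y$room_clustering)) y <- y$room_clustering
  args <- y[names(y) %in% names(formals(room_filter_config))]
  if (!is.null(args$room_weights))
    args$room_weights <- lapply(args$room_weights, as.numeric)
  do.call(room_filter_config, args)
}

# Centered moving average with shrinking windows at the boundaries.
moving_average <- function(x, w_rows) {
  n <- length(x)
  half_lo <- (w_rows - 1L) %/% 2L
  half_hi <- w_rows - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Filtered, weighted per-room PIR scores
#'
#' For each room, `score = short_weight * MA_short(PIR) +
#' long_weight * MA_long(PIR)` with centered moving averages (shrinking at
#' the boundaries) over the room-level PIR (OR over the room's boxes).
#'
#' @param grid A feature grid.
#' @param cfg A [room_filter_config()].
#' @param rooms Canonical room order.
#' @return Numeric matrix, one column per room; each score lies in
#'   `[0, short_weight + long_weight]`.
#' @export
filter_pir <- function(grid, cfg = room_filter_config(),
                       rooms = grid_rooms(grid)) {
  raw <- room_pir_matrix(grid, rooms)
  ws <- as.integer(cfg$short_window_s / TICK_S)
  wl <- as.integer(cfg$long_window_s / TICK_S)
  scores <- matrix(0, nrow = nrow(raw), ncol = length(rooms),
                   dimnames = list(NULL, rooms))
  for (i in seq_along(rooms)) {
    w <- cfg$room_weights[[rooms[i]]]
    if (is.null(w)) w <- cfg$default_weights
    scores[, i] <- w[1] * moving_average(raw[, i], ws) +
      w[2] * moving_average(raw[, i], wl)
  }
  scores
}

#' Detect activity / no-activity periods
#'
#' A row is active when the maximum room score reaches the activity
#' threshold. No-activity runs shorter than `min_gap_s` are absorbed into
#' the surrounding activity period. Finally, within `edge_keep_s` of each
#' activity-period boundary the raw PIR refines the boundary to the
#' first/last raw firing, so short information peaks at the edges (e.g. the
#' last movement before leaving the flat) are preserved even when the
#' filters smooth them below threshold.
#'
#' @param scores Score matrix from [filter_pir()].
#' @param raw_any Integer vector: 1 where any room's raw PIR fired.
#' @param cfg A [room_filter_config()].
#' @return data.frame with `start_row`, `end_row` (inclusive) and
#'   `is_active`, partitioning the rows.
#' @export
detect_activity_periods <- function(scores, raw_any,
                                    cfg = room_filter_config()) {
  n <- nrow(scores)
  stopifnot(length(raw_any) == n, n > 0L)
  mx <- do.call(pmax, as.data.frame(scores))
  active <- mx >= cfg$activity_threshold

  # absorb short no-activity runs that touch an activity period
  r <- rle(active)
  k <- length(r$lengths)
  if (k > 1L) {
    for (j in seq_len(k)) {
      if (!r$values[j] && r$lengths[j] * TICK_S < cfg$min_gap_s) {
        touches_active <- (j > 1L && r$values[j - 1L]) ||
          (j < k && r$values[j + 1L])
        if (touches_active) r$values[j] <- TRUE
      }
    }
    active <- inverse.rle(r)
    r <- rle(active)
  }

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  per <- data.frame(start_row = starts, end_row = ends,
                    is_active = r$values)

  # raw-PIR edge refinement, bounded by the neighbouring active periods
  ext <- as.integer(cfg$edge_keep_s %/% TICK_S)
  if (ext > 0L && any(per$is_active)) {
    act_idx <- which(per$is_active)
    for (j in act_idx) {
      s <- per$start_row[j]
      lo_bound <- if (j > 1L) per$start_row[j - 1L] else 1L
      lo <- max(s - ext, lo_bound)
      if (lo < s) {
        hit <- which(raw_any[lo:(s - 1L)] == 1L)
        if (length(hit) > 0L) per$start_row[j] <- lo + hit[1L] - 1L
      }
      e <- per$end_row[j]
      hi_bound <- if (j < nrow(per)) per$end_row[j + 1L] else n
      hi <- min(e + ext, hi_bound)
      if (hi > e) {
        hit <- which(raw_any[(e + 1L):hi] == 1L)
        if (length(hit) > 0L) per$end_row[j] <- e + hit[length(hit)]
      }
    }
    # shrink inactive neighbours accordingly and drop emptied ones
    for (j in seq_len(nrow(per))) {
      if (per$is_active[j]) next
      if (j > 1L) per$start_row[j] <- max(per$start_row[j],
                                          per$end_row[j - 1L] + 1L)
      if (j < nrow(per)) per$end_row[j] <- min(per$end_row[j],
                                               per$start_row[j + 1L] - 1L)
    }
    per <- per[per$start_row <= per$end_row, , drop = FALSE]
    rownames(per) <- NULL
  }
  per
}

#' Detect room change points within activity periods
#'
#' Within each active period the current room is the one with the maximal
#' filtered score (ties go to the room earliest in canonical order); a
#' change point is set at each row where the current room changes.
#'
#' @param scores Score matrix from [filter_pir()].
#' @param periods Periods from [detect_activity_periods()].
#' @return Ascending row indices.
#' @export
detect_room_changepoints <- function(scores, periods) {
  current <- max.col(scores, ties.method = "first")
  cps <- integer(0)
  for (j in which(periods$is_active)) {
    rows <- periods$start_row[j]:periods$end_row[j]
    if (length(rows) < 2L) next
    rm <- current[rows]
    cps <- c(cps, rows[which(diff(rm) != 0L) + 1L])
  }
  sort(cps)
}

#' Merge activity-period boundaries with room change points
#'
#' @param activity_boundaries Row indices at which a new activity or
#'   no-activity period starts.
#' @param room_changepoints Row indices from [detect_room_changepoints()].
#' @return Sorted, deduplicated union (strictly ascending).
#' @export
merge_changepoints <- function(activity_boundaries, room_changepoints) {
  sort(unique(c(as.integer(activity_boundaries),
                as.integer(room_changepoints))))
}

#' Build room-based segments
#'
#' Compresses each inter-change-point period as in [compress_segments()],
#' then assigns each segment its most likely room: the room with the largest
#' summed weighted score over the segment for segments inside activity
#' periods, `"NONE"` for no-activity segments.
#'
#' @param grid A feature grid.
#' @param changepoints Merged change points from [merge_changepoints()].
#' @param cfg A [room_filter_config()] (used to recompute scores and
#'   activity periods for the room assignment).
#' @param rooms Canonical room order.
#' @return A segment table with `room` and `activity_degree` filled in.
#' @export
build_room_segments <- function(grid, changepoints,
                                cfg = room_filter_config(),
                                rooms = grid_rooms(grid)) {
  segs <- compress_segments(grid, changepoints, rooms)
  scores <- filter_pir(grid, cfg, rooms)
  raw_any <- as.integer(rowSums(room_pir_matrix(grid, rooms)) > 0)
  periods <- detect_activity_periods(scores, raw_any, cfg)
  active_row <- logical(nrow(grid))
  for (j in which(periods$is_active))
    active_row[periods$start_row[j]:periods$end_row[j]] <- TRUE

  starts <- unique(c(1L, as.integer(changepoints)))
  seg_of_row <- findInterval(seq_len(nrow(grid)), starts)
  room_sum <- rowsum(scores, seg_of_row)
  seg_active <- rowsum(as.numeric(active_row), seg_of_row)[, 1] > 0
  best <- max.col(room_sum, ties.method = "first")
  segs$room <- ifelse(seg_active, rooms[best], NO_ROOM)
  segs
}

#' Exclude short activity segments
#'
#' Removes active segments strictly shorter than `min_activity_s` (a segment
#' of exactly the threshold duration is kept); no-activity segments are
#' never removed. Removed spans are annexed to the preceding segment (or the
#' following one for a leading victim), with feature statistics pooled
#' exactly (duration-weighted means, pooled population variances,
#' elementwise min/max), so the covered span is conserved.
#'
#' @param segments A room segment table.
#' @param min_activity_s Exclusion threshold in seconds.
#' @return The filtered segment table with prev/next tokens rebuilt.
#' @export
exclude_short_segments <- function(segments, min_activity_s = 20) {
  stopifnot(min_activity_s >= 0)
  if (nrow(segments) <= 1L) return(segments)
  victim <- !is.na(segments$room) & segments$room != NO_ROOM &
    segments$duration_s < min_activity_s
  if (!any(victim)) return(segments)
  if (all(victim)) victim[1L] <- FALSE  # degenerate: keep something

  survivors <- which(!victim)
  fi <- findInterval(seq_len(nrow(segments)), survivors)
  # leading victims (before the first survivor) go to the following survivor
  owner <- survivors[pmax(fi, 1L)]

  feat_stems <- unique(sub("_(mean|var|min|max|first|last)$", "",
                           grep("_(mean|var|min|max|first|last)$",
                                names(segments), value = TRUE)))
  grp <- split(seq_len(nrow(segments)), owner)
  rows <- lapply(grp, function(idx) {
    keep <- segments[idx[idx %in% survivors][1L], , drop = FALSE]
    if (length(idx) == 1L) return(keep)
    sub <- segments[idx, , drop = FALSE]
    w <- sub$n_rows
    for (stem in feat_stems) {
      m <- sub[[paste0(stem, "_mean")]]
      v <- sub[[paste0(stem, "_var")]]
      pooled_mean <- sum(w * m) / sum(w)
      keep[[paste0(stem, "_mean")]] <- pooled_mean
      keep[[paste0(stem, "_var")]] <-
        max(sum(w * (v + m^2)) / sum(w) - pooled_mean^2, 0)
      keep[[paste0(stem, "_min")]] <- min(sub[[paste0(stem, "_min")]])
      keep[[paste0(stem, "_max")]] <- max(sub[[paste0(stem, "_max")]])
      keep[[paste0(stem, "_first")]] <- sub[[paste0(stem, "_first")]][1L]
      keep[[paste0(stem, "_last")]] <-
        sub[[paste0(stem, "_last")]][nrow(sub)]
    }
    keep$start_s <- min(sub$start_s)
    keep$end_s <- max(sub$end_s)
    keep$duration_s <- keep$end_s - keep$start_s
    keep$n_rows <- sum(w)
    keep$activity_degree <- sum(w * sub$activity_degree) / sum(w)
    keep$truth_visitor <- as.integer(sum(w * sub$truth_visitor) /
                                       sum(w) >= 0.5)
    keep$tod_s <- keep$start_s %% DAY_S
    keep
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start_s), , drop = FALSE]
  out$segment_id <- seq_len(nrow(out))
  out$prev_token <- c(-1L, out$token[-nrow(out)])
  out$next_token <- c(out$token[-1L], -1L)
  rownames(out) <- NULL
  out
}

#' Room-based segmentation of a feature grid
#'
#' Full chain: [filter_pir()], [detect_activity_periods()],
#' [detect_room_changepoints()], [merge_changepoints()],
#' [build_room_segments()] and (optionally) [exclude_short_segments()].
#'
#' @param grid A feature grid.
#' @param cfg A [room_filter_config()].
#' @param exclude_short Apply the short-activity filter
#'   (`cfg$min_activity_s`)?
#' @return A segment table.
#' @export
segment_rooms <- function(grid, cfg = room_filter_config(),
                          exclude_short = TRUE) {
  rooms <- grid_rooms(grid)
  scores <- filter_pir(grid, cfg, rooms)
  raw_any <- as.integer(rowSums(room_pir_matrix(grid, rooms)) > 0)
  periods <- detect_activity_periods(scores, raw_any, cfg)
  boundaries <- periods$start_row[-1L]
  room_cps <- detect_room_changepoints(scores, periods)
  merged <- merge_changepoints(boundaries, room_cps)
  segs <- build_room_segments(grid, merged, cfg, rooms)
  if (exclude_short) segs <- exclude_short_segments(segs, cfg$min_activity_s)
  segs
}
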