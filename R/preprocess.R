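# Preprocessing: box-to-room mapping, resampling of the raw event stream
# onto a 5-s grid, and assembly of the wide per-room feature table with
# aligned ground-truth labels.

#' Annotate a reading stream with room codes and feature-column names
#'
#' Each record is assigned its canonical room code and the feature column it
#' will populate, named `{ROOM}_{channel}`. When two boxes in one room share
#' a channel (e.g. two living-room boxes), the boxes are disambiguated with
#' `_a`/`_b` suffixes in box-id order: `LIVING_a_pir`, `LIVING_b_pir`.
#'
#' @param stream data.frame with columns `time_s`, `box_id`, `channel`,
#'   `value`.
#' @param mapping data.frame with columns `box_id`, `room_code`.
#' @return The stream with additional `room` and `colname` columns.
#' @export
map_boxes_to_rooms <- function(stream, mapping) {
  stopifnot(all(c("time_s", "box_id", "channel", "value") %in% names(stream)),
            all(c("box_id", "room_code") %in% names(mapping)))
  idx <- match(stream$box_id, mapping$box_id)
  if (anyNA(idx)) {
    missing_boxes <- unique(stream$box_id[is.na(idx)])
    stop("box id(s) not present in room mapping: ",
         paste(missing_boxes, collapse = ", "))
  }
  stream$room <- mapping$room_code[idx]

  # suffix letters for boxes whose (room, channel) pairs collide
  key <- unique(data.frame(box_id = stream$box_id, room = stream$room,
                           channel = stream$channel,
                           stringsAsFactors = FALSE))
  key <- key[order(key$room, key$channel, key$box_id), ]
  dup <- stats::ave(seq_len(nrow(key)), key$room, key$channel,
                    FUN = length) > 1L
  suffixed_boxes <- unique(key$box_id[dup])
  suffix <- character(0)
  for (r in unique(key$room)) {
    b <- sort(unique(key$box_id[key$room == r &
                                  key$box_id %in% suffixed_boxes]))
    if (length(b) > 0L) suffix[b] <- letters[seq_along(b)]
  }
  sfx <- suffix[stream$box_id]
  stream$colname <- ifelse(is.na(sfx),
                           paste(stream$room, stream$channel, sep = "_"),
                           paste(stream$room, sfx, stream$channel, sep = "_"))
  stream
}

#' Resample a mapped reading stream onto the 5-s grid
#'
#' Each reading is assigned to the nearest 5-s grid point (halves round up,
#' so 7.5 s goes to 10 s). When several readings of one column collide on a
#' grid point, PIR takes the maximum and continuous channels the mean. Grid
#' points with no reading carry the last observed value of the column
#' (forward fill; leading gaps take the first observed value); missing PIR
#' is 0 (no evidence of motion).
#'
#' @param stream A mapped stream from [map_boxes_to_rooms()] (non-empty).
#' @return data.frame with `time_s` (ascending multiples of 5) and one
#'   column per `colname`, one row per grid point from 0 to the last
#'   observed grid time.
#' @export
resample_to_grid <- function(stream) {
  stopifnot(nrow(stream) > 0L, "colname" %in% names(stream))
  dt <- data.table::as.data.table(
    stream[, c("time_s", "colname", "channel", "value")])
  dt[, gi := floor(time_s / TICK_S + 0.5)]
  agg <- dt[, .(value = if (channel[1L] == "pir") max(value)
                else mean(value)),
            by = .(colname, gi, channel)]
  wide <- data.table::dcast(agg, gi ~ colname, value.var = "value")
  full <- data.table::data.table(gi = 0:max(agg$gi))
  wide <- wide[full, on = "gi"]
  is_pir <- vapply(names(wide), function(nm) grepl("_pir$", nm), TRUE)
  for (nm in setdiff(names(wide), "gi")) {
    if (is_pir[[nm]]) {
      data.table::set(wide, which(is.na(wide[[nm]])), nm, 0)
    } else {
      v <- data.table::nafill(wide[[nm]], type = "locf")
      v <- data.table::nafill(v, type = "nocb")
      data.table::set(wide, NULL, nm, v)
    }
  }
  out <- as.data.frame(wide)
  out$time_s <- out$gi * TICK_S
  out$gi <- NULL
  out[, c("time_s", setdiff(names(out), "time_s"))]
}

#' Assemble the labeled wide feature grid
#'
#' Orders the resampled columns by the layout's canonical room order, adds
#' the acceleration magnitude feature (when a box carries the three
#' acceleration axes), the weekday feature and the aligned ground truth:
#' `truth_label` is the label of the log interval covering each row
#' (intervals are half-open `[start, end)`; ties between nested intervals go
#' to the shorter interval, i.e. the interrupting activity), `"AWAY"` inside
#' away periods and `"NONE"` when at home without a logged activity.
#' `truth_visitor` is the visitor flag of the covering interval.
#'
#' @param grid Unlabeled grid from [resample_to_grid()].
#' @param layout The home's [home_layout()].
#' @param log Ground-truth logbook (`start_s`, `end_s`, `label`, `visitor`).
#' @return The feature grid: `time_s`, room/channel feature columns,
#'   `weekday`, `truth_label`, `truth_visitor`.
#' @export
build_feature_grid <- function(grid, layout, log) {
  stopifnot("time_s" %in% names(grid))
  feat <- setdiff(names(grid), "time_s")

  # acceleration magnitude per accelerometer box
  ax <- grep("accel_x$", feat, value = TRUE)
  for (col in ax) {
    stem <- sub("accel_x$", "", col)
    if (all(paste0(stem, c("accel_y", "accel_z")) %in% feat)) {
      grid[[paste0(stem, "accel_mag")]] <-
        sqrt(grid[[col]]^2 + grid[[paste0(stem, "accel_y")]]^2 +
               grid[[paste0(stem, "accel_z")]]^2)
    }
  }
  feat <- setdiff(names(grid), "time_s")

  # canonical column order: layout room order, then channel order
  room_of <- function(cols) {
    out <- rep(NA_character_, length(cols))
    for (r in layout$rooms[order(-nchar(layout$rooms))]) {
      hit <- is.na(out) & startsWith(cols, paste0(r, "_"))
      out[hit] <- r
    }
    out
  }
  rooms <- room_of(feat)
  chan_rank <- function(cols) {
    ranks <- rep(length(CHANNELS) + 1L, length(cols))
    for (i in seq_along(CHANNELS)) {
      ranks[grepl(paste0("_", CHANNELS[i], "$"), cols)] <- i
    }
    ranks[grepl("_accel_mag$", cols)] <- length(CHANNELS) + 1L
    ranks
  }
  ord <- order(match(rooms, layout$rooms), chan_rank(feat), feat)
  grid <- grid[, c("time_s", feat[ord])]

  grid$weekday <- as.integer((grid$time_s %/% DAY_S) %% 7)

  n <- nrow(grid)
  span_end <- grid$time_s[n] + TICK_S
  truth <- rep(NONE_LABEL, n)
  visitor <- rep(0L, n)
  if (nrow(log) > 0L) {
    if (any(log$end_s > span_end + TICK_S / 2) || any(log$start_s < 0))
      stop("log interval extends beyond the grid span")
    o <- order(log$end_s - log$start_s, decreasing = TRUE)
    for (i in o) {  # longest first: shorter (interrupting) intervals win
      idx <- which(grid$time_s >= log$start_s[i] &
                     grid$time_s < log$end_s[i])
      truth[idx] <- log$label[i]
      visitor[idx] <- log$visitor[i]
    }
  }
  grid$truth_label <- truth
  grid$truth_visitor <- visitor
  grid
}

#' Full preprocessing of one home dataset
#'
#' Convenience wrapper: [map_boxes_to_rooms()], [resample_to_grid()] and
#' [build_feature_grid()] in sequence.
#'
#' @param dataset A `home_dataset`.
#' @return A labeled feature grid.
#' @export
preprocess_home <- function(dataset) {
  stopifnot(inherits(dataset, "home_dataset"))
  mapping <- data.frame(box_id = dataset$layout$boxes$box_id,
                        room_code = dataset$layout$boxes$room,
                        stringsAsFactors = FALSE)
  mapped <- map_boxes_to_rooms(dataset$readings, mapping)
  build_feature_grid(resample_to_grid(mapped), dataset$layout, dataset$log)
}
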