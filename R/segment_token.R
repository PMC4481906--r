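# Initial clustering: PIR-constellation tokens, token change points, and
# compression of inter-change-point periods into single feature rows.

#' Infer the canonical room list of a feature grid
#'
#' Rooms are recovered from the PIR columns in column order (which
#' [build_feature_grid()] sets to the layout's canonical room order); the
#' `_a`/`_b` box suffixes of multi-box rooms are collapsed.
#'
#' @param grid A feature grid.
#' @return Character vector of room codes.
#' @export
grid_rooms <- function(grid) {
  pir_cols <- grep("_pir$", names(grid), value = TRUE)
  if (length(pir_cols) == 0L) stop("grid has no PIR columns")
  unique(sub("(_[a-z])?_pir$", "", pir_cols))
}

# n x R binary matrix: room-level PIR (OR over the room's boxes)
room_pir_matrix <- function(grid, rooms = grid_rooms(grid)) {
  pir_cols <- grep("_pir$", names(grid), value = TRUE)
  col_room <- sub("(_[a-z])?_pir$", "", pir_cols)
  m <- matrix(0L, nrow = nrow(grid), ncol = length(rooms),
              dimnames = list(NULL, rooms))
  for (i in seq_along(rooms)) {
    cols <- pir_cols[col_room == rooms[i]]
    v <- grid[[cols[1L]]]
    for (cc in cols[-1L]) v <- pmax(v, grid[[cc]])
    m[, i] <- as.integer(v > 0)
  }
  m
}

#' Compute the PIR-constellation token sequence
#'
#' The token at each grid row is a bitmask over the ordered room list: with
#' R rooms, room r contributes `2^(R - r)` when any of its PIR sensors reads
#' 1, so rooms `(KITCHEN, BATHROOM, LIVING)` with PIR `(1, 0, 1)` give token
#' `5` (binary 101). The all-zero constellation (token 0) is the motionless
#' state.
#'
#' @param grid A feature grid with at least one PIR column.
#' @param rooms Canonical room order; defaults to [grid_rooms()].
#' @return Integer vector of tokens, one per row, all `< 2^length(rooms)`.
#' @export
compute_tokens <- function(grid, rooms = grid_rooms(grid)) {
  m <- room_pir_matrix(grid, rooms)
  R <- length(rooms)
  as.integer(m %*% 2^(R - seq_len(R)))
}

#' Detect token change points
#'
#' A change point is set wherever the constellation switches to a
#' *different active* constellation: transitions into the motionless state
#' are neglected, and a return from motionless to the same last-active token
#' creates no change point.
#'
#' @param tokens Integer token sequence (non-empty); 0 = motionless.
#' @return Ascending 1-based row indices at which a new segment starts.
#' @export
detect_token_changepoints <- function(tokens) {
  stopifnot(length(tokens) > 0L)
  active <- which(tokens != 0L)
  if (length(active) < 2L) return(integer(0))
  ta <- tokens[active]
  active[which(diff(ta) != 0L) + 1L]
}

# Shared compression kernel: one segment per run of seg_id (ascending
# integers). Computes mean / population variance / min / max / first / last
# for every feature column, the segment token (modal non-motionless token),
# prev/next token context, activity degree, modal truth and bookkeeping.
compress_rows <- function(grid, seg_id, rooms = grid_rooms(grid)) {
  stopifnot(nrow(grid) > 0L, length(seg_id) == nrow(grid))
  feat <- setdiff(names(grid),
                  c("time_s", "weekday", "truth_label", "truth_visitor"))
  tokens <- compute_tokens(grid, rooms)
  any_pir <- as.integer(rowSums(room_pir_matrix(grid, rooms)) > 0)

  dt <- data.table::as.data.table(grid[, feat, drop = FALSE])
  dt[, seg := seg_id]
  m1 <- dt[, lapply(.SD, mean), by = seg, .SDcols = feat]
  m2 <- dt[, lapply(.SD, function(x) mean(x * x)), by = seg, .SDcols = feat]
  mn <- dt[, lapply(.SD, min), by = seg, .SDcols = feat]
  mx <- dt[, lapply(.SD, max), by = seg, .SDcols = feat]
  fi <- dt[, lapply(.SD, data.table::first), by = seg, .SDcols = feat]
  la <- dt[, lapply(.SD, data.table::last), by = seg, .SDcols = feat]
  stats <- list(mean = m1, var = m2, min = mn, max = mx,
                first = fi, last = la)
  out <- data.frame(segment_id = m1$seg)
  for (s in names(stats)) {
    block <- as.data.frame(stats[[s]])[, feat, drop = FALSE]
    if (s == "var") {
      mm <- as.data.frame(m1)[, feat, drop = FALSE]
      block <- pmax(block - mm * mm, 0)  # population variance
    }
    names(block) <- paste0(feat, "_", s)
    out <- cbind(out, block)
  }

  misc <- data.table::data.table(
    seg = seg_id, time_s = grid$time_s, tok = tokens, any = any_pir,
    truth = grid$truth_label, vis = grid$truth_visitor,
    weekday = grid$weekday, row_id = seq_len(nrow(grid)))
  base <- misc[, .(start_s = time_s[1L],
                   end_s = time_s[.N] + TICK_S,
                   n_rows = .N,
                   activity_degree = mean(any),
                   truth_visitor = as.integer(mean(vis) >= 0.5),
                   weekday = weekday[1L]), by = seg]
  out$start_s <- base$start_s
  out$end_s <- base$end_s
  out$duration_s <- base$end_s - base$start_s
  out$n_rows <- base$n_rows
  out$activity_degree <- base$activity_degree
  out$truth_visitor <- base$truth_visitor
  out$weekday <- base$weekday
  out$tod_s <- out$start_s %% DAY_S

  # segment token: modal non-motionless token (smallest wins ties), 0 when
  # the whole segment is motionless
  tk <- misc[tok != 0L, .N, by = .(seg, tok)]
  data.table::setorder(tk, seg, -N, tok)
  tk <- tk[!duplicated(seg)]
  out$token <- tk$tok[match(out$segment_id, tk$seg)]
  out$token[is.na(out$token)] <- 0L
  out$prev_token <- c(-1L, out$token[-nrow(out)])
  out$next_token <- c(out$token[-1L], -1L)

  # modal truth label; ties go to the label covering the latest row
  tr <- misc[, .(n = .N, last_row = max(row_id)), by = .(seg, truth)]
  data.table::setorder(tr, seg, -n, -last_row)
  tr <- tr[!duplicated(seg)]
  out$truth_label <- tr$truth[match(out$segment_id, tr$seg)]

  out$room <- NA_character_
  out$segment_id <- seq_len(nrow(out))
  out
}

#' Compress inter-change-point periods into segments
#'
#' The periods between consecutive change points (including before the first
#' and after the last) are each compressed to one row carrying the mean,
#' population variance, min, max, first and last of every feature column,
#' the period's token and the tokens of the neighbouring periods (sentinel
#' -1 at the boundaries), the activity degree (fraction of rows with any PIR
#' firing) and the modal ground-truth label.
#'
#' @param grid A feature grid (non-empty).
#' @param changepoints Ascending row indices from
#'   [detect_token_changepoints()].
#' @param rooms Canonical room order.
#' @return A segment table (one row per segment).
#' @export
compress_segments <- function(grid, changepoints,
                              rooms = grid_rooms(grid)) {
  if (nrow(grid) == 0L) stop("cannot compress an empty grid")
  stopifnot(!is.unsorted(changepoints, strictly = TRUE),
            all(changepoints >= 1L), all(changepoints <= nrow(grid)))
  starts <- unique(c(1L, as.integer(changepoints)))
  seg_id <- findInterval(seq_len(nrow(grid)), starts)
  compress_rows(grid, seg_id, rooms)
}

#' Token-based segmentation of a feature grid
#'
#' Convenience wrapper: [compute_tokens()],
#' [detect_token_changepoints()] and [compress_segments()].
#'
#' @param grid A feature grid.
#' @return A segment table.
#' @export
segment_tokens <- function(grid) {
  rooms <- grid_rooms(grid)
  cps <- detect_token_changepoints(compute_tokens(grid, rooms))
  compress_segments(grid, cps, rooms)
}
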