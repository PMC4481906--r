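# Room-based segmentation: weighted moving-average filters, activity
# periods with raw-PIR edge refinement, room change points, merging, the
# short-activity filter, and recovery of true transitions on easy data.

test_that("filter scores follow the weighted moving averages", {
  g <- manual_grid(list(KITCHEN = rep(0, 10)))
  cfg <- room_filter_config(short_window_s = 15, long_window_s = 300)
  expect_equal(unname(filter_pir(g, cfg)[, "KITCHEN"]), rep(0, 10))

  g1 <- manual_grid(list(KITCHEN = rep(1, 100)))
  s1 <- filter_pir(g1, room_filter_config())[, "KITCHEN"]
  expect_equal(unname(s1), rep(2, 100))   # weights (1,1), MA of a constant

  # single firing, window 3 rows, weight (1,0): 1/3 at the firing row
  g2 <- manual_grid(list(KITCHEN = c(0, 0, 0, 0, 1, 0, 0, 0, 0)))
  cfg2 <- room_filter_config(short_window_s = 15, long_window_s = 300,
                             room_weights = list(KITCHEN = c(1, 0)))
  s2 <- filter_pir(g2, cfg2)[, "KITCHEN"]
  expect_equal(s2[5], 1 / 3)
  expect_equal(s2[1], 0)
})

test_that("bathroom short-term movement is up-weighted by default", {
  g <- manual_grid(list(BATHROOM = c(rep(0, 5), 1, rep(0, 5)),
                        KITCHEN = c(rep(0, 5), 1, rep(0, 5))))
  s <- filter_pir(g, room_filter_config())
  expect_gt(s[6, "BATHROOM"], s[6, "KITCHEN"])
})

test_that("a YAML room_clustering block overrides the defaults it names", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("room_clustering:",
               "  short_window_s: 10",
               "  activity_threshold: 0.1",
               "  room_weights:",
               "    BATHROOM: [3, 1]",
               "    KITCHEN: [1, 2]"), path)
  cfg <- room_filter_config_from_yaml(path)
  expect_equal(cfg$short_window_s, 10)
  expect_equal(cfg$activity_threshold, 0.1)
  expect_equal(cfg$room_weights$BATHROOM, c(3, 1))
  expect_equal(cfg$room_weights$KITCHEN, c(1, 2))
  expect_equal(cfg$long_window_s, 300)   # untouched default
})

test_that("window configuration errors are caught", {
  expect_error(room_filter_config(short_window_s = 2), "5-s grid step")
  expect_error(room_filter_config(short_window_s = 300,
                                  long_window_s = 15))
  expect_error(room_filter_config(short_window_s = 12), "whole multiples")
})

test_that("an all-quiet day is one no-activity period", {
  g <- manual_grid(list(KITCHEN = rep(0, 200)))
  s <- filter_pir(g, room_filter_config())
  per <- detect_activity_periods(s, rep(0L, 200), room_filter_config())
  expect_equal(nrow(per), 1L)
  expect_false(per$is_active)
  expect_equal(per$start_row, 1L)
  expect_equal(per$end_row, 200L)
})

test_that("short quiet gaps are absorbed into the activity period", {
  # 30 min on / 10 min off / 30 min on with min_gap 15 min -> one period
  pir <- c(rep(1, 360), rep(0, 120), rep(1, 360))
  g <- manual_grid(list(KITCHEN = pir))
  cfg <- room_filter_config(min_gap_s = 900)
  s <- filter_pir(g, cfg)
  per <- detect_activity_periods(s, as.integer(pir), cfg)
  expect_equal(sum(per$is_active), 1L)
  act <- per[per$is_active, ]
  expect_lte(act$start_row, 2L)
  expect_gte(act$end_row, 839L)
})

test_that("raw firings at the edges extend the filtered boundary", {
  # an isolated 2-row burst just after the end of a long active period,
  # with the threshold set so that smoothing alone clips the burst: the
  # raw-PIR edge rule must recover it
  pir <- c(rep(1, 240), rep(0, 3), 1, 1, rep(0, 300))
  g <- manual_grid(list(KITCHEN = pir))
  cfg <- room_filter_config(activity_threshold = 1.2, min_gap_s = 0,
                            edge_keep_s = 30)
  cfg0 <- room_filter_config(activity_threshold = 1.2, min_gap_s = 0,
                             edge_keep_s = 0)
  s <- filter_pir(g, cfg)
  no_edge <- detect_activity_periods(s, as.integer(pir), cfg0)
  with_edge <- detect_activity_periods(s, as.integer(pir), cfg)
  end_no <- max(no_edge$end_row[no_edge$is_active])
  end_with <- max(with_edge$end_row[with_edge$is_active])
  last_firing <- max(which(pir == 1))
  expect_lt(end_no, last_firing)
  expect_equal(end_with, last_firing)
})

test_that("room change points fire where the dominant room changes", {
  quiet <- rep(0, 120)
  k <- c(rep(1, 60), quiet[1:60])
  l <- c(quiet[1:60], rep(1, 60))
  g <- manual_grid(list(KITCHEN = k, LIVING = l))
  cfg <- room_filter_config()
  s <- filter_pir(g, cfg)
  per <- detect_activity_periods(s, as.integer(pmax(k, l)), cfg)
  cps <- detect_room_changepoints(s, per)
  expect_length(cps, 1L)
  expect_lt(abs(cps - 61L), cfg$long_window_s / 5)

  # constant dominance: no change points
  g2 <- manual_grid(list(KITCHEN = rep(1, 60), LIVING = rep(0, 60)))
  s2 <- filter_pir(g2, cfg)
  per2 <- detect_activity_periods(s2, rep(1L, 60), cfg)
  expect_length(detect_room_changepoints(s2, per2), 0L)

  # exact tie throughout: canonical-order room wins, no change points
  g3 <- manual_grid(list(KITCHEN = rep(1, 60), LIVING = rep(1, 60)))
  s3 <- filter_pir(g3, cfg)
  per3 <- detect_activity_periods(s3, rep(1L, 60), cfg)
  expect_length(detect_room_changepoints(s3, per3), 0L)
})

test_that("change-point lists merge into a sorted unique union", {
  expect_equal(merge_changepoints(c(10, 50), c(50, 80)), c(10, 50, 80))
  expect_equal(merge_changepoints(integer(0), integer(0)), integer(0))
  out <- merge_changepoints(c(30, 10, 10), c(20, 30))
  expect_true(all(diff(out) > 0))
})

test_that("room segments carry room, duration and activity degree", {
  pir_b <- c(rep(0, 200), rep(1, 40), rep(0, 200))
  g <- manual_grid(list(KITCHEN = rep(0, 440), BATHROOM = pir_b))
  segs <- segment_rooms(g, exclude_short = FALSE)
  active <- segs[segs$room != "NONE", ]
  expect_equal(nrow(active), 1L)
  expect_equal(active$room, "BATHROOM")
  none <- segs[segs$room == "NONE", ]
  expect_true(all(none$activity_degree == 0))
  # the active segment contains the burst plus the filters' reach, so its
  # firing fraction is positive but below 1
  expect_gte(active$activity_degree, 0.4)
  expect_lt(active$activity_degree, 1)
  expect_true(active$start_s <= 1000 && active$end_s >= 1200)
})

test_that("mixed segments report the firing-row fraction", {
  pir <- c(rep(1, 12), rep(0, 28))
  g <- manual_grid(list(KITCHEN = pir))
  segs <- compress_segments(g, integer(0))
  expect_equal(segs$activity_degree, 12 / 40)
})

test_that("short-activity exclusion is strict and conserves the span", {
  grid <- cached_grid(n_days = 1, seed = 7)
  segs <- segment_rooms(grid, exclude_short = FALSE)
  kept <- exclude_short_segments(segs, 20)
  active_kept <- kept[kept$room != "NONE", ]
  expect_true(all(active_kept$duration_s >= 20))
  # strictness: a 20-s segment survives a 20-s threshold
  exact <- segs[segs$room != "NONE" & segs$duration_s == 20, ]
  if (nrow(exact) > 0) {
    expect_true(any(kept$start_s %in% exact$start_s))
  }
  expect_equal(sum(kept$duration_s), sum(segs$duration_s))
  expect_equal(kept$start_s[-1], kept$end_s[-nrow(kept)])
  # threshold 0 is the identity
  expect_equal(nrow(exclude_short_segments(segs, 0)), nrow(segs))
  # pooled means stay within the observed range
  expect_true(all(kept$KITCHEN_temp_mean >= kept$KITCHEN_temp_min - 1e-9))
  expect_true(all(kept$KITCHEN_temp_mean <= kept$KITCHEN_temp_max + 1e-9))
})

test_that("pooled moments after annexation equal direct recomputation", {
  g <- manual_grid(list(KITCHEN = c(rep(1, 10), 1, 1, rep(0, 80)),
                        BATHROOM = c(rep(0, 12), rep(1, 2), rep(0, 78))),
                   temp = rnorm(92, 21))
  segs <- build_room_segments(g, c(13L, 15L),
                              room_filter_config(min_gap_s = 0))
  merged <- exclude_short_segments(segs, 20)
  expect_lt(nrow(merged), nrow(segs))
  # recompute the absorbing segment's stats straight from the grid
  m <- merged[1, ]
  rows <- which(g$time_s >= m$start_s & g$time_s < m$end_s)
  expect_equal(m$KITCHEN_temp_mean, mean(g$KITCHEN_temp[rows]))
  expect_equal(m$KITCHEN_temp_var,
               mean(g$KITCHEN_temp[rows]^2) - mean(g$KITCHEN_temp[rows])^2,
               tolerance = 1e-12)
  expect_equal(m$KITCHEN_temp_min, min(g$KITCHEN_temp[rows]))
  expect_equal(m$KITCHEN_temp_max, max(g$KITCHEN_temp[rows]))
})

test_that("segments partition the grid for the full room pipeline", {
  grid <- cached_grid(n_days = 1, seed = 7)
  segs <- segment_rooms(grid)
  expect_equal(segs$start_s[1], 0)
  expect_equal(segs$end_s[nrow(segs)], nrow(grid) * 5)
  expect_equal(segs$start_s[-1], segs$end_s[-nrow(segs)])
  expect_equal(sum(segs$duration_s), nrow(grid) * 5)
})

test_that("raising the activity threshold never adds active time", {
  grid <- cached_grid(n_days = 1, seed = 7)
  rooms <- grid_rooms(grid)
  raw_any <- as.integer(rowSums(piradl:::room_pir_matrix(grid, rooms)) > 0)
  prev_active <- Inf
  for (thr in c(0.02, 0.05, 0.1, 0.3, 0.8)) {
    cfg <- room_filter_config(activity_threshold = thr)
    s <- filter_pir(grid, cfg, rooms)
    per <- detect_activity_periods(s, raw_any, cfg)
    act <- sum((per$end_row - per$start_row + 1)[per$is_active])
    expect_lte(act, prev_active)
    prev_active <- act
  }
})

test_that("merged change points recover true room transitions on easy data", {
  home <- cached_home(n_days = 2, seed = 19)
  grid <- cached_grid(n_days = 2, seed = 19)
  cfg <- room_filter_config()
  rooms <- grid_rooms(grid)
  scores <- filter_pir(grid, cfg, rooms)
  raw_any <- as.integer(rowSums(piradl:::room_pir_matrix(grid, rooms)) > 0)
  periods <- detect_activity_periods(scores, raw_any, cfg)
  merged <- merge_changepoints(periods$start_row[-1],
                               detect_room_changepoints(scores, periods))
  cp_times <- grid$time_s[merged]

  specs <- default_activity_specs()
  room_of <- vapply(specs, `[[`, "", "room")
  log <- home$log[order(home$log$start_s), ]
  log$room <- ifelse(log$label == "AWAY", NA, room_of[log$label])
  trans <- log$start_s[-1][!is.na(log$room[-1]) &
                             !is.na(log$room[-nrow(log)]) &
                             log$room[-1] != log$room[-nrow(log)] &
                             log$start_s[-1] == log$end_s[-nrow(log)]]
  matched <- vapply(trans, function(t0)
    any(abs(cp_times - t0) <= cfg$long_window_s), TRUE)
  expect_gte(mean(matched), 0.9)
})
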