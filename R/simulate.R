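# Synthetic smart-home generator: a single resident follows a semi-Markov
# daily schedule over the activity specifications; sensor boxes sample every
# channel every 5 s (0.2 Hz). Stands in for undeposited real study data.

DAY_S <- 86400
TICK_S <- 5
TICKS_PER_DAY <- DAY_S / TICK_S

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based derivation: child seeds for days, homes or experiments are
#' deterministic functions of the master seed and an index, and stay within
#' the 32-bit integer range R requires.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer counter.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 +
                as.numeric(index) * 69621 + 1) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

in_window <- function(t_clock, windows) {
  any(vapply(windows, function(w) t_clock >= w[1] && t_clock < w[2], TRUE))
}

# One day's activity schedule: morning sleep from midnight to wake time,
# then a semi-Markov walk over eligible activities (weighted by their daily
# rates, never repeating the previous label) interleaved with away episodes,
# then evening sleep to midnight. Times are day-local seconds. Uses the
# current RNG state.
build_day_schedule <- function(specs, away_rate, away_meanlog, away_sdlog,
                               away_window) {
  wake <- clamp(rnorm(1, hours(6.5), 1800), hours(5), hours(8.5))
  bed <- clamp(rnorm(1, hours(22.25), 1800), hours(20.5), hours(23.5))
  starts <- 0
  ends <- wake
  labels <- "Sleeping"
  t <- wake
  last <- "Sleeping"
  non_sleep <- specs[vapply(specs, `[[`, "", "label") != "Sleeping"]
  while (t < bed - 120) {
    elig <- non_sleep[vapply(non_sleep, function(s) {
      s$label != last && in_window(t %% DAY_S, s$windows)
    }, TRUE)]
    w <- vapply(elig, `[[`, 0, "rate")
    cand <- vapply(elig, `[[`, "", "label")
    if (away_rate > 0 && last != AWAY_LABEL &&
        t %% DAY_S >= away_window[1] && t %% DAY_S < away_window[2]) {
      cand <- c(cand, AWAY_LABEL)
      w <- c(w, away_rate)
    }
    if (length(cand) == 0L || sum(w) <= 0) {
      cand <- AWAY_LABEL
      w <- 1
    }
    lab <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
    dur <- if (lab == AWAY_LABEL) {
      rlnorm(1, away_meanlog, away_sdlog)
    } else {
      rlnorm(1, specs[[lab]]$duration_meanlog, specs[[lab]]$duration_sdlog)
    }
    dur <- clamp(dur, 60, bed - t)
    starts <- c(starts, t)
    ends <- c(ends, t + dur)
    labels <- c(labels, lab)
    t <- t + dur
    last <- lab
  }
  starts <- c(starts, t)
  ends <- c(ends, DAY_S)
  labels <- c(labels, "Sleeping")
  data.frame(start = starts, end = ends, label = labels,
             stringsAsFactors = FALSE)
}

# Shared per-day generator; overlap and visitor handling live here so that
# simulate_day (spec surface, no overlap/visitors) and simulate_home share
# one code path. Returns day-absolute times.
simulate_day_impl <- function(layout, specs, noise, day_index, seed,
                              overlap_prob, visitor_rate,
                              away_rate = 1, away_median_min = 90,
                              away_sdlog = 0.5,
                              away_window = c(hours(8), hours(19))) {
  stopifnot(inherits(layout, "home_layout"),
            inherits(noise, "sensor_noise_model"),
            length(specs) > 0)
  labs <- vapply(specs, `[[`, "", "label")
  names(specs) <- labs
  bad <- setdiff(vapply(specs, `[[`, "", "room"), layout$rooms)
  if (length(bad) > 0L)
    stop("activity spec references unknown room(s): ",
         paste(bad, collapse = ", "))
  set.seed(derive_seed(seed, day_index))

  sched <- build_day_schedule(specs, away_rate, log(away_median_min * 60),
                              away_sdlog, away_window)

  # Overlapping activities: a long base activity is interrupted by a nested
  # activity in another room (the resident leaves and returns); the nested
  # interval is logged in addition to the uninterrupted base interval.
  nested <- sched[0, ]
  if (overlap_prob > 0) {
    for (i in seq_len(nrow(sched))) {
      lab <- sched$label[i]
      dur <- sched$end[i] - sched$start[i]
      if (lab %in% c(AWAY_LABEL, "Sleeping") || dur < 900) next
      if (runif(1) >= overlap_prob) next
      mid_clock <- ((sched$start[i] + sched$end[i]) / 2) %% DAY_S
      others <- specs[vapply(specs, function(s) {
        s$room != specs[[lab]]$room && s$label != "Sleeping" &&
          in_window(mid_clock, s$windows)
      }, TRUE)]
      if (length(others) == 0L) next
      o <- others[[sample(length(others), 1L)]]
      nd <- clamp(rlnorm(1, o$duration_meanlog, o$duration_sdlog),
                  60, dur - 120)
      ns <- sched$start[i] + runif(1, 60, dur - nd - 60)
      nested <- rbind(nested, data.frame(start = ns, end = ns + nd,
                                         label = o$label,
                                         stringsAsFactors = FALSE))
    }
  }

  # Visitor episodes: a second occupant in a single room (preferring the
  # rooms the study's visitor model looked at), distinct from the resident's
  # room at episode start.
  visitors <- data.frame(start = numeric(0), end = numeric(0),
                         room = character(0), stringsAsFactors = FALSE)
  n_vis <- if (visitor_rate > 0) rpois(1, visitor_rate) else 0L
  if (n_vis > 0L) {
    for (v in seq_len(n_vis)) {
      vs <- runif(1, hours(9), hours(19))
      vd <- clamp(rlnorm(1, log(3600), 0.4), 900, hours(3))
      res_i <- which(sched$start <= vs & sched$end > vs)
      res_room <- if (length(res_i) > 0 &&
                        sched$label[res_i[1]] != AWAY_LABEL) {
        specs[[sched$label[res_i[1]]]]$room
      } else NA_character_
      prefer <- intersect(c("TV_ROOM", "LIVING", "BATHROOM"), layout$rooms)
      cand <- setdiff(prefer, res_room)
      if (length(cand) == 0L) cand <- setdiff(layout$rooms, res_room)
      visitors <- rbind(visitors, data.frame(
        start = vs, end = min(vs + vd, DAY_S),
        room = if (length(cand) == 1L) cand else sample(cand, 1L),
        stringsAsFactors = FALSE))
    }
  }

  # Per-tick occupant state (nested intervals painted last, so the
  # interrupting activity is current where it overlaps its base activity).
  tt <- TICK_S * (0:(TICKS_PER_DAY - 1))
  res_room <- rep(NA_character_, TICKS_PER_DAY)
  res_move <- numeric(TICKS_PER_DAY)
  res_awake <- logical(TICKS_PER_DAY)
  res_label <- rep(NA_character_, TICKS_PER_DAY)
  res_box <- rep(NA_character_, TICKS_PER_DAY)
  paint <- function(iv) {
    idx <- which(tt >= iv$start & tt < iv$end)
    if (length(idx) == 0L) return(invisible())
    if (iv$label == AWAY_LABEL) {
      res_room[idx] <<- NA_character_
      res_move[idx] <<- 0
      res_awake[idx] <<- FALSE
      res_label[idx] <<- AWAY_LABEL
      res_box[idx] <<- NA_character_
    } else {
      s <- specs[[iv$label]]
      res_room[idx] <<- s$room
      res_move[idx] <<- s$movement_prob
      res_awake[idx] <<- s$label != "Sleeping"
      res_label[idx] <<- s$label
      res_box[idx] <<- if (is.na(s$box_id)) NA_character_ else s$box_id
    }
  }
  for (i in seq_len(nrow(sched))) paint(sched[i, ])
  for (i in seq_len(nrow(nested))) paint(nested[i, ])

  vis_room <- rep(NA_character_, TICKS_PER_DAY)
  for (i in seq_len(nrow(visitors))) {
    idx <- which(tt >= visitors$start[i] & tt < visitors$end[i])
    vis_room[idx] <- visitors$room[i]
  }

  # Channel synthesis per box.
  abs_t <- day_index * DAY_S + tt
  clock_h <- tt / 3600
  occupied_room <- function(room) {
    (!is.na(res_room) & res_room == room) |
      (!is.na(vis_room) & vis_room == room)
  }
  daylight <- pmax(0, sin(pi * (clock_h - 6) / 14)) * (clock_h >= 6 &
                                                         clock_h <= 20)
  parts <- vector("list", nrow(layout$boxes) * length(CHANNELS))
  k <- 0L
  for (b in seq_len(nrow(layout$boxes))) {
    box <- layout$boxes$box_id[b]
    room <- layout$boxes$room[b]
    chans <- layout$boxes$channels[[b]]
    occ <- occupied_room(room)
    res_here <- !is.na(res_room) & res_room == room
    vis_here <- !is.na(vis_room) & vis_room == room
    # box preference: activities tied to another box in the same room only
    # weakly reach this box's PIR field of view
    pref <- ifelse(res_here & !is.na(res_box) & res_box != box, 0.3, 1)
    lamp <- (res_here & res_awake) | vis_here
    for (ch in chans) {
      val <- switch(ch,
        pir = {
          p_move <- 1 - (1 - res_here * res_move * pref) * (1 - vis_here * 0.9)
          p <- noise$pir_false_prob +
            (noise$pir_hit_prob - noise$pir_false_prob) * p_move
          as.numeric(rbinom(TICKS_PER_DAY, 1L, p))
        },
        temp = noise$temp_base +
          noise$temp_amplitude * sin(2 * pi * (clock_h - 8) / 24) +
          0.5 * occ + rnorm(TICKS_PER_DAY, 0, 0.1),
        lux = pmax(0, noise$lux_night +
                     (noise$lux_day - noise$lux_night) * daylight +
                     noise$lamp_lux_bonus * lamp +
                     rnorm(TICKS_PER_DAY, 0, 5)),
        humidity = {
          shower <- as.numeric(!is.na(res_label) & res_label == "Grooming")
          a <- exp(-TICK_S / 600)  # ~10-min decay after the shower
          s <- as.numeric(stats::filter(shower, a, method = "recursive"))
          noise$humidity_base +
            noise$humidity_shower_spike * pmin(1, (1 - a) * s / (1 - a^36)) +
            rnorm(TICKS_PER_DAY, 0, 0.15)
        },
        accel_x = {
          event <- rbinom(TICKS_PER_DAY, 1L, 0.02 * res_here)
          rnorm(TICKS_PER_DAY, 0, noise$accel_idle) +
            event * noise$accel_event_magnitude
        },
        accel_y = rnorm(TICKS_PER_DAY, 0, noise$accel_idle),
        accel_z = rnorm(TICKS_PER_DAY, 0, noise$accel_idle)
      )
      k <- k + 1L
      parts[[k]] <- data.frame(time_s = abs_t, box_id = box, channel = ch,
                               value = val, stringsAsFactors = FALSE)
    }
  }
  readings <- do.call(rbind, parts[seq_len(k)])
  rownames(readings) <- NULL

  log_iv <- rbind(sched, nested)
  log_iv <- log_iv[order(log_iv$start, log_iv$end), , drop = FALSE]
  visitor_flag <- rep(0L, nrow(log_iv))
  for (i in seq_len(nrow(visitors))) {
    visitor_flag[log_iv$start < visitors$end[i] &
                   log_iv$end > visitors$start[i]] <- 1L
  }
  log <- data.frame(start_s = day_index * DAY_S + log_iv$start,
                    end_s = day_index * DAY_S + log_iv$end,
                    label = log_iv$label, visitor = visitor_flag,
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(readings = readings, log = log)
}

#' Simulate one day of smart-home sensor data
#'
#' Draws a semi-Markov occupant trajectory (activity, room, duration) from
#' the activity specifications, interleaved with away-from-home episodes,
#' and synthesises 0.2 Hz readings for every box channel. Deterministic
#' given its arguments.
#'
#' @param layout A [home_layout()].
#' @param specs List of [activity_spec()] objects (non-empty; every room
#'   must exist in `layout`).
#' @param noise A [sensor_noise_model()].
#' @param day_index Zero-based day number; timestamps are offset by
#'   `day_index * 86400` and the weekday feature is `day_index %% 7`.
#' @param seed Integer seed; the day's RNG stream is derived from
#'   `(seed, day_index)` via [derive_seed()].
#' @param away_rate Relative per-day rate of away-from-home episodes
#'   (0 disables them).
#' @return List with elements `readings` (data.frame `time_s`, `box_id`,
#'   `channel`, `value`) and `log` (data.frame `start_s`, `end_s`, `label`,
#'   `visitor`; away periods carry label `"AWAY"`).
#' @export
simulate_day <- function(layout, specs, noise, day_index, seed,
                         away_rate = 1) {
  simulate_day_impl(layout, specs, noise, day_index, seed,
                    overlap_prob = 0, visitor_rate = 0,
                    away_rate = away_rate)
}

#' Simulate a multi-day home dataset
#'
#' Concatenates per-day simulations (day-distinct derived seeds). With
#' probability `overlap_prob` a sufficiently long activity is interrupted by
#' a second activity in another room and resumed; `visitor_rate` visitor
#' episodes per day place a second occupant in a different room, firing its
#' PIR concurrently, and set the visitor flag on overlapping log intervals.
#'
#' @inheritParams simulate_day
#' @param n_days Number of days (>= 1).
#' @param overlap_prob Probability that a long activity is interrupted by a
#'   nested activity.
#' @param visitor_rate Mean visitor episodes per day (Poisson).
#' @param home_id Identifier stored with the dataset.
#' @return An object of class `home_dataset`: list with `home_id`, `layout`,
#'   `readings`, `log`, `n_days`.
#' @export
simulate_home <- function(layout = default_home_layout(),
                          specs = default_activity_specs(layout),
                          noise = sensor_noise_model(),
                          n_days = 1, seed = 1,
                          overlap_prob = 0.1, visitor_rate = 0.25,
                          home_id = "home01", away_rate = 1) {
  stopifnot(n_days >= 1)
  days <- lapply(seq_len(n_days) - 1L, function(d) {
    simulate_day_impl(layout, specs, noise, d, seed,
                      overlap_prob = overlap_prob,
                      visitor_rate = visitor_rate, away_rate = away_rate)
  })
  structure(list(home_id = home_id, layout = layout,
                 readings = do.call(rbind, lapply(days, `[[`, "readings")),
                 log = do.call(rbind, lapply(days, `[[`, "log")),
                 n_days = as.integer(n_days)),
            class = "home_dataset")
}

#' @export
print.home_dataset <- function(x, ...) {
  cat(sprintf("<home_dataset '%s': %d day(s), %d rooms, %d boxes, %d readings, %d log intervals>\n",
              x$home_id, x$n_days, length(x$layout$rooms),
              nrow(x$layout$boxes), nrow(x$readings), nrow(x$log)))
  invisible(x)
}

#' Write a home dataset to a directory
#'
#' Emits `readings.csv` (`time_s`, `box_id`, `channel`, `value`),
#' `logbook.csv` (`start_s`, `end_s`, `label`, `visitor`) and `rooms.csv`
#' (`box_id`, `room_code`); the trio round-trips losslessly through
#' [read_dataset()].
#'
#' @param dataset A `home_dataset`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "home_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("readings.csv", "logbook.csv", "rooms.csv"))
  data.table::fwrite(dataset$readings, paths[1])
  data.table::fwrite(dataset$log, paths[2])
  data.table::fwrite(data.frame(box_id = dataset$layout$boxes$box_id,
                                room_code = dataset$layout$boxes$room),
                     paths[3])
  invisible(paths)
}

#' Read a home dataset written by [write_dataset()]
#'
#' @param directory Directory holding `readings.csv`, `logbook.csv`,
#'   `rooms.csv`.
#' @param home_id Identifier to attach; defaults to the directory name.
#' @return A `home_dataset`. The layout is reconstructed from `rooms.csv`
#'   (room order = first appearance) and the channels observed per box.
#' @export
read_dataset <- function(directory, home_id = basename(directory)) {
  readings <- as.data.frame(data.table::fread(
    file.path(directory, "readings.csv"),
    colClasses = c(box_id = "character", channel = "character")))
  log <- as.data.frame(data.table::fread(
    file.path(directory, "logbook.csv"),
    colClasses = c(label = "character")))
  if (nrow(log) == 0L)
    log <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0), visitor = integer(0))
  rooms_tbl <- as.data.frame(data.table::fread(
    file.path(directory, "rooms.csv"), colClasses = "character"))
  chan_by_box <- split(readings$channel, readings$box_id)
  boxes <- data.frame(box_id = rooms_tbl$box_id, room = rooms_tbl$room_code,
                      stringsAsFactors = FALSE)
  boxes$channels <- lapply(boxes$box_id, function(b) {
    unique(chan_by_box[[b]])
  })
  layout <- home_layout(unique(rooms_tbl$room_code), boxes)
  structure(list(home_id = home_id, layout = layout, readings = readings,
                 log = log,
                 n_days = as.integer(ceiling((max(readings$time_s) + TICK_S) /
                                               DAY_S))),
            class = "home_dataset")
}
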