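# The synthetic-home generator: determinism, noise-model contracts,
# coverage/conservation, channel placement, and file round-trips.

test_that("identical arguments give byte-identical simulations", {
  a <- simulate_day(tiny_layout(), tiny_specs(), sensor_noise_model(),
                    day_index = 3, seed = 99)
  b <- simulate_day(tiny_layout(), tiny_specs(), sensor_noise_model(),
                    day_index = 3, seed = 99)
  expect_identical(a, b)
  h1 <- simulate_home(n_days = 2, seed = 123, home_id = "x")
  h2 <- simulate_home(n_days = 2, seed = 123, home_id = "x")
  expect_identical(h1, h2)
})

test_that("different seeds or day indices give different days", {
  base <- simulate_day(tiny_layout(), tiny_specs(), sensor_noise_model(),
                       day_index = 0, seed = 1)
  other_seed <- simulate_day(tiny_layout(), tiny_specs(),
                             sensor_noise_model(), day_index = 0, seed = 2)
  expect_false(identical(base$readings$value, other_seed$readings$value))
})

test_that("a spec referencing an unknown room is a configuration error", {
  bad <- list(activity_spec("Cooking", "GARAGE", log(600), 0.3,
                            list(c(0, 86400)), 1))
  expect_error(simulate_day(tiny_layout(), bad, sensor_noise_model(),
                            0, 1),
               "unknown room")
})

test_that("no spurious firings when pir_false_prob is 0 and nobody is home", {
  # away_rate 0 removes away episodes; an all-away day is forced by specs
  # whose windows never open. Instead: zero false prob and a movement-free
  # sleeping-only schedule in the bedroom means other rooms never fire.
  noise <- sensor_noise_model(pir_hit_prob = 0.8, pir_false_prob = 0)
  specs <- list(activity_spec("Sleeping", "BEDROOM", log(3600), 0.2,
                              list(c(hours(21), 86400)), 1,
                              movement_prob = 0))
  day <- simulate_day(tiny_layout(), specs, noise, 0, 5, away_rate = 1)
  pir <- day$readings[day$readings$channel == "pir", ]
  expect_equal(sum(pir$value), 0)
})

test_that("empirical PIR firing rates recover the configured probabilities", {
  # long-run Monte-Carlo check against the noise model: occupied rooms fire
  # at pir_hit_prob (always-moving specs), unoccupied rooms at
  # pir_false_prob, each within 3 standard errors
  noise <- sensor_noise_model(pir_hit_prob = 0.8, pir_false_prob = 0.02)
  layout <- tiny_layout()
  specs <- tiny_specs()
  rooms_of <- c(Cooking = "KITCHEN", Grooming = "BATHROOM",
                Sleeping = "BEDROOM")
  occ_fire <- occ_n <- un_fire <- un_n <- 0
  for (d in 0:199) {
    day <- simulate_day(layout, specs, noise, d, seed = 2024,
                        away_rate = 0)
    pir <- day$readings[day$readings$channel == "pir", ]
    tt <- 5 * (0:17279) + d * 86400
    occupied_room <- rep(NA_character_, 17280)
    for (i in seq_len(nrow(day$log))) {
      lab <- day$log$label[i]
      if (lab == "AWAY") next
      idx <- tt >= day$log$start_s[i] & tt < day$log$end_s[i]
      occupied_room[idx] <- rooms_of[[lab]]
    }
    moving <- !is.na(occupied_room) &
      occupied_room != "BEDROOM"  # Sleeping spec moves with prob < 1
    for (b in seq_len(nrow(layout$boxes))) {
      v <- pir$value[pir$box_id == layout$boxes$box_id[b]]
      room <- layout$boxes$room[b]
      occ <- moving & occupied_room == room
      un <- is.na(occupied_room) | occupied_room != room
      occ_fire <- occ_fire + sum(v[occ]); occ_n <- occ_n + sum(occ)
      un_fire <- un_fire + sum(v[un]); un_n <- un_n + sum(un)
    }
  }
  p_occ <- occ_fire / occ_n
  p_un <- un_fire / un_n
  expect_lt(abs(p_occ - 0.8), 3 * sqrt(0.8 * 0.2 / occ_n))
  expect_lt(abs(p_un - 0.02), 3 * sqrt(0.02 * 0.98 / un_n))
})

test_that("log plus away periods cover each day exactly without overlap", {
  home <- simulate_home(n_days = 3, seed = 31, overlap_prob = 0,
                        visitor_rate = 0)
  log <- home$log[order(home$log$start_s), ]
  expect_equal(log$start_s[1], 0)
  expect_equal(log$end_s[nrow(log)], 3 * 86400)
  expect_equal(log$start_s[-1], log$end_s[-nrow(log)])
  expect_true(all(log$end_s > log$start_s))
  expect_true(all(home$readings$time_s >= 0 &
                    home$readings$time_s < 3 * 86400))
})

test_that("overlap and visitor switches control the corresponding episodes", {
  plain <- simulate_home(n_days = 2, seed = 8, overlap_prob = 0,
                         visitor_rate = 0)
  expect_equal(sum(plain$log$visitor), 0)
  log <- plain$log[order(plain$log$start_s), ]
  expect_true(all(log$start_s[-1] >= log$end_s[-nrow(log)]))

  vis <- simulate_home(n_days = 6, seed = 8, overlap_prob = 0,
                       visitor_rate = 2)
  expect_gt(sum(vis$log$visitor), 0)

  ovl <- simulate_home(n_days = 8, seed = 8, overlap_prob = 0.9,
                       visitor_rate = 0)
  o <- ovl$log[order(ovl$log$start_s), ]
  overlaps <- any(o$start_s[-1] < o$end_s[-nrow(o)])
  expect_true(overlaps)
})

test_that("same-label log intervals never overlap", {
  home <- simulate_home(n_days = 6, seed = 13, overlap_prob = 0.8,
                        visitor_rate = 1)
  for (lab in unique(home$log$label)) {
    iv <- home$log[home$log$label == lab, ]
    iv <- iv[order(iv$start_s), ]
    if (nrow(iv) > 1L)
      expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)]),
                  label = paste("non-overlap for", lab))
  }
})

test_that("reading counts follow boxes x channels x ticks", {
  home <- cached_home(n_days = 1, seed = 7)
  n_channels <- sum(lengths(home$layout$boxes$channels))
  expect_equal(nrow(home$readings), n_channels * 86400 / 5)
  pir_boxes <- sum(vapply(home$layout$boxes$channels,
                          function(ch) "pir" %in% ch, TRUE))
  expect_equal(sum(home$readings$channel == "pir"),
               pir_boxes * 86400 / 5)
})

test_that("humidity and acceleration live on exactly one box each", {
  home <- cached_home(n_days = 1, seed = 7)
  hum_boxes <- unique(home$readings$box_id[home$readings$channel ==
                                             "humidity"])
  acc_boxes <- unique(home$readings$box_id[grepl("^accel",
                                                 home$readings$channel)])
  expect_length(hum_boxes, 1L)
  expect_length(acc_boxes, 1L)
  expect_equal(home$layout$boxes$room[home$layout$boxes$box_id == hum_boxes],
               "BATHROOM")
  acc_channels <- unique(home$readings$channel[home$readings$box_id ==
                                                 acc_boxes])
  expect_setequal(acc_channels, c("accel_x", "accel_y", "accel_z"))
})

test_that("PIR firing rate is highest in the activity's own room", {
  # the signal contract the whole pipeline rests on, checked empirically
  home <- cached_home(n_days = 1, seed = 7)
  grid <- cached_grid(n_days = 1, seed = 7)
  rooms_of <- c(Cooking = "KITCHEN", Grooming = "BATHROOM",
                Sleeping = "BEDROOM", Toileting = "BATHROOM",
                `Watching TV` = "TV_ROOM", `Seated activity` = "LIVING",
                Eating = "LIVING", `Get ready for bed` = "BATHROOM")
  pir_cols <- grep("_pir$", names(grid), value = TRUE)
  for (lab in intersect(names(rooms_of), unique(grid$truth_label))) {
    rows <- grid$truth_label == lab
    if (sum(rows) < 50) next
    rates <- vapply(pir_cols, function(cc) mean(grid[[cc]][rows]), 0)
    room_rate <- max(rates[startsWith(pir_cols,
                                      paste0(rooms_of[[lab]], "_"))])
    other_rate <- max(rates[!startsWith(pir_cols,
                                        paste0(rooms_of[[lab]], "_"))])
    expect_gt(room_rate, other_rate)
  }
})

test_that("datasets round-trip through write_dataset/read_dataset", {
  home <- simulate_home(n_days = 1, seed = 77, home_id = "rt",
                        visitor_rate = 0.5)
  dir <- withr::local_tempdir()
  paths <- write_dataset(home, dir)
  expect_true(all(file.exists(paths)))
  back <- read_dataset(dir, home_id = "rt")
  expect_equal(back$readings, home$readings)
  expect_equal(back$log, home$log)
  expect_equal(back$layout$rooms, home$layout$rooms)
  expect_equal(back$layout$boxes$channels, home$layout$boxes$channels)
  expect_equal(back$n_days, home$n_days)
})

test_that("an empty logbook writes a header-only file", {
  home <- simulate_home(n_days = 1, seed = 7, home_id = "e")
  home$log <- home$log[0, ]
  dir <- withr::local_tempdir()
  write_dataset(home, dir)
  lines <- readLines(file.path(dir, "logbook.csv"))
  expect_length(lines, 1L)
  back <- read_dataset(dir)
  expect_equal(nrow(back$log), 0L)
})
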