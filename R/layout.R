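# Domain vocabulary: homes, rooms, sensor boxes, ADL specifications and the
# sensor noise model used by the synthetic-home generator.

# Canonical channel order; constructors normalise channel sets to this order
# so that written datasets round-trip exactly.
CHANNELS <- c("pir", "temp", "lux", "humidity",
              "accel_x", "accel_y", "accel_z")

AWAY_LABEL <- "AWAY"
NONE_LABEL <- "NONE"
NO_ROOM <- "NONE"

#' The eight activity-of-daily-living labels
#'
#' Returns the eight ADL classes recognised by the pipeline, in canonical
#' report order (the order used in rendered metric tables).
#'
#' @return Character vector of length 8.
#' @export
adl_labels <- function() {
  c("Cooking", "Eating", "Get ready for bed", "Grooming",
    "Seated activity", "Sleeping", "Toileting", "Watching TV")
}

#' Describe a smart-home sensor installation
#'
#' A home layout lists the rooms of a flat (canonical room codes, shared
#' across homes so that models transfer) and the sensor boxes installed in
#' them, each with its set of measurement channels.
#'
#' @param rooms Character vector of unique room codes, e.g.
#'   `c("KITCHEN", "BATHROOM", ...)`. The order is canonical: it fixes the
#'   bit order of PIR-constellation tokens and all tie-breaks.
#' @param boxes data.frame with columns `box_id` (character, unique), `room`
#'   (must appear in `rooms`) and `channels` (list column of character
#'   vectors drawn from `r toString(CHANNELS)`).
#' @return An object of class `home_layout`.
#' @export
home_layout <- function(rooms, boxes) {
  stopifnot(is.character(rooms), length(rooms) > 0L)
  if (anyDuplicated(rooms)) stop("room codes must be unique")
  stopifnot(is.data.frame(boxes),
            all(c("box_id", "room", "channels") %in% names(boxes)))
  if (anyDuplicated(boxes$box_id)) stop("box ids must be unique")
  bad <- setdiff(boxes$room, rooms)
  if (length(bad) > 0L)
    stop("box room(s) not in room list: ", paste(bad, collapse = ", "))
  boxes$channels <- lapply(boxes$channels, function(ch) {
    unknown <- setdiff(ch, CHANNELS)
    if (length(unknown) > 0L)
      stop("unknown channel(s): ", paste(unknown, collapse = ", "))
    CHANNELS[CHANNELS %in% ch]
  })
  n_hum <- sum(vapply(boxes$channels, function(ch) "humidity" %in% ch, TRUE))
  n_acc <- sum(vapply(boxes$channels,
                      function(ch) any(grepl("^accel", ch)), TRUE))
  if (n_hum > 1L) stop("at most one box may carry the humidity channel")
  if (n_acc > 1L) stop("at most one box may carry acceleration channels")
  structure(list(rooms = rooms,
                 boxes = boxes,
                 bathroom_has_humidity = n_hum == 1L,
                 fridge_box_has_acceleration = n_acc == 1L),
            class = "home_layout")
}

#' Default six-room, eight-box layout
#'
#' One PIR/temperature/luminescence box per room, two in the living room
#' (one targeting the dining table, one the sofa), a humidity channel on the
#' bathroom box (flush-handle position) and a three-axis acceleration box on
#' the kitchen fridge door.
#'
#' @return A `home_layout`.
#' @export
default_home_layout <- function() {
  ptl <- c("pir", "temp", "lux")
  home_layout(
    rooms = c("KITCHEN", "BATHROOM", "BEDROOM", "LIVING", "TV_ROOM", "HALL"),
    boxes = data.frame(
      box_id = sprintf("box%02d", 1:8),
      room = c("KITCHEN", "BATHROOM", "BEDROOM", "LIVING", "LIVING",
               "TV_ROOM", "HALL", "KITCHEN"),
      channels = I(list(ptl, c(ptl, "humidity"), ptl, ptl, ptl, ptl, ptl,
                        c("accel_x", "accel_y", "accel_z")))
    )
  )
}

#' Specify one activity of daily living for the simulator
#'
#' @param label Activity name (one of [adl_labels()] for the default set,
#'   but any unique label is accepted).
#' @param room Room code in which the activity takes place.
#' @param duration_meanlog,duration_sdlog Log-normal duration parameters
#'   (seconds on the natural scale; `duration_sdlog > 0`).
#' @param windows List of numeric pairs `c(start_s, end_s)` of clock time
#'   (seconds since midnight, within `[0, 86400)`) in which the activity may
#'   start.
#' @param rate Mean occurrences per day; used as the relative draw weight
#'   among activities eligible at a given clock time.
#' @param movement_prob Probability that the occupant is moving (and so can
#'   trigger the room's PIR) in any 5-s sample during this activity.
#' @param box_id Optional preferred box within the room; PIR firings
#'   concentrate on this box (other boxes in the same room see attenuated
#'   motion), emulating e.g. a dining-table box versus a sofa box.
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(label, room, duration_meanlog, duration_sdlog,
                          windows, rate, movement_prob = 1, box_id = NA) {
  stopifnot(is.character(label), nchar(label) > 0L,
            duration_sdlog > 0, rate >= 0,
            movement_prob >= 0, movement_prob <= 1)
  for (w in windows) {
    if (length(w) != 2L || w[1] < 0 || w[1] >= 86400 ||
        w[2] <= w[1] || w[2] > 86400)
      stop("activity windows must lie within [00:00, 24:00)")
  }
  structure(list(label = label, room = room,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 windows = windows, rate = rate,
                 movement_prob = movement_prob, box_id = box_id),
            class = "activity_spec")
}

hours <- function(h) h * 3600

#' Default activity specifications
#'
#' Eight ADLs with realistic rooms, log-normal durations and times of day:
#' short frequent toileting, long nightly sleep (low movement), morning
#' grooming versus evening get-ready-for-bed in the bathroom, meals at meal
#' times on the dining-table box versus seated activity on the sofa box.
#'
#' @param layout Layout whose rooms/boxes the specs refer to; used to pick
#'   the two living-room boxes for eating versus seated activity.
#' @return Named list of [activity_spec()] objects.
#' @export
default_activity_specs <- function(layout = default_home_layout()) {
  living_boxes <- layout$boxes$box_id[layout$boxes$room == "LIVING" &
    vapply(layout$boxes$channels, function(ch) "pir" %in% ch, TRUE)]
  table_box <- if (length(living_boxes) >= 1L) living_boxes[1L] else NA
  sofa_box <- if (length(living_boxes) >= 2L) living_boxes[2L] else NA
  lp <- function(median_s, sdlog) list(meanlog = log(median_s), sdlog = sdlog)
  mk <- function(label, room, median_min, sdlog, windows, rate,
                 movement_prob = 1, box_id = NA) {
    p <- lp(median_min * 60, sdlog)
    activity_spec(label, room, p$meanlog, p$sdlog, windows, rate,
                  movement_prob, box_id)
  }
  specs <- list(
    mk("Cooking", "KITCHEN", 35, 0.4,
       list(c(hours(10.5), hours(13)), c(hours(17), hours(19.5))), 2),
    mk("Eating", "LIVING", 25, 0.35,
       list(c(hours(7), hours(9)), c(hours(12), hours(14)),
            c(hours(18.5), hours(20.5))), 3, box_id = table_box),
    mk("Get ready for bed", "BATHROOM", 12, 0.3,
       list(c(hours(20.5), hours(23.5))), 1),
    mk("Grooming", "BATHROOM", 20, 0.3,
       list(c(hours(6), hours(10))), 1),
    mk("Seated activity", "LIVING", 50, 0.5,
       list(c(0, 86400)), 2, box_id = sofa_box),
    mk("Sleeping", "BEDROOM", 7 * 60, 0.15,
       list(c(hours(21), 86400)), 1, movement_prob = 0.2),
    mk("Toileting", "BATHROOM", 3, 0.4,
       list(c(0, 86400)), 4),
    mk("Watching TV", "TV_ROOM", 90, 0.4,
       list(c(hours(17), hours(23))), 1.5)
  )
  names(specs) <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(names(specs))) stop("activity labels must be unique")
  specs
}

#' Sensor noise model for the synthetic home
#'
#' @param pir_hit_prob Probability a PIR sample fires while its room is
#'   occupied and the occupant moves.
#' @param pir_false_prob Probability of a spurious firing per 5-s sample in
#'   an unoccupied room. Must be below `pir_hit_prob`.
#' @param temp_base,temp_amplitude Daily temperature sinusoid (deg C),
#'   peaking mid-afternoon.
#' @param lux_day,lux_night Ambient illuminance levels (lx).
#' @param lamp_lux_bonus Added lx in an occupied room while the occupant is
#'   awake (lamp on).
#' @param humidity_base,humidity_shower_spike Bathroom absolute humidity
#'   (g/m^3): baseline and the added spike while (and shortly after)
#'   showering during grooming.
#' @param accel_idle Standard deviation of idle fridge-door acceleration
#'   noise (m/s^2).
#' @param accel_event_magnitude Acceleration of a fridge-door opening event
#'   (m/s^2); events occur sporadically while the kitchen is occupied.
#' @return An object of class `sensor_noise_model`.
#' @export
sensor_noise_model <- function(pir_hit_prob = 0.8, pir_false_prob = 5e-4,
                               temp_base = 21, temp_amplitude = 2,
                               lux_day = 300, lux_night = 5,
                               lamp_lux_bonus = 150,
                               humidity_base = 8, humidity_shower_spike = 6,
                               accel_idle = 0.05,
                               accel_event_magnitude = 2.5) {
  stopifnot(pir_hit_prob >= 0, pir_hit_prob <= 1,
            pir_false_prob >= 0, pir_false_prob <= 1)
  if (pir_hit_prob <= pir_false_prob)
    stop("pir_hit_prob must exceed pir_false_prob")
  structure(list(pir_hit_prob = pir_hit_prob,
                 pir_false_prob = pir_false_prob,
                 temp_base = temp_base, temp_amplitude = temp_amplitude,
                 lux_day = lux_day, lux_night = lux_night,
                 lamp_lux_bonus = lamp_lux_bonus,
                 humidity_base = humidity_base,
                 humidity_shower_spike = humidity_shower_spike,
                 accel_idle = accel_idle,
                 accel_event_magnitude = accel_event_magnitude),
            class = "sensor_noise_model")
}
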