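# Shared fixtures: minimal layouts, hand-built grids, and small simulated
# homes reused across test files.

# Three-room, PIR-only layout for fast Monte-Carlo checks.
tiny_layout <- function() {
  home_layout(
    rooms = c("KITCHEN", "BATHROOM", "BEDROOM"),
    boxes = data.frame(
      box_id = c("b1", "b2", "b3"),
      room = c("KITCHEN", "BATHROOM", "BEDROOM"),
      channels = I(list("pir", "pir", "pir"))
    )
  )
}

# Always-moving activity specs on the tiny layout (so occupied-room PIR
# firing rates equal the configured hit probability exactly).
tiny_specs <- function() {
  list(
    activity_spec("Cooking", "KITCHEN", log(1800), 0.3,
                  list(c(0, 86400)), 3),
    activity_spec("Grooming", "BATHROOM", log(1200), 0.3,
                  list(c(0, 86400)), 2),
    activity_spec("Sleeping", "BEDROOM", log(7 * 3600), 0.2,
                  list(c(hours(21), 86400)), 1)
  )
}

# Hand-built feature grid: n rows, given per-room PIR columns (a named list
# of 0/1 vectors), a constant temperature column, labels optional.
manual_grid <- function(pir, temp = NULL, truth = NULL) {
  n <- length(pir[[1L]])
  g <- data.frame(time_s = 5 * (seq_len(n) - 1L))
  for (room in names(pir)) g[[paste0(room, "_pir")]] <- pir[[room]]
  g$KITCHEN_temp <- if (is.null(temp)) rep(21, n) else temp
  g$weekday <- 0L
  g$truth_label <- if (is.null(truth)) rep("NONE", n) else truth
  g$truth_visitor <- 0L
  g
}

# A small cached simulated home (default layout) shared by the slower tests.
cached_home <- local({
  store <- new.env(parent = emptyenv())
  function(n_days = 1, seed = 7, visitor_rate = 0, overlap_prob = 0) {
    key <- paste(n_days, seed, visitor_rate, overlap_prob, sep = "_")
    if (is.null(store[[key]])) {
      store[[key]] <- simulate_home(n_days = n_days, seed = seed,
                                    visitor_rate = visitor_rate,
                                    overlap_prob = overlap_prob,
                                    home_id = paste0("h", seed))
    }
    store[[key]]
  }
})

cached_grid <- local({
  store <- new.env(parent = emptyenv())
  function(n_days = 1, seed = 7, visitor_rate = 0, overlap_prob = 0) {
    key <- paste(n_days, seed, visitor_rate, overlap_prob, sep = "_")
    if (is.null(store[[key]])) {
      store[[key]] <- preprocess_home(cached_home(n_days, seed,
                                                  visitor_rate,
                                                  overlap_prob))
    }
    store[[key]]
  }
})

# Independent brute-force oracle for the token change-point rule: a plain
# state-machine transcription, kept deliberately separate from the
# vectorised implementation it checks.
brute_force_changepoints <- function(tokens) {
  last_active <- NA_integer_
  cps <- integer(0)
  for (i in seq_along(tokens)) {
    if (tokens[i] != 0L) {
      if (!is.na(last_active) && tokens[i] != last_active)
        cps <- c(cps, i)
      last_active <- tokens[i]
    }
  }
  cps
}

# Independent brute-force confusion tally (per-element loop).
brute_force_confusion <- function(pred, truth, activity) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == activity
    t <- truth[i] == activity
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}
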