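# Small builders shared across the suite. Fixtures are constructed in code;
# nothing is read from disk except files the tests themselves write to
# tempdir().

toy_nest <- function(brood = rbind(c(40, 40), c(60, 50)),
                     pots = rbind(c(20, 80)),
                     bounds = c(xmin = 0, xmax = 100, ymin = 0, ymax = 100),
                     mm_per_px = 1) {
  nest_map(brood, pots, bounds, mm_per_px)
}

toy_segment <- function(df, video_id = "v1", frame_rate_hz = 1.5,
                        duration_s = 120) {
  video_segment(video_id = video_id, colony_id = "c1",
                duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                detections = df)
}

# straight-line track builder
track_df <- function(bee_id, frames, x, y) {
  data.frame(frame_index = frames, time_s = frames / 1.5, bee_id = bee_id,
             x_px = x, y_px = y, stringsAsFactors = FALSE)
}

# random multi-bee segment on the toy arena
random_segment <- function(n_bees = 4, n_frames = 10, seed = 1,
                           bounds = c(0, 100, 0, 100)) {
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(n_bees), function(b)
    track_df(sprintf("b%02d", b), 0:(n_frames - 1),
             runif(n_frames, bounds[1], bounds[2]),
             runif(n_frames, bounds[3], bounds[4]))))
  toy_segment(df)
}

# labelled activity sequences for a homogeneous two-state chain
simulate_chain <- function(n_frames, p_ai, p_ia, temp = 20, bee_id = "b1",
                           video_id = "v1") {
  state <- integer(n_frames)
  state[1] <- rbinom(1, 1, p_ia / (p_ai + p_ia))
  for (t in 2:n_frames) {
    state[t] <- if (state[t - 1] == 1) {
      if (runif(1) < p_ai) 0L else 1L
    } else {
      if (runif(1) < p_ia) 1L else 0L
    }
  }
  data.frame(bee_id = bee_id, video_id = video_id,
             frame_index = 0:(n_frames - 1),
             state = ifelse(state == 1, "active", "inactive"),
             body_temp_c = temp, stringsAsFactors = FALSE)
}

# small simulated colony reused by several test files (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_colony(sim_params(n_bees = 8, seed = 99))
    cache
  }
})
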