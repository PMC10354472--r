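# Synthetic colony generator: seeded trajectories, thermal stacks, probe
# logs and censuses with the statistical structure the analysis assumes,
# plus the ground truth needed for parameter-recovery tests.

#' True tracking-to-thermal warp specification
#'
#' The synthetic dual-camera geometry: an affine map (per-axis scale and
#' offset) plus a smooth sinusoidal perturbation, giving the registration
#' stage a non-trivial but recoverable target.
#'
#' @param sx,sy per-axis scale (thermal px per tracking px).
#' @param ox,oy offsets, thermal px.
#' @param amp_px sinusoid amplitude, thermal px.
#' @param period_px sinusoid period, tracking px.
#' @param phase radians.
#' @return list warp specification.
#' @export
default_warp_spec <- function(sx = 0.14, sy = 0.155, ox = 20, oy = 15,
                              amp_px = 3, period_px = 3500, phase = 0.7) {
  list(sx = sx, sy = sy, ox = ox, oy = oy, amp_px = amp_px,
       period_px = period_px, phase = phase)
}

#' Apply the true synthetic warp to tracking-pixel points
#' @param pts matrix/data.frame with two columns (x, y), tracking px.
#' @param warp a [default_warp_spec()] list.
#' @return matrix of thermal-pixel coordinates.
#' @export
warp_true <- function(pts, warp) {
  pts <- as.matrix(pts)
  cbind(warp$ox + warp$sx * pts[, 1] +
          warp$amp_px * sin(2 * pi * pts[, 2] / warp$period_px + warp$phase),
        warp$oy + warp$sy * pts[, 2] +
          warp$amp_px * cos(2 * pi * pts[, 1] / warp$period_px + warp$phase))
}

#' Simulation parameters
#'
#' Defaults describe a queenright colony of 16 workers imaged at 1.5 Hz in
#' 2-min clips every 9.5 min; `mode = "microcolony"` switches the cadence to
#' 20-s clips at 3.75 Hz every 2 min. Transition probabilities are per
#' frame. Kernel amplitudes/widths are in degrees C and thermal px; the
#' sensor model maps temperature to raw counts as
#' `counts = (T - sensor_offset) / sensor_gain + noise`.
#'
#' @param n_bees number of workers.
#' @param seed RNG seed; a fixed seed makes output bitwise reproducible.
#' @param mode `"queenright"` or `"microcolony"` (sets clip cadence).
#' @param imidacloprid logical, 10 ppb dietary arm.
#' @param p_ai_base active->inactive probability at warm body temperature.
#' @param p_ai_slope increase in p_ai per degree C of body temperature below
#'   24 C.
#' @param delta_ai_imid additive increase in p_ai under imidacloprid when
#'   body temperature < `t_thresh`.
#' @param t_thresh body-temperature threshold for the imidacloprid effect,
#'   degrees C.
#' @param p_ia_base inactive->active probability per frame.
#' @param thermotaxis_gain drift toward the brood centre of mass, tracking
#'   px per frame per degree C of air temperature below 24.
#' @param step_scale_px per-axis step s.d. of active bees, tracking px.
#' @param inactive_jitter_px per-axis tag-centroid jitter of inactive bees.
#' @param off_nest_frac fraction of workers starting off-nest (uniform over
#'   the arena) at baseline; the rest start on the nest.
#' @param body_heat_c,body_sigma_px per-bee local warming: Gaussian kernel
#'   amplitude (C) and s.d. (thermal px).
#' @param brood_heat_c,brood_sigma_px per-brood-item warming kernel.
#' @param sensor_gain,sensor_offset,sensor_noise_sd thermal camera model
#'   (C per count, C, counts).
#' @param thermal_width,thermal_height thermal frame size, px.
#' @param warp true camera geometry, see [default_warp_spec()].
#' @param growth named numeric Poisson growth-model coefficients
#'   (`b0`, `b_size`, `b_cold`, `b_imid`, `b_ci`, `b_3way`); linear
#'   predictor `b0 + b_size*log10(size) + b_cold*cold + b_imid*imid +
#'   b_ci*cold*imid + b_3way*cold*imid*log10(size) + block`.
#' @param block_sd s.d. of Gaussian block effects in the growth model.
#' @param clip_duration_s,clip_interval_min,frame_rate_hz video cadence.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_bees = 16L, seed = 1L, mode = "queenright",
                       imidacloprid = FALSE,
                       p_ai_base = 0.07, p_ai_slope = 0.015,
                       delta_ai_imid = 0.1, t_thresh = 18,
                       p_ia_base = 0.05,
                       thermotaxis_gain = 0.6, step_scale_px = 25,
                       inactive_jitter_px = 1.5, off_nest_frac = 0.4,
                       body_heat_c = 0.3, body_sigma_px = 25,
                       brood_heat_c = 0.6, brood_sigma_px = 60,
                       sensor_gain = 0.05, sensor_offset = -20,
                       sensor_noise_sd = 1.0,
                       thermal_width = 640L, thermal_height = 512L,
                       warp = default_warp_spec(),
                       growth = c(b0 = 2.0, b_size = 1.5, b_cold = -0.1,
                                  b_imid = -0.1, b_ci = -1.2, b_3way = 0.75),
                       block_sd = 0.2,
                       clip_duration_s = NULL, clip_interval_min = NULL,
                       frame_rate_hz = NULL) {
  mode <- match.arg(mode, c("queenright", "microcolony"))
  cadence <- if (mode == "queenright")
    list(dur = 120, int = 9.5, hz = 1.5) else list(dur = 20, int = 2, hz = 3.75)
  p <- list(n_bees = as.integer(n_bees), seed = as.integer(seed), mode = mode,
            imidacloprid = imidacloprid,
            p_ai_base = p_ai_base, p_ai_slope = p_ai_slope,
            delta_ai_imid = delta_ai_imid, t_thresh = t_thresh,
            p_ia_base = p_ia_base,
            thermotaxis_gain = thermotaxis_gain,
            step_scale_px = step_scale_px,
            inactive_jitter_px = inactive_jitter_px,
            off_nest_frac = off_nest_frac,
            body_heat_c = body_heat_c, body_sigma_px = body_sigma_px,
            brood_heat_c = brood_heat_c, brood_sigma_px = brood_sigma_px,
            sensor_gain = sensor_gain, sensor_offset = sensor_offset,
            sensor_noise_sd = sensor_noise_sd,
            thermal_width = as.integer(thermal_width),
            thermal_height = as.integer(thermal_height),
            warp = warp, growth = growth, block_sd = block_sd,
            clip_duration_s = clip_duration_s %||% cadence$dur,
            clip_interval_min = clip_interval_min %||% cadence$int,
            frame_rate_hz = frame_rate_hz %||% cadence$hz)
  probs <- c(p$p_ai_base, p$p_ia_base, p$delta_ai_imid)
  if (any(probs < 0 | probs > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (p$n_bees < 1L) stop("n_bees must be >= 1")
  class(p) <- "sim_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default synthetic nest map
#'
#' Arena of 4096 x 3000 tracking px at 0.0476 mm/px (a 19.5 x 13 cm growth
#' chamber). Brood items scale with colony size (worker:brood ratio 2:1,
#' minimum 2) and sit on a compact grid around the arena centre; four wax
#' pots sit on a ring outside the brood area.
#'
#' @param n_bees colony size (sets brood count).
#' @param n_pots number of wax pots.
#' @return A [nest_map()].
#' @export
make_default_nest <- function(n_bees = 16L, n_pots = 4L) {
  bounds <- c(xmin = 0, xmax = 4096, ymin = 0, ymax = 3000)
  centre <- c(2048, 1500)
  n_brood <- max(2L, round(n_bees / 2))
  # compact spiral grid, spacing ~165 tracking px
  k <- seq_len(n_brood) - 1L
  r <- 165 * sqrt(k)
  th <- k * 2.399963  # golden angle: even packing
  brood <- cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
  ang <- 2 * pi * (seq_len(n_pots) - 1L) / n_pots + 0.4
  pots <- cbind(centre[1] + 1300 * cos(ang), centre[2] + 1000 * sin(ang))
  nest_map(brood, pots, bounds, mm_per_px = 0.0476)
}

#' Simulate a tagged colony under a temperature protocol
#'
#' Runs the two-state (moving/stationary) agent-based model at frame cadence
#' over the full protocol and emits detections for the clips a tracking
#' camera would record. See [sim_params()] for the dynamics.
#'
#' @param params a [sim_params()].
#' @param protocol a [temperature_protocol()].
#' @param nest a [nest_map()] with at least one brood centroid.
#' @param colony_id identifier used in video and bee ids.
#' @param max_min optional observation cutoff, minutes: emit only clips
#'   starting before this time (trajectories are identical to the
#'   corresponding frames of a full-length run).
#' @return list of class `colony_sim` with elements `segments` (list of
#'   [video_segment()]), `truth` (data.frame aligned 1:1 with detections:
#'   true state, body temperature, per-frame true p_ai), and the inputs.
#' @export
simulate_colony <- function(params, protocol = make_queenright_protocol(),
                            nest = make_default_nest(params$n_bees),
                            colony_id = "c1", max_min = NULL) {
  stopifnot(inherits(params, "sim_params"),
            inherits(protocol, "temperature_protocol"))
  if (nrow(nest$brood) == 0L)
    stop("nest has no brood centroids: thermotaxis target undefined")
  set.seed(params$seed)
  fr <- params$frame_rate_hz
  total_min <- protocol_duration_min(protocol)
  # max_min shortens the observation window only: frames up to max_min are
  # identical to a full-length run (same RNG draw order)
  if (!is.null(max_min)) total_min <- min(total_min, max_min)
  n_frames <- floor(total_min * 60 * fr)
  t_s <- (seq_len(n_frames) - 1L) / fr
  t_air <- protocol_temperature(protocol, t_s / 60)

  clip_frames <- round(params$clip_duration_s * fr)
  clip_starts_s <- seq(0, total_min * 60 - params$clip_duration_s,
                       by = params$clip_interval_min * 60)
  emit <- rep(FALSE, n_frames)
  video_of <- rep(NA_integer_, n_frames)
  within_of <- rep(NA_integer_, n_frames)
  for (v in seq_along(clip_starts_s)) {
    i0 <- floor(clip_starts_s[v] * fr) + 1L
    idx <- i0:(i0 + clip_frames - 1L)
    emit[idx] <- TRUE
    video_of[idx] <- v
    within_of[idx] <- seq_along(idx) - 1L
  }

  com <- colMeans(nest$brood)
  b <- nest$bounds
  # baseline mix: most workers rest on the nest, a fraction sits off-nest
  # (as in real colonies at ambient temperature)
  sd0 <- 200 + 40 * sqrt(nrow(nest$brood))
  off <- stats::runif(params$n_bees) < params$off_nest_frac
  x0 <- ifelse(off, stats::runif(params$n_bees, b["xmin"], b["xmax"]),
               stats::rnorm(params$n_bees, com[1], sd0))
  y0 <- ifelse(off, stats::runif(params$n_bees, b["ymin"], b["ymax"]),
               stats::rnorm(params$n_bees, com[2], sd0))
  x0 <- pmin(pmax(x0, b["xmin"]), b["xmax"])
  y0 <- pmin(pmax(y0, b["ymin"]), b["ymax"])
  act0 <- params$p_ia_base / (params$p_ia_base + params$p_ai_base)
  s0 <- as.integer(stats::runif(params$n_bees) < act0)

  brood_th <- warp_true(nest$brood, params$warp)
  res <- sim_loop_cpp(x0, y0, s0, t_air, emit,
                      params$p_ai_base, params$p_ai_slope,
                      params$delta_ai_imid,
                      as.integer(isTRUE(params$imidacloprid)),
                      params$t_thresh, params$p_ia_base,
                      params$thermotaxis_gain, params$step_scale_px,
                      params$inactive_jitter_px,
                      params$body_heat_c, params$body_sigma_px,
                      params$brood_heat_c, params$brood_sigma_px,
                      brood_th[, 1], brood_th[, 2], com[1], com[2],
                      unlist(params$warp[c("sx", "sy", "ox", "oy", "amp_px",
                                           "period_px", "phase")]),
                      as.numeric(b))

  bee_ids <- sprintf("%s_bee%03d", colony_id, seq_len(params$n_bees))
  e_frames <- which(emit)
  n_emit <- length(e_frames)
  truth <- data.frame(
    video_id = rep(sprintf("%s_v%03d", colony_id, video_of[e_frames]),
                   times = params$n_bees),
    frame_index = rep(within_of[e_frames], times = params$n_bees),
    global_frame = rep(e_frames - 1L, times = params$n_bees),
    time_s = rep(t_s[e_frames], times = params$n_bees),
    t_air_c = rep(t_air[e_frames], times = params$n_bees),
    bee_id = rep(bee_ids, each = n_emit),
    x_px = as.vector(res$x), y_px = as.vector(res$y),
    state = as.vector(res$state),
    body_temp_c = as.vector(res$temp),
    p_ai_true = as.vector(res$p_ai),
    stringsAsFactors = FALSE)

  v_of_emit <- video_of[e_frames]
  w_of_emit <- within_of[e_frames]
  segments <- lapply(seq_along(clip_starts_s), function(v) {
    idx <- which(v_of_emit == v)
    video_segment(
      video_id = sprintf("%s_v%03d", colony_id, v),
      colony_id = colony_id,
      start_time = sprintf("2026-01-01T00:00:00Z+%.1fs", clip_starts_s[v]),
      duration_s = params$clip_duration_s, frame_rate_hz = fr,
      detections = data.frame(
        frame_index = rep(w_of_emit[idx], times = params$n_bees),
        time_s = rep(w_of_emit[idx] / fr, times = params$n_bees),
        bee_id = rep(bee_ids, each = length(idx)),
        x_px = as.vector(res$x[idx, , drop = FALSE]),
        y_px = as.vector(res$y[idx, , drop = FALSE]),
        stringsAsFactors = FALSE))
  })
  structure(list(segments = segments, truth = truth, params = params,
                 protocol = protocol, nest = nest, colony_id = colony_id),
            class = "colony_sim")
}

#' Evaluate the true thermal field at arbitrary thermal-pixel points
#'
#' `T(x, y) = ambient + brood_heat * sum K(brood) + body_heat * sum K(bees)`
#' with isotropic Gaussian kernels; heat sources only add, so the field
#' never drops below ambient.
#'
#' @param pts matrix of thermal-px points (columns x, y).
#' @param ambient_c air temperature.
#' @param bees_th matrix of bee positions in thermal px (may have 0 rows).
#' @param brood_th matrix of brood positions in thermal px.
#' @param params a [sim_params()].
#' @return numeric vector of temperatures.
#' @export
thermal_field_at <- function(pts, ambient_c, bees_th, brood_th, params) {
  pts <- as.matrix(pts)
  out <- rep(ambient_c, nrow(pts))
  add <- function(src, amp, sigma) {
    if (length(src) == 0L) return()
    for (k in seq_len(nrow(src))) {
      d2 <- (pts[, 1] - src[k, 1])^2 + (pts[, 2] - src[k, 2])^2
      out <<- out + amp * exp(-d2 / (2 * sigma^2))
    }
  }
  add(as.matrix(brood_th), params$brood_heat_c, params$brood_sigma_px)
  add(as.matrix(bees_th), params$body_heat_c, params$body_sigma_px)
  out
}

#' Default probe layout for synthetic thermal frames
#'
#' Mirrors the study geometry: one probe in the warm inner nest (at the
#' warped brood centre of mass when a nest map is given) and two in the
#' cooler periphery, so per-frame calibration sees a usable temperature
#' spread.
#'
#' @param width,height thermal frame size, px.
#' @param nest optional [nest_map()]; with `warp`, places probe p1 at the
#'   nest centre.
#' @param warp true warp spec (needed with `nest`).
#' @return data.frame of three probe annotations (0-based thermal px).
#' @export
default_probes <- function(width = 640L, height = 512L, nest = NULL,
                           warp = NULL) {
  p <- data.frame(probe_id = c("p1", "p2", "p3"),
                  x_px = c(0.5, 0.08, 0.92) * (width - 1),
                  y_px = c(0.5, 0.1, 0.85) * (height - 1))
  if (!is.null(nest) && !is.null(warp)) {
    com <- warp_true(matrix(colMeans(nest$brood), 1), warp)
    p$x_px[1] <- min(max(com[1], 0), width - 1)
    p$y_px[1] <- min(max(com[2], 0), height - 1)
  }
  p
}

#' Render synthetic thermal frames, probe logs and ground truth
#'
#' For each supplied frame of bee positions (tracking px), maps bees through
#' the true warp, evaluates the thermal field on the pixel grid and converts
#' it to raw sensor counts via the linear sensor model plus Gaussian count
#' noise. The probe log reports disc-mean true temperature at each probe
#' annotation (the probes are ground truth, mirroring internal calibration
#' against trusted in-nest sensors).
#'
#' @param positions list of n x 2 matrices of bee positions per frame,
#'   tracking px.
#' @param times_s numeric vector of frame times, seconds.
#' @param params a [sim_params()].
#' @param protocol a [temperature_protocol()] supplying the ambient air
#'   temperature at each frame time.
#' @param nest a [nest_map()].
#' @param probes probe annotation data.frame (thermal px); >= 2 required.
#' @param noise logical; FALSE renders noiseless counts.
#' @param probe_radius_px disc radius for probe readings (matches the
#'   calibration default).
#' @return list with `stack` (a [thermal_stack()] of count matrices, stored
#'   unrounded), `probe_log`, and `truth` (sensor gain/offset and true
#'   body temperature of each bee at each frame).
#' @export
render_thermal <- function(positions, times_s, params, protocol, nest,
                           probes = NULL, noise = TRUE,
                           probe_radius_px = 3) {
  stopifnot(length(positions) == length(times_s))
  if (is.null(probes))
    probes <- default_probes(params$thermal_width, params$thermal_height,
                             nest, params$warp)
  if (nrow(probes) < 2L) stop("need >= 2 probe annotations")
  w <- params$thermal_width; h <- params$thermal_height
  if (any(probes$x_px < 0 | probes$x_px > w - 1 |
          probes$y_px < 0 | probes$y_px > h - 1))
    stop("probe annotation outside frame")
  brood_th <- warp_true(nest$brood, params$warp)

  add_kernel <- function(field, cx, cy, amp, sigma) {
    r <- ceiling(4 * sigma)
    xi <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
    yi <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
    if (!length(xi) || !length(yi)) return(field)
    kx <- exp(-(xi - cx)^2 / (2 * sigma^2))
    ky <- exp(-(yi - cy)^2 / (2 * sigma^2))
    field[yi + 1L, xi + 1L] <- field[yi + 1L, xi + 1L] +
      amp * outer(ky, kx)
    field
  }

  frames <- vector("list", length(positions))
  body_truth <- vector("list", length(positions))
  probe_rows <- vector("list", length(positions))
  for (f in seq_along(positions)) {
    amb <- protocol_temperature(protocol, times_s[f] / 60)
    field <- matrix(amb, h, w)
    for (k in seq_len(nrow(brood_th)))
      field <- add_kernel(field, brood_th[k, 1], brood_th[k, 2],
                          params$brood_heat_c, params$brood_sigma_px)
    bees_th <- warp_true(positions[[f]], params$warp)
    for (k in seq_len(nrow(bees_th)))
      field <- add_kernel(field, bees_th[k, 1], bees_th[k, 2],
                          params$body_heat_c, params$body_sigma_px)
    counts <- (field - params$sensor_offset) / params$sensor_gain
    if (noise && params$sensor_noise_sd > 0)
      counts <- counts + stats::rnorm(length(counts),
                                      sd = params$sensor_noise_sd)
    frames[[f]] <- counts
    body_truth[[f]] <- data.frame(
      frame = f, bee = seq_len(nrow(bees_th)),
      body_temp_c = thermal_field_at(bees_th, amb, bees_th, brood_th,
                                     params))
    pt <- vapply(seq_len(nrow(probes)), function(p)
      disc_mean(field, probes$x_px[p], probes$y_px[p],
                probe_radius_px)$mean, numeric(1))
    probe_rows[[f]] <- data.frame(time_s = times_s[f],
                                  probe_id = probes$probe_id,
                                  temp_c = pt)
  }
  list(stack = thermal_stack(frames, times_s, probes),
       probe_log = do.call(rbind, probe_rows),
       truth = list(sensor_gain = params$sensor_gain,
                    sensor_offset = params$sensor_offset,
                    warp = params$warp,
                    body_temps = do.call(rbind, body_truth)))
}

#' Simulate final-census colony productivity
#'
#' Total productivity is Poisson with log-linear predictor
#' `b0 + b_size*log10(size) + b_cold*cold + b_imid*imid + b_ci*cold*imid +
#' b_3way*cold*imid*log10(size) + block`, with Gaussian block effects. The
#' two-way `b_ci` plus positive `b_3way` reproduce the pattern of combined
#' cold and imidacloprid stress hitting small colonies hardest.
#'
#' @param params a [sim_params()] (supplies `growth` and `block_sd`).
#' @param meta data.frame with `colony_id`, `cold`, `imidacloprid`,
#'   `colony_size_at_treatment`, `block_id` (see [colony_meta()]).
#' @param seed RNG seed.
#' @return census data.frame with attribute `"truth"` holding the
#'   generating coefficients and block effects.
#' @export
simulate_census <- function(params, meta, seed = params$seed) {
  g <- params$growth
  if (any(!is.finite(g))) stop("growth coefficients must be finite")
  set.seed(seed)
  blocks <- sort(unique(meta$block_id))
  block_eff <- stats::rnorm(length(blocks), 0, params$block_sd)
  names(block_eff) <- blocks
  L <- log10(meta$colony_size_at_treatment)
  cold <- as.numeric(meta$cold); imid <- as.numeric(meta$imidacloprid)
  lp <- g["b0"] + g["b_size"] * L + g["b_cold"] * cold + g["b_imid"] * imid +
    g["b_ci"] * cold * imid + g["b_3way"] * cold * imid * L +
    block_eff[meta$block_id]
  if (any(lp > 30))
    stop("Poisson rate overflow; linear predictor = ",
         max(lp), " at row ", which.max(lp))
  census <- data.frame(colony_id = meta$colony_id,
                       total_productivity = stats::rpois(nrow(meta), exp(lp)),
                       days_to_census = 41L,
                       stringsAsFactors = FALSE)
  attr(census, "truth") <- list(growth = g, block_effects = block_eff)
  census
}

#' Pooled frame-wise speeds of a simulated colony
#'
#' Convenience for threshold estimation: frame-wise speeds of every bee in
#' every emitted clip, pooled at the colony level.
#'
#' @param sim a `colony_sim`.
#' @param max_gap largest bridged detection gap, frames.
#' @return numeric vector of speeds, px/frame.
#' @export
pooled_speeds <- function(sim, max_gap = 3) {
  unlist(lapply(sim$segments, function(s)
    unlist(lapply(split(s$detections, s$detections$bee_id), function(tr)
      frame_speeds(tr, max_gap)$speed_px_frame))), use.names = FALSE)
}

#' Activity sequences of a simulated colony
#'
#' Builds per-bee activity sequences (with true body temperatures attached)
#' either by labelling trajectories through the speed threshold — the full
#' measurement path — or directly from the generator's true states.
#'
#' @param sim a `colony_sim`.
#' @param threshold activity threshold (px/frame); NULL estimates it from
#'   [pooled_speeds()] via [activity_threshold()]. Ignored for
#'   `states = "truth"`.
#' @param states `"labelled"` (speed-threshold labelling) or `"truth"`.
#' @param max_gap largest bridged gap, frames.
#' @return stacked data.frame of sequences (`bee_id`, `video_id`,
#'   `frame_index`, `state`, `body_temp_c`).
#' @export
sim_activity_sequences <- function(sim, threshold = NULL,
                                   states = c("labelled", "truth"),
                                   max_gap = 3) {
  states <- match.arg(states)
  tr <- sim$truth
  if (states == "truth") {
    out <- tr[, c("bee_id", "video_id", "frame_index")]
    out$state <- ifelse(tr$state == 1, "active", "inactive")
    out$body_temp_c <- tr$body_temp_c
    return(out)
  }
  if (is.null(threshold))
    threshold <- activity_threshold(pooled_speeds(sim, max_gap))$threshold
  sq <- do.call(rbind, lapply(sim$segments, function(s) {
    do.call(rbind, lapply(split(s$detections, s$detections$bee_id),
                          function(x) {
      l <- label_states(x, threshold, max_gap)
      l$video_id <- s$video_id
      l
    }))
  }))
  key <- paste(sq$video_id, sq$frame_index, sq$bee_id)
  tkey <- paste(tr$video_id, tr$frame_index, tr$bee_id)
  sq$body_temp_c <- tr$body_temp_c[match(key, tkey)]
  rownames(sq) <- NULL
  sq
}
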