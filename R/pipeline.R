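# One-command orchestration: simulate (or ingest) -> thermal -> metrics ->
# centrality -> markov -> stats -> report, config-driven and seeded.

pipeline_config_schema <- list(
  top = c("mode", "seed", "synthetic", "ingest", "thermal", "metrics",
          "markov", "census"),
  synthetic = c("n_bees", "mode", "arms", "delta_ai_imid"),
  ingest = c("data_dir", "schema_mode"),
  thermal = c("enabled", "frame_stride", "n_control_points"),
  metrics = c("bin_size_mm", "contact_threshold_mm", "max_gap"),
  markov = c("temp_lo", "temp_hi", "temp_by", "min_count", "t_thresh"),
  census = c("enabled", "n_colonies")
)

#' Build and validate a pipeline configuration
#'
#' Accepts a JSON file path or a nested list; unknown keys anywhere are
#' rejected before any stage runs. Tables and maps use the package's CSV and
#' JSON formats throughout (the deployment environment has no YAML parser,
#' so configuration is JSON).
#'
#' @param config path to a JSON config or a list.
#' @return validated config list of class `pipeline_config`, with defaults
#'   filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  sch <- pipeline_config_schema
  unknown <- setdiff(names(config), sch$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(sch)[-1])) {
    bad <- setdiff(names(config[[sec]]), sch[[sec]])
    if (length(bad))
      stop("unknown key(s) in config$", sec, ": ",
           paste(bad, collapse = ", "))
  }
  defaults <- list(
    mode = "synthetic", seed = 1L,
    synthetic = list(n_bees = 8L, mode = "queenright",
                     arms = c("control", "imidacloprid"),
                     delta_ai_imid = 0.1),
    ingest = list(data_dir = NULL, schema_mode = "queenright"),
    thermal = list(enabled = FALSE, frame_stride = 25L,
                   n_control_points = 25L),
    metrics = list(bin_size_mm = 20, contact_threshold_mm = 10, max_gap = 3),
    markov = list(temp_lo = 10, temp_hi = 30, temp_by = 2, min_count = 50,
                  t_thresh = 18),
    census = list(enabled = TRUE, n_colonies = 40L))
  out <- utils::modifyList(defaults, config)
  out$mode <- match.arg(out$mode, c("synthetic", "ingest"))
  if (out$mode == "ingest" && is.null(out$ingest$data_dir))
    stop("ingest mode needs ingest$data_dir")
  class(out) <- "pipeline_config"
  out
}

#' Write a simulated colony as a dataset directory
#'
#' Emits detections.csv, nest_map.json and ground_truth.csv in the
#' package's interchange layout; optionally a thermal stack + probe log.
#'
#' @param sim a `colony_sim` from [simulate_colony()].
#' @param dir output directory (created).
#' @param thermal optional output of [render_thermal()] to include.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, thermal = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_detections(sim$segments, file.path(dir, "detections.csv"))
  write_nest_map(sim$nest, file.path(dir, "nest_map.json"))
  utils::write.csv(format(sim$truth, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(thermal)) {
    write_thermal_stack(thermal$stack, file.path(dir, "thermal_stack.tif"))
    write_probe_log(thermal$probe_log, file.path(dir, "probe_log.csv"))
  }
  invisible(dir)
}

arm_sim <- function(cfg, arm, arm_index) {
  params <- sim_params(n_bees = cfg$synthetic$n_bees,
                       seed = cfg$seed * 1000L + arm_index,
                       mode = cfg$synthetic$mode,
                       imidacloprid = (arm == "imidacloprid"),
                       delta_ai_imid = cfg$synthetic$delta_ai_imid)
  protocol <- if (cfg$synthetic$mode == "queenright")
    make_queenright_protocol() else make_microcolony_protocol()
  simulate_colony(params, protocol, make_default_nest(params$n_bees),
                  colony_id = arm)
}

sim_body_temps <- function(cfg, sim) {
  if (!isTRUE(cfg$thermal$enabled)) {
    # ground-truth body temperatures pass straight through
    return(sim$truth[, c("video_id", "frame_index", "bee_id",
                         "body_temp_c")])
  }
  tr <- sim$truth
  frames <- unique(tr[, c("video_id", "frame_index", "global_frame",
                          "time_s")])
  frames <- frames[order(frames$global_frame), ]
  frames <- frames[seq(1, nrow(frames), by = cfg$thermal$frame_stride), ]
  pos <- lapply(seq_len(nrow(frames)), function(i) {
    sel <- tr[tr$global_frame == frames$global_frame[i], ]
    as.matrix(sel[order(sel$bee_id), c("x_px", "y_px")])
  })
  th <- render_thermal(pos, frames$time_s, sim$params, sim$protocol,
                       sim$nest)
  cal <- calibrate_stack(th$stack, th$probe_log)
  ctrl <- registration_points(sim$nest, sim$params$warp,
                              n = cfg$thermal$n_control_points)
  warp <- fit_warp(ctrl)
  rows <- list()
  for (i in seq_len(nrow(frames))) {
    sel <- tr[tr$global_frame == frames$global_frame[i], ]
    sel <- sel[order(sel$bee_id), ]
    bt <- extract_body_temp(cal$frames_c[[i]],
                            data.frame(bee_id = sel$bee_id,
                                       frame_index = sel$frame_index,
                                       x_px = sel$x_px, y_px = sel$y_px),
                            warp)
    bt$video_id <- sel$video_id
    rows[[i]] <- bt
  }
  bt <- do.call(rbind, rows)
  data.frame(video_id = bt$video_id, frame_index = bt$frame_index,
             bee_id = bt$bee_id, body_temp_c = bt$temp_c)
}

#' Synthetic calibration-point pairs for registration
#'
#' Stands in for the manually annotated calibration coordinates: a regular
#' grid over the arena mapped through the true warp.
#'
#' @param nest a [nest_map()].
#' @param warp true warp spec.
#' @param n approximate number of pairs (rounded to a square grid).
#' @return data.frame with `x_tr`, `y_tr`, `x_th`, `y_th`.
#' @export
registration_points <- function(nest, warp, n = 25) {
  k <- max(2L, round(sqrt(n)))
  b <- nest$bounds
  g <- expand.grid(x_tr = seq(b["xmin"], b["xmax"], length.out = k),
                   y_tr = seq(b["ymin"], b["ymax"], length.out = k))
  th <- warp_true(g, warp)
  data.frame(g, x_th = th[, 1], y_th = th[, 2])
}

attach_body_temps <- function(sequences, body_temps) {
  key <- paste(sequences$video_id, sequences$frame_index, sequences$bee_id)
  bkey <- paste(body_temps$video_id, body_temps$frame_index,
                body_temps$bee_id)
  sequences$body_temp_c <- body_temps$body_temp_c[match(key, bkey)]
  sequences
}

stage_msg <- function(name, ...) {
  message(sprintf("[nestwatch:%s] %s", name, sprintf(...)))
}

#' Run the full pipeline
#'
#' Synthetic mode simulates one colony per treatment arm under the
#' configured protocol, then runs thermal extraction (or passes ground-truth
#' body temperatures through when `thermal$enabled` is FALSE), behavioural
#' metrics, centrality scoring, Markov transition estimation with the
#' control-vs-imidacloprid contrast, and the simulated-census productivity
#' model. Ingest mode runs the behavioural stages on a dataset directory.
#' All outputs are CSV/JSON in `out_dir`, with a manifest of input hashes,
#' seed and versions; a fixed seed reproduces every file byte-identically.
#'
#' @param config a [pipeline_config()] (or list/path accepted by it).
#' @param out_dir report directory (created).
#' @return list of stage outputs, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  written <- character()
  emit <- function(obj, file, writer = utils::write.csv) {
    p <- file.path(out_dir, file)
    if (identical(writer, utils::write.csv))
      utils::write.csv(format(obj, digits = 15, trim = TRUE,
                              scientific = FALSE), p,
                       row.names = FALSE, quote = FALSE)
    else writer(obj, p)
    written <<- c(written, p)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (cfg$mode == "synthetic") {
    arms <- cfg$synthetic$arms
    sims <- run_stage("simulate", {
      out <- lapply(seq_along(arms), function(i) arm_sim(cfg, arms[i], i))
      names(out) <- arms
      out
    })
    stage_msg("simulate", "%d arms x %d bees, %d segments each",
              length(arms), cfg$synthetic$n_bees,
              length(sims[[1]]$segments))
    nest <- sims[[1]]$nest
    body_temps <- run_stage("thermal",
                            lapply(sims, function(s) sim_body_temps(cfg, s)))
    metrics <- run_stage("metrics", {
      lapply(arms, function(a) {
        m <- compute_behaviour_table(
          sims[[a]]$segments, nest,
          bin_size_mm = cfg$metrics$bin_size_mm,
          contact_threshold_mm = cfg$metrics$contact_threshold_mm,
          max_gap = cfg$metrics$max_gap)
        m$arm <- a
        m
      })
    })
    names(metrics) <- arms
    all_metrics <- do.call(rbind, metrics)
    emit(all_metrics, "behaviour.csv")
    model <- run_stage("centrality",
                       centrality_model(all_metrics, "queenright_11"))
    scores <- run_stage("centrality", {
      s <- score_centrality(all_metrics, model)
      s$arm <- all_metrics$arm
      # per-video air temperature for reporting
      tmap <- unique(do.call(rbind, lapply(sims, function(x)
        x$truth[, c("video_id", "t_air_c")])))
      agg <- stats::aggregate(t_air_c ~ video_id, tmap, mean)
      s$t_air_c <- agg$t_air_c[match(s$video_id, agg$video_id)]
      s
    })
    emit(scores, "centrality_scores.csv")
    stage_msg("centrality", "PC1 explains %.1f%% of variance",
              100 * model$var_explained[1])

    bins <- seq(cfg$markov$temp_lo, cfg$markov$temp_hi,
                by = cfg$markov$temp_by)
    thr <- attr(all_metrics, "threshold")$threshold
    seqs <- run_stage("markov", {
      out <- lapply(arms, function(a) {
        sq <- do.call(rbind, lapply(sims[[a]]$segments, function(s) {
          do.call(rbind, lapply(split(s$detections, s$detections$bee_id),
                                function(tr) {
            l <- label_states(tr, thr, cfg$metrics$max_gap)
            l$video_id <- s$video_id
            l
          }))
        }))
        attach_body_temps(sq, body_temps[[a]])
      })
      names(out) <- arms
      out
    })
    transitions <- do.call(rbind, lapply(arms, function(a)
      estimate_transitions(seqs[[a]], bins, arm = a,
                           min_count = cfg$markov$min_count)))
    emit(transitions, "transitions.csv")
    if (all(c("control", "imidacloprid") %in% arms)) {
      contrast <- run_stage("markov",
        arm_contrast(seqs[["control"]], seqs[["imidacloprid"]], bins,
                     t_thresh = cfg$markov$t_thresh,
                     min_count = cfg$markov$min_count))
      emit(contrast, "arm_contrast.json",
           function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                               digits = NA))
      outputs$contrast <- contrast
    }
    if (isTRUE(cfg$census$enabled)) {
      prod <- run_stage("stats", {
        n <- cfg$census$n_colonies
        set.seed(cfg$seed + 77L)
        meta <- do.call(rbind, lapply(seq_len(n), function(i)
          colony_meta(sprintf("col%02d", i),
                      imidacloprid = i %% 2 == 0, cold = (i %/% 2) %% 2 == 0,
                      colony_size_at_treatment =
                        round(10^stats::runif(1, log10(2), log10(40))),
                      block_id = sprintf("b%d", 1 + i %% 4))))
        census <- simulate_census(sims[[1]]$params, meta,
                                  seed = cfg$seed + 78L)
        productivity_analysis(census, meta)
      })
      emit(prod$predictions, "productivity_predictions.csv")
      outputs$productivity <- prod
    }
    outputs <- c(outputs, list(sims = sims, metrics = all_metrics,
                               model = model, scores = scores,
                               transitions = transitions))
  } else {
    dd <- cfg$ingest$data_dir
    segs <- run_stage("ingest",
                      read_detections(file.path(dd, "detections.csv"),
                                      cfg$ingest$schema_mode))
    nest <- run_stage("ingest",
                      read_nest_map(file.path(dd, "nest_map.json")))
    metrics <- run_stage("metrics", compute_behaviour_table(
      segs, nest, bin_size_mm = cfg$metrics$bin_size_mm,
      contact_threshold_mm = cfg$metrics$contact_threshold_mm,
      max_gap = cfg$metrics$max_gap))
    emit(metrics, "behaviour.csv")
    model <- run_stage("centrality",
                       centrality_model(metrics, "queenright_11"))
    scores <- run_stage("centrality", score_centrality(metrics, model))
    emit(scores, "centrality_scores.csv")
    outputs <- list(segments = segs, metrics = metrics, model = model,
                    scores = scores)
  }

  manifest <- list(
    package = "nestwatch",
    version = as.character(utils::packageVersion("nestwatch")),
    seed = cfg$seed, mode = cfg$mode,
    config = unclass(cfg),
    files = lapply(sort(written), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outputs)
}
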