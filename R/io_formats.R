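# Readers and writers for the pipeline's tabular formats.
#
# Conventions (stated in every file header comment this package writes):
# pixel coordinates are 0-based, origin top-left, x rightward, y downward;
# time is seconds from video start; tables are UTF-8 CSV with "." decimal.

DETECTION_COLS <- c("frame_index", "time_s", "bee_id", "x_px", "y_px")

#' Construct a video segment
#'
#' A video segment is the analysis unit: one short clip of one colony, with
#' all tag detections recorded in it.
#'
#' @param video_id,colony_id identifiers.
#' @param start_time absolute start timestamp (ISO-8601 string) or NA.
#' @param duration_s clip duration, seconds.
#' @param frame_rate_hz nominal frame rate, Hz (> 0).
#' @param detections data.frame with columns `frame_index`, `time_s`,
#'   `bee_id`, `x_px`, `y_px`.
#' @return An object of class `video_segment`.
#' @export
video_segment <- function(video_id, colony_id = NA_character_,
                          start_time = NA_character_,
                          duration_s, frame_rate_hz, detections) {
  stopifnot(is.data.frame(detections),
            all(DETECTION_COLS %in% names(detections)))
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  detections <- detections[order(detections$bee_id, detections$frame_index),
                           DETECTION_COLS]
  rownames(detections) <- NULL
  structure(list(video_id = as.character(video_id),
                 colony_id = as.character(colony_id),
                 start_time = start_time,
                 duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz,
                 detections = detections),
            class = "video_segment")
}

#' @export
print.video_segment <- function(x, ...) {
  cat(sprintf("<video_segment %s: %d detections, %d bees, %.0f s @ %.2f Hz>\n",
              x$video_id, nrow(x$detections),
              length(unique(x$detections$bee_id)),
              x$duration_s, x$frame_rate_hz))
  invisible(x)
}

schema_defaults <- function(schema_mode) {
  switch(schema_mode,
         queenright  = list(duration_s = 120, frame_rate_hz = 1.5),
         microcolony = list(duration_s = 20,  frame_rate_hz = 3.75),
         stop("schema_mode must be 'queenright' or 'microcolony'"))
}

#' Read a detection table into video segments
#'
#' The file is a CSV whose header names the five detection fields
#' (`frame_index`, `time_s`, `bee_id`, `x_px`, `y_px`) plus `video_id`;
#' optional columns `colony_id`, `start_time`, `duration_s`, `frame_rate_hz`
#' carry segment metadata (constant within a video). Rows violating the
#' detection invariants are rejected and logged, never silently dropped:
#' rows in = rows kept + rows rejected. Duplicate (bee, frame) pairs keep
#' the first occurrence.
#'
#' @param path CSV file path.
#' @param schema_mode `"queenright"` (2-min clips, ~1.5 Hz) or
#'   `"microcolony"` (20-s clips, ~3.75 Hz); supplies defaults for missing
#'   segment metadata.
#' @return A list of `video_segment`; attribute `"log"` holds a data.frame
#'   of rejected rows with reasons.
#' @export
read_detections <- function(path, schema_mode = "queenright") {
  defaults <- schema_defaults(schema_mode)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("video_id", DETECTION_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("detection file is missing required column(s): ",
         paste(missing, collapse = ", "))
  log <- data.frame(row = integer(), reason = character())
  if (nrow(df) == 0L) {
    warning("empty detection file: ", path)
    out <- list()
    attr(out, "log") <- log
    return(out)
  }
  bad <- !is.finite(df$frame_index) | df$frame_index < 0 |
    !is.finite(df$x_px) | !is.finite(df$y_px) | !is.finite(df$time_s)
  if (any(bad)) {
    log <- rbind(log, data.frame(row = which(bad),
                                 reason = "non-finite or negative field"))
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df[, c("video_id", "bee_id", "frame_index")])
  if (any(dup)) {
    log <- rbind(log, data.frame(row = which(dup),
                                 reason = "duplicate (bee, frame); kept first"))
    warning(sum(dup), " duplicate (bee, frame) row(s) dropped (kept first)")
    df <- df[!dup, , drop = FALSE]
  }
  segs <- lapply(split(df, df$video_id), function(d) {
    video_segment(
      video_id = d$video_id[1L],
      colony_id = if ("colony_id" %in% names(d)) d$colony_id[1L] else NA,
      start_time = if ("start_time" %in% names(d)) d$start_time[1L] else NA,
      duration_s = if ("duration_s" %in% names(d)) d$duration_s[1L]
                   else defaults$duration_s,
      frame_rate_hz = if ("frame_rate_hz" %in% names(d)) d$frame_rate_hz[1L]
                      else defaults$frame_rate_hz,
      detections = d[, DETECTION_COLS])
  })
  out <- unname(segs[order(names(segs))])
  attr(out, "log") <- log
  out
}

#' Write video segments to a detection CSV
#'
#' Inverse of [read_detections()]; round-trips all detection fields exactly
#' (full double precision).
#'
#' @param segments list of `video_segment`.
#' @param path output CSV path.
#' @export
write_detections <- function(segments, path) {
  rows <- lapply(segments, function(s) {
    cbind(data.frame(video_id = s$video_id, colony_id = s$colony_id,
                     start_time = s$start_time, duration_s = s$duration_s,
                     frame_rate_hz = s$frame_rate_hz),
          s$detections)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("# detections: 0-based pixel coords, origin top-left;",
                   "time_s from video start"), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a nest map
#'
#' Locations of brood items and wax pots in tracking-camera pixels, plus the
#' arena bounding box and the physical scale.
#'
#' @param brood matrix/data.frame with columns x_px, y_px (may have 0 rows).
#' @param pots same layout as `brood`.
#' @param bounds named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @param mm_per_px positive physical scale.
#' @return An object of class `nest_map`.
#' @export
nest_map <- function(brood, pots, bounds, mm_per_px) {
  as_xy <- function(m) {
    m <- as.matrix(m)
    if (length(m) == 0L) return(matrix(numeric(), 0, 2,
                                       dimnames = list(NULL, c("x_px", "y_px"))))
    if (ncol(m) != 2L) stop("centroids need two columns (x_px, y_px)")
    colnames(m) <- c("x_px", "y_px")
    m
  }
  brood <- as_xy(brood); pots <- as_xy(pots)
  bounds <- as.numeric(bounds[c("xmin", "xmax", "ymin", "ymax")])
  names(bounds) <- c("xmin", "xmax", "ymin", "ymax")
  if (any(!is.finite(bounds)) || bounds["xmax"] <= bounds["xmin"] ||
      bounds["ymax"] <= bounds["ymin"]) stop("invalid arena bounds")
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    stop("mm_per_px must be a positive scale")
  inside <- function(m) {
    nrow(m) == 0L ||
      all(m[, 1] >= bounds["xmin"] & m[, 1] <= bounds["xmax"] &
          m[, 2] >= bounds["ymin"] & m[, 2] <= bounds["ymax"])
  }
  if (!inside(brood) || !inside(pots))
    stop("centroid outside arena bounds")
  structure(list(brood = brood, pots = pots, bounds = bounds,
                 mm_per_px = mm_per_px),
            class = "nest_map")
}

#' Read a nest map from JSON
#' @param path JSON file with fields `brood`, `pots`, `bounds`, `mm_per_px`.
#' @return A `nest_map`.
#' @export
read_nest_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("brood", "pots", "bounds", "mm_per_px"))
    if (is.null(j[[f]])) stop("nest map missing field: ", f)
  to_mat <- function(x) {
    if (length(x) == 0L) matrix(numeric(), 0, 2) else
      matrix(as.numeric(unlist(x)), ncol = 2, byrow = !is.matrix(x))
  }
  b <- if (is.matrix(j$brood)) j$brood else to_mat(j$brood)
  p <- if (is.matrix(j$pots)) j$pots else to_mat(j$pots)
  nest_map(b, p, unlist(j$bounds), j$mm_per_px)
}

#' Write a nest map to JSON
#' @param nest a `nest_map`.
#' @param path output path.
#' @export
write_nest_map <- function(nest, path) {
  jsonlite::write_json(
    list(comment = "0-based pixel coords, origin top-left, x right, y down",
         brood = unname(apply(nest$brood, 1, as.numeric, simplify = FALSE)),
         pots = unname(apply(nest$pots, 1, as.numeric, simplify = FALSE)),
         bounds = as.list(nest$bounds),
         mm_per_px = nest$mm_per_px),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

BEHAVIOUR_SCHEMA_VERSION <- "1"

#' The eleven headline behavioural metrics, in export order
#' @return Character vector of column names.
#' @export
behaviour_metric_names <- function() {
  c("brood_interaction_rate", "pot_interaction_rate",
    "mean_spatial_correlation", "mean_contact_rate", "degree_centrality",
    "moving_speed", "distance_to_centre", "median_dist_all_brood",
    "median_dist_all_pots", "min_dist_closest_brood", "min_dist_closest_pot")
}

#' Write a behaviour table
#'
#' One row per (bee, video); deterministic column order; values re-readable
#' losslessly to better than 1e-9.
#'
#' @param records data.frame with columns `bee_id`, `video_id`, the eleven
#'   metrics of [behaviour_metric_names()], and any extra columns (e.g.
#'   `activity_fraction`), all sharing one schema.
#' @param path output CSV path.
#' @export
write_behaviour_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  lead <- c("bee_id", "video_id")
  if (nrow(records) > 0 && !all(lead %in% names(records)))
    stop("behaviour records need bee_id and video_id")
  known <- intersect(c(lead, behaviour_metric_names()), names(records))
  extra <- setdiff(names(records), known)
  df <- records[, c(known, extra), drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# behaviour table v%s; 0-based px coords; NA = missing",
                     BEHAVIOUR_SCHEMA_VERSION), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behaviour table written by [write_behaviour_table()]
#' @param path CSV path.
#' @return data.frame of records.
#' @export
read_behaviour_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a probe temperature log
#'
#' @param path CSV with columns `time_s`, `probe_id`, `temp_c` (readings
#'   roughly every 20 s).
#' @return data.frame ordered by probe then time.
#' @export
read_probe_log <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "probe_id", "temp_c")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("probe log missing column(s): ", paste(missing, collapse = ", "))
  df[order(df$probe_id, df$time_s), need]
}

#' Write a probe temperature log
#' @param log data.frame with `time_s`, `probe_id`, `temp_c`.
#' @param path output CSV path.
#' @export
write_probe_log <- function(log, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# probe log: temp_c at time_s (s from video start)", con)
  utils::write.csv(format(log, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct colony metadata
#'
#' @param colony_id identifier.
#' @param species species label.
#' @param imidacloprid logical: 10 ppb dietary imidacloprid arm.
#' @param cold logical: cold-stress arm.
#' @param colony_size_at_treatment positive integer.
#' @param block_id experimental block.
#' @return One-row data.frame with an `arm` factor column
#'   (control/cold/imidacloprid/combined).
#' @export
colony_meta <- function(colony_id, species = "B. impatiens",
                        imidacloprid, cold, colony_size_at_treatment,
                        block_id = "1") {
  stopifnot(is.logical(imidacloprid), is.logical(cold),
            colony_size_at_treatment >= 1)
  arm <- c("control", "cold", "imidacloprid", "combined")[
    1L + cold + 2L * imidacloprid]
  data.frame(colony_id = as.character(colony_id), species = species,
             imidacloprid = imidacloprid, cold = cold,
             colony_size_at_treatment = as.integer(colony_size_at_treatment),
             block_id = as.character(block_id), arm = arm,
             stringsAsFactors = FALSE)
}

#' Read / write census records
#'
#' Census CSV columns: `colony_id`, `total_productivity` (workers plus
#' reproductives, alive and dead, at final census), `days_to_census`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_census <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("colony_id", "total_productivity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("census missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$total_productivity < 0 |
          df$total_productivity != round(df$total_productivity)))
    stop("total_productivity must be non-negative integers")
  df
}

#' @rdname read_census
#' @param census data.frame of census records.
#' @export
write_census <- function(census, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# census: total_productivity = workers + reproductives incl. dead",
             con)
  utils::write.csv(census, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a dataset directory against all format invariants
#'
#' Checks every recognised file in `dir` (detections.csv, nest_map.json,
#' probe_log.csv, census.csv, thermal stack + sidecar) and cross-checks
#' detections against the nest-map arena bounds.
#'
#' @param dir dataset directory.
#' @param schema_mode passed to [read_detections()].
#' @return Invisibly, a data.frame of (file, status, detail); errors are
#'   reported per file, not thrown.
#' @export
validate_dataset <- function(dir, schema_mode = "queenright") {
  res <- data.frame(file = character(), status = character(),
                    detail = character())
  note <- function(file, status, detail = "") {
    res <<- rbind(res, data.frame(file = file, status = status,
                                  detail = detail))
  }
  nest <- NULL
  nm <- file.path(dir, "nest_map.json")
  if (file.exists(nm)) {
    nest <- tryCatch(read_nest_map(nm), error = function(e) {
      note("nest_map.json", "FAIL", conditionMessage(e)); NULL })
    if (!is.null(nest)) note("nest_map.json", "OK")
  }
  det <- file.path(dir, "detections.csv")
  if (file.exists(det)) {
    segs <- tryCatch(
      withCallingHandlers(
        read_detections(det, schema_mode),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) { note("detections.csv", "FAIL",
                                 conditionMessage(e)); NULL })
    if (!is.null(segs)) {
      n_rej <- nrow(attr(segs, "log"))
      status <- if (n_rej > 0) "WARN" else "OK"
      detail <- sprintf("%d segments, %d rejected rows", length(segs), n_rej)
      if (!is.null(nest)) {
        b <- nest$bounds
        out_of_bounds <- sum(vapply(segs, function(s) {
          d <- s$detections
          sum(d$x_px < b["xmin"] | d$x_px > b["xmax"] |
              d$y_px < b["ymin"] | d$y_px > b["ymax"])
        }, numeric(1)))
        if (out_of_bounds > 0) {
          status <- "WARN"
          detail <- paste0(detail, sprintf("; %d detections outside arena",
                                           out_of_bounds))
        }
      }
      note("detections.csv", status, detail)
    }
  }
  for (f in c("probe_log.csv", "census.csv")) {
    p <- file.path(dir, f)
    if (file.exists(p)) {
      reader <- if (f == "probe_log.csv") read_probe_log else read_census
      ok <- tryCatch({ reader(p); TRUE },
                     error = function(e) { note(f, "FAIL",
                                                conditionMessage(e)); FALSE })
      if (ok) note(f, "OK")
    }
  }
  ts <- file.path(dir, "thermal_stack.tif")
  if (file.exists(ts)) {
    ok <- tryCatch({ read_thermal_stack(ts); TRUE },
                   error = function(e) { note("thermal_stack.tif", "FAIL",
                                              conditionMessage(e)); FALSE })
    if (ok) note("thermal_stack.tif", "OK")
  }
  if (nrow(res) == 0L) warning("no recognised dataset files in ", dir)
  invisible(res)
}
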