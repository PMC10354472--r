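# The per-bee, per-video behavioural metrics: spatial occupancy,
# element-interaction rates, pairwise spatial correlation, contact networks,
# speed/activity and the distance metrics, plus on/off-nest classification.

#' Spatial bin edges covering the arena
#' @param nest a [nest_map()].
#' @param bin_size_mm bin edge length in mm (converted via the nest scale).
#' @return list with `xb`, `yb` break vectors and `bin_px`.
#' @export
arena_bins <- function(nest, bin_size_mm = 20) {
  bin_px <- bin_size_mm / nest$mm_per_px
  b <- nest$bounds
  nx <- max(1L, ceiling((b["xmax"] - b["xmin"]) / bin_px - 1e-9))
  ny <- max(1L, ceiling((b["ymax"] - b["ymin"]) / bin_px - 1e-9))
  xb <- b["xmin"] + bin_px * (0:nx)
  yb <- b["ymin"] + bin_px * (0:ny)
  list(xb = xb, yb = yb, bin_px = bin_px)
}

bin_index <- function(v, breaks) {
  i <- findInterval(v, breaks, rightmost.closed = FALSE)
  pmin(pmax(i, 1L), length(breaks) - 1L)
}

#' Occupancy distribution of one bee in one video
#'
#' Normalised 2-D histogram of the bee's detections over arena bins.
#'
#' @param segment a [video_segment()].
#' @param bee_id which bee.
#' @param nest a [nest_map()].
#' @param bin_size_mm spatial bin size.
#' @return list of class `occupancy_grid`: `p` (matrix, rows = y bins),
#'   `bins`, `bee_id`, `video_id`, `n_detections`. Errors if the bee has no
#'   detections.
#' @export
occupancy_distribution <- function(segment, bee_id, nest, bin_size_mm = 20) {
  d <- segment$detections[segment$detections$bee_id == bee_id, ]
  if (nrow(d) == 0L) stop("no detections for bee ", bee_id)
  bins <- arena_bins(nest, bin_size_mm)
  occupancy_from_xy(d$x_px, d$y_px, bins, bee_id, segment$video_id)
}

occupancy_from_xy <- function(x, y, bins, bee_id = NA, video_id = NA) {
  nx <- length(bins$xb) - 1L; ny <- length(bins$yb) - 1L
  ix <- bin_index(x, bins$xb); iy <- bin_index(y, bins$yb)
  p <- matrix(0, ny, nx)
  tab <- table(factor(iy, levels = seq_len(ny)),
               factor(ix, levels = seq_len(nx)))
  p[] <- as.numeric(tab) / length(x)
  structure(list(p = p, bins = bins, bee_id = bee_id, video_id = video_id,
                 n_detections = length(x)),
            class = "occupancy_grid")
}

#' Interaction rate with nest elements
#'
#' Sum over bins of occupancy probability times the number of elements of
#' the requested kind in the bin; linear in element counts.
#'
#' @param grid an `occupancy_grid`.
#' @param nest a [nest_map()] binned identically to the grid.
#' @param kind `"brood"` or `"pots"`.
#' @return numeric rate (>= 0).
#' @export
element_interaction_rate <- function(grid, nest, kind = c("brood", "pots")) {
  kind <- match.arg(kind)
  el <- nest[[kind]]
  if (nrow(el) == 0L) return(0)
  bins <- grid$bins
  if (el[1, 1] > max(bins$xb) || el[1, 2] > max(bins$yb))
    stop("grid and nest do not share arena bins")
  ix <- bin_index(el[, 1], bins$xb); iy <- bin_index(el[, 2], bins$yb)
  counts <- matrix(0, nrow(grid$p), ncol(grid$p))
  for (k in seq_along(ix))
    counts[iy[k], ix[k]] <- counts[iy[k], ix[k]] + 1
  sum(grid$p * counts)
}

#' Pearson spatial correlation between two occupancy grids
#'
#' @param grid_i,grid_j `occupancy_grid`s on identical bins.
#' @return correlation over flattened bin probabilities, or NA when either
#'   grid is constant (zero variance).
#' @export
spatial_correlation <- function(grid_i, grid_j) {
  if (!identical(dim(grid_i$p), dim(grid_j$p)))
    stop("grids are binned differently")
  a <- as.vector(grid_i$p); b <- as.vector(grid_j$p)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Contact events within a video
#'
#' All unordered bee pairs closer than `threshold_mm` between tag centroids,
#' per frame.
#'
#' @param segment a [video_segment()].
#' @param nest a [nest_map()] (supplies `mm_per_px`).
#' @param threshold_mm physical contact threshold (default 10 mm = 1 cm).
#' @return data.frame `frame_index`, `bee_a`, `bee_b` (a < b), `dist_mm`.
#' @export
contact_events <- function(segment, nest, threshold_mm = 10) {
  if (is.null(nest$mm_per_px)) stop("missing mm_per_px scale")
  thr_px <- threshold_mm / nest$mm_per_px
  d <- segment$detections
  out <- lapply(split(d, d$frame_index), function(fr) {
    n <- nrow(fr)
    if (n < 2L) return(NULL)
    dm <- as.matrix(stats::dist(fr[, c("x_px", "y_px")]))
    idx <- which(upper.tri(dm) & dm < thr_px, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    a <- fr$bee_id[idx[, 1]]; b <- fr$bee_id[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(frame_index = fr$frame_index[1], bee_a = a, bee_b = b,
               dist_mm = dm[idx] * nest$mm_per_px,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame_index = integer(), bee_a = character(),
                      bee_b = character(), dist_mm = numeric())
  rownames(res) <- NULL
  res[order(res$frame_index, res$bee_a, res$bee_b), ]
}

#' Per-bee contact rate and degree centrality
#'
#' Contact rate is total contacts involving the bee divided by the number of
#' frames in which the bee was detected; degree centrality is the number of
#' distinct partners over the video.
#'
#' @param events output of [contact_events()].
#' @param segment the same [video_segment()].
#' @return data.frame `bee_id`, `contact_rate`, `degree_centrality`.
#' @export
contact_summary <- function(events, segment) {
  d <- segment$detections
  bees <- sort(unique(d$bee_id))
  frames_detected <- table(factor(d$bee_id, levels = bees))
  rows <- lapply(bees, function(b) {
    ev <- events[events$bee_a == b | events$bee_b == b, ]
    partners <- setdiff(unique(c(ev$bee_a, ev$bee_b)), b)
    data.frame(bee_id = b,
               contact_rate = nrow(ev) / as.numeric(frames_detected[b]),
               degree_centrality = length(partners),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Frame-wise speeds of one bee's track
#'
#' Speed between consecutive detections is displacement divided by the frame
#' gap (px/frame), assigned to the first frame of the pair; gaps longer than
#' `max_gap` frames break the track and yield no speed.
#'
#' @param track data.frame of one bee's detections (sorted by frame).
#' @param max_gap largest bridged gap, frames.
#' @return data.frame `frame_index`, `gap`, `speed_px_frame` (one row per
#'   bridged pair).
#' @export
frame_speeds <- function(track, max_gap = 3) {
  if (nrow(track) < 2L)
    return(data.frame(frame_index = integer(), gap = integer(),
                      speed_px_frame = numeric()))
  gap <- diff(track$frame_index)
  disp <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2)
  keep <- gap <= max_gap
  data.frame(frame_index = track$frame_index[-nrow(track)][keep],
             gap = gap[keep], speed_px_frame = (disp / gap)[keep])
}

#' Activity threshold from the bimodal speed distribution
#'
#' Kernel-density valley between the two largest modes of the pooled
#' frame-wise speed sample; when the KDE has a single mode the boundary of a
#' two-cluster (k-means) split is used instead, flagged in the output.
#'
#' @param speeds pooled frame-wise speeds (>= 100 values).
#' @return list `threshold`, `method` (`"kde_valley"` or
#'   `"mixture_fallback"`).
#' @export
activity_threshold <- function(speeds) {
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) < 100L)
    stop("need >= 100 frame-wise speed samples (have ", length(speeds), ")")
  if (stats::sd(speeds) < 1e-12)
    stop("all speeds identical: no bimodality to threshold")
  den <- stats::density(speeds, n = 1024)
  y <- den$y
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_peak) >= 2L) {
    top2 <- is_peak[order(y[is_peak], decreasing = TRUE)][1:2]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1L
    return(list(threshold = den$x[valley], method = "kde_valley"))
  }
  km <- stats::kmeans(speeds, centers = 2, nstart = 5)
  list(threshold = mean(sort(km$centers)), method = "mixture_fallback")
}

#' Moving speed and activity fraction of one track
#'
#' @param track one bee's detections.
#' @param threshold activity threshold, px/frame.
#' @param max_gap largest bridged gap, frames.
#' @return list `moving_speed` (mean speed over frames above threshold; NA
#'   when never moving), `activity_fraction`, `n_speed_frames`.
#' @export
moving_speed_and_activity <- function(track, threshold, max_gap = 3) {
  sp <- frame_speeds(track, max_gap)
  if (nrow(sp) == 0L)
    return(list(moving_speed = NA_real_, activity_fraction = NA_real_,
                n_speed_frames = 0L))
  moving <- sp$speed_px_frame > threshold
  list(moving_speed = if (any(moving)) mean(sp$speed_px_frame[moving])
                      else NA_real_,
       activity_fraction = mean(moving),
       n_speed_frames = nrow(sp))
}

#' Distance metrics of one track
#'
#' The nest centre is social: the mean position of all detections of all
#' bees in the video. "All"-element distances are medians over every
#' (frame, element) pair; "closest"-element distances take the per-frame
#' minimum first, then the median over frames. Also returns the mean
#' distance to concurrently detected nest-mates (used by the microcolony
#' variable set).
#'
#' @param track focal bee's detections.
#' @param all_detections all detections in the video (all bees).
#' @param nest a [nest_map()].
#' @param mean_nestmates compute `mean_dist_nestmates` (per-frame loop;
#'   [compute_behaviour_table()] obtains it from its fused pass instead).
#' @return named list of `distance_to_centre`, `median_dist_all_brood`,
#'   `median_dist_all_pots`, `min_dist_closest_brood`,
#'   `min_dist_closest_pot`, `mean_dist_nestmates` (px; NA where elements
#'   are absent).
#' @export
distance_metrics <- function(track, all_detections, nest,
                             mean_nestmates = TRUE) {
  if (nrow(track) == 0L) stop("empty track")
  centre <- c(mean(all_detections$x_px), mean(all_detections$y_px))
  d_centre <- sqrt((track$x_px - centre[1])^2 + (track$y_px - centre[2])^2)
  el_stats <- function(el) {
    if (nrow(el) == 0L) return(list(all = NA_real_, closest = NA_real_))
    dm <- outer(track$x_px, el[, 1], "-")^2 +
      outer(track$y_px, el[, 2], "-")^2
    dm <- sqrt(dm)
    list(all = stats::median(dm), closest = stats::median(apply(dm, 1, min)))
  }
  br <- el_stats(nest$brood); po <- el_stats(nest$pots)
  other <- if (mean_nestmates)
    all_detections[all_detections$bee_id != track$bee_id[1], ] else
    all_detections[0, ]
  mean_nm <- if (nrow(other) == 0L) NA_real_ else {
    per_frame <- vapply(seq_len(nrow(track)), function(i) {
      o <- other[other$frame_index == track$frame_index[i], ]
      if (nrow(o) == 0L) return(NA_real_)
      mean(sqrt((o$x_px - track$x_px[i])^2 + (o$y_px - track$y_px[i])^2))
    }, numeric(1))
    if (all(is.na(per_frame))) NA_real_ else mean(per_frame, na.rm = TRUE)
  }
  list(distance_to_centre = mean(d_centre),
       median_dist_all_brood = br$all, median_dist_all_pots = po$all,
       min_dist_closest_brood = br$closest, min_dist_closest_pot = po$closest,
       mean_dist_nestmates = mean_nm)
}

#' Classify a position as on-nest, off-nest or intermediate
#'
#' On-nest: nearest brood closer than 10 mm (1 cm); off-nest: further than
#' 20 mm (2 cm); otherwise intermediate.
#'
#' @param x_px,y_px position, tracking px.
#' @param nest a [nest_map()] with >= 1 brood centroid.
#' @return character vector in {"on", "off", "intermediate"}.
#' @export
classify_on_off_nest <- function(x_px, y_px, nest) {
  if (nrow(nest$brood) == 0L) stop("no brood: on/off-nest undefined")
  d2 <- outer(x_px, nest$brood[, 1], "-")^2 +
    outer(y_px, nest$brood[, 2], "-")^2
  d_mm <- sqrt(apply(d2, 1, min)) * nest$mm_per_px
  ifelse(d_mm < 10, "on", ifelse(d_mm > 20, "off", "intermediate"))
}

#' Compute the behaviour table for a set of video segments
#'
#' One row per (bee, video): the eleven headline metrics plus auxiliary
#' columns (`activity_fraction`, `mean_dist_nestmates`, `moving_speed_mm_s`,
#' `on_off_nest` at first detection, detection count). The activity
#' threshold is estimated once from speeds pooled across all segments
#' (per-colony pooling) unless supplied.
#'
#' @param segments list of [video_segment()].
#' @param nest a [nest_map()].
#' @param bin_size_mm spatial bin size for occupancy grids.
#' @param contact_threshold_mm contact threshold.
#' @param threshold activity threshold (px/frame); NULL = estimate by
#'   [activity_threshold()] on the pooled sample.
#' @param max_gap largest bridged detection gap, frames.
#' @return data.frame; attribute `"threshold"` records the threshold and
#'   method used.
#' @export
compute_behaviour_table <- function(segments, nest, bin_size_mm = 20,
                                    contact_threshold_mm = 10,
                                    threshold = NULL, max_gap = 3) {
  if (is.null(threshold)) {
    pooled <- unlist(lapply(segments, function(s) {
      unlist(lapply(split(s$detections, s$detections$bee_id),
                    function(tr) frame_speeds(tr, max_gap)$speed_px_frame))
    }))
    thr <- activity_threshold(pooled)
  } else {
    thr <- list(threshold = threshold, method = "supplied")
  }
  bins <- arena_bins(nest, bin_size_mm)
  thr_px <- contact_threshold_mm / nest$mm_per_px
  seg_tables <- vector("list", length(segments))
  col_min <- function(dm) do.call(pmin, as.data.frame(dm))
  for (si in seq_along(segments)) {
    s <- segments[[si]]
    d <- s$detections
    x <- d$x_px; y <- d$y_px
    bees <- sort(unique(d$bee_id))
    nb <- length(bees)
    by_bee <- split(seq_len(nrow(d)), factor(d$bee_id, levels = bees))
    flat <- vapply(by_bee, function(idx)
      as.vector(occupancy_from_xy(x[idx], y[idx], bins)$p),
      numeric((length(bins$xb) - 1L) * (length(bins$yb) - 1L)))
    cors <- if (nb > 1L) suppressWarnings(stats::cor(flat)) else
      matrix(NA_real_, 1, 1)
    diag(cors) <- NA
    # fused per-frame pass (compiled): contact counts, partner sets and
    # nest-mate distances from one pairwise scan per frame
    ord <- order(d$frame_index)
    n_per_frame <- tabulate(factor(d$frame_index[ord]))
    cp <- contact_pass_cpp(x[ord], y[ord],
                           c(0L, cumsum(n_per_frame)),
                           match(d$bee_id[ord], bees) - 1L,
                           nb, thr_px)
    contact_n <- cp$contact_n
    partner <- cp$partner
    nm_sum <- cp$nm_sum
    nm_frames <- cp$nm_frames
    centre <- c(mean(x), mean(y))
    fps <- s$frame_rate_hz
    el_cols <- function(el, idx) {
      if (nrow(el) == 0L) return(c(NA_real_, NA_real_))
      dm <- sqrt(outer(x[idx], el[, 1], "-")^2 +
                   outer(y[idx], el[, 2], "-")^2)
      c(stats::median(dm), stats::median(col_min(dm)))
    }
    n <- nb
    tab <- data.frame(
      bee_id = bees, video_id = s$video_id,
      brood_interaction_rate = NA_real_, pot_interaction_rate = NA_real_,
      mean_spatial_correlation = NA_real_,
      mean_contact_rate = NA_real_, degree_centrality = NA_integer_,
      moving_speed = NA_real_, distance_to_centre = NA_real_,
      median_dist_all_brood = NA_real_, median_dist_all_pots = NA_real_,
      min_dist_closest_brood = NA_real_, min_dist_closest_pot = NA_real_,
      activity_fraction = NA_real_, mean_dist_nestmates = NA_real_,
      moving_speed_mm_s = NA_real_, on_off_nest = NA_character_,
      n_detections = NA_integer_, stringsAsFactors = FALSE)
    for (k in seq_len(nb)) {
      idx <- by_bee[[k]]
      g <- list(p = matrix(flat[, k], length(bins$yb) - 1L), bins = bins)
      class(g) <- "occupancy_grid"
      fi <- d$frame_index[idx]
      sp <- if (length(idx) < 2L) numeric(0) else {
        gap <- diff(fi)
        (sqrt(diff(x[idx])^2 + diff(y[idx])^2) / gap)[gap <= max_gap]
      }
      moving <- sp > thr$threshold
      msa <- list(
        moving_speed = if (any(moving)) mean(sp[moving]) else NA_real_,
        activity_fraction = if (length(sp)) mean(moving) else NA_real_)
      br <- el_cols(nest$brood, idx); po <- el_cols(nest$pots, idx)
      tab$brood_interaction_rate[k] <-
        element_interaction_rate(g, nest, "brood")
      tab$pot_interaction_rate[k] <-
        element_interaction_rate(g, nest, "pots")
      tab$mean_spatial_correlation[k] <-
        if (nb > 1L) mean(cors[, k], na.rm = TRUE) else NA_real_
      tab$mean_contact_rate[k] <- contact_n[k] / length(idx)
      tab$degree_centrality[k] <- sum(partner[k, ])
      tab$moving_speed[k] <- msa$moving_speed
      tab$distance_to_centre[k] <-
        mean(sqrt((x[idx] - centre[1])^2 + (y[idx] - centre[2])^2))
      tab$median_dist_all_brood[k] <- br[1]
      tab$median_dist_all_pots[k] <- po[1]
      tab$min_dist_closest_brood[k] <- br[2]
      tab$min_dist_closest_pot[k] <- po[2]
      tab$activity_fraction[k] <- msa$activity_fraction
      tab$mean_dist_nestmates[k] <-
        if (nm_frames[k] > 0) nm_sum[k] / nm_frames[k] else NA_real_
      tab$moving_speed_mm_s[k] <- msa$moving_speed * nest$mm_per_px * fps
      tab$on_off_nest[k] <-
        classify_on_off_nest(x[idx[1]], y[idx[1]], nest)
      tab$n_detections[k] <- length(idx)
    }
    seg_tables[[si]] <- tab
  }
  out <- do.call(rbind, seg_tables)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}
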