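# Thermal pipeline: per-frame calibration of raw counts against in-nest
# probes, smooth non-rigid registration of tracking coordinates into
# thermal frames, and disc-mean temperature extraction.

probe_counts <- function(frame, probes, radius_px = 3) {
  vapply(seq_len(nrow(probes)), function(p)
    disc_mean(frame, probes$x_px[p], probes$y_px[p], radius_px)$mean,
    numeric(1))
}

#' Calibrate one thermal frame against probe readings
#'
#' Fits the linear sensor model `T = gain * counts + offset` by least
#' squares over the probes (each probe's count value is the mean over a
#' small disc at its annotation) and maps the whole frame through the fit.
#'
#' @param raw_frame numeric matrix of raw counts (rows = image rows).
#' @param probes data.frame of probe annotations (`probe_id`, `x_px`,
#'   `y_px`, 0-based thermal px).
#' @param probe_temps_c numeric vector of contemporaneous probe
#'   temperatures, one per probe row.
#' @param probe_radius_px disc radius for probe count extraction.
#' @return list with `calibration` (frame gain/offset/residual_rmse/
#'   n_probes_used/calibrated flag) and `frame_c` (calibrated frame in
#'   degrees C, or NULL when the fit is degenerate).
#' @export
calibrate_frame <- function(raw_frame, probes, probe_temps_c,
                            probe_radius_px = 3) {
  if (nrow(probes) < 2L || length(probe_temps_c) != nrow(probes))
    stop("need >= 2 probes with contemporaneous readings")
  counts <- probe_counts(raw_frame, probes, probe_radius_px)
  degenerate <- stats::sd(counts) < 1e-12
  if (!degenerate) {
    fit <- stats::lm.fit(cbind(1, counts), probe_temps_c)
    offset <- fit$coefficients[1]; gain <- fit$coefficients[2]
    rmse <- sqrt(mean(fit$residuals^2))
    degenerate <- !is.finite(gain) || abs(gain) < 1e-15
  }
  if (degenerate) {
    return(list(calibration = list(gain = NA_real_, offset = NA_real_,
                                   residual_rmse = NA_real_,
                                   n_probes_used = nrow(probes),
                                   calibrated = FALSE),
                frame_c = NULL))
  }
  list(calibration = list(gain = unname(gain), offset = unname(offset),
                          residual_rmse = rmse,
                          n_probes_used = nrow(probes), calibrated = TRUE),
       frame_c = gain * raw_frame + offset)
}

#' Calibrate every frame of a thermal stack
#'
#' Probe temperatures are linearly interpolated in time from the probe log
#' (entries roughly every 20 s) to each frame timestamp, then
#' [calibrate_frame()] is applied per frame.
#'
#' @param stack a [thermal_stack()].
#' @param probe_log data.frame with `time_s`, `probe_id`, `temp_c`.
#' @param probe_radius_px disc radius for probe count extraction.
#' @return list with `frames_c` (list of calibrated matrices, NULL where
#'   degenerate) and `calibrations` (one row per frame).
#' @export
calibrate_stack <- function(stack, probe_log, probe_radius_px = 3) {
  ids <- stack$probes$probe_id
  interp <- lapply(ids, function(id) {
    d <- probe_log[probe_log$probe_id == id, ]
    if (nrow(d) == 0L) stop("probe log has no entries for probe ", id)
    stats::approx(d$time_s, d$temp_c, xout = stack$timestamps_s,
                  rule = 2)$y
  })
  frames_c <- vector("list", length(stack$frames))
  cal <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    temps <- vapply(interp, `[`, numeric(1), f)
    res <- calibrate_frame(stack$frames[[f]], stack$probes, temps,
                           probe_radius_px)
    frames_c[[f]] <- res$frame_c
    cal[[f]] <- data.frame(frame_index = f - 1L,
                           gain = res$calibration$gain,
                           offset = res$calibration$offset,
                           residual_rmse = res$calibration$residual_rmse,
                           n_probes_used = res$calibration$n_probes_used,
                           calibrated = res$calibration$calibrated)
  }
  list(frames_c = frames_c, calibrations = do.call(rbind, cal))
}

tps_u <- function(r2) {
  # thin-plate kernel U(r) = r^2 log r, with U(0) = 0
  out <- r2 * log(pmax(r2, .Machine$double.eps)) / 2
  out[r2 == 0] <- 0
  out
}

#' Fit a smooth non-rigid tracking-to-thermal warp
#'
#' Thin-plate-spline displacement field through annotated control-point
#' pairs: the minimiser of squared control-point error plus a bending-energy
#' penalty weighted by `lambda`. Any affine map lies in the penalty null
#' space, so exact affine geometry is reproduced exactly; `lambda = 0` gives
#' exact interpolation.
#'
#' @param control data.frame/matrix with columns `x_tr`, `y_tr` (tracking
#'   px) and `x_th`, `y_th` (thermal px); >= 4 non-collinear pairs.
#' @param lambda smoothness weight (scaled by the squared mean control-point
#'   spacing so its effect is resolution-independent).
#' @return object of class `warp_model` (control points, TPS weights,
#'   affine part, residual RMSE in thermal px).
#' @export
fit_warp <- function(control, lambda = 1e-3) {
  control <- as.data.frame(control)
  need <- c("x_tr", "y_tr", "x_th", "y_th")
  stopifnot(all(need %in% names(control)))
  n <- nrow(control)
  if (n < 4L) stop("need >= 4 control-point pairs")
  if (anyDuplicated(control[, c("x_tr", "y_tr")]))
    stop("duplicate control points in tracking frame: rows ",
         paste(which(duplicated(control[, c("x_tr", "y_tr")])),
               collapse = ", "))
  # normalise tracking coordinates to a unit-scale box so the bordered TPS
  # system is well conditioned regardless of arena resolution
  ctr <- c(mean(control$x_tr), mean(control$y_tr))
  scl <- max(stats::sd(control$x_tr), stats::sd(control$y_tr))
  if (scl < 1e-12) stop("duplicate control points")
  u <- (control$x_tr - ctr[1]) / scl
  v <- (control$y_tr - ctr[2]) / scl
  P <- cbind(1, u, v)
  if (qr(P)$rank < 3L)
    stop("control points are collinear; the affine part is unidentifiable")
  D2 <- as.matrix(stats::dist(cbind(u, v)))^2
  K <- tps_u(D2)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(as.matrix(control[, c("x_th", "y_th")]), matrix(0, 3, 2))
  sol <- solve(A, rhs)
  w <- sol[seq_len(n), , drop = FALSE]
  a <- sol[n + 1:3, , drop = FALSE]
  model <- structure(list(control = control, centre = ctr, scale = scl,
                          weights = w, affine = a,
                          lambda = lambda), class = "warp_model")
  pred <- predict_warp(model, control[, c("x_tr", "y_tr")])
  model$residual_rmse <- sqrt(mean((pred -
    as.matrix(control[, c("x_th", "y_th")]))^2))
  model
}

#' Map tracking-pixel points through a fitted warp
#' @param model a `warp_model` from [fit_warp()].
#' @param pts matrix/data.frame of tracking-px points (columns x, y).
#' @return matrix of thermal-px coordinates.
#' @export
predict_warp <- function(model, pts) {
  pts <- as.matrix(pts)
  u <- (pts[, 1] - model$centre[1]) / model$scale
  v <- (pts[, 2] - model$centre[2]) / model$scale
  cu <- (model$control$x_tr - model$centre[1]) / model$scale
  cv <- (model$control$y_tr - model$centre[2]) / model$scale
  D2 <- outer(u, cu, "-")^2 + outer(v, cv, "-")^2
  U <- tps_u(D2)
  cbind(1, u, v) %*% model$affine + U %*% model$weights
}

#' @export
print.warp_model <- function(x, ...) {
  cat(sprintf("<warp_model: %d control pairs, lambda %.2g, residual %.4g px>\n",
              nrow(x$control), x$lambda, x$residual_rmse))
  invisible(x)
}

# mean over all pixels whose centre lies within radius_px of the
# (possibly fractional) point (cx, cy), clipped at frame edges
disc_mean <- function(frame_c, cx, cy, radius_px) {
  h <- nrow(frame_c); w <- ncol(frame_c)
  xi <- max(0, ceiling(cx - radius_px)):min(w - 1, floor(cx + radius_px))
  yi <- max(0, ceiling(cy - radius_px)):min(h - 1, floor(cy + radius_px))
  g <- expand.grid(px = xi, py = yi)
  keep <- (g$px - cx)^2 + (g$py - cy)^2 <= radius_px^2
  list(mean = mean(frame_c[cbind(g$py[keep] + 1L, g$px[keep] + 1L)]),
       n = sum(keep))
}

#' Extract a bee's body temperature from a calibrated frame
#'
#' Maps the tag centroid through the warp and averages the calibrated
#' temperature over all pixels within `radius_px` (default 20 thermal px,
#' about 6 mm), clipping the disc at frame edges. A mapped centre outside
#' the frame yields `valid = FALSE` rather than an error.
#'
#' @param frame_c calibrated frame, degrees C (from [calibrate_frame()]).
#' @param detection one-row data.frame with `bee_id`, `frame_index`,
#'   `x_px`, `y_px` in tracking px.
#' @param warp a `warp_model` (or any object accepted by [predict_warp()]).
#' @param radius_px disc radius, thermal px.
#' @return one-row data.frame: `bee_id`, `frame_index`, `temp_c`,
#'   `radius_px`, `n_pixels_averaged`, `valid`.
#' @export
extract_body_temp <- function(frame_c, detection, warp, radius_px = 20) {
  if (is.null(frame_c)) stop("frame is uncalibrated")
  if (radius_px <= 0) stop("radius_px must be > 0")
  th <- predict_warp(warp, cbind(detection$x_px, detection$y_px))
  h <- nrow(frame_c); w <- ncol(frame_c)
  out <- data.frame(bee_id = detection$bee_id,
                    frame_index = detection$frame_index,
                    temp_c = NA_real_, radius_px = radius_px,
                    n_pixels_averaged = 0L, valid = FALSE)
  for (i in seq_len(nrow(th))) {
    if (th[i, 1] < 0 || th[i, 1] > w - 1 ||
        th[i, 2] < 0 || th[i, 2] > h - 1) next
    dm <- disc_mean(frame_c, th[i, 1], th[i, 2], radius_px)
    out$temp_c[i] <- dm$mean
    out$n_pixels_averaged[i] <- dm$n
    out$valid[i] <- TRUE
  }
  out
}

#' Extract brood temperatures from a calibrated frame
#'
#' [extract_body_temp()] applied to every brood centroid of the nest map.
#'
#' @param frame_c calibrated frame, degrees C.
#' @param nest a [nest_map()].
#' @param warp a `warp_model`.
#' @param radius_px disc radius, thermal px.
#' @return data.frame with one row per brood item.
#' @export
extract_brood_temp <- function(frame_c, nest, warp, radius_px = 20) {
  if (nrow(nest$brood) == 0L) stop("nest has no brood centroids")
  rows <- lapply(seq_len(nrow(nest$brood)), function(k) {
    r <- extract_body_temp(frame_c,
                           data.frame(bee_id = sprintf("brood%02d", k),
                                      frame_index = NA_integer_,
                                      x_px = nest$brood[k, 1],
                                      y_px = nest$brood[k, 2]),
                           warp, radius_px)
    names(r)[names(r) == "bee_id"] <- "brood_id"
    r
  })
  do.call(rbind, rows)
}

#' Extract body temperatures for all detections across a stack
#'
#' Convenience driver: calibrates the stack, matches each detection to the
#' thermal frame nearest in time and extracts disc-mean body temperature.
#'
#' @param stack a [thermal_stack()].
#' @param probe_log probe temperature log.
#' @param segments list of [video_segment()] whose detections carry times
#'   comparable to the stack timestamps (column `abs_time_s` if present,
#'   otherwise `time_s`).
#' @param warp a `warp_model`.
#' @param radius_px disc radius, thermal px.
#' @param max_dt_s detections further than this from any thermal frame are
#'   skipped.
#' @return data.frame of body-temperature readings with video and time
#'   columns.
#' @export
extract_body_temps_stack <- function(stack, probe_log, segments, warp,
                                     radius_px = 20, max_dt_s = 0.5) {
  cal <- calibrate_stack(stack, probe_log)
  out <- list()
  for (s in segments) {
    d <- s$detections
    tt <- if ("abs_time_s" %in% names(d)) d$abs_time_s else d$time_s
    fi <- vapply(tt, function(t) which.min(abs(stack$timestamps_s - t)),
                 integer(1))
    ok <- abs(stack$timestamps_s[fi] - tt) <= max_dt_s &
      cal$calibrations$calibrated[fi]
    if (!any(ok)) next
    rows <- lapply(which(ok), function(i) {
      r <- extract_body_temp(cal$frames_c[[fi[i]]], d[i, ], warp, radius_px)
      r$video_id <- s$video_id
      r$time_s <- tt[i]
      r
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
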