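# Temperature protocols: piecewise-linear air-temperature schedules applied
# to whole nests during cold-stress trials.

#' Construct a temperature protocol
#'
#' A protocol is an ordered list of piecewise-linear segments, each defined by
#' a duration in minutes and start/end air temperatures in degrees Celsius.
#' Temperature is linear within a segment and continuous across segment
#' joints.
#'
#' @param segments data.frame with columns `duration_min`, `start_c`, `end_c`.
#' @return An object of class `temperature_protocol`.
#' @export
temperature_protocol <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("duration_min", "start_c", "end_c") %in% names(segments)))
  if (nrow(segments) == 0L) stop("protocol needs at least one segment")
  if (any(segments$duration_min <= 0)) stop("segment durations must be > 0")
  if (nrow(segments) > 1L) {
    joints <- segments$start_c[-1L] - segments$end_c[-nrow(segments)]
    if (any(abs(joints) > 1e-9))
      stop("protocol discontinuous at segment joint(s): ",
           paste(which(abs(joints) > 1e-9), collapse = ", "))
  }
  structure(list(segments = segments), class = "temperature_protocol")
}

#' Queenright-colony cold exposure protocol
#'
#' The whole-colony exposure: hold at 24 C for 10 min, ramp down to 10 C over
#' 60 min (0.25 C/min), hold at 10 C for 120 min, ramp back to 24 C over
#' 60 min, then hold at 24 C for 20 min. Total 270 min (4.5 h).
#'
#' @return A `temperature_protocol`.
#' @export
make_queenright_protocol <- function() {
  temperature_protocol(data.frame(
    duration_min = c(10, 60, 120, 60, 20),
    start_c      = c(24, 24,  10, 10, 24),
    end_c        = c(24, 10,  10, 24, 24)
  ))
}

#' Microcolony cold-stress protocol
#'
#' Ramp from 22 C down to 10 C over 65 min (0.18 C/min), hold at 10 C for
#' 180 min, ramp back to 22 C over 65 min. Total 310 min.
#'
#' @return A `temperature_protocol`.
#' @export
make_microcolony_protocol <- function() {
  temperature_protocol(data.frame(
    duration_min = c(65, 180, 65),
    start_c      = c(22,  10, 10),
    end_c        = c(10,  10, 22)
  ))
}

#' Total protocol duration in minutes
#' @param protocol a `temperature_protocol`.
#' @return Numeric scalar, minutes.
#' @export
protocol_duration_min <- function(protocol) {
  sum(protocol$segments$duration_min)
}

#' Air temperature at elapsed time
#'
#' Linear interpolation within segments; times beyond the protocol end return
#' the final temperature (the nest is no longer actively controlled).
#'
#' @param protocol a `temperature_protocol`.
#' @param t_min numeric vector of elapsed times in minutes (>= 0).
#' @return Numeric vector of air temperatures, degrees Celsius.
#' @export
protocol_temperature <- function(protocol, t_min) {
  seg <- protocol$segments
  ends <- cumsum(seg$duration_min)
  starts <- c(0, ends[-length(ends)])
  out <- numeric(length(t_min))
  for (i in seq_along(t_min)) {
    t <- t_min[i]
    if (t < 0) stop("negative time")
    if (t >= ends[length(ends)]) {
      out[i] <- seg$end_c[nrow(seg)]
    } else {
      k <- which(t < ends)[1L]
      frac <- (t - starts[k]) / seg$duration_min[k]
      out[i] <- seg$start_c[k] + frac * (seg$end_c[k] - seg$start_c[k])
    }
  }
  out
}

#' Ramp rate of a protocol segment
#' @param protocol a `temperature_protocol`.
#' @param segment integer index.
#' @return Absolute rate of change, degrees C per minute.
#' @export
segment_ramp_rate <- function(protocol, segment) {
  seg <- protocol$segments[segment, ]
  abs(seg$end_c - seg$start_c) / seg$duration_min
}
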