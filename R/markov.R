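# Markov activity analysis: per-frame state labelling from the speed
# threshold, transition-probability estimation per body-temperature bin,
# and treatment-arm contrasts.

#' Label per-frame activity states
#'
#' A frame is active when the frame-wise speed assigned to it (displacement
#' to the next detection within `max_gap` frames, divided by the gap)
#' exceeds the activity threshold; frames with no bridgeable next detection
#' have undefined (NA) state.
#'
#' @param track one bee's detections (data.frame, sorted by frame), with an
#'   optional `body_temp_c` column carried through.
#' @param threshold activity threshold, px/frame.
#' @param max_gap largest bridged gap, frames.
#' @return data.frame `bee_id`, `frame_index`, `state` ("active"/
#'   "inactive"/NA), `body_temp_c` (NA when absent).
#' @export
label_states <- function(track, threshold, max_gap = 3) {
  sp <- frame_speeds(track, max_gap)
  state <- rep(NA_character_, nrow(track))
  m <- match(sp$frame_index, track$frame_index)
  state[m] <- ifelse(sp$speed_px_frame > threshold, "active", "inactive")
  if (all(is.na(state)))
    warning("no speed-defined frames for bee ", track$bee_id[1])
  data.frame(bee_id = track$bee_id,
             frame_index = track$frame_index,
             state = state,
             body_temp_c = if ("body_temp_c" %in% names(track))
               track$body_temp_c else NA_real_,
             stringsAsFactors = FALSE)
}

#' Wilson score confidence interval for a binomial proportion
#' @param k successes, `n` trials, `conf` level.
#' @param n number of trials.
#' @param conf confidence level.
#' @return data.frame `lo`, `hi` (vectorised over `k`, `n`).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  data.frame(lo = pmax(0, ctr - hw), hi = pmin(1, ctr + hw))
}

# consecutive same-bee frame pairs usable as single Markov steps; frame
# indices restart per video, so split by (bee, video) when videos present
transition_pairs <- function(sequences) {
  grp <- if ("video_id" %in% names(sequences))
    paste(sequences$bee_id, sequences$video_id) else sequences$bee_id
  do.call(rbind, lapply(split(sequences, grp), function(s) {
    s <- s[order(s$frame_index), ]
    if (nrow(s) < 2L) return(NULL)
    one <- diff(s$frame_index) == 1L
    from <- s$state[-nrow(s)]; to <- s$state[-1L]
    keep <- one & !is.na(from) & !is.na(to)
    if (!any(keep)) return(NULL)
    data.frame(bee_id = s$bee_id[1],
               temp_c = s$body_temp_c[-nrow(s)][keep],
               from = from[keep], to = to[keep],
               stringsAsFactors = FALSE)
  }))
}

#' Estimate activity-state transition probabilities by temperature bin
#'
#' Each consecutive same-bee frame pair (gap of exactly one frame, both
#' states defined) is one Bernoulli trial conditioned on the first frame's
#' state, assigned to the temperature bin of the first frame's body
#' temperature. Pairs with missing body temperature are excluded from
#' binning. Probabilities with fewer than `min_count` opportunities are
#' suppressed (NA).
#'
#' @param sequences stacked [label_states()] output (column `bee_id`
#'   distinguishes bees).
#' @param temp_bins vector of bin edges, degrees C.
#' @param arm treatment arm label attached to every row.
#' @param min_count minimum opportunities per estimate.
#' @param conf confidence level for Wilson intervals.
#' @return data.frame, one row per bin: bounds, counts, `p_ai`/`p_ia` with
#'   Wilson CIs, `arm`.
#' @export
estimate_transitions <- function(sequences, temp_bins = seq(10, 30, by = 2),
                                 arm = "control", min_count = 50,
                                 conf = 0.95) {
  if (length(temp_bins) < 2L) stop("need at least one temperature bin")
  pr <- transition_pairs(sequences)
  pr <- pr[!is.na(pr$temp_c), , drop = FALSE]
  bin <- cut(pr$temp_c, temp_bins, right = FALSE)
  rows <- lapply(seq_len(length(temp_bins) - 1L), function(b) {
    sel <- pr[which(as.integer(bin) == b), ]
    n_a <- sum(sel$from == "active")
    n_ai <- sum(sel$from == "active" & sel$to == "inactive")
    n_i <- sum(sel$from == "inactive")
    n_ia <- sum(sel$from == "inactive" & sel$to == "active")
    p_ai <- if (n_a >= min_count) n_ai / n_a else NA_real_
    p_ia <- if (n_i >= min_count) n_ia / n_i else NA_real_
    ci_ai <- if (is.na(p_ai)) data.frame(lo = NA_real_, hi = NA_real_)
             else wilson_ci(n_ai, n_a, conf)
    ci_ia <- if (is.na(p_ia)) data.frame(lo = NA_real_, hi = NA_real_)
             else wilson_ci(n_ia, n_i, conf)
    data.frame(temp_lo = temp_bins[b], temp_hi = temp_bins[b + 1L],
               n_active = n_a, n_ai = n_ai, p_ai = p_ai,
               p_ai_lo = ci_ai$lo, p_ai_hi = ci_ai$hi,
               n_inactive = n_i, n_ia = n_ia, p_ia = p_ia,
               p_ia_lo = ci_ia$lo, p_ia_hi = ci_ia$hi,
               arm = arm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-bee opportunity (active first frame) and a->i transition counts per
# temperature bin: rows = bees, cols = bins
bee_bin_counts <- function(pairs, temp_bins) {
  nb <- length(temp_bins) - 1L
  act <- pairs[pairs$from == "active", ]
  bin <- as.integer(cut(act$temp_c, temp_bins, right = FALSE))
  keep <- !is.na(bin)
  act <- act[keep, ]; bin <- bin[keep]
  bees <- sort(unique(pairs$bee_id))
  f_bee <- factor(act$bee_id, levels = bees)
  n_a <- table(f_bee, factor(bin, levels = seq_len(nb)))
  n_ai <- table(f_bee[act$to == "inactive"],
                factor(bin[act$to == "inactive"], levels = seq_len(nb)))
  list(n_a = unclass(n_a), n_ai = unclass(n_ai), bees = bees)
}

contrast_from_counts <- function(cc, ci, sel_c, sel_i, temp_bins, t_thresh,
                                 min_count) {
  na_c <- colSums(cc$n_a[sel_c, , drop = FALSE])
  ai_c <- colSums(cc$n_ai[sel_c, , drop = FALSE])
  na_i <- colSums(ci$n_a[sel_i, , drop = FALSE])
  ai_i <- colSums(ci$n_ai[sel_i, , drop = FALSE])
  diff_in <- function(use) {
    ok <- use[na_c[use] >= min_count & na_i[use] >= min_count]
    if (!length(ok)) return(NA_real_)
    w <- na_c[ok] + na_i[ok]
    sum(w * (ai_i[ok] / na_i[ok] - ai_c[ok] / na_c[ok])) / sum(w)
  }
  nb <- length(temp_bins) - 1L
  c(below = diff_in(which(temp_bins[-1] <= t_thresh)),
    above = diff_in(intersect(which(temp_bins[-(nb + 1)] >= t_thresh),
                              seq_len(nb))))
}

#' Treatment-arm contrast in the active-to-inactive probability
#'
#' Difference (imidacloprid minus control) in p(a->i), pooled over shared
#' temperature bins with opportunity-weighted averaging, reported separately
#' below and above the body-temperature threshold. The CI is a bee-level
#' bootstrap (resampling bees within each arm).
#'
#' @param seq_control,seq_imid stacked [label_states()] outputs per arm.
#' @param temp_bins bin edges, degrees C.
#' @param t_thresh body-temperature threshold, degrees C.
#' @param min_count minimum opportunities per bin per arm.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @return list with `below` and `above`, each `c(diff, lo, hi)` (NA when
#'   not estimable), plus `n_boot`.
#' @export
arm_contrast <- function(seq_control, seq_imid,
                         temp_bins = seq(10, 30, by = 2), t_thresh = 18,
                         min_count = 50, n_boot = 200, conf = 0.95) {
  pr_c <- transition_pairs(seq_control)
  pr_i <- transition_pairs(seq_imid)
  pr_c <- pr_c[!is.na(pr_c$temp_c), ]; pr_i <- pr_i[!is.na(pr_i$temp_c), ]
  cc <- bee_bin_counts(pr_c, temp_bins)
  ci <- bee_bin_counts(pr_i, temp_bins)
  est <- contrast_from_counts(cc, ci, seq_along(cc$bees),
                              seq_along(ci$bees), temp_bins, t_thresh,
                              min_count)
  boot <- t(vapply(seq_len(n_boot), function(r) {
    contrast_from_counts(cc, ci,
                         sample.int(length(cc$bees), replace = TRUE),
                         sample.int(length(ci$bees), replace = TRUE),
                         temp_bins, t_thresh, min_count)
  }, numeric(2)))
  a <- (1 - conf) / 2
  qs <- function(v) if (all(is.na(v))) c(NA_real_, NA_real_) else
    stats::quantile(v, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(below = c(diff = unname(est["below"]),
                 lo = qs(boot[, 1])[1], hi = qs(boot[, 1])[2]),
       above = c(diff = unname(est["above"]),
                 lo = qs(boot[, 2])[1], hi = qs(boot[, 2])[2]),
       n_boot = n_boot)
}

#' Activity fraction by body-temperature bin
#'
#' Share of state-defined frames labelled active in each bin, with Wilson
#' CIs.
#'
#' @inheritParams estimate_transitions
#' @return data.frame per bin: bounds, `n_frames`, `activity`, CI, `arm`.
#' @export
activity_vs_temp <- function(sequences, temp_bins = seq(10, 30, by = 2),
                             arm = "control", min_count = 50, conf = 0.95) {
  if (length(temp_bins) < 2L) stop("need at least one temperature bin")
  s <- sequences[!is.na(sequences$state) & !is.na(sequences$body_temp_c), ]
  bin <- cut(s$body_temp_c, temp_bins, right = FALSE)
  rows <- lapply(seq_len(length(temp_bins) - 1L), function(b) {
    sel <- s[which(as.integer(bin) == b), ]
    n <- nrow(sel)
    k <- sum(sel$state == "active")
    act <- if (n >= min_count) k / n else NA_real_
    ci <- if (is.na(act)) data.frame(lo = NA_real_, hi = NA_real_)
          else wilson_ci(k, n, conf)
    data.frame(temp_lo = temp_bins[b], temp_hi = temp_bins[b + 1L],
               n_frames = n, activity = act, lo = ci$lo, hi = ci$hi,
               arm = arm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
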