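test_that("occupancy grids are normalised histograms", {
  nest <- toy_nest()
  seg <- toy_segment(track_df("b1", 0:3, c(5, 5, 5, 5), c(5, 5, 5, 5)))
  g <- occupancy_distribution(seg, "b1", nest, bin_size_mm = 20)
  expect_equal(sum(g$p), 1)
  expect_equal(max(g$p), 1)          # stationary bee: one bin holds all mass
  seg4 <- toy_segment(track_df("b1", 0:3, c(5, 25, 45, 65),
                               c(5, 25, 45, 65)))
  g4 <- occupancy_distribution(seg4, "b1", nest, bin_size_mm = 20)
  expect_equal(sort(g4$p[g4$p > 0]), rep(0.25, 4))
  expect_error(occupancy_distribution(seg, "nope", nest), "no detections")
})

test_that("occupancy normalisation holds across random segments", {
  nest <- toy_nest()
  for (seed in 1:25) {
    seg <- random_segment(n_bees = 2, n_frames = sample(1:30, 1),
                          seed = seed)
    g <- occupancy_distribution(seg, "b01", nest, bin_size_mm = 15)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
  }
})

test_that("element interaction rate equals the brute-force double loop", {
  set.seed(12)
  for (rep in 1:40) {
    n_el <- sample(1:6, 1)
    nest <- nest_map(cbind(runif(n_el, 0, 100), runif(n_el, 0, 100)),
                     matrix(numeric(), 0, 2),
                     c(xmin = 0, xmax = 100, ymin = 0, ymax = 100), 1)
    seg <- random_segment(1, sample(2:20, 1), seed = 1000 + rep)
    g <- occupancy_distribution(seg, "b01", nest, bin_size_mm = 20)
    # brute force: count detections and elements per bin, sum p * count
    bins <- g$bins
    brute <- 0
    for (iy in seq_len(nrow(g$p))) for (ix in seq_len(ncol(g$p))) {
      n_el <- sum(nest$brood[, 1] >= bins$xb[ix] &
                    nest$brood[, 1] < bins$xb[ix + 1] &
                    nest$brood[, 2] >= bins$yb[iy] &
                    nest$brood[, 2] < bins$yb[iy + 1])
      brute <- brute + g$p[iy, ix] * n_el
    }
    expect_equal(element_interaction_rate(g, nest, "brood"), brute,
                 tolerance = 1e-9)
    expect_equal(element_interaction_rate(g, nest, "pots"), 0)
  }
})

test_that("all mass on a 3-element bin gives rate 3", {
  nest <- nest_map(rbind(c(5, 5), c(6, 6), c(7, 7)), matrix(numeric(), 0, 2),
                   c(xmin = 0, xmax = 100, ymin = 0, ymax = 100), 1)
  seg <- toy_segment(track_df("b1", 0:2, c(5, 6, 7), c(5, 6, 7)))
  g <- occupancy_distribution(seg, "b1", nest, bin_size_mm = 20)
  expect_equal(element_interaction_rate(g, nest, "brood"), 3)
})

test_that("spatial correlation matches the textbook formula", {
  nest <- toy_nest()
  a <- occupancy_distribution(random_segment(1, 20, 1), "b01", nest)
  expect_equal(spatial_correlation(a, a), 1)
  set.seed(2)
  for (rep in 1:30) {
    s1 <- random_segment(1, sample(3:25, 1), seed = 2000 + rep)
    s2 <- random_segment(1, sample(3:25, 1), seed = 3000 + rep)
    g1 <- occupancy_distribution(s1, "b01", nest)
    g2 <- occupancy_distribution(s2, "b01", nest)
    x <- as.vector(g1$p); y <- as.vector(g2$p)
    brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(spatial_correlation(g1, g2), brute, tolerance = 1e-9)
  }
})

test_that("disjoint single-bin grids on a two-bin arena correlate at -1", {
  nest <- nest_map(rbind(c(5, 5)), matrix(numeric(), 0, 2),
                   c(xmin = 0, xmax = 40, ymin = 0, ymax = 19), 1)
  g1 <- occupancy_distribution(toy_segment(track_df("b1", 0:1, c(5, 6),
                                                    c(5, 5))), "b1", nest)
  g2 <- occupancy_distribution(toy_segment(track_df("b1", 0:1, c(30, 31),
                                                    c(5, 5))), "b1", nest)
  expect_equal(dim(g1$p), c(1L, 2L))
  expect_equal(spatial_correlation(g1, g2), -1)
  # constant grid (uniform zero variance) is NA
  gz <- g1; gz$p[] <- 0.5
  expect_true(is.na(spatial_correlation(gz, gz)))
})

test_that("contact events equal the O(n^2) brute-force scan", {
  nest <- toy_nest()
  for (seed in 1:30) {
    seg <- random_segment(n_bees = 5, n_frames = 8, seed = 4000 + seed)
    ev <- contact_events(seg, nest, threshold_mm = 25)
    d <- seg$detections
    brute <- 0
    for (f in unique(d$frame_index)) {
      fr <- d[d$frame_index == f, ]
      for (i in seq_len(nrow(fr) - 1)) for (j in (i + 1):nrow(fr)) {
        dist <- sqrt((fr$x_px[i] - fr$x_px[j])^2 +
                       (fr$y_px[i] - fr$y_px[j])^2)
        if (dist * nest$mm_per_px < 25) brute <- brute + 1
      }
    }
    expect_equal(nrow(ev), brute)
    # symmetric graph bookkeeping: sum of degrees = 2 |edges|
    cs <- contact_summary(ev, seg)
    edges <- unique(ev[, c("bee_a", "bee_b")])
    expect_equal(sum(cs$degree_centrality), 2 * nrow(edges))
  }
})

test_that("glued and distant bees hit the contact-rate corner cases", {
  nest <- toy_nest()
  glued <- toy_segment(rbind(track_df("a", 0:9, 50, 50),
                             track_df("b", 0:9, 50.5, 50)))
  ev <- contact_events(glued, nest)
  cs <- contact_summary(ev, glued)
  expect_equal(cs$contact_rate, c(1, 1))
  expect_equal(cs$degree_centrality, c(1, 1))
  far <- toy_segment(rbind(track_df("a", 0:4, 5, 5),
                           track_df("b", 0:4, 50, 50),
                           track_df("c", 0:4, 95, 95)))
  cs2 <- contact_summary(contact_events(far, nest), far)
  expect_equal(cs2$contact_rate, c(0, 0, 0))
  expect_equal(cs2$degree_centrality, c(0, 0, 0))
})

test_that("activity threshold finds the KDE valley between two modes", {
  set.seed(13)
  speeds <- c(abs(rnorm(400, 0.2, 0.1)), rnorm(400, 5, 0.5))
  thr <- activity_threshold(speeds)
  expect_equal(thr$method, "kde_valley")
  expect_gt(thr$threshold, 0.5)
  expect_lt(thr$threshold, 4.0)
  # permutation invariance
  thr2 <- activity_threshold(sample(speeds))
  expect_equal(thr$threshold, thr2$threshold)
})

test_that("unimodal speeds take the flagged fallback path", {
  set.seed(14)
  speeds <- rnorm(500, 3, 0.3)
  thr <- activity_threshold(speeds)
  expect_equal(thr$method, "mixture_fallback")
  expect_error(activity_threshold(rep(1, 200)), "identical")
  expect_error(activity_threshold(rnorm(50)), ">= 100")
})

test_that("moving speed and activity match a hand-worked example", {
  # frames 0..5, positions hopping: speeds 5, 0, 10, 0, 5 px/frame
  tr <- track_df("b1", 0:5, c(0, 5, 5, 15, 15, 20), 0)
  msa <- moving_speed_and_activity(tr, threshold = 1)
  expect_equal(msa$moving_speed, mean(c(5, 10, 5)))
  expect_equal(msa$activity_fraction, 3 / 5)
  # gap rule: gap of 2 divides displacement, gap > 3 breaks the track
  tr2 <- track_df("b1", c(0, 2, 10), c(0, 8, 100), 0)
  sp <- frame_speeds(tr2, max_gap = 3)
  expect_equal(sp$speed_px_frame, 4)   # 8 px over 2 frames; 8-frame gap cut
  still <- track_df("b1", 0:9, 7, 7)
  msa3 <- moving_speed_and_activity(still, threshold = 1)
  expect_true(is.na(msa3$moving_speed))
  expect_equal(msa3$activity_fraction, 0)
  expect_true(is.na(moving_speed_and_activity(tr[1, ], 1)$moving_speed))
})

test_that("distance metrics equal brute-force per-frame enumeration", {
  nest <- toy_nest()
  for (seed in 1:30) {
    seg <- random_segment(n_bees = 3, n_frames = 6, seed = 5000 + seed)
    d <- seg$detections
    tr <- d[d$bee_id == "b01", ]
    dm <- distance_metrics(tr, d, nest)
    centre <- c(mean(d$x_px), mean(d$y_px))
    expect_equal(dm$distance_to_centre,
                 mean(sqrt((tr$x_px - centre[1])^2 +
                             (tr$y_px - centre[2])^2)), tolerance = 1e-9)
    all_b <- as.vector(sapply(seq_len(nrow(nest$brood)), function(k)
      sqrt((tr$x_px - nest$brood[k, 1])^2 +
             (tr$y_px - nest$brood[k, 2])^2)))
    expect_equal(dm$median_dist_all_brood, median(all_b), tolerance = 1e-9)
    per_frame_min <- sapply(seq_len(nrow(tr)), function(i)
      min(sqrt((nest$brood[, 1] - tr$x_px[i])^2 +
                 (nest$brood[, 2] - tr$y_px[i])^2)))
    expect_equal(dm$min_dist_closest_brood, median(per_frame_min),
                 tolerance = 1e-9)
  }
})

test_that("single bee at the social centre has zero distance to it", {
  seg <- toy_segment(track_df("b1", 0:4, 33, 44))
  dm <- distance_metrics(seg$detections, seg$detections, toy_nest())
  expect_equal(dm$distance_to_centre, 0)
})

test_that("one constant brood at 50 px gives matching all/closest medians", {
  nest <- nest_map(rbind(c(50, 0)), matrix(numeric(), 0, 2),
                   c(xmin = 0, xmax = 100, ymin = 0, ymax = 100), 1)
  seg <- toy_segment(track_df("b1", 0:3, 0, 0))
  dm <- distance_metrics(seg$detections, seg$detections, nest)
  expect_equal(dm$median_dist_all_brood, 50)
  expect_equal(dm$min_dist_closest_brood, 50)
  expect_true(is.na(dm$median_dist_all_pots))
})

test_that("on/off-nest classification follows the 1 cm / 2 cm rule", {
  nest <- toy_nest()   # brood at (40,40) and (60,50); 1 px = 1 mm
  expect_equal(classify_on_off_nest(45, 40, nest), "on")          # 5 mm
  expect_equal(classify_on_off_nest(40, 15, nest), "off")         # 25 mm
  expect_equal(classify_on_off_nest(40, 25, nest), "intermediate") # 15 mm
  empty <- nest_map(matrix(numeric(), 0, 2), rbind(c(1, 1)),
                    c(xmin = 0, xmax = 100, ymin = 0, ymax = 100), 1)
  expect_error(classify_on_off_nest(5, 5, empty), "brood")
})

test_that("all metrics are translation invariant", {
  nest <- toy_nest()
  seg <- random_segment(n_bees = 4, n_frames = 40, seed = 77)
  shift <- c(30, 20)
  d2 <- seg$detections
  d2$x_px <- d2$x_px + shift[1]; d2$y_px <- d2$y_px + shift[2]
  nest2 <- nest_map(sweep(nest$brood, 2, -shift), sweep(nest$pots, 2, -shift),
                    c(xmin = 0, xmax = 160, ymin = 0, ymax = 160),
                    nest$mm_per_px)
  nest1 <- nest_map(nest$brood, nest$pots,
                    c(xmin = -shift[1], xmax = 160 - shift[1],
                      ymin = -shift[2], ymax = 160 - shift[2]),
                    nest$mm_per_px)
  m1 <- compute_behaviour_table(list(seg), nest1, threshold = 2)
  m2 <- compute_behaviour_table(list(toy_segment(d2)), nest2, threshold = 2)
  for (col in behaviour_metric_names())
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9, label = col)
})

test_that("the behaviour-table driver agrees with the standalone operations", {
  nest <- toy_nest()
  seg <- random_segment(n_bees = 4, n_frames = 30, seed = 123)
  m <- compute_behaviour_table(list(seg), nest, threshold = 2)
  ev <- contact_events(seg, nest)
  cs <- contact_summary(ev, seg)
  expect_equal(m$mean_contact_rate, cs$contact_rate, tolerance = 1e-12)
  expect_equal(m$degree_centrality, cs$degree_centrality)
  for (b in unique(seg$detections$bee_id)) {
    tr <- seg$detections[seg$detections$bee_id == b, ]
    dm <- distance_metrics(tr, seg$detections, nest)
    row <- m[m$bee_id == b, ]
    expect_equal(row$distance_to_centre, dm$distance_to_centre,
                 tolerance = 1e-12)
    expect_equal(row$mean_dist_nestmates, dm$mean_dist_nestmates,
                 tolerance = 1e-12)
    msa <- moving_speed_and_activity(tr, 2)
    expect_equal(row$moving_speed, msa$moving_speed, tolerance = 1e-12)
  }
})
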