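probes3 <- data.frame(probe_id = c("p1", "p2", "p3"),
                      x_px = c(10, 50, 30), y_px = c(10, 20, 45))

# synthetic 60x60 frame with a known linear sensor and spatial gradient
linear_frame <- function(gain, offset) {
  temp <- outer(1:60, 1:60, function(y, x) 20 + 0.1 * x + 0.05 * y)
  list(temp = temp, counts = (temp - offset) / gain)
}

test_that("calibration recovers any (gain, offset) exactly without noise", {
  for (go in list(c(1, 0), c(2, 5), c(0.05, -20), c(-0.3, 7))) {
    lf <- linear_frame(go[1], go[2])
    # disc-mean probe temperatures computed independently (brute force)
    temps <- sapply(seq_len(3), function(k) {
      off <- expand.grid(dx = -3:3, dy = -3:3)
      off <- off[off$dx^2 + off$dy^2 <= 9, ]
      mean(lf$temp[cbind(probes3$y_px[k] + off$dy + 1,
                         probes3$x_px[k] + off$dx + 1)])
    })
    res <- calibrate_frame(lf$counts, probes3, temps)
    expect_true(res$calibration$calibrated)
    expect_equal(res$calibration$gain, go[1], tolerance = 1e-9)
    expect_equal(res$calibration$offset, go[2], tolerance = 1e-9)
    expect_equal(res$calibration$residual_rmse, 0, tolerance = 1e-7)
    expect_equal(res$frame_c, lf$temp, tolerance = 1e-8)
  }
})

test_that("gain=1 offset=0 calibration returns the raw frame", {
  lf <- linear_frame(1, 0)
  off <- expand.grid(dx = -3:3, dy = -3:3); off <- off[off$dx^2 + off$dy^2 <= 9, ]
  temps <- sapply(seq_len(3), function(k)
    mean(lf$temp[cbind(probes3$y_px[k] + off$dy + 1,
                       probes3$x_px[k] + off$dx + 1)]))
  res <- calibrate_frame(lf$counts, probes3, temps)
  expect_equal(res$frame_c, lf$counts, tolerance = 1e-9)
})

test_that("degenerate probe data flags the frame uncalibrated", {
  frame <- matrix(100, 60, 60)
  res <- calibrate_frame(frame, probes3, c(20, 25, 30))  # counts identical
  expect_false(res$calibration$calibrated)
  expect_null(res$frame_c)
  expect_error(calibrate_frame(frame, probes3[1, , drop = FALSE], 20),
               ">= 2 probes")
})

test_that("calibration stays accurate under count noise", {
  set.seed(31)
  gain <- 0.05; offset <- -20
  errs <- replicate(40, {
    lf <- linear_frame(gain, offset)
    noisy <- lf$counts + rnorm(length(lf$counts), sd = 1)  # 1 count = 0.05 C
    off <- expand.grid(dx = -3:3, dy = -3:3)
    off <- off[off$dx^2 + off$dy^2 <= 9, ]
    temps <- sapply(seq_len(3), function(k)
      mean(lf$temp[cbind(probes3$y_px[k] + off$dy + 1,
                         probes3$x_px[k] + off$dx + 1)]))
    res <- calibrate_frame(noisy, probes3, temps)
    mean(abs(res$frame_c - lf$temp))
  })
  expect_lt(mean(errs), 0.15)
})

test_that("identity control pairs give an identity warp", {
  set.seed(8)
  cp <- data.frame(x_tr = runif(10, 0, 500), y_tr = runif(10, 0, 500))
  cp$x_th <- cp$x_tr; cp$y_th <- cp$y_tr
  w <- fit_warp(cp)
  expect_lt(w$residual_rmse, 1e-6)
  pts <- cbind(runif(30, 0, 500), runif(30, 0, 500))
  expect_equal(predict_warp(w, pts), pts, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("affine warps are reproduced exactly from 12 pairs", {
  set.seed(9)
  cp <- data.frame(x_tr = runif(12, 0, 2000), y_tr = runif(12, 0, 2000))
  A <- matrix(c(0.21, 0.04, -0.03, 0.18), 2)
  cp$x_th <- 7 + A[1, 1] * cp$x_tr + A[1, 2] * cp$y_tr
  cp$y_th <- -4 + A[2, 1] * cp$x_tr + A[2, 2] * cp$y_tr
  w <- fit_warp(cp)
  held <- cbind(runif(50, 0, 2000), runif(50, 0, 2000))
  truth <- cbind(7 + A[1, 1] * held[, 1] + A[1, 2] * held[, 2],
                 -4 + A[2, 1] * held[, 1] + A[2, 2] * held[, 2])
  expect_lt(max(abs(predict_warp(w, held) - truth)), 0.1)
})

test_that("degenerate control configurations fail loudly", {
  cp <- data.frame(x_tr = 1:5, y_tr = 2 * (1:5), x_th = 1:5, y_th = 1:5)
  expect_error(fit_warp(cp), "collinear")
  cp2 <- data.frame(x_tr = c(1, 1, 2, 3), y_tr = c(1, 1, 5, 2),
                    x_th = 1:4, y_th = 1:4)
  expect_error(fit_warp(cp2), "[Dd]uplicate")
  expect_error(fit_warp(cp2[1:3, ]), ">= 4")
})

test_that("the simulator's smooth warp is recovered from 25 control pairs", {
  warp <- default_warp_spec()
  nest <- make_default_nest(8)
  ctrl <- registration_points(nest, warp, 25)
  w <- fit_warp(ctrl)
  set.seed(10)
  held <- cbind(runif(300, 0, 4096), runif(300, 0, 3000))
  err2 <- rowSums((predict_warp(w, held) - warp_true(held, warp))^2)
  expect_lt(sqrt(mean(err2)), 0.5)
})

identity_warp <- function() {
  cp <- data.frame(x_tr = c(0, 100, 0, 100, 50), y_tr = c(0, 0, 100, 100, 37))
  cp$x_th <- cp$x_tr; cp$y_th <- cp$y_tr
  fit_warp(cp, lambda = 0)
}

test_that("disc means match brute-force pixel enumeration", {
  w <- identity_warp()
  frame <- matrix(20, 100, 100); frame[, 51:100] <- 30  # half plane
  det <- data.frame(bee_id = "b1", frame_index = 0, x_px = 49.5, y_px = 50)
  r <- extract_body_temp(frame, det, w, radius_px = 10)
  # brute force over integer pixels
  g <- expand.grid(x = 0:99, y = 0:99)
  sel <- (g$x - 49.5)^2 + (g$y - 50)^2 <= 100
  expect_equal(r$temp_c, mean(frame[cbind(g$y[sel] + 1, g$x[sel] + 1)]),
               tolerance = 1e-12)
  expect_equal(r$n_pixels_averaged, sum(sel))
  # uniform frame: mean equals the constant
  det2 <- data.frame(bee_id = "b1", frame_index = 0, x_px = 25, y_px = 25)
  r2 <- extract_body_temp(matrix(30, 50, 50), det2, w, radius_px = 5)
  expect_equal(r2$temp_c, 30)
})

test_that("disc clipping at the frame edge and off-frame centres", {
  w <- identity_warp()
  frame <- matrix(25, 40, 40)
  det_edge <- data.frame(bee_id = "b", frame_index = 0, x_px = 1, y_px = 1)
  r <- extract_body_temp(frame, det_edge, w, radius_px = 10)
  expect_true(r$valid)
  expect_lt(r$n_pixels_averaged, sum(expand.grid(-10:10, -10:10)[[1]]^2 +
                                       expand.grid(-10:10, -10:10)[[2]]^2
                                     <= 100))
  det_off <- data.frame(bee_id = "b", frame_index = 0, x_px = 90, y_px = 90)
  r2 <- extract_body_temp(frame, det_off, w, radius_px = 10)
  expect_false(r2$valid)
  expect_error(extract_body_temp(NULL, det_edge, w), "uncalibrated")
})

test_that("disc mean commutes with frame-wide additive constants", {
  w <- identity_warp()
  set.seed(11)
  frame <- matrix(runif(2500, 10, 30), 50, 50)
  det <- data.frame(bee_id = "b", frame_index = 0, x_px = 25, y_px = 25)
  a <- extract_body_temp(frame, det, w, radius_px = 8)$temp_c
  b <- extract_body_temp(frame + 3.25, det, w, radius_px = 8)$temp_c
  expect_equal(b - a, 3.25, tolerance = 1e-12)
})

test_that("brood temperatures follow the local field", {
  nest <- toy_nest()
  cp <- data.frame(x_tr = c(0, 100, 0, 100), y_tr = c(0, 0, 100, 100))
  cp$x_th <- cp$x_tr; cp$y_th <- cp$y_tr
  w <- fit_warp(cp, lambda = 0)
  uni <- matrix(22, 100, 100)
  bt <- extract_brood_temp(uni, nest, w, radius_px = 5)
  expect_equal(bt$temp_c, rep(22, 2))
  # single Gaussian source at brood 1 makes brood 1 warmest
  g <- outer(0:99, 0:99, function(y, x)
    22 + 5 * exp(-((x - 40)^2 + (y - 40)^2) / (2 * 8^2)))
  bt2 <- extract_brood_temp(g, nest, w, radius_px = 5)
  expect_gt(bt2$temp_c[1], bt2$temp_c[2])
})

test_that("extracted body temperature tracks the simulated truth", {
  p <- sim_params(n_bees = 10, seed = 15)
  sim <- simulate_colony(p)
  tr <- sim$truth
  gf <- sort(unique(tr$global_frame))
  sel <- gf[round(seq(1, length(gf), length.out = 12))]
  pos <- lapply(sel, function(g) {
    s <- tr[tr$global_frame == g, ]; s <- s[order(s$bee_id), ]
    as.matrix(s[, c("x_px", "y_px")])
  })
  th <- render_thermal(pos, tr$time_s[match(sel, tr$global_frame)], p,
                       sim$protocol, sim$nest)
  cal <- calibrate_stack(th$stack, th$probe_log)
  w <- fit_warp(registration_points(sim$nest, p$warp, 25))
  e <- do.call(rbind, lapply(seq_along(sel), function(i) {
    s <- tr[tr$global_frame == sel[i], ]; s <- s[order(s$bee_id), ]
    bt <- extract_body_temp(cal$frames_c[[i]],
                            data.frame(bee_id = s$bee_id,
                                       frame_index = s$frame_index,
                                       x_px = s$x_px, y_px = s$y_px), w)
    data.frame(est = bt$temp_c, truth = s$body_temp_c)
  }))
  expect_gt(cor(e$est, e$truth), 0.95)
})
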