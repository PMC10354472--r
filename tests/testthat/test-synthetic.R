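test_that("simulation is bitwise reproducible under a fixed seed", {
  a <- simulate_colony(sim_params(n_bees = 4, seed = 123))
  b <- simulate_colony(sim_params(n_bees = 4, seed = 123))
  expect_identical(a$truth, b$truth)
  expect_identical(a$segments[[5]]$detections, b$segments[[5]]$detections)
  c <- simulate_colony(sim_params(n_bees = 4, seed = 124))
  expect_false(identical(a$truth$x_px, c$truth$x_px))
})

test_that("cold-phase clustering requires thermotaxis", {
  # with gain = 0 the cold-warm contrast in distance-to-centre is a small
  # random-walk residue; with the default gain it is a large negative shift
  contrast <- function(gain) {
    p <- sim_params(n_bees = 12, seed = 5, thermotaxis_gain = gain,
                    off_nest_frac = 1)  # start uniform
    tr <- simulate_colony(p)$truth
    com <- colMeans(make_default_nest(12)$brood)
    d <- sqrt((tr$x_px - com[1])^2 + (tr$y_px - com[2])^2)
    mean(d[tr$t_air_c <= 12]) - mean(d[tr$t_air_c >= 23])
  }
  with_drift <- contrast(0.6)
  no_drift <- contrast(0)
  expect_lt(with_drift, -400)               # strong centripetal shift
  expect_lt(abs(no_drift), 0.3 * abs(with_drift))
})

test_that("delta_ai_imid = 0 makes arms identical at matched seeds", {
  a <- simulate_colony(sim_params(n_bees = 4, seed = 9, delta_ai_imid = 0,
                                  imidacloprid = FALSE))
  b <- simulate_colony(sim_params(n_bees = 4, seed = 9, delta_ai_imid = 0,
                                  imidacloprid = TRUE))
  expect_identical(a$truth$x_px, b$truth$x_px)
  expect_identical(a$truth$state, b$truth$state)
})

test_that("imidacloprid raises a->i frequency by ~delta below threshold", {
  sim <- simulate_colony(sim_params(n_bees = 16, seed = 21,
                                    imidacloprid = TRUE,
                                    delta_ai_imid = 0.1))
  ctl <- simulate_colony(sim_params(n_bees = 16, seed = 21,
                                    imidacloprid = FALSE))
  freq_ai <- function(sim, below) {
    tr <- sim$truth
    tr <- tr[order(tr$bee_id, tr$video_id, tr$frame_index), ]
    same_run <- diff(tr$frame_index) == 1 &
      tr$bee_id[-1] == tr$bee_id[-nrow(tr)] &
      tr$video_id[-1] == tr$video_id[-nrow(tr)]
    from <- tr$state[-nrow(tr)]; to <- tr$state[-1]
    temp <- tr$body_temp_c[-nrow(tr)]
    sel <- same_run & from == 1 &
      (if (below) temp < 18 else temp >= 18)
    c(k = sum(to[sel] == 0), n = sum(sel))
  }
  ci <- freq_ai(sim, TRUE); cc <- freq_ai(ctl, TRUE)
  diff_below <- ci["k"] / ci["n"] - cc["k"] / cc["n"]
  se <- sqrt(ci["k"] / ci["n"] * (1 - ci["k"] / ci["n"]) / ci["n"] +
               cc["k"] / cc["n"] * (1 - cc["k"] / cc["n"]) / cc["n"])
  expect_lt(abs(diff_below - 0.1), 4 * se + 0.02)
  wi <- freq_ai(sim, FALSE); wc <- freq_ai(ctl, FALSE)
  expect_lt(abs(wi["k"] / wi["n"] - wc["k"] / wc["n"]), 0.02)
})

test_that("ground-truth transition frequencies match the specified p_ai", {
  # property: per-bin empirical a->i frequencies fall in binomial CIs of
  # the opportunity-weighted true p_ai for >= 95% of populated bins
  hits <- 0; total <- 0
  for (seed in 1:3) {
    tr <- simulate_colony(sim_params(n_bees = 8, seed = seed))$truth
    tr <- tr[order(tr$bee_id, tr$video_id, tr$frame_index), ]
    n <- nrow(tr)
    ok <- diff(tr$frame_index) == 1 & tr$bee_id[-1] == tr$bee_id[-n] &
      tr$video_id[-1] == tr$video_id[-n]
    from <- tr$state[-n][ok]; to <- tr$state[-1][ok]
    p_true <- tr$p_ai_true[-n][ok]; temp <- tr$body_temp_c[-n][ok]
    bin <- cut(temp, seq(10, 30, 2))
    for (b in levels(bin)) {
      sel <- bin == b & from == 1
      nb <- sum(sel)
      if (nb < 100) next
      k <- sum(to[sel] == 0)
      ci <- wilson_ci(k, nb)
      total <- total + 1
      if (mean(p_true[sel]) >= ci$lo && mean(p_true[sel]) <= ci$hi)
        hits <- hits + 1
    }
  }
  expect_gte(total, 10)
  expect_gte(hits / total, 0.95)
})

test_that("rendered thermal field adds heat only and obeys the sensor model", {
  p <- sim_params(n_bees = 3, seed = 2, sensor_noise_sd = 0)
  nest <- make_default_nest(3)
  pos <- list(rbind(c(1000, 1000), c(2000, 1500), c(3000, 2000)))
  th <- render_thermal(pos, 60, p, make_queenright_protocol(), nest,
                       noise = FALSE)
  amb <- protocol_temperature(make_queenright_protocol(), 1)
  field <- th$stack$frames[[1]] * p$sensor_gain + p$sensor_offset
  expect_true(all(field >= amb - 1e-9))   # heat sources only add
  # zero-amplitude kernels give a uniform frame at ambient
  p0 <- sim_params(n_bees = 3, seed = 2, body_heat_c = 0, brood_heat_c = 0,
                   sensor_gain = 1, sensor_offset = 0, sensor_noise_sd = 0)
  th0 <- render_thermal(pos, 60, p0, make_queenright_protocol(), nest,
                        noise = FALSE)
  expect_equal(max(abs(th0$stack$frames[[1]] - amb)), 0, tolerance = 1e-12)
})

test_that("simulated census obeys the Poisson growth model", {
  p <- sim_params(growth = c(b0 = log(50), b_size = 0, b_cold = 0,
                             b_imid = 0, b_ci = 0, b_3way = 0),
                  block_sd = 0)
  meta <- do.call(rbind, lapply(1:500, function(i)
    colony_meta(paste0("c", i), imidacloprid = i %% 2 == 0,
                cold = i %% 3 == 0, colony_size_at_treatment = 10)))
  cen <- simulate_census(p, meta, seed = 4)
  m <- mean(cen$total_productivity)
  expect_lt(abs(m - 50), 4 * sqrt(50 / 500))     # CLT band
  # determinism
  cen2 <- simulate_census(p, meta, seed = 4)
  expect_identical(cen, cen2)
})

test_that("combined-arm deficit is largest in small colonies", {
  p <- sim_params()   # defaults: b_ci < 0, b_3way > 0
  g <- p$growth
  lp <- function(size, cold, imid)
    g["b0"] + g["b_size"] * log10(size) + g["b_cold"] * cold +
    g["b_imid"] * imid + g["b_ci"] * cold * imid +
    g["b_3way"] * cold * imid * log10(size)
  deficit <- function(size)   # log-scale shortfall vs additive expectation
    (lp(size, 1, 0) + lp(size, 0, 1) - lp(size, 0, 0)) - lp(size, 1, 1)
  expect_gt(deficit(4), deficit(40))
  expect_gt(deficit(4), 0)
})

test_that("census overflow fails loudly", {
  p <- sim_params(growth = c(b0 = 100, b_size = 0, b_cold = 0, b_imid = 0,
                             b_ci = 0, b_3way = 0))
  meta <- colony_meta("c1", imidacloprid = FALSE, cold = FALSE,
                      colony_size_at_treatment = 10)
  expect_error(simulate_census(p, meta, seed = 1), "overflow")
})

test_that("empty brood list is a hard failure for the simulator", {
  nest <- nest_map(matrix(numeric(), 0, 2), rbind(c(10, 10)),
                   c(xmin = 0, xmax = 100, ymin = 0, ymax = 100), 1)
  expect_error(simulate_colony(sim_params(n_bees = 2, seed = 1),
                               nest = nest), "brood")
})
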