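make_trace <- function(t, len, cell = "c1", pilus = "p1") {
  data.frame(cell_id = cell, pilus_id = pilus, t_s = t, length_um = len)
}

test_that("a monotone linear decrease yields exactly one full-range event", {
  tr <- make_trace(0:10, seq(5, 0, by = -0.5))
  ev <- detect_retractions(tr, min_drop = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$L_ini_um, 5)
  expect_equal(ev$L_final_um, 0)
  expect_equal(ev$t_ini_s, 0)
  expect_equal(ev$t_final_s, 10)
  expect_equal(ev$speed_um_per_s, 0.5)
})

test_that("constant traces yield no events and short traces error", {
  expect_equal(nrow(detect_retractions(make_trace(0:5, rep(3, 6)))), 0)
  expect_error(detect_retractions(make_trace(0:1, c(3, 2))), "too short")
})

test_that("two drops separated by a plateau become two events at the plateau edges", {
  t <- 0:14
  len <- c(6, 5, 4, 3, 3, 3, 3, 3, 3, 2, 1, 1, 1, 1, 1)
  tr <- make_trace(t, len)
  ev <- detect_retractions(tr, min_drop = 0.5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t_ini_s, c(0, 8))
  expect_equal(ev$t_final_s, c(3, 10))
  expect_equal(ev$L_ini_um, c(6, 3))
  expect_equal(ev$L_final_um, c(3, 1))
  # events are ordered and non-overlapping
  expect_true(all(diff(ev$t_ini_s) > 0))
  expect_true(all(ev$t_final_s[-nrow(ev)] <= ev$t_ini_s[-1]))
  # boundaries agree with the brute-force run scan on the raw trace
  oracle <- retraction_oracle(t, len, min_drop = 0.5)
  expect_equal(ev$t_ini_s, oracle$t_ini_s)
  expect_equal(ev$t_final_s, oracle$t_final_s)
})

test_that("sub-threshold drops are discarded", {
  tr <- make_trace(0:6, c(3, 3, 2.8, 2.8, 2.8, 2.7, 2.7))
  expect_equal(nrow(detect_retractions(tr, min_drop = 0.5)), 0)
})

test_that("speeds match the endpoint formula and noiseless traces are exact", {
  ev <- data.frame(L_ini_um = 5, L_final_um = 2, t_ini_s = 0, t_final_s = 10)
  expect_equal(retraction_speed(ev), 0.3)
  ev2 <- data.frame(L_ini_um = 14, L_final_um = 0, t_ini_s = 3, t_final_s = 10)
  expect_equal(retraction_speed(ev2), 2)
  expect_error(retraction_speed(
    data.frame(L_ini_um = 5, L_final_um = 2, t_ini_s = 1, t_final_s = 1)
  ), "non-positive")

  # inverse of the generator at grid-aligned speeds
  for (v in c(0.3, 0.5, 1, 2)) {
    L0 <- if (v == 0.3) 3 else 4   # retraction time on the 0.5 s grid
    sim <- simulate_retraction_trace(v, L0 = L0, noise_sd = 0, frame_interval = 0.5)
    ev <- detect_retractions(sim$trace, min_drop = 0.5)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$speed_um_per_s, v, tolerance = 1e-12)
  }
})

test_that("the endpoint estimator is unbiased under Gaussian length noise", {
  speeds <- vapply(1:60, function(i) {
    sim <- simulate_retraction_trace(0.5, L0 = 4, noise_sd = 0.05,
                                     frame_interval = 0.5, seed = 400 + i)
    ev <- detect_retractions(sim$trace, min_drop = 0.5)
    ev$speed_um_per_s[which.max(ev$L_ini_um - ev$L_final_um)]
  }, numeric(1))
  se <- sd(speeds) / sqrt(length(speeds))
  expect_lt(abs(mean(speeds) - 0.5), 3 * se + 0.01)
})

test_that("speed-length relation detects dependence and independence", {
  # speeds proportional to initial length -> r = 1
  ev <- data.frame(L_ini_um = 2:9, L_final_um = 0, t_ini_s = 0, t_final_s = 2)
  rel <- speed_length_relation(ev)
  expect_equal(rel$estimate, 1, tolerance = 1e-12)

  # independent speeds: small r, usually insignificant
  set.seed(5)
  ev2 <- data.frame(L_ini_um = runif(100, 2, 8),
                    L_final_um = runif(100, 2, 8) - 1, t_ini_s = 0,
                    t_final_s = 1 / runif(100, 0.3, 1))
  ev2$L_ini_um <- ev2$L_final_um + 1
  rel2 <- speed_length_relation(ev2)
  expect_lt(abs(rel2$estimate), 0.3)
  expect_equal(rel2$n, 100)

  expect_error(speed_length_relation(ev2[1:2, ]), "at least 3")
  ev3 <- data.frame(L_ini_um = c(2, 3, 4), L_final_um = 0,
                    t_ini_s = 0, t_final_s = c(2, 3, 4) / 0.5)
  expect_warning(rel3 <- speed_length_relation(ev3), "zero variance")
  expect_true(rel3$degenerate && is.na(rel3$estimate))
})

test_that("mean retraction speed follows the replicate-mean convention", {
  ev <- data.frame(
    L_ini_um = rep(3, 6), L_final_um = 0, t_ini_s = 0,
    t_final_s = 3 / c(0.1, 0.3, 0.2, 0.4, 0.3, 0.5),
    replicate_id = rep(c("R1", "R2", "R3"), each = 2)
  )
  res <- mean_retraction_speed(ev)
  expect_equal(unname(res$replicate_means), c(0.2, 0.3, 0.4))
  expect_equal(res$grand_mean, 0.3)
  expect_equal(res$sem, sd(c(0.2, 0.3, 0.4)) / sqrt(3), tolerance = 1e-12)
  expect_equal(res$sem, 0.05773503, tolerance = 1e-6)

  # all speeds equal -> SEM 0; single replicate -> SEM flagged undefined
  ev0 <- ev; ev0$t_final_s <- 10
  expect_equal(mean_retraction_speed(ev0)$sem, 0)
  res1 <- mean_retraction_speed(ev[ev$replicate_id == "R1", ])
  expect_true(is.na(res1$sem) && !res1$sem_defined)
  expect_error(mean_retraction_speed(ev[0, ]), "no retraction events")
})
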