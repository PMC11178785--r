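wt_like <- function(...) {
  phenotype_preset("test", mode_fractions = c(twitcher = 1, tethered = 0, roller = 0),
                   ...)
}

test_that("presets validate their invariants", {
  expect_error(phenotype_preset("x", mode_fractions = c(0.5, 0.4, 0.0)), "sum to 1")
  expect_error(wt_like(retraction_speed_min = 0.1), "0.3, 2")
  expect_error(wt_like(retraction_speed_max = 3), "0.3, 2")
  expect_error(wt_like(pilus_nucleation_rate = -1), "positive")
  expect_error(wt_like(recoil_prob = 1.5), "at most 1")
  presets <- builtin_presets()
  expect_true(all(c("WT", "daapF", "darlJ", "daapB") %in% names(presets)))
  for (p in presets) expect_s3_class(validate_preset(p), "phenotype_preset")
  # the pilus-deficient strain preset is dominated by immobile cells,
  # the WT preset by twitchers
  expect_gt(presets$WT$mode_fractions[["twitcher"]], 0.8)
  expect_gt(presets$daapB$mode_fractions[["roller"]], 0)
})

test_that("presets round-trip through YAML", {
  p <- wt_like(pilus_nucleation_rate = 0.123, localization_noise_sd = 0.01)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_presets(p, path)
  back <- read_presets(path)[["test"]]
  expect_equal(unclass(back), unclass(p))
})

test_that("degenerate tethered preset yields a perfectly still track", {
  p <- phenotype_preset("still", mode_fractions = c(0, 1, 0),
                        tether_jitter_sd = 0, localization_noise_sd = 0,
                        duration = 30)
  sim <- simulate_track(p, "tethered", seed = 4)
  expect_equal(nrow(sim$track), 31)
  expect_true(all(sim$track$x_um == 0) && all(sim$track$y_um == 0))
  expect_equal(net_displacement(sim$track), 0)
})

test_that("noiseless rollers are collinear with persistence ratio 1 and alpha 2", {
  p <- phenotype_preset("roll", mode_fractions = c(0, 0, 1),
                        roller_speed = 0.4, roller_dwell_max = 0,
                        localization_noise_sd = 0, duration = 120)
  sim <- simulate_track(p, "roller", seed = 8)
  expect_equal(persistence_ratio(sim$track), 1, tolerance = 1e-12)
  m <- msd_all_pairs(sim$track, 1)
  expect_equal(fit_alpha(m, max_lag_fraction = 0.25), 2, tolerance = 1e-6)
  # long tethered tracks are strongly subdiffusive
  pt <- phenotype_preset("teth", mode_fractions = c(0, 1, 0),
                         tether_jitter_sd = 0.2, localization_noise_sd = 0,
                         duration = 300)
  mt <- msd_all_pairs(simulate_track(pt, "tethered", seed = 8)$track, 1)
  expect_lt(fit_alpha(mt, max_lag_fraction = 0.25), 0.5)
})

test_that("a single slow pilus pulls the cell 0.3 um per frame toward its anchor", {
  p <- wt_like(pilus_nucleation_rate = 1e6, multi_pilus_max = 1,
               pilus_length_mean = 3, pilus_length_sd = 0,
               retraction_speed_mean = 0.3, retraction_speed_sd = 0,
               recoil_prob = 0, localization_noise_sd = 0, duration = 12)
  sim <- simulate_track(p, "twitcher", seed = 2)
  steps <- sqrt(diff(sim$track$x_um)^2 + diff(sim$track$y_um)^2)
  # pilus nucleates in the first sub-step: 10 full frames of exactly 0.3 um
  expect_equal(steps[1:10], rep(0.3, 10), tolerance = 1e-9)
  # motion is directed at the recorded anchor, 3 um from the start
  anchor <- c(sim$events$anchor_x_um[1], sim$events$anchor_y_um[1])
  expect_equal(sqrt(sum(anchor^2)), 3, tolerance = 1e-9)
  p10 <- c(sim$track$x_um[11], sim$track$y_um[11])
  expect_equal(p10, anchor, tolerance = 1e-6)
  expect_equal(sim$events$speed_um_per_s[1], 0.3)
})

test_that("unknown modes are rejected", {
  expect_error(simulate_track(wt_like(), "glider", seed = 1), "unknown mode")
})

test_that("simulation is deterministic and per-track streams are order-free", {
  p <- builtin_presets()$WT
  p$duration <- 40
  a <- simulate_cohort(p, 12, 3, seed = 33)
  b <- simulate_cohort(p, 12, 3, seed = 33)
  expect_identical(a$cohort$tracks, b$cohort$tracks)
  expect_identical(a$modes, b$modes)
  # a track keeps its trajectory when the cohort grows
  c14 <- simulate_cohort(p, 14, 3, seed = 33)
  ga <- a$cohort$tracks[a$cohort$tracks$track_id == "WT_0003", c("t_s", "x_um", "y_um")]
  gc <- c14$cohort$tracks[c14$cohort$tracks$track_id == "WT_0003", c("t_s", "x_um", "y_um")]
  expect_equal(ga$x_um, gc$x_um)
})

test_that("modes are drawn at the preset fractions and spread round-robin", {
  p <- builtin_presets()$WT
  p$duration <- 5
  sim <- simulate_cohort(p, 200, 3, seed = 21)
  expect_equal(sort(unique(sim$modes$replicate_id)), c("R1", "R2", "R3"))
  expect_equal(as.vector(table(sim$modes$replicate_id)), c(67, 67, 66))
  # exact binomial 99% bounds for the twitcher count at n = 200
  p_tw <- p$mode_fractions[["twitcher"]]
  n_tw <- sum(sim$modes$mode == "twitcher")
  bounds <- stats::qbinom(c(0.005, 0.995), 200, p_tw)
  expect_gte(n_tw, bounds[1])
  expect_lte(n_tw, bounds[2])
  # degenerate fractions: everything tethered
  pt <- p; pt$mode_fractions <- c(twitcher = 0, tethered = 1, roller = 0)
  expect_true(all(simulate_cohort(pt, 10, 2, seed = 1)$modes$mode == "tethered"))
})

test_that("twitcher frame steps respect the physical bound", {
  p <- wt_like(pilus_nucleation_rate = 0.2, localization_noise_sd = 0.05,
               duration = 120)
  bound <- 2 * p$frame_interval + p$recoil_step + 4 * p$localization_noise_sd
  for (seed in 1:5) {
    tr <- simulate_track(p, "twitcher", seed = seed)$track
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    expect_lte(max(steps), bound + 1e-9)
  }
})

test_that("twitcher displacement is isotropic in the ensemble", {
  p <- builtin_presets()$WT
  p$duration <- 60
  disp <- t(vapply(1:150, function(i) {
    tr <- simulate_track(p, "twitcher", seed = 1000 + i)$track
    c(tr$x_um[nrow(tr)] - tr$x_um[1], tr$y_um[nrow(tr)] - tr$y_um[1])
  }, numeric(2)))
  # mean displacement vector indistinguishable from zero (3 sigma per axis)
  for (axis in 1:2) {
    se <- sd(disp[, axis]) / sqrt(nrow(disp))
    expect_lt(abs(mean(disp[, axis])), 3 * se)
  }
})

test_that("retraction traces shrink linearly and respect their timing", {
  sim <- simulate_retraction_trace(0.3, 3, noise_sd = 0, frame_interval = 0.5,
                                   seed = 1)
  tr <- sim$trace
  # 3 um at 0.3 um/s: zero reached exactly at t = 10 s
  expect_equal(tr$length_um[tr$t_s == 0], 3)
  expect_equal(min(tr$t_s[tr$length_um == 0]), 10)
  expect_equal(diff(tr$t_s), rep(0.5, nrow(tr) - 1))
  expect_error(simulate_retraction_trace(-1, 3), "positive")
  expect_error(simulate_retraction_trace(0.3, 20), "14")
})
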