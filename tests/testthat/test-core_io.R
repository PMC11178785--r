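test_that("track tables round-trip exactly, including gapped multi-track cohorts", {
  for (args in list(list(n_tracks = 1, n_points = 3),
                    list(n_tracks = 100, n_points = 12, gap_prob = 0.2, seed = 42))) {
    cohort <- do.call(random_cohort, args)
    path <- withr::local_tempfile(fileext = ".csv")
    write_tracks(cohort, path)
    back <- read_tracks(path)
    expect_identical(back$tracks, cohort$tracks)
    expect_equal(back$frame_interval, cohort$frame_interval)
  }
})

test_that("an empty cohort writes a header-only file", {
  cohort <- motility_cohort(data.frame(
    track_id = character(0), replicate_id = character(0), group = character(0),
    t_s = numeric(0), x_um = numeric(0), y_um = numeric(0)
  ), frame_interval = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(cohort, path)
  expect_identical(readLines(path), "track_id,replicate_id,group,t_s,x_um,y_um")
})

test_that("a 3-row single-track table is echoed into one 3-point track", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,replicate_id,group,t_s,x_um,y_um",
               "a,R1,WT,0,0,0", "a,R1,WT,1,1,0", "a,R1,WT,2,1,1"), path)
  cohort <- read_tracks(path)
  expect_length(unique(cohort$tracks$track_id), 1)
  expect_equal(nrow(cohort$tracks), 3)
  expect_equal(cohort$tracks$x_um, c(0, 1, 1))
  expect_equal(cohort$frame_interval, 1)
})

test_that("invalid tables are rejected with the offending track or line named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,replicate_id,group,t_s,x_um,y_um",
               "a,R1,WT,0,0,0", "a,R1,WT,0,1,0"), path)
  expect_error(read_tracks(path), "track 'a'")

  writeLines(c("track_id,replicate_id,group,t_s,x_um,y_um",
               "a,R1,WT,0,0,0", "a,R1,WT,1,oops,0"), path)
  expect_error(read_tracks(path), "line 3")

  writeLines(c("id,rep,grp,t,x,y", "a,R1,WT,0,0,0"), path)
  expect_error(read_tracks(path), "header")

  # spacing must sit on the frame grid
  expect_error(
    motility_cohort(data.frame(track_id = "a", replicate_id = "R1", group = "g",
                               t_s = c(0, 1, 2.5), x_um = 0:2, y_um = 0:2),
                    frame_interval = 1),
    "integer multiple"
  )
})

test_that("pixel size converts source coordinates to micrometres once", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,replicate_id,group,t_s,x_um,y_um",
               "a,R1,WT,0,10,20", "a,R1,WT,1,20,40"), path)
  cohort <- read_tracks(path, pixel_size = 0.1)
  expect_equal(cohort$tracks$x_um, c(1, 2))
  expect_equal(cohort$tracks$y_um, c(2, 4))
})

test_that("a minimal TrackMate XML with two linked spots becomes one 2-point track", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate_fixture(
    path,
    spots = data.frame(id = c(10, 11), x = c(1.5, 2.5), y = c(3, 3.5), t = c(0, 1)),
    edges = data.frame(source = 10, target = 11)
  )
  cohort <- read_tracks(path, format = "trackmate_xml")
  expect_equal(nrow(cohort$tracks), 2)
  expect_length(unique(cohort$tracks$track_id), 1)
  expect_equal(cohort$tracks$x_um, c(1.5, 2.5))
  expect_equal(cohort$tracks$t_s, c(0, 1))

  # pixel-size conversion applies to XML sources too
  cohort_px <- read_tracks(path, format = "trackmate_xml", pixel_size = 2)
  expect_equal(cohort_px$tracks$x_um, c(3, 5))
})

test_that("TrackMate edges referencing unknown spots are rejected", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate_fixture(
    path,
    spots = data.frame(id = 10, x = 1, y = 1, t = 0),
    edges = data.frame(source = 10, target = 99)
  )
  expect_error(read_tracks(path, format = "trackmate_xml"), "unknown spot ID 99")
})

test_that("pilus traces validate lengths and round-trip", {
  tr <- data.frame(cell_id = "c1", pilus_id = "p1",
                   t_s = c(0, 0.5, 1), length_um = c(3, 2.8, 2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pilus_traces(tr, path)
  back <- read_pilus_traces(path)
  expect_equal(back$length_um, tr$length_um)

  tr$length_um[2] <- -1
  expect_error(write_pilus_traces(tr, path), "non-negative")
  tr$length_um[2] <- 15
  expect_error(validate_pilus_traces <- write_pilus_traces(tr, path), "maximum")
})

test_that("configs round-trip through YAML and reject bad values", {
  cfg <- analysis_config(non_motile_threshold = 3, msd_max_lag_fraction = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_analysis_config(cfg, path)
  back <- read_analysis_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(analysis_config(msd_max_lag_fraction = 0), "msd_max_lag_fraction")
  expect_error(analysis_config(alpha_subdiffusive_max = 1.5,
                               alpha_superdiffusive_min = 1.2), "must be below")
})
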