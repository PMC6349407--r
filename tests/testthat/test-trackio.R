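test_that("delimited tables round-trip through write_tracks/read_tracks", {
  pop <- make_population(list(
    a = rbind(c(0, 0, 0), c(1.5, 0.25, 0), c(3, 0.5, 0.1)),
    "zellé_β" = rbind(c(5, 5, 5), c(5, 6, 5), c(5, 7, 5)),
    c = rbind(c(10, 0, 0), c(10.123456789, 0, 0), c(10.2, -3.7, 2))
  ), dt = 1 / 6, midline_x = -20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(pop, path)
  back <- read_tracks(path, "delimited_table")
  expect_equal(back$tracks, pop$tracks)
  expect_equal(back$dt, pop$dt)
  expect_equal(back$midline_x, pop$midline_x)
  expect_equal(back$n_frames, pop$n_frames)

  # empty population: header-only file, round-trips to zero tracks
  empty <- population(pop$tracks[0, ], dt = 1 / 6, midline_x = -20)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(empty, path2)
  back2 <- read_tracks(path2, "delimited_table")
  expect_equal(nrow(back2$tracks), 0L)
  expect_equal(back2$n_frames, 0L)
})

test_that("a minimal two-cell delimited fixture parses to two 3-frame tracks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_id,frame,x_um,y_um,z_um",
    "a,0,1,2,3", "a,1,2,2,3", "a,2,3,2,3",
    "b,0,9,9,9", "b,1,9,8,9", "b,2,9,7,9"
  ), path)
  pop <- read_tracks(path, "delimited_table", dt = 1 / 6, midline_x = 0)
  expect_s3_class(pop, "population")
  expect_equal(sort(unique(pop$tracks$cell_id)), c("a", "b"))
  expect_equal(pop$n_frames, 3L)
  expect_equal(track_positions(pop, "a")[, "x_um"], c(1, 2, 3),
               ignore_attr = TRUE)
})

test_that("TrackMate XML spots are read back verbatim as one calibrated track", {
  path <- withr::local_tempfile(fileext = ".xml")
  trackmate_xml_fixture(path)
  pop <- read_tracks(path, "trackmate_xml", dt = 1 / 6, midline_x = 0)
  expect_equal(unique(pop$tracks$cell_id), "track_0")
  pos <- track_positions(pop, "track_0")
  expect_equal(pos[, "x_um"], c(12.5, 14.0, 16.25, 19.0), ignore_attr = TRUE)
  expect_equal(pos[, "y_um"], c(40.25, 41.0, 41.5, 42.75), ignore_attr = TRUE)
  expect_equal(pos[, "z_um"], c(3.0, 3.5, 4.0, 4.25), ignore_attr = TRUE)
  expect_equal(pop$n_frames, 4L)
})

test_that("malformed inputs raise errors naming the offending record", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate><Model><AllSpots><SpotsInFrame frame="0">
    <Spot ID="7" FRAME="0" POSITION_Y="1" POSITION_Z="1" POSITION_T="0"/>
    </SpotsInFrame></AllSpots><AllTracks/></Model></TrackMate>', path)
  expect_error(read_tracks(path, "trackmate_xml", dt = 1 / 6, midline_x = 0),
               "7.*POSITION_X")

  # non-uniform frame spacing is a validation error
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,frame,t_hr,x_um,y_um,z_um",
               "a,0,0,1,1,1", "a,1,0.1,2,1,1", "a,2,0.5,3,1,1"), path2)
  expect_error(read_tracks(path2, "delimited_table", midline_x = 0),
               "[Nn]on-uniform")

  # midline metadata is mandatory
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,frame,t_hr,x_um,y_um,z_um",
               "a,0,0,1,1,1", "a,1,0.5,2,1,1"), path3)
  expect_error(read_tracks(path3, "delimited_table"), "midline_x")
})

test_that("validation flags cells missing frames and applies gap policies", {
  tracks <- tibble::tibble(
    cell_id = c(rep("full", 4), "gappy", "gappy", "gappy", "tail", "tail"),
    frame = c(0:3, 0L, 1L, 3L, 0L, 1L),
    x_um = c(0, 1, 2, 3, 10, 12, 20, 5, 5),
    y_um = 0, z_um = 0
  )
  pop <- population(tracks, dt = 1 / 6, midline_x = -1)

  res <- validate_population(pop)
  expect_equal(res$report$flagged,
               res$report$cell_id %in% c("gappy", "tail"))
  expect_equal(res$report$missing_frames[res$report$cell_id == "gappy"], "2")
  expect_equal(unique(res$population$tracks$cell_id), "full")

  # interpolation fills the single interior gap at the frame midpoint
  res2 <- validate_population(pop, gaps = "interpolate")
  g <- track_positions(res2$population, "gappy")
  expect_equal(g[3, "x_um"], (12 + 20) / 2, ignore_attr = TRUE)
  # a trailing gap cannot be interpolated: cell dropped
  expect_false("tail" %in% res2$population$tracks$cell_id)

  # idempotence: validating a validated population changes nothing
  res3 <- validate_population(res$population)
  expect_false(any(res3$report$flagged))
  expect_equal(res3$population$tracks, res$population$tracks)

  # fully complete population: zero flags
  ok <- validate_population(make_population(list(
    a = rbind(c(0, 0, 0), c(1, 0, 0)), b = rbind(c(2, 0, 0), c(3, 0, 0)))))
  expect_false(any(ok$report$flagged))
})

test_that("population invariants are enforced at construction", {
  bad <- tibble::tibble(cell_id = "a", frame = 0:1, x_um = c(0, NaN),
                        y_um = 0, z_um = 0)
  expect_error(population(bad, dt = 1 / 6, midline_x = 0), "finite")
  expect_error(population(tibble::tibble(
    cell_id = "a", frame = 0:1, x_um = c(5, 6), y_um = 0, z_um = 0,
    side = "left"
  ), dt = 1 / 6, midline_x = 0), "side")
  expect_error(population(tibble::tibble(
    cell_id = "a", frame = 0:1, x_um = 1, y_um = 0, z_um = 0
  ), dt = -1, midline_x = 0), "dt")
})
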