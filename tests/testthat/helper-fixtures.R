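# Fixtures are built in code; nothing binary ships with the tests.

PHASE_TO_CLASS <- c(rest = "non_migratory", slow = "slow",
                    moderate = "moderate", fast = "fast")

# Population from a named list of per-cell position matrices (rows = frames).
make_population <- function(cells, dt = 1 / 6, midline_x = 0, side = NULL,
                            condition = "test") {
  tracks <- dplyr::bind_rows(lapply(names(cells), function(id) {
    pos <- cells[[id]]
    tibble::tibble(
      cell_id = id, frame = seq_len(nrow(pos)) - 1L,
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      condition = condition
    )
  }))
  if (!is.null(side)) tracks$side <- side
  population(tracks, dt = dt, midline_x = midline_x)
}

# Random-walk population independent of the package's generative model.
random_population <- function(n_cells, n_frames, dt = 1 / 6, seed = 1,
                             step_sd = 3) {
  set.seed(seed)
  cells <- lapply(seq_len(n_cells), function(i) {
    steps <- matrix(rnorm(3 * (n_frames - 1), sd = step_sd), ncol = 3)
    pos <- apply(rbind(c(100, 50, 10), steps), 2, cumsum)
    pos
  })
  names(cells) <- sprintf("rw%04d", seq_len(n_cells))
  make_population(cells, dt = dt)
}

# Minimal TrackMate-style XML: one track of four spots with known positions.
trackmate_xml_fixture <- function(path) {
  xml <- '<?xml version="1.0" encoding="UTF-8"?>
<TrackMate version="7.0.0">
  <Model spatialunits="micron" timeunits="sec">
    <AllSpots nspots="4">
      <SpotsInFrame frame="0">
        <Spot ID="1001" FRAME="0" POSITION_X="12.5" POSITION_Y="40.25" POSITION_Z="3.0" POSITION_T="0"/>
      </SpotsInFrame>
      <SpotsInFrame frame="1">
        <Spot ID="1002" FRAME="1" POSITION_X="14.0" POSITION_Y="41.0" POSITION_Z="3.5" POSITION_T="600"/>
      </SpotsInFrame>
      <SpotsInFrame frame="2">
        <Spot ID="1003" FRAME="2" POSITION_X="16.25" POSITION_Y="41.5" POSITION_Z="4.0" POSITION_T="1200"/>
      </SpotsInFrame>
      <SpotsInFrame frame="3">
        <Spot ID="1004" FRAME="3" POSITION_X="19.0" POSITION_Y="42.75" POSITION_Z="4.25" POSITION_T="1800"/>
      </SpotsInFrame>
    </AllSpots>
    <AllTracks>
      <Track TRACK_ID="0" NUMBER_SPOTS="4">
        <Edge SPOT_SOURCE_ID="1001" SPOT_TARGET_ID="1002"/>
        <Edge SPOT_SOURCE_ID="1002" SPOT_TARGET_ID="1003"/>
        <Edge SPOT_SOURCE_ID="1003" SPOT_TARGET_ID="1004"/>
      </Track>
    </AllTracks>
  </Model>
</TrackMate>'
  writeLines(xml, path)
  path
}

# Brute-force Kuiper V: ECDF differences evaluated from every cyclic origin.
kuiper_oracle <- function(a, b) {
  pooled <- c(a, b) %% 360
  vs <- vapply(pooled, function(origin) {
    ra <- (a - origin) %% 360
    rb <- (b - origin) %% 360
    xs <- sort(unique(c(ra, rb)))
    Fa <- stats::ecdf(ra)(xs)
    Fb <- stats::ecdf(rb)(xs)
    max(Fa - Fb) + max(Fb - Fa)
  }, numeric(1))
  list(V = max(vs), all_origins = vs)
}
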