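test_that("a photon exactly at a cell end time belongs to the next cell", {
  cfg <- cfg_2d(rows = 2, cols = 2, line_frequency_hz = 1e6,
                bidirectional = FALSE)
  s <- build_snake_2d(cfg, 0)   # ends 5e5, 9e5, 1.5e6, 1.9e6; window opens 1e5
  expect_identical(find_cell(s, 500000), 2L)
  expect_identical(find_cell(s, 499999), 1L)
  expect_identical(find_cell(s, 99999), CELL_DISCARDED_EARLY)
  expect_identical(find_cell(s, 100000), 1L)
  # inter-line turnaround gap (after 9e5, before 1.1e6)
  expect_identical(find_cell(s, 1000000), CELL_DISCARDED_EARLY)
  expect_identical(find_cell(s, 1900000), CELL_AFTER_FRAME)
})

test_that("binary-search allocation equals the linear-scan oracle", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_snake()
    span <- max(s$end_ps) - s$frame_start_ps
    t <- round(runif(200, s$frame_start_ps - 0.1 * span,
                     max(s$end_ps) + 0.1 * span))
    fast <- find_cell(s, t)
    slow <- vapply(t, function(tt) linear_find_cell(s, tt), integer(1))
    expect_identical(fast, slow)
  }
})

test_that("line syncs alone produce frames and no records", {
  cfg <- cfg_2d(rows = 4, cols = 4)
  syncs <- tag_stream(rep(1L, 10), (0:9) * cfg$line_period_ps)
  out <- process_stream(syncs, cfg)
  expect_identical(nrow(out$records), 0L)
  expect_identical(out$stats$frames, 2L)   # floor(10 / 4)
  expect_identical(out$stats$total_spectral, 0L)
})

test_that("a photon placed mid-cell lands on that cell's coordinate", {
  cfg <- cfg_2d(rows = 4, cols = 4, bidirectional = FALSE)
  s <- build_snake_2d(cfg, 0)
  i <- which(s$row == 2L & s$col == 3L)
  t_photon <- (s$start_ps[i] + s$end_ps[i]) / 2
  n_lines <- 8L  # two frames of syncs
  tags <- tag_stream(c(rep(1L, n_lines), 2L),
                     c((0:(n_lines - 1)) * cfg$line_period_ps, t_photon))
  tags <- tags[order(tags$time_ps), ]
  out <- process_stream(tags, cfg)
  expect_identical(nrow(out$records), 1L)
  expect_identical(out$records$row, 2L)
  expect_identical(out$records$col, 3L)
  expect_identical(out$records$frame, 0L)
})

test_that("every spectral tag is classified into exactly one outcome", {
  cfg <- cfg_2d(rows = 8, cols = 8)
  gt <- make_phantom("blobs", c(8, 8), seed = 2)
  sim <- simulate_acquisition(gt, sim_params(cfg, n_frames = 3, seed = 3))
  s <- build_snake_2d(cfg, 0)
  # inject photons into turnaround, before any sync, and after the last frame
  extras <- tag_stream(rep(2L, 3),
                       c(10, max(s$end_ps) + 100,       # pre-sync-ish, turnaround
                         max(sim$tags$time_ps) + 1e9))  # far after the last frame
  tags <- rbind(sim$tags, extras)
  tags <- tags[order(tags$time_ps), ]
  out <- process_stream(tags, cfg)
  st <- out$stats
  expect_identical(st$allocated + st$discarded_early + st$after_frame + st$pre_sync,
                   st$total_spectral)
  expect_identical(st$total_spectral, nrow(sim$ledger) + 3L)
  expect_gt(st$pre_sync + st$discarded_early + st$after_frame, 0L)
})

test_that("identical stream and configuration give identical records", {
  cfg <- cfg_2d(rows = 8, cols = 8)
  gt <- make_phantom("blobs", c(8, 8), seed = 2)
  sim <- simulate_acquisition(gt, sim_params(cfg, n_frames = 2, seed = 3))
  r1 <- process_stream(sim$tags, cfg)$records
  r2 <- process_stream(sim$tags, cfg)$records
  expect_identical(r1, r2)
})

test_that("frame syncs divide into equally spaced line starts", {
  cfg <- cfg_2d(rows = 4, cols = 4, line_frequency_hz = 4e6,
                frame_rate_hz = 1e6)
  expect_equal(infer_line_starts(c(0, 1000000), 4, cfg),
               c(0, 250000, 500000, 750000, 1000000, 1250000, 1500000, 1750000))
  # a single sync falls back to the nominal frame period
  expect_equal(infer_line_starts(0, 4, cfg),
               (0:3) * cfg$line_period_ps)
  # jittered syncs: spacing tracks each measured interval
  fs <- c(0, 1020000, 1990000)
  got <- infer_line_starts(fs, 4, cfg)
  expect_equal(got[1:4], round((0:3) * 1020000 / 4))
  expect_equal(got[5:8], 1020000 + round((0:3) * (1990000 - 1020000) / 4))
})

test_that("a frame-sync-only wiring reconstructs as exactly as line syncs", {
  cfg <- experiment_config(
    channels = list(channel_spec(4, "frame_sync"), channel_spec(2, "spectral")),
    rows = 8, columns = 8, line_frequency_hz = 1e5, frame_rate_hz = 1e5 / 8)
  gt <- make_phantom("blobs", c(8, 8), seed = 6)
  sim <- simulate_acquisition(gt, sim_params(cfg, n_frames = 3, seed = 8))
  recon <- process_stream(sim$tags, cfg)
  rep <- round_trip_report(gt, recon, sim$ledger, cfg)
  expect_true(rep$photon_conservation)
  expect_equal(rep$per_voxel_exactness, 1.0)
})

test_that("dropped line syncs are inferred at nominal spacing", {
  cfg <- cfg_2d(rows = 4, cols = 4, bidirectional = FALSE)
  Tl <- cfg$line_period_ps
  full <- (0:7) * Tl
  tags <- tag_stream(rep(1L, 7), full[-4])   # drop the 4th sync
  out <- process_stream(tags, cfg)
  expect_identical(out$stats$inferred_lines, 1L)
  expect_identical(out$stats$frames, 2L)
})

test_that("photons before any sync are counted, never fatal", {
  cfg <- cfg_2d(rows = 2, cols = 2)
  tags <- tag_stream(c(2L, 2L, 1L, 1L, 1L),
                     c(5, 10, 1000, 1000 + cfg$line_period_ps,
                       1000 + 2 * cfg$line_period_ps))
  out <- process_stream(tags, cfg)
  expect_identical(out$stats$pre_sync, 2L)
  expect_identical(out$stats$frames, 1L)
})

test_that("tags on undeclared channels are warned about and ignored", {
  cfg <- cfg_2d(rows = 2, cols = 2)
  tags <- tag_stream(c(1L, 9L, 1L, 1L),
                     c(0, 10, cfg$line_period_ps, 2 * cfg$line_period_ps))
  expect_warning(out <- process_stream(tags, cfg), "undeclared")
  expect_identical(out$stats$total_spectral, 0L)
})
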