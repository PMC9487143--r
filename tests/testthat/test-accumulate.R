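fake_records <- function(row, col, plane = 0L, frame = 0L, channel = 2L) {
  data.frame(spectral_channel = channel, demux_stream = NA_integer_,
             frame = frame, row = row, col = col, plane = plane,
             time_ps = seq_along(row))
}

test_that("duplicate records accumulate as a multiset count", {
  buf <- frame_buffer(4, 4)
  buf <- increment(buf, fake_records(c(1L, 1L, 1L), c(2L, 2L, 2L)))
  expect_identical(buf[2, 3, 1], 3L)
  expect_identical(sum(buf), 3L)
})

test_that("increment is order-independent and splits commute with merging", {
  set.seed(9)
  recs <- fake_records(sample(0:5, 300, TRUE), sample(0:5, 300, TRUE),
                       sample(0:1, 300, TRUE))
  whole <- increment(frame_buffer(6, 6, 2), recs)
  permuted <- increment(frame_buffer(6, 6, 2), recs[sample(nrow(recs)), ])
  split <- increment(increment(frame_buffer(6, 6, 2), recs[1:100, ]),
                     recs[101:300, ])
  expect_identical(unclass(permuted), unclass(whole))
  expect_identical(unclass(split), unclass(whole))
  expect_identical(sum(whole), 300L)   # conservation
})

test_that("a large random batch conserves its photon count exactly", {
  set.seed(10)
  n <- 2e4
  recs <- fake_records(sample(0:31, n, TRUE), sample(0:31, n, TRUE),
                       sample(0:3, n, TRUE))
  buf <- increment(frame_buffer(32, 32, 4), recs)
  expect_identical(sum(buf), as.integer(n))
})

test_that("records outside the buffer are a hard error", {
  buf <- frame_buffer(4, 4)
  expect_error(increment(buf, fake_records(4L, 0L)), "bounds")
  expect_error(increment(buf, fake_records(0L, 0L, frame = 2L)), "frame")
})

test_that("a window of one displays the frame itself", {
  view <- rolling_view(1)
  f1 <- increment(frame_buffer(4, 4), fake_records(1L, 1L))
  view <- push_frame(view, f1)
  expect_equal(current_sum(view), array(as.numeric(f1), dim = dim(f1)))
})

test_that("the ring evicts the oldest frame after N pushes", {
  n <- 5
  view <- rolling_view(n)
  const <- increment(frame_buffer(3, 3), fake_records(0L, 0L))
  for (i in seq_len(n + 1)) view <- push_frame(view, const)
  disp <- current_sum(view, check = TRUE)
  expect_equal(disp, array(as.numeric(const) * n, dim = dim(const)))
  expect_equal(current_sum(view, average = TRUE),
               array(as.numeric(const), dim = dim(const)))
})

test_that("warm-up sums only the frames pushed so far", {
  view <- rolling_view(10)
  f <- increment(frame_buffer(2, 2), fake_records(1L, 0L))
  view <- push_frame(view, f)
  view <- push_frame(view, f)
  expect_equal(current_sum(view)[2, 1, 1], 2)
})

test_that("the depth projection sums frames then takes the plane maximum", {
  z <- array(0L, dim = c(4, 4, 2, 3))
  expect_equal(summed_projection(z), matrix(0, 4, 4))
  one <- array(0L, dim = c(4, 4, 2, 1))
  one[2, 3, 2, 1] <- 1L
  proj <- summed_projection(one)
  expect_equal(sum(proj), 1)
  expect_equal(proj[2, 3], 1)
  # a photon repeated across frames sums before the maximum is taken
  rep3 <- array(0L, dim = c(4, 4, 2, 3))
  rep3[2, 3, 1, ] <- 1L
  rep3[2, 3, 2, 2] <- 5L
  expect_equal(summed_projection(rep3)[2, 3], 5)
})

test_that("per-channel and per-stream buffers are never blended", {
  recs <- rbind(
    data.frame(spectral_channel = 2L, demux_stream = 0L, frame = 0L,
               row = 0L, col = 0L, plane = 0L, time_ps = 1),
    data.frame(spectral_channel = 2L, demux_stream = 1L, frame = 0L,
               row = 0L, col = 0L, plane = 0L, time_ps = 2),
    data.frame(spectral_channel = 3L, demux_stream = NA_integer_, frame = 0L,
               row = 1L, col = 1L, plane = 0L, time_ps = 3))
  cfg <- cfg_2d(rows = 2, cols = 2)
  out <- accumulate_run(recs, cfg)
  expect_setequal(names(out), c("ch2.s0", "ch2.s1", "ch3"))
  expect_equal(sum(out$ch2.s0), 1)
  expect_equal(sum(out$ch2.s1), 1)
  expect_equal(sum(out$ch3), 1)
})

test_that("the summed projection recovers the vessel phantom's silhouette", {
  # slow (galvo-style) scan: the per-pixel dwell spans full TAG cycles, so a
  # short recording samples every plane and the depth projection should
  # correlate strongly with the phantom's own 2D silhouette
  cfg <- experiment_config(
    channels = list(channel_spec(1, "line_sync"), channel_spec(2, "spectral"),
                    channel_spec(5, "tag_sync")),
    rows = 32, columns = 32, planes = 8,
    line_frequency_hz = 1920, tag_frequency_hz = 189000)
  gt <- make_phantom("vessels3d", c(32, 32, 8), seed = 2)
  sim <- simulate_acquisition(gt, sim_params(cfg, brightness = 1,
                                             n_frames = 3, seed = 101))
  recon <- process_stream(sim$tags, cfg)
  rep <- round_trip_report(gt, recon, sim$ledger, cfg)
  expect_gte(rep$ncc, 0.9)
  expect_equal(rep$per_voxel_exactness, 1.0)
})

test_that("end-to-end counts equal the allocator's allocated total", {
  cfg <- cfg_2d(rows = 12, cols = 12)
  gt <- make_phantom("grid", c(12, 12), spacing = 4)
  sim <- simulate_acquisition(gt, sim_params(cfg, n_frames = 4, seed = 13))
  recon <- process_stream(sim$tags, cfg)
  stacks <- accumulate_run(recon$records, cfg)
  expect_equal(sum(Reduce(`+`, stacks)), recon$stats$allocated)
})
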