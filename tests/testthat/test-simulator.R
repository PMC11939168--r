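test_that("noiseless geometry: disjoint cage intervals with exactly two fences", {
  res <- simulate_inspection(simulation_config(n_cages = 3, seed = 11))
  cages <- res$truth$cages
  expect_equal(nrow(cages), 3)
  expect_true(all(cages$exit_frame[-3] < cages$entry_frame[-1]))  # disjoint
  for (i in 1:3) {
    for (f in seq(cages$entry_frame[i], cages$exit_frame[i])) {
      det <- res$stream$frames[[f + 1]]$detections
      expect_equal(sum(det$label == "fence"), 2)
    }
  }
  expect_true(all(cages$occupancy >= 5 & cages$occupancy <= 8))
  # all confidences are 1 before noise
  expect_true(all(stream_to_df(res$stream)$confidence == 1))
})

test_that("simulation is bit-identical for equal seeds", {
  a <- simulate_inspection(simulation_config(n_cages = 2, seed = 5))
  b <- simulate_inspection(simulation_config(n_cages = 2, seed = 5))
  expect_identical(a$stream$frames, b$stream$frames)
  expect_identical(a$truth$cages, b$truth$cages)
  c <- simulate_inspection(simulation_config(n_cages = 2, seed = 6))
  expect_false(identical(a$truth$heads, c$truth$heads))
})

test_that("kinematics: a cage interior takes width/speed*fps frames to traverse", {
  sim <- simulation_config()
  res <- simulate_inspection(simulation_config(n_cages = 2, seed = 1))
  expect_equal(res$truth$frames_per_cage,
               sim$cage_width_m / sim$robot_speed_mps * sim$fps)  # = 90
  expect_equal(res$truth$frames_per_cage, 90)
  # consecutive cages are one pitch apart in frames
  step_px <- sim$robot_speed_mps / sim$fps * sim$px_per_m
  pitch_px <- (2 * sim$fence_width_m + sim$cage_width_m +
                 sim$gap_between_cages_m) * sim$px_per_m
  expect_equal(diff(res$truth$cages$entry_frame), round(pitch_px / step_px))
})

test_that("degenerate configs are rejected with advice", {
  expect_error(simulate_inspection(simulation_config(fps = 0.1,
                                                     robot_speed_mps = 1)),
               "increase fps", class = "cagecount_config_error")
  expect_error(simulation_config(occupancy_range = c(0, 3)),
               class = "cagecount_config_error")
})

test_that("all-zero noise is the identity on the stream", {
  res <- simulate_inspection(simulation_config(n_cages = 2, seed = 3))
  out <- apply_noise(res$stream, zero_noise(), seed = 123)
  expect_identical(out$frames, res$stream$frames)
})

test_that("head_miss_prob = 1 removes every chicken head", {
  res <- simulate_inspection(simulation_config(n_cages = 2, seed = 3))
  out <- apply_noise(res$stream, noise_config(head_miss_prob = 1, fp_rate = 0,
                                              jitter_px_sd = 0,
                                              fence_dropout_prob = 0,
                                              confidence_model = NULL),
                     seed = 1)
  df <- stream_to_df(out)
  expect_equal(sum(df$label == "chicken_head"), 0)
  expect_gt(sum(df$label == "fence"), 0)
})

test_that("empirical miss fraction matches the Bernoulli rate", {
  res <- simulate_inspection(simulation_config(n_cages = 10, seed = 8))
  n_before <- sum(stream_to_df(res$stream)$label == "chicken_head")
  expect_gt(n_before, 10000)   # plenty of head-frames for a tight check
  p <- 0.2
  out <- apply_noise(res$stream, noise_config(head_miss_prob = p, fp_rate = 0,
                                              jitter_px_sd = 0,
                                              fence_dropout_prob = 0,
                                              confidence_model = NULL),
                     seed = 21)
  n_after <- sum(stream_to_df(out)$label == "chicken_head")
  miss_frac <- 1 - n_after / n_before
  tol <- 3 * sqrt(p * (1 - p) / n_before)
  expect_lt(abs(miss_frac - p), tol)
})

test_that("moderate miss noise keeps one record per cage with max <= occupancy", {
  for (seed in c(2, 9, 17)) {
    res <- simulate_inspection(simulation_config(n_cages = 4, seed = seed))
    noisy <- apply_noise(res$stream,
                         noise_config(head_miss_prob = 0.1, fp_rate = 0,
                                      jitter_px_sd = 1,
                                      fence_dropout_prob = 0,
                                      confidence_model = c(0.9, 0.03)),
                         seed = seed + 100)
    recs <- count_stream(noisy)
    expect_equal(nrow(recs), 4)
    expect_true(all(recs$max_count <= res$truth$cages$occupancy))
  }
})

test_that("isolated dropout bursts shorter than N preserve the emission count", {
  cfg <- counter_config()
  res <- simulate_inspection(simulation_config(n_cages = 3, seed = 4))
  drop_one_fence <- function(stream, frames) {
    for (f in frames) {
      d <- stream$frames[[f + 1]]$detections
      victim <- which(d$label == "fence")
      if (length(victim))
        stream$frames[[f + 1]]$detections <- d[-victim[1], , drop = FALSE]
    }
    stream
  }
  cages <- res$truth$cages
  # 9-frame bursts mid-cage, at a cage entry, and straddling a cage exit
  bursts <- list(cages$entry_frame[2] + 20 + 0:8,
                 cages$entry_frame[1] + 0:8,
                 cages$exit_frame[3] - 4 + 0:8)
  mutated <- res$stream
  for (b in bursts) mutated <- drop_one_fence(mutated, b)
  recs <- count_stream(mutated, cfg)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$max_count, cages$occupancy)
})

test_that("random dropout bursts agree with the run-length oracle", {
  # unconstrained burst process: back-to-back bursts may legitimately merge
  # into runs >= N and split a cage; the machine must track the oracle.
  cfg <- counter_config()
  for (seed in c(4, 13)) {
    res <- simulate_inspection(simulation_config(n_cages = 3, seed = seed))
    noisy <- apply_noise(res$stream,
                         noise_config(head_miss_prob = 0, fp_rate = 0,
                                      jitter_px_sd = 0,
                                      fence_dropout_prob = 0.05,
                                      dropout_len_range = c(3, 9),
                                      confidence_model = NULL),
                         seed = seed)
    f_seq <- vapply(noisy$frames,
                    function(f) sum(f$detections$label == "fence"), integer(1))
    expect_equal(nrow(count_stream(noisy, cfg, flush = FALSE)),
                 ref_emission_count(f_seq, N = 10))
  }
})

test_that("the worked-example fixture has 11 heads, 3 outside, 8 kept", {
  fx <- make_worked_example_frame()
  det <- fx$detections
  heads <- det[det$label == "chicken_head", ]
  fences <- det[det$label == "fence", ]
  expect_equal(nrow(heads), 11)
  for (mode in c("outer", "inner")) {
    span <- cage_span(fences, mode)
    expect_equal(nrow(heads_in_span(heads, span, "center")), 8)
  }
  # the excluded three lie beyond the outer railing envelope
  outer <- cage_span(fences, "outer")
  cx <- (heads$x_min + heads$x_max) / 2
  expect_equal(sum(cx < outer$x_low | cx > outer$x_high), 3)
})

test_that("noise injection moves the key frame with the surviving maximum", {
  res <- simulate_inspection(simulation_config(n_cages = 1, seed = 31))
  base <- count_stream(res$stream)
  noisy <- apply_noise(res$stream,
                       noise_config(head_miss_prob = 0.4, fp_rate = 0,
                                    jitter_px_sd = 0, fence_dropout_prob = 0,
                                    confidence_model = NULL),
                       seed = 77)
  recs <- count_stream(noisy)
  expect_equal(nrow(recs), 1)
  # recompute the argmax of in-span counts on the noisy stream directly
  cfg <- counter_config()
  counts <- vapply(noisy$frames, function(fr) {
    det <- fr$detections
    fences <- det[det$label == "fence", , drop = FALSE]
    if (nrow(fences) != 2) return(-1L)
    span <- cage_span(fences, cfg$span_mode)
    nrow(heads_in_span(det[det$label == "chicken_head", , drop = FALSE],
                       span, cfg$membership))
  }, integer(1))
  expect_equal(recs$max_count, max(counts))
  expect_equal(recs$key_frame_index, which.max(counts) - 1L)
})
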