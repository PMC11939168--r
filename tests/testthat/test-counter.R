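two_fences <- function(x = c(100, 1050)) {
  detections(label = c("fence", "fence"), x_min = x, y_min = 40,
             x_max = x + 80, y_max = 700, confidence = 0.95)
}

test_that("cage_span computes outer and inner lateral thresholds", {
  fences <- detections(label = c("fence", "fence"),
                       x_min = c(100, 1050), y_min = 0,
                       x_max = c(180, 1130), y_max = 700)
  outer <- cage_span(fences, "outer")
  expect_equal(c(outer$x_low, outer$x_high), c(100, 1130))
  inner <- cage_span(fences, "inner")
  expect_equal(c(inner$x_low, inner$x_high), c(180, 1050))
  # order of the two rows must not matter for inner (left = smaller center)
  inner_rev <- cage_span(fences[2:1, ], "inner")
  expect_equal(c(inner_rev$x_low, inner_rev$x_high), c(180, 1050))

  overlapping <- detections(label = c("fence", "fence"),
                            x_min = c(100, 150), y_min = 0,
                            x_max = c(300, 350), y_max = 700)
  expect_error(cage_span(overlapping, "inner"), "degenerate",
               class = "cagecount_contract_error")
  expect_error(cage_span(fences[1, , drop = FALSE], "outer"),
               "exactly 2", class = "cagecount_contract_error")
})

test_that("heads_in_span filters by center with closed bounds, preserving order", {
  span <- structure(list(x_low = 200, x_high = 800), class = "cage_span")
  heads <- detections(label = rep("chicken_head", 4),
                      x_min = c(150, 180, 400, 900),
                      y_min = 100, x_max = c(250, 260, 500, 1000), y_max = 200)
  # centers: 200 (on x_low, kept), 220, 450, 950 (out)
  kept <- heads_in_span(heads, span, "center")
  expect_equal(nrow(kept), 3)
  expect_equal(kept$x_min, c(150, 180, 400))
  # full_box requires containment
  expect_equal(nrow(heads_in_span(heads, span, "full_box")), 1)
  expect_equal(nrow(heads_in_span(heads[0, ], span, "center")), 0)
})

test_that("a 9-frame single-fence burst is a false detection; 10 frames emit", {
  # counting at max 6, then a short burst, then two fences again
  s9 <- make_fence_frames(c(rep(2, 5), rep(1, 9), 2), heads_on_two = 6)
  state <- new_counter_state()
  emitted <- list()
  for (fr in s9$frames) {
    res <- counter_step(state, fr)
    state <- res$state
    if (!is.null(res$record)) emitted[[length(emitted) + 1]] <- res$record
  }
  expect_length(emitted, 0)
  expect_equal(state$running_max, 6L)      # original maximum maintained
  expect_equal(state$phase, "COUNTING")

  s10 <- make_fence_frames(c(rep(2, 5), rep(1, 10)), heads_on_two = 6)
  recs <- count_stream(s10, flush = FALSE)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$max_count, 6L)
  expect_equal(recs$key_frame_index, 0L)   # earliest frame attaining the max
})

test_that("idle zero-fence frames and three-fence frames leave the machine alone", {
  s <- make_fence_frames(rep(0, 20))
  expect_equal(nrow(count_stream(s)), 0)

  state <- new_counter_state()
  for (fr in make_fence_frames(c(2, 2, 3, 3, 3, 2))$frames)
    state <- counter_step(state, fr)$state
  expect_equal(state$phase, "COUNTING")
  expect_equal(state$single_fence_streak, 0L)

  # a three-fence frame mid-transition neither resets nor advances the streak
  state <- new_counter_state()
  for (fr in make_fence_frames(c(2, 1, 1, 3, 1))$frames)
    state <- counter_step(state, fr)$state
  expect_equal(state$single_fence_streak, 3L)
  expect_equal(state$phase, "TRANSITION")
})

test_that("a short dropout between cages merges them into one record", {
  # two 5-bird cages separated by only 9 sub-two-fence frames
  s <- make_fence_frames(c(rep(2, 6), rep(1, 9), rep(2, 6)), heads_on_two = 5)
  recs <- count_stream(s)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$max_count, 5L)
})

test_that("end-of-stream flush emits the pending cage", {
  s <- make_fence_frames(rep(2, 8), heads_on_two = 7)
  recs <- count_stream(s)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$max_count, 7L)
  expect_equal(count_stream(s, flush = FALSE)$max_count, integer(0))
})

test_that("low-confidence detections are invisible to the machine", {
  fences <- two_fences()
  fences$confidence <- c(0.95, 0.1)      # second fence below threshold
  fr <- frame_record(0L, fences, c(1280, 720), fps = 30)
  state <- counter_step(new_counter_state(), fr)$state
  expect_equal(state$phase, "IDLE")      # saw one fence, not two
})

test_that("running max is non-decreasing within a cage segment", {
  res <- simulate_inspection(simulation_config(n_cages = 2, seed = 42))
  state <- new_counter_state()
  prev_max <- 0L
  for (fr in res$stream$frames) {
    out <- counter_step(state, fr)
    if (is.null(out$record) && out$state$cages_emitted == state$cages_emitted) {
      expect_gte(out$state$running_max, prev_max)
      prev_max <- out$state$running_max
    } else prev_max <- 0L
    state <- out$state
  }
})

test_that("emissions match the run-length oracle on random fence sequences", {
  withr::with_seed(99, {
    for (case in 1:60) {
      f_seq <- sample(0:3, sample(20:60, 1), replace = TRUE,
                      prob = c(0.2, 0.3, 0.4, 0.1))
      s <- make_fence_frames(f_seq)
      got <- nrow(count_stream(s, flush = FALSE))
      expect_identical(got, as.integer(ref_emission_count(f_seq, N = 10)),
                       label = paste("seq", case))
    }
  })
  # a single two-fence frame resets the streak: interleave 9-runs with resets
  f_seq <- rep(c(2, rep(1, 9)), 5)
  expect_equal(nrow(count_stream(make_fence_frames(f_seq), flush = FALSE)), 0)
})

test_that("zero-fence streak participation is configurable", {
  f_seq <- c(2, 2, rep(0, 10))
  on <- counter_config(zero_fence_in_streak = TRUE)
  off <- counter_config(zero_fence_in_streak = FALSE)
  expect_equal(nrow(count_stream(make_fence_frames(f_seq, heads_on_two = 3),
                                 on, flush = FALSE)), 1)
  expect_equal(nrow(count_stream(make_fence_frames(f_seq, heads_on_two = 3),
                                 off, flush = FALSE)), 0)
})

test_that("select_key_frame returns the earliest frame attaining the maximum", {
  # per-frame in-span counts 3, 5, 5, 4 -> key frame is the first with 5
  counts <- c(3, 5, 5, 4)
  frames <- lapply(seq_along(counts), function(i) {
    det <- two_fences()
    cx <- seq(300, 900, length.out = counts[i])
    det <- rbind(det, detections(label = rep("chicken_head", counts[i]),
                                 x_min = cx - 20, y_min = 300,
                                 x_max = cx + 20, y_max = 340, confidence = 0.9))
    frame_record(i - 1L, det, c(1280, 720), fps = 30)
  })
  s <- detection_stream(frames, fps = 30)
  recs <- count_stream(s)
  expect_equal(recs$key_frame_index, 1L)
  kf <- select_key_frame(s, recs[1, ])
  expect_equal(kf$frame_index, 1L)
  expect_equal(sum(kf$detections$label == "chicken_head"), 5)

  single <- detection_stream(frames[2], fps = 30)
  single$frames[[1]]$frame_index <- 1L
  rec1 <- count_stream(single)
  expect_equal(select_key_frame(single, rec1[1, ])$frame_index, 1L)
  expect_error(select_key_frame(s, data.frame(key_frame_index = 99L)),
               "not present", class = "cagecount_contract_error")
})

test_that("adding in-span false heads never lowers the count; removing never raises it", {
  base <- make_fence_frames(c(rep(2, 4), rep(1, 10)), heads_on_two = 5)
  rec0 <- count_stream(base, flush = FALSE)$max_count
  # inject an extra in-span head into frame 2
  plus <- base
  extra <- detections("chicken_head", 480, 300, 520, 340, 0.9)
  plus$frames[[2]]$detections <- rbind(plus$frames[[2]]$detections, extra)
  expect_gte(count_stream(plus, flush = FALSE)$max_count, rec0)
  # remove a head from every counting frame
  minus <- base
  for (i in 1:4) {
    d <- minus$frames[[i]]$detections
    drop <- which(d$label == "chicken_head")[1]
    minus$frames[[i]]$detections <- d[-drop, , drop = FALSE]
  }
  expect_lte(count_stream(minus, flush = FALSE)$max_count, rec0)
})
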