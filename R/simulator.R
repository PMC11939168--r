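# Synthetic inspection-stream simulator.
#
# The world is a 1-D row of cages filmed by a camera moving parallel to the
# row at fixed standoff, so horizontal translation is the only motion that
# matters to the counting rule and projection is a pure x-shift (no
# perspective).  Each cage is [left fence | interior | right fence]; heads
# are static world points inside the interior (the counter's max-over-frames
# behaviour is exercised through occlusion noise rather than bird motion).
# Cage modules are spaced at least one view width apart so that at most one
# cage is ever imaged at a time -- the geometric realization of the
# acquisition protocol, which controls the standoff so the field of view
# covers two railings without including a third.  That spacing is what makes
# the fence count fall to one (and briefly zero) between cages, which is the
# signal the N-frame transition rule keys on.

#' Simulation configuration
#'
#' Defaults mirror the acquisition setup: 1280x720 frames at 30 FPS from a
#' robot moving at 0.2 m/s about 50 cm from cages of 40x60x40 cm holding 5-8
#' birds.  `px_per_m = 1200` makes a 0.6 m cage span 720 px of the 1280 px
#' frame.  `gap_between_cages_m` defaults to 1.1 m (at least one view width)
#' so only one cage is in view at a time; see the methods vignette.
#'
#' @param n_cages number of cages in the row.
#' @param occupancy_range `c(min, max)` birds per cage, default `c(5, 8)`.
#' @param fps frames per second.
#' @param robot_speed_mps robot speed in m/s.
#' @param frame_width_px,frame_height_px frame size in pixels.
#' @param px_per_m projection scale.
#' @param cage_width_m interior cage width.
#' @param fence_width_m railing width.
#' @param gap_between_cages_m spacing between cage modules.
#' @param head_size_m nominal head box side.
#' @param seed integer seed; the stream is bit-identical for equal seeds.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cages = 5, occupancy_range = c(5, 8),
                              fps = 30, robot_speed_mps = 0.2,
                              frame_width_px = 1280, frame_height_px = 720,
                              px_per_m = 1200, cage_width_m = 0.6,
                              fence_width_m = 0.05, gap_between_cages_m = 1.1,
                              head_size_m = 0.06, seed = 1L) {
  if (n_cages < 1) stop_config("n_cages must be >= 1")
  if (occupancy_range[1] < 1 || occupancy_range[2] < occupancy_range[1])
    stop_config("occupancy_range must satisfy 1 <= min <= max")
  if (any(c(fps, robot_speed_mps, frame_width_px, frame_height_px, px_per_m,
            cage_width_m, fence_width_m, head_size_m) <= 0) ||
      gap_between_cages_m < 0)
    stop_config("physical dimensions must be positive")
  structure(list(n_cages = as.integer(n_cages),
                 occupancy_range = as.integer(occupancy_range), fps = fps,
                 robot_speed_mps = robot_speed_mps,
                 frame_width_px = frame_width_px,
                 frame_height_px = frame_height_px, px_per_m = px_per_m,
                 cage_width_m = cage_width_m, fence_width_m = fence_width_m,
                 gap_between_cages_m = gap_between_cages_m,
                 head_size_m = head_size_m, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Detector-noise configuration
#'
#' Simplest distributions exhibiting the relevant failure modes: Bernoulli
#' per-head misses (occlusion), Poisson false-positive heads, Gaussian box
#' jitter, and fence-dropout bursts that remove one of the two railings for
#' a sampled number of consecutive frames (exercising the N-frame rule).
#'
#' @param head_miss_prob per-head per-frame miss probability.
#' @param fp_rate expected false heads per frame.
#' @param jitter_px_sd sd of the Gaussian localization jitter (pixels).
#' @param fence_dropout_prob per-frame probability that a dropout burst
#'   starts.
#' @param dropout_len_range `c(min, max)` burst length in frames.
#' @param confidence_model `c(mean, sd)` of the Gaussian confidence score,
#'   clipped to `[0, 1]`; `NULL` leaves confidences untouched.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(head_miss_prob = 0.05, fp_rate = 0.02,
                         jitter_px_sd = 2, fence_dropout_prob = 0.01,
                         dropout_len_range = c(2, 6),
                         confidence_model = c(mean = 0.9, sd = 0.05)) {
  probs <- c(head_miss_prob, fence_dropout_prob)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must be in [0, 1]")
  if (fp_rate < 0 || jitter_px_sd < 0) stop_config("rates must be >= 0")
  if (dropout_len_range[1] < 1 || dropout_len_range[2] < dropout_len_range[1])
    stop_config("dropout_len_range must satisfy 1 <= min <= max")
  structure(list(head_miss_prob = head_miss_prob, fp_rate = fp_rate,
                 jitter_px_sd = jitter_px_sd,
                 fence_dropout_prob = fence_dropout_prob,
                 dropout_len_range = dropout_len_range,
                 confidence_model = confidence_model),
            class = "noise_config")
}

#' Zero-noise configuration (identity under [apply_noise()])
#' @return a `noise_config` with every noise source disabled.
#' @export
zero_noise <- function() {
  noise_config(head_miss_prob = 0, fp_rate = 0, jitter_px_sd = 0,
               fence_dropout_prob = 0, dropout_len_range = c(1, 1),
               confidence_model = NULL)
}

#' Simulate one inspection pass
#'
#' Generates a noise-free detection stream (every detection confidence 1.0)
#' plus per-cage ground truth.  Deterministic given `sim$seed`.
#'
#' @param sim a [simulation_config()].
#' @return `list(stream = detection_stream, truth = simulation_truth)`;
#'   the truth holds per-cage occupancy, entry/exit/center frame indices and
#'   static head world positions.
#' @export
simulate_inspection <- function(sim = simulation_config()) {
  step_px <- sim$robot_speed_mps / sim$fps * sim$px_per_m
  frames_per_cage <- sim$cage_width_m / sim$robot_speed_mps * sim$fps
  if (frames_per_cage < 1)
    stop_config(paste("fewer than 1 frame per cage; increase fps or reduce",
                      "robot_speed_mps"))
  W <- sim$frame_width_px; H <- sim$frame_height_px
  fence_px <- sim$fence_width_m * sim$px_per_m
  cage_px <- sim$cage_width_m * sim$px_per_m
  gap_px <- sim$gap_between_cages_m * sim$px_per_m
  if (gap_px < W)
    warning("gap between cages is narrower than the view; ",
            "two cages may be imaged at once", call. = FALSE)
  pitch <- 2 * fence_px + cage_px + gap_px
  base <- (seq_len(sim$n_cages) - 1) * pitch
  lf_s <- base; lf_e <- base + fence_px
  int_s <- lf_e; int_e <- lf_e + cage_px
  rf_s <- int_e; rf_e <- int_e + fence_px

  half <- sim$head_size_m * sim$px_per_m / 2
  res <- withr::with_seed(sim$seed, {
    occupancy <- sample(seq(sim$occupancy_range[1], sim$occupancy_range[2]),
                        sim$n_cages, replace = TRUE)
    heads <- quick_df(list(
      cage_id = rep(seq_len(sim$n_cages), occupancy),
      x_center = runif(sum(occupancy),
                       rep(int_s, occupancy) + half + 1,
                       rep(int_e, occupancy) - half - 1),
      y_center = runif(sum(occupancy), 0.15 * H + half, 0.85 * H - half)))
    list(occupancy = occupancy, heads = heads)
  })
  occupancy <- res$occupancy; heads <- res$heads

  cam0 <- -W
  n_frames <- as.integer(ceiling((rf_e[sim$n_cages] + 16 * step_px - cam0) /
                                   step_px)) + 1L
  fence_y <- c(0.04 * H, 0.96 * H)
  obj <- quick_df(list(
    label = c(rep("fence", 2 * sim$n_cages), rep("chicken_head", nrow(heads))),
    ws = c(rbind(lf_s, rf_s), heads$x_center - half),
    we = c(rbind(lf_e, rf_e), heads$x_center + half),
    y1 = c(rep(fence_y[1], 2 * sim$n_cages), heads$y_center - half),
    y2 = c(rep(fence_y[2], 2 * sim$n_cages), heads$y_center + half)))

  # Per object, the frame range over which its box strictly overlaps the view.
  f_lo <- pmax(0L, as.integer(floor((obj$ws - W - cam0) / step_px)) + 1L)
  f_hi <- pmin(n_frames - 1L, as.integer(ceiling((obj$we - cam0) / step_px)) - 1L)
  n_vis <- pmax(0L, f_hi - f_lo + 1L)
  idx <- rep.int(seq_len(nrow(obj)), n_vis)
  f_all <- sequence(n_vis, from = f_lo)
  cam <- cam0 + f_all * step_px
  flat <- quick_df(list(frame = f_all, label = obj$label[idx],
                        x_min = pmax(0, obj$ws[idx] - cam),
                        y_min = obj$y1[idx],
                        x_max = pmin(W, obj$we[idx] - cam),
                        y_max = obj$y2[idx]))
  ord <- order(flat$frame, idx)
  flat <- flat[ord, , drop = FALSE]
  by_frame <- split(seq_len(nrow(flat)),
                    factor(flat$frame, levels = 0:(n_frames - 1L)))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    rows <- by_frame[[f]]
    d <- quick_df(list(label = flat$label[rows],
                       x_min = flat$x_min[rows], y_min = flat$y_min[rows],
                       x_max = flat$x_max[rows], y_max = flat$y_max[rows],
                       confidence = rep(1, length(rows))))
    frames[[f]] <- structure(list(frame_index = f - 1L,
                                  timestamp_s = (f - 1L) / sim$fps,
                                  detections = d, image_size = c(W, H)),
                             class = "frame_record")
  }

  cages <- quick_df(list(
    cage_id = seq_len(sim$n_cages),
    occupancy = as.integer(occupancy),
    entry_frame = as.integer(floor((rf_s - W - cam0) / step_px)) + 1L,
    exit_frame = as.integer(ceiling((lf_e - cam0) / step_px)) - 1L,
    center_frame = as.integer(round(((lf_s + rf_e) / 2 - W / 2 - cam0) / step_px)),
    x_low = lf_s, x_high = rf_e))
  truth <- structure(list(cages = cages, heads = heads, config = sim,
                          step_px = step_px, cam0 = cam0,
                          frames_per_cage = frames_per_cage),
                     class = "simulation_truth")
  meta <- list(generator = "cagecount::simulate_inspection",
               seed = sim$seed,
               config_hash = config_hash(unclass(sim)))
  stream <- detection_stream(frames, fps = sim$fps, metadata = meta)
  list(stream = stream, truth = truth)
}

#' Inject detector noise into a stream
#'
#' Each head is independently dropped with `head_miss_prob`; survivors are
#' jittered by centered Gaussian noise; false heads are added as a Poisson
#' count process at uniform positions; fence-dropout bursts remove one of
#' the visible fences (a random side per burst) for a sampled number of
#' consecutive frames.  Reproducible given `seed`; geometry and noise seeds
#' are deliberately separate so one layout can be re-noised.
#'
#' @param stream a [detection_stream()] (typically from
#'   [simulate_inspection()]).
#' @param noise a [noise_config()].
#' @param seed integer noise seed.
#' @param truth optional `simulation_truth`, carried through untouched (the
#'   noise model does not depend on it).
#' @return a new `detection_stream`.
#' @export
apply_noise <- function(stream, noise = noise_config(), seed = 1L,
                        truth = NULL) {
  withr::with_seed(seed, {
    burst_left <- 0L
    drop_side <- "right"
    frames <- lapply(stream$frames, function(fr) {
      d <- fr$detections
      W <- fr$image_size[1]; H <- fr$image_size[2]
      if (burst_left == 0L && noise$fence_dropout_prob > 0 &&
          runif(1) < noise$fence_dropout_prob) {
        burst_left <<- sample(seq(noise$dropout_len_range[1],
                                  noise$dropout_len_range[2]), 1L)
        drop_side <<- sample(c("left", "right"), 1L)
      }
      is_fence <- d$label == "fence"
      if (burst_left > 0L) {
        burst_left <<- burst_left - 1L
        if (any(is_fence)) {
          cx <- (d$x_min + d$x_max) / 2
          victim <- if (drop_side == "left")
            which(is_fence)[which.min(cx[is_fence])]
          else which(is_fence)[which.max(cx[is_fence])]
          d <- d[-victim, , drop = FALSE]
          is_fence <- d$label == "fence"
        }
      }
      is_head <- d$label == "chicken_head"
      if (any(is_head) && noise$head_miss_prob > 0) {
        drop <- is_head & (runif(nrow(d)) < noise$head_miss_prob)
        d <- d[!drop, , drop = FALSE]
        is_head <- d$label == "chicken_head"
      }
      if (any(is_head) && noise$jitter_px_sd > 0) {
        k <- sum(is_head)
        dx <- rnorm(k, 0, noise$jitter_px_sd)
        dy <- rnorm(k, 0, noise$jitter_px_sd)
        d$x_min[is_head] <- d$x_min[is_head] + dx
        d$x_max[is_head] <- d$x_max[is_head] + dx
        d$y_min[is_head] <- d$y_min[is_head] + dy
        d$y_max[is_head] <- d$y_max[is_head] + dy
        d <- clamp_boxes(d, fr$image_size)
        d <- d[d$x_min < d$x_max & d$y_min < d$y_max, , drop = FALSE]
      }
      if (noise$fp_rate > 0) {
        k <- rpois(1, noise$fp_rate)
        if (k > 0) {
          half <- runif(k, 25, 45)
          cx <- runif(k, half, W - half)
          cy <- runif(k, half, H - half)
          fp <- quick_df(list(label = rep("chicken_head", k),
                              x_min = cx - half, y_min = cy - half,
                              x_max = cx + half, y_max = cy + half,
                              confidence = rep(1, k)))
          d <- rbind(d, fp)
        }
      }
      if (!is.null(noise$confidence_model) && nrow(d)) {
        d$confidence <- pmin(1, pmax(0, rnorm(nrow(d),
                                              noise$confidence_model[1],
                                              noise$confidence_model[2])))
      }
      rownames(d) <- NULL
      structure(list(frame_index = fr$frame_index,
                     timestamp_s = fr$timestamp_s,
                     detections = d, image_size = fr$image_size),
                class = "frame_record")
    })
    meta <- stream$metadata
    meta$noise_seed <- seed
    meta$noise_config_hash <- config_hash(unclass(noise))
    detection_stream(frames, fps = stream$fps, metadata = meta)
  })
}

#' Worked-example fixture frame
#'
#' A single frame with two fence boxes and 11 chicken-head boxes, exactly 3
#' of whose x-centers lie outside the fence span (clear of the railings, so
#' both span modes retain the same 8 heads).  This reconstructs the
#' published worked example in which 11 heads are detected but 3 fall
#' outside the valid area, leaving a count of 8.
#'
#' @return a [frame_record()].
#' @export
make_worked_example_frame <- function() {
  fences <- detections(label = c("fence", "fence"),
                       x_min = c(100, 1050), y_min = c(40, 40),
                       x_max = c(180, 1130), y_max = c(700, 700),
                       confidence = 0.92)
  inside_cx <- c(260, 350, 430, 520, 610, 700, 800, 950)
  outside_cx <- c(45, 70, 1185)
  cx <- c(inside_cx, outside_cx)
  cy <- c(250, 420, 310, 500, 270, 440, 360, 520, 300, 480, 380)
  half <- 35
  heads <- detections(label = rep("chicken_head", 11),
                      x_min = cx - half, y_min = cy - half,
                      x_max = cx + half, y_max = cy + half,
                      confidence = c(0.88, 0.91, 0.85, 0.9, 0.87, 0.93, 0.86,
                                     0.89, 0.84, 0.9, 0.82))
  frame_record(0L, rbind(fences, heads), image_size = c(1280, 720), fps = 30)
}
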