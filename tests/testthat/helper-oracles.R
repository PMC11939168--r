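# Independent reference implementations used as oracles.  These deliberately
# take different algorithmic routes from the package code they check.

# Emission count from a fence-count sequence, by run-length scanning:
# drop uninformative frames (>= 3 fences; 0 fences when they do not feed the
# streak), then walk maximal runs.  A run of two-fence frames arms the
# counter; an armed maximal run of sub-two-fence frames of length >= N emits
# exactly one cage.
ref_emission_count <- function(f_seq, N = 10, zero_in_streak = TRUE) {
  informative <- f_seq == 2 | f_seq == 1 | (f_seq == 0 & zero_in_streak)
  s <- f_seq[informative]
  if (!length(s)) return(0L)
  sym <- ifelse(s == 2, "T", "D")
  runs <- rle(sym)
  armed <- FALSE
  emissions <- 0L
  for (i in seq_along(runs$values)) {
    if (runs$values[i] == "T") {
      armed <- TRUE
    } else if (armed && runs$lengths[i] >= N) {
      emissions <- emissions + 1L
      armed <- FALSE
    }
  }
  emissions
}

# Build a stream whose frames carry the requested fence counts (disjoint
# fence boxes; optional fixed in-span head count on two-fence frames).
make_fence_frames <- function(f_seq, heads_on_two = 0, fps = 30) {
  frames <- lapply(seq_along(f_seq), function(i) {
    k <- f_seq[i]
    det <- empty_det()
    if (k > 0) {
      x0 <- 100 + (seq_len(k) - 1) * 300
      det <- detections(label = rep("fence", k),
                        x_min = x0, y_min = 40, x_max = x0 + 60, y_max = 700)
    }
    if (k == 2 && heads_on_two > 0) {
      cx <- seq(200, 360, length.out = heads_on_two)
      det <- rbind(det, detections(label = rep("chicken_head", heads_on_two),
                                   x_min = cx - 20, y_min = 300,
                                   x_max = cx + 20, y_max = 340))
    }
    frame_record(i - 1L, det, image_size = c(1280, 720), fps = fps)
  })
  detection_stream(frames, fps = fps)
}

empty_det <- function() detections()

# Optimal one-to-one match count by exhaustive assignment (n <= ~7).
ref_optimal_match_count <- function(preds, truths, thr) {
  np <- nrow(preds); nt <- nrow(truths)
  if (!np || !nt) return(0L)
  iou <- outer(seq_len(np), seq_len(nt), Vectorize(function(i, j)
    box_iou(unlist(preds[i, c("x_min", "y_min", "x_max", "y_max")]),
            unlist(truths[j, c("x_min", "y_min", "x_max", "y_max")]))))
  admissible <- iou >= thr
  best <- 0L
  recurse <- function(i, used) {
    if (i > np) return(0L)
    skip <- recurse(i + 1L, used)
    take <- 0L
    for (j in which(admissible[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      take <- max(take, 1L + recurse(i + 1L, used2))
    }
    max(skip, take)
  }
  recurse(1L, logical(nt))
}

# Reference COCO-style AP: naive loop matching per frame, then for each of
# the 101 recall points scan every prefix operating point for the maximum
# precision at recall >= r.  O(n * 101) direct definition, no envelope trick.
ref_average_precision <- function(preds, truths, thr) {
  frames <- union(unique(preds$frame_index), unique(truths$frame_index))
  conf <- numeric(0); tp <- logical(0); n_truth <- 0L
  for (fr in frames) {
    p <- preds[preds$frame_index == fr, , drop = FALSE]
    t <- truths[truths$frame_index == fr, , drop = FALSE]
    n_truth <- n_truth + nrow(t)
    if (!nrow(p)) next
    p <- p[order(-p$confidence), , drop = FALSE]
    used <- logical(nrow(t))
    for (i in seq_len(nrow(p))) {
      best_j <- 0L; best_iou <- -1
      for (j in seq_len(nrow(t))) {
        if (used[j]) next
        v <- box_iou(unlist(p[i, c("x_min", "y_min", "x_max", "y_max")]),
                     unlist(t[j, c("x_min", "y_min", "x_max", "y_max")]))
        if (v >= thr && v > best_iou) { best_iou <- v; best_j <- j }
      }
      hit <- best_j > 0L
      if (hit) used[best_j] <- TRUE
      conf <- c(conf, p$confidence[i]); tp <- c(tp, hit)
    }
  }
  if (n_truth == 0L) return(0)
  if (!length(conf)) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_truth
  pts <- seq(0, 1, by = 0.01)
  mean(vapply(pts, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

ref_ap_50_95 <- function(preds, truths) {
  mean(vapply(seq(0.5, 0.95, by = 0.05), function(thr)
    ref_average_precision(preds, truths, thr), numeric(1)))
}

# Random multi-frame prediction/truth sets for AP checks.
random_detection_set <- function(seed, n_truth = 20, n_frames = 4) {
  withr::with_seed(seed, {
    fr <- sample(0:(n_frames - 1), n_truth, replace = TRUE)
    cx <- runif(n_truth, 60, 1220); cy <- runif(n_truth, 60, 660)
    w <- runif(n_truth, 30, 90); h <- runif(n_truth, 30, 90)
    truths <- data.frame(frame_index = fr, label = "chicken_head",
                         x_min = cx - w / 2, y_min = cy - h / 2,
                         x_max = cx + w / 2, y_max = cy + h / 2,
                         confidence = 1)
    # predictions: perturbed copies of most truths plus some false positives
    keep <- runif(n_truth) < 0.85
    p <- truths[keep, , drop = FALSE]
    p$x_min <- p$x_min + rnorm(nrow(p), 0, 6)
    p$x_max <- p$x_max + rnorm(nrow(p), 0, 6)
    p$y_min <- p$y_min + rnorm(nrow(p), 0, 6)
    p$y_max <- p$y_max + rnorm(nrow(p), 0, 6)
    nfp <- rpois(1, 4)
    fp <- data.frame(frame_index = sample(0:(n_frames - 1), nfp, replace = TRUE),
                     label = "chicken_head",
                     x_min = runif(nfp, 0, 1100), y_min = runif(nfp, 0, 500),
                     x_max = 0, y_max = 0, confidence = 0)
    fp$x_max <- fp$x_min + runif(nfp, 30, 90)
    fp$y_max <- fp$y_min + runif(nfp, 30, 90)
    preds <- rbind(p, fp)
    preds <- preds[preds$x_min < preds$x_max & preds$y_min < preds$y_max, ]
    preds$confidence <- runif(nrow(preds), 0.1, 1)
    list(preds = preds, truths = truths)
  })
}

# Random small stream for I/O round-trip checks.
random_stream <- function(seed, n_frames = 5) {
  withr::with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(i) {
      k <- sample(0:5, 1)
      det <- empty_det()
      if (k > 0) {
        x1 <- runif(k, 0, 1100); y1 <- runif(k, 0, 600)
        det <- detections(label = sample(c("chicken_head", "fence"), k, TRUE),
                          x_min = x1, y_min = y1,
                          x_max = x1 + runif(k, 20, 150),
                          y_max = y1 + runif(k, 20, 110),
                          confidence = round(runif(k), 6))
      }
      frame_record(i - 1L, det, image_size = c(1280, 720), fps = 30)
    })
    detection_stream(frames, fps = 30,
                     metadata = list(run = sprintf("rt-%d", seed)))
  })
}

expect_stream_equal <- function(a, b, tol = 1e-6, check_meta = TRUE) {
  expect_equal(length(a$frames), length(b$frames))
  expect_equal(a$fps, b$fps, tolerance = tol)
  if (check_meta) expect_equal(a$metadata, b$metadata)
  for (i in seq_along(a$frames)) {
    fa <- a$frames[[i]]; fb <- b$frames[[i]]
    expect_identical(fa$frame_index, fb$frame_index)
    expect_equal(fa$timestamp_s, fb$timestamp_s, tolerance = tol)
    expect_equal(fa$image_size, fb$image_size, tolerance = tol)
    expect_identical(fa$detections$label, fb$detections$label)
    for (col in c("x_min", "y_min", "x_max", "y_max", "confidence"))
      expect_equal(fa$detections[[col]], fb$detections[[col]], tolerance = tol)
  }
}
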