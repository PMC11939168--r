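# The threshold-processing state machine.
#
# Per frame the machine looks only at the number of detected fences f and the
# horizontal coordinates of boxes:
#   f == 2  : counting is active.  The pair of fence boxes defines the
#             lateral span of the cage; chicken heads inside the span are
#             counted and the per-cage running maximum is updated.  Any
#             transition streak is cancelled (a short fence dropout is a
#             detector false negative, not a cage boundary).
#   f <= 1  : once counting has begun, consecutive such frames accumulate a
#             transition streak.  When the streak reaches N (default 10)
#             frames the cage is deemed passed and its record is emitted.
#   f >= 3  : the frame is ignored outright (more than one cage should never
#             be fully in view at the working standoff).
# Only horizontal coordinates matter; vertical extent is ignored.

#' Counter configuration
#'
#' @param transition_frames N, consecutive sub-two-fence frames that end a
#'   cage (default 10).
#' @param confidence_min detections below this score are discarded before any
#'   logic (default 0.25).
#' @param span_mode `"outer"` (envelope of both fence boxes, default) or
#'   `"inner"` (between the facing fence edges).
#' @param membership `"center"` keeps heads whose x-center lies in the span
#'   (closed interval, default); `"full_box"` requires the whole box inside.
#' @param zero_fence_in_streak treat zero-fence frames like single-fence
#'   frames for the transition streak (default `TRUE`; a zero-fence frame
#'   mid-transition would otherwise stall the machine).
#' @return list of class `counter_config`.
#' @export
counter_config <- function(transition_frames = 10, confidence_min = 0.25,
                           span_mode = c("outer", "inner"),
                           membership = c("center", "full_box"),
                           zero_fence_in_streak = TRUE) {
  span_mode <- match.arg(span_mode)
  membership <- match.arg(membership)
  if (!is.numeric(transition_frames) || transition_frames < 1)
    stop_config("transition_frames must be >= 1")
  if (confidence_min < 0 || confidence_min > 1)
    stop_config("confidence_min must be in [0, 1]")
  structure(list(transition_frames = as.integer(transition_frames),
                 confidence_min = confidence_min,
                 span_mode = span_mode, membership = membership,
                 zero_fence_in_streak = isTRUE(zero_fence_in_streak)),
            class = "counter_config")
}

#' Fresh counter state
#'
#' Phase is one of IDLE (no cage being counted), COUNTING (two fences in
#' view), TRANSITION (sub-two-fence streak in progress).
#'
#' @return list of class `counter_state`.
#' @export
new_counter_state <- function() {
  structure(list(phase = "IDLE", running_max = 0L,
                 key_frame_index = NA_integer_, key_timestamp_s = NA_real_,
                 single_fence_streak = 0L, cages_emitted = 0L),
            class = "counter_state")
}

#' Lateral span of a cage from its fence pair
#'
#' `outer` returns the envelope (min of both `x_min`, max of both `x_max`);
#' `inner` returns the interval between the left fence's right edge and the
#' right fence's left edge, "left" being the fence with the smaller center x.
#'
#' @param fences detection `data.frame` with exactly two `fence` rows.
#' @param mode `"outer"` or `"inner"`.
#' @return list of class `cage_span` with `x_low`, `x_high`.
#' @export
cage_span <- function(fences, mode = c("outer", "inner")) {
  mode <- match.arg(mode)
  if (!is.data.frame(fences) || nrow(fences) != 2)
    stop_contract("cage_span requires exactly 2 fence detections, got %d",
                  if (is.data.frame(fences)) nrow(fences) else NA_integer_)
  if (any(fences$label != "fence"))
    stop_contract("cage_span: non-fence detection supplied")
  if (mode == "outer") {
    span <- c(min(fences$x_min), max(fences$x_max))
  } else {
    left <- which.min((fences$x_min + fences$x_max) / 2)
    span <- c(fences$x_max[left], fences$x_min[3 - left])
    if (span[1] >= span[2])
      stop_contract("degenerate inner span: fences overlap in x (%.1f >= %.1f)",
                    span[1], span[2])
  }
  structure(list(x_low = span[1], x_high = span[2]), class = "cage_span")
}

#' Filter heads to a cage span
#'
#' With `membership = "center"` a head is kept when its x-center lies in the
#' closed interval `[x_low, x_high]`; with `"full_box"` its whole box must
#' lie inside.  Input order is preserved.
#'
#' @param heads detection `data.frame` of `chicken_head` rows (already
#'   confidence-filtered).
#' @param span a [cage_span()].
#' @param membership `"center"` or `"full_box"`.
#' @return the retained subset of `heads`.
#' @export
heads_in_span <- function(heads, span, membership = c("center", "full_box")) {
  membership <- match.arg(membership)
  if (!nrow(heads)) return(heads)
  keep <- if (membership == "center") {
    cx <- (heads$x_min + heads$x_max) / 2
    cx >= span$x_low & cx <= span$x_high
  } else {
    heads$x_min >= span$x_low & heads$x_max <= span$x_high
  }
  heads[keep, , drop = FALSE]
}

#' Advance the counter by one frame
#'
#' @param state a `counter_state`.
#' @param frame a [frame_record()].
#' @param config a [counter_config()].
#' @return `list(state = updated state, record = cage record row or NULL)`;
#'   a record is returned only on the frame where the transition streak
#'   reaches N.
#' @export
counter_step <- function(state, frame, config = counter_config()) {
  det <- frame$detections
  if (nrow(det) && config$confidence_min > 0)
    det <- det[det$confidence >= config$confidence_min, , drop = FALSE]
  is_fence <- det$label == "fence"
  f <- sum(is_fence)
  record <- NULL

  if (f == 2) {
    span <- tryCatch(cage_span(det[is_fence, , drop = FALSE], config$span_mode),
                     cagecount_contract_error = function(e) NULL)
    if (is.null(span)) {
      # Degenerate inner span (overlapping fence boxes): treat the frame as
      # uninformative, like f >= 3 -- no counting, streak untouched.
      return(list(state = state, record = NULL))
    }
    state$single_fence_streak <- 0L
    state$phase <- "COUNTING"
    heads <- det[!is_fence, , drop = FALSE]
    n_in <- nrow(heads_in_span(heads, span, config$membership))
    if (n_in > state$running_max) {
      state$running_max <- as.integer(n_in)
      state$key_frame_index <- frame$frame_index
      state$key_timestamp_s <- frame$timestamp_s
    }
  } else if (f == 1 || (f == 0 && config$zero_fence_in_streak)) {
    if (state$phase %in% c("COUNTING", "TRANSITION")) {
      state$single_fence_streak <- state$single_fence_streak + 1L
      state$phase <- "TRANSITION"
      if (state$single_fence_streak == config$transition_frames) {
        record <- quick_df(list(cage_id = state$cages_emitted + 1L,
                                max_count = state$running_max,
                                key_frame_index = state$key_frame_index,
                                timestamp_s = state$key_timestamp_s))
        state$cages_emitted <- state$cages_emitted + 1L
        state$running_max <- 0L
        state$key_frame_index <- NA_integer_
        state$key_timestamp_s <- NA_real_
        state$single_fence_streak <- 0L
        state$phase <- "IDLE"
      }
    }
  }
  # f >= 3 (or f == 0 when zero_fence_in_streak is off): frame ignored.
  list(state = state, record = record)
}

#' Count cages over a whole stream
#'
#' Folds [counter_step()] over the frames in order.  At end of stream a
#' pending cage (phase not IDLE, running max > 0) is flushed so the last cage
#' of a row is not lost when the robot stops.
#'
#' @param stream a [detection_stream()].
#' @param config a [counter_config()].
#' @param flush emit the pending cage at end of stream (default `TRUE`).
#' @return `data.frame` of class `cage_records` with columns `cage_id`,
#'   `max_count`, `key_frame_index`, `timestamp_s`; cage ids consecutive
#'   from 1.
#' @export
count_stream <- function(stream, config = counter_config(), flush = TRUE) {
  state <- new_counter_state()
  records <- vector("list", 8L)
  n_rec <- 0L
  for (frame in stream$frames) {
    res <- counter_step(state, frame, config)
    state <- res$state
    if (!is.null(res$record)) {
      n_rec <- n_rec + 1L
      if (n_rec > length(records)) records <- c(records, vector("list", n_rec))
      records[[n_rec]] <- res$record
    }
  }
  if (flush && state$phase != "IDLE" && state$running_max > 0) {
    n_rec <- n_rec + 1L
    records[[n_rec]] <- quick_df(list(cage_id = state$cages_emitted + 1L,
                                      max_count = state$running_max,
                                      key_frame_index = state$key_frame_index,
                                      timestamp_s = state$key_timestamp_s))
  }
  out <- if (n_rec) do.call(rbind, records[seq_len(n_rec)]) else
    quick_df(list(cage_id = integer(), max_count = integer(),
                  key_frame_index = integer(), timestamp_s = numeric()))
  rownames(out) <- NULL
  class(out) <- c("cage_records", "data.frame")
  out
}

#' Retrieve the key frame of a cage record
#'
#' The key frame is the earliest frame attaining the cage's maximum in-span
#' head count (ties broken by earliest frame at counting time).
#'
#' @param stream the stream the record was produced from.
#' @param record one row of a `cage_records` data.frame.
#' @return the [frame_record()] at the record's key frame index.
#' @export
select_key_frame <- function(stream, record) {
  kf <- record$key_frame_index[1]
  if (is.na(kf)) stop_contract("record has no key frame (max_count is 0)")
  idx <- vapply(stream$frames, function(f) f$frame_index, integer(1))
  pos <- match(kf, idx)
  if (is.na(pos))
    stop_contract("key frame index %d not present in stream", kf)
  stream$frames[[pos]]
}
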