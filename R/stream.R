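# Canonical in-memory containers for detection streams.
#
# A detection is one labeled, scored, axis-aligned pixel box in one frame.
# Coordinates are 0-based continuous pixels with the origin at the top-left
# corner and x increasing rightward (the "horizontal coordinate" the counting
# rule operates on).  Only continuous overlap/membership tests are performed,
# so corners are plain floats with no half-open pixel semantics.

#' Build a detection table
#'
#' Constructs the per-frame detection `data.frame` used throughout the
#' package, with columns `label`, `x_min`, `y_min`, `x_max`, `y_max`,
#' `confidence`.
#'
#' @param label character vector, each `"chicken_head"` or `"fence"`.
#' @param x_min,y_min,x_max,y_max box corners in pixels (numeric vectors).
#' @param confidence detection scores in `[0, 1]`; default 1.
#' @return a `data.frame` with one row per detection.
#' @examples
#' detections("chicken_head", 576, 288, 704, 432, 0.9)
#' @export
detections <- function(label = character(), x_min = numeric(),
                       y_min = numeric(), x_max = numeric(),
                       y_max = numeric(), confidence = 1) {
  n <- length(label)
  if (n > 0 && length(confidence) == 1) confidence <- rep(confidence, n)
  det <- quick_df(list(label = as.character(label),
                       x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                       x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                       confidence = as.numeric(confidence)))
  validate_detections(det)
  det
}

empty_detections <- function() detections()

validate_detections <- function(det, where = "detections") {
  bad <- setdiff(det$label, CAGECOUNT_LABELS)
  if (length(bad))
    stop_parse("%s: unknown label(s) %s", where, paste(unique(bad), collapse = ", "))
  if (any(det$x_min >= det$x_max) || any(det$y_min >= det$y_max))
    stop_parse("%s: degenerate box (x_min >= x_max or y_min >= y_max)", where)
  if (any(det$confidence < 0 | det$confidence > 1) || anyNA(det$confidence))
    stop_parse("%s: confidence outside [0, 1]", where)
  invisible(det)
}

#' Build a frame record
#'
#' One frame of a detection stream: its index, timestamp, detections and
#' image size.  Boxes partially outside the frame are clamped to it (common
#' at frame edges while the camera traverses the row); a box entirely outside
#' becomes degenerate and is rejected.
#'
#' @param frame_index non-negative integer frame number.
#' @param detections a detection `data.frame` (see [detections()]).
#' @param image_size `c(width, height)` in pixels.
#' @param timestamp_s seconds from stream start; defaults to
#'   `frame_index / fps` when `fps` is given.
#' @param fps frames per second, used only to derive a missing timestamp.
#' @param clamp clamp boxes to the frame before validating (default `TRUE`).
#' @return a list of class `frame_record`.
#' @export
frame_record <- function(frame_index, detections = empty_detections(),
                         image_size = c(1280, 720), timestamp_s = NULL,
                         fps = NULL, clamp = TRUE) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0)
    stop_parse("frame_index must be a non-negative integer")
  if (is.null(timestamp_s)) {
    if (is.null(fps)) stop_config("frame_record: supply timestamp_s or fps")
    timestamp_s <- frame_index / fps
  }
  if (clamp) detections <- clamp_boxes(detections, image_size)
  validate_detections(detections,
                      where = sprintf("frame %d", frame_index))
  structure(list(frame_index = frame_index,
                 timestamp_s = as.numeric(timestamp_s),
                 detections = detections,
                 image_size = as.numeric(image_size)),
            class = "frame_record")
}

#' Build a detection stream
#'
#' An ordered sequence of frame records plus the acquisition frame rate and
#' free-form metadata.  Frame indices must be strictly increasing.
#'
#' @param frames list of [frame_record()] objects.
#' @param fps frames per second (> 0).
#' @param metadata named list carried through stream I/O.
#' @return a list of class `detection_stream`.
#' @export
detection_stream <- function(frames, fps = 30, metadata = list()) {
  if (!is.numeric(fps) || fps <= 0) stop_config("fps must be > 0")
  s <- structure(list(frames = frames, fps = as.numeric(fps),
                      metadata = metadata),
                 class = "detection_stream")
  validate_stream(s)
  s
}

#' Validate a detection stream
#'
#' Checks fps, strict monotonicity of frame indices, and per-frame detection
#' validity.  Called by constructors and readers; exported because hand-built
#' streams (tests, adapters) should be checkable too.
#'
#' @param stream a `detection_stream`.
#' @return the stream, invisibly; errors on violation.
#' @export
validate_stream <- function(stream) {
  if (stream$fps <= 0) stop_config("fps must be > 0")
  idx <- vapply(stream$frames, function(f) f$frame_index, integer(1))
  if (length(idx) > 1 && any(diff(idx) <= 0))
    stop_parse("frame indices must be strictly increasing (saw %d after %d)",
               idx[which(diff(idx) <= 0)[1] + 1], idx[which(diff(idx) <= 0)[1]])
  invisible(stream)
}

#' @export
print.detection_stream <- function(x, ...) {
  n_det <- sum(vapply(x$frames, function(f) nrow(f$detections), integer(1)))
  cat(sprintf("<detection_stream> %d frames @ %g fps, %d detections\n",
              length(x$frames), x$fps, n_det))
  invisible(x)
}

#' Flatten a stream to a detection table
#'
#' @param stream a `detection_stream`.
#' @return `data.frame` with columns `frame_index`, `timestamp_s`, `label`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `confidence`.
#' @export
stream_to_df <- function(stream) {
  if (!length(stream$frames))
    return(cbind(quick_df(list(frame_index = integer(), timestamp_s = numeric())),
                 empty_detections()))
  parts <- lapply(stream$frames, function(f) {
    d <- f$detections
    d$frame_index <- rep(f$frame_index, nrow(d))
    d$timestamp_s <- rep(f$timestamp_s, nrow(d))
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("frame_index", "timestamp_s", "label",
          "x_min", "y_min", "x_max", "y_max", "confidence")]
}
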