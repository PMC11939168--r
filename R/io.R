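# Stream I/O in three dialects.
#
# jsonl is the canonical dialect: streams are naturally frame-sequential, so
# one frame per line with an optional leading header object ({"fps": ...,
# "metadata": {...}}) keeps reading incremental.  COCO-style JSON and
# per-frame YOLO txt directories are supported for interoperability with
# detector toolchains.  YOLO class ids default to 0 = chicken_head,
# 1 = fence, overridable via `class_map`.

DIALECTS <- c("jsonl", "coco_json", "yolo_txt_dir")

#' Read a detection stream
#'
#' @param path file (jsonl, coco_json) or directory (yolo_txt_dir).
#' @param dialect one of `"jsonl"`, `"coco_json"`, `"yolo_txt_dir"`.
#' @param image_size `c(width, height)`; required for `yolo_txt_dir`, whose
#'   rows are normalized.
#' @param fps frames per second; required for `yolo_txt_dir` (jsonl/coco
#'   carry it).
#' @param class_map named integer vector mapping labels to YOLO class ids.
#' @return a [detection_stream()].
#' @export
read_stream <- function(path, dialect = c("jsonl", "coco_json", "yolo_txt_dir"),
                        image_size = NULL, fps = NULL,
                        class_map = c(chicken_head = 0L, fence = 1L)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_config("input path does not exist: %s", path)
  switch(dialect,
         jsonl = read_stream_jsonl(path),
         coco_json = read_stream_coco(path),
         yolo_txt_dir = read_stream_yolo(path, image_size, fps, class_map))
}

#' Write a detection stream
#'
#' Round-trip guarantee: `read_stream(write_stream(s))` reproduces `s` up to
#' 1e-6 in coordinates and confidences.  The yolo_txt_dir dialect does not
#' carry fps or metadata; they must be re-supplied on read.
#'
#' @param stream a [detection_stream()].
#' @param path output file or directory.
#' @inheritParams read_stream
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path,
                         dialect = c("jsonl", "coco_json", "yolo_txt_dir"),
                         class_map = c(chicken_head = 0L, fence = 1L)) {
  dialect <- match.arg(dialect)
  validate_stream(stream)
  switch(dialect,
         jsonl = write_stream_jsonl(stream, path),
         coco_json = write_stream_coco(stream, path),
         yolo_txt_dir = write_stream_yolo(stream, path, class_map))
  invisible(path)
}

# ---- jsonl ------------------------------------------------------------------

frame_to_list <- function(f) {
  d <- f$detections
  dets <- lapply(seq_len(nrow(d)), function(i) {
    list(label = d$label[i],
         box = c(d$x_min[i], d$y_min[i], d$x_max[i], d$y_max[i]),
         confidence = d$confidence[i])
  })
  list(frame_index = f$frame_index, timestamp_s = f$timestamp_s,
       image_size = f$image_size, detections = dets)
}

list_to_frame <- function(rec, where) {
  det <- rec$detections
  if (is.null(det) || length(det) == 0) {
    d <- empty_detections()
  } else if (is.data.frame(det)) {     # jsonlite simplification path
    box <- do.call(rbind, det$box)
    d <- quick_df(list(label = as.character(det$label),
                       x_min = as.numeric(box[, 1]), y_min = as.numeric(box[, 2]),
                       x_max = as.numeric(box[, 3]), y_max = as.numeric(box[, 4]),
                       confidence = as.numeric(det$confidence)))
  } else {
    d <- quick_df(list(
      label = vapply(det, function(x) as.character(x$label), character(1)),
      x_min = vapply(det, function(x) as.numeric(x$box[1]), numeric(1)),
      y_min = vapply(det, function(x) as.numeric(x$box[2]), numeric(1)),
      x_max = vapply(det, function(x) as.numeric(x$box[3]), numeric(1)),
      y_max = vapply(det, function(x) as.numeric(x$box[4]), numeric(1)),
      confidence = vapply(det, function(x) as.numeric(x$confidence %||% 1),
                          numeric(1))))
  }
  tryCatch(
    frame_record(rec$frame_index, d, as.numeric(rec$image_size),
                 timestamp_s = rec$timestamp_s),
    error = function(e) stop_parse("%s: %s", where, conditionMessage(e)))
}

read_stream_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_parse("%s: empty jsonl stream", path)
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e)
               stop_parse("%s:%d: malformed JSON (%s)", path, i,
                          conditionMessage(e)))
  })
  fps <- 30
  metadata <- list()
  first <- recs[[1]]
  if (is.null(first$frame_index)) {            # header line
    fps <- first$fps %||% 30
    metadata <- first$metadata %||% list()
    recs <- recs[-1]
  }
  frames <- lapply(seq_along(recs), function(i)
    list_to_frame(recs[[i]], sprintf("%s:%d", path, i + 1)))
  detection_stream(frames, fps = fps, metadata = metadata)
}

write_stream_jsonl <- function(stream, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  header <- list(fps = stream$fps, metadata = stream$metadata)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(10),
                              null = "null"), con)
  for (f in stream$frames)
    writeLines(jsonlite::toJSON(frame_to_list(f), auto_unbox = TRUE,
                                digits = I(10), null = "null"), con)
}

# ---- COCO-style JSON --------------------------------------------------------

COCO_CATEGORIES <- data.frame(id = c(1L, 2L),
                              name = c("chicken_head", "fence"))

read_stream_coco <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_parse("%s: malformed JSON (%s)", path,
                               conditionMessage(e)))
  imgs <- doc$images
  if (is.null(imgs) || !nrow(imgs)) stop_parse("%s: no images", path)
  fps <- doc$info$fps %||% 30
  metadata <- doc$info$metadata %||% list()
  if (is.null(imgs$frame_index)) imgs$frame_index <- imgs$id - 1L
  imgs <- imgs[order(imgs$frame_index), ]
  ann <- doc$annotations
  cat_name <- setNames(doc$categories$name, doc$categories$id)
  frames <- lapply(seq_len(nrow(imgs)), function(i) {
    im <- imgs[i, ]
    rows <- if (is.null(ann) || !nrow(ann)) integer() else
      which(ann$image_id == im$id)
    if (length(rows)) {
      bbox <- ann$bbox
      bbox <- if (is.list(bbox)) do.call(rbind, bbox[rows]) else bbox[rows, , drop = FALSE]
      labels <- cat_name[as.character(ann$category_id[rows])]
      if (anyNA(labels))
        stop_parse("%s: annotation references unknown category id", path)
      d <- quick_df(list(label = unname(labels),
                         x_min = bbox[, 1], y_min = bbox[, 2],
                         x_max = bbox[, 1] + bbox[, 3],
                         y_max = bbox[, 2] + bbox[, 4],
                         confidence = as.numeric(ann$score[rows])))
    } else d <- empty_detections()
    frame_record(im$frame_index, d, c(im$width, im$height), fps = fps)
  })
  detection_stream(frames, fps = fps, metadata = metadata)
}

write_stream_coco <- function(stream, path) {
  images <- lapply(seq_along(stream$frames), function(i) {
    f <- stream$frames[[i]]
    list(id = i, frame_index = f$frame_index,
         file_name = sprintf("frame_%06d.jpg", f$frame_index),
         width = f$image_size[1], height = f$image_size[2])
  })
  cat_id <- setNames(COCO_CATEGORIES$id, COCO_CATEGORIES$name)
  anns <- list()
  k <- 0L
  for (i in seq_along(stream$frames)) {
    d <- stream$frames[[i]]$detections
    for (j in seq_len(nrow(d))) {
      k <- k + 1L
      anns[[k]] <- list(id = k, image_id = i,
                        category_id = unname(cat_id[d$label[j]]),
                        bbox = c(d$x_min[j], d$y_min[j],
                                 d$x_max[j] - d$x_min[j],
                                 d$y_max[j] - d$y_min[j]),
                        score = d$confidence[j])
    }
  }
  doc <- list(info = list(fps = stream$fps, metadata = stream$metadata),
              images = images, annotations = anns,
              categories = lapply(seq_len(nrow(COCO_CATEGORIES)), function(i)
                as.list(COCO_CATEGORIES[i, ])))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(10),
                              null = "null"), path)
}

# ---- YOLO txt directory -----------------------------------------------------

yolo_frame_file <- function(frame_index) sprintf("frame_%06d.txt", frame_index)

read_stream_yolo <- function(path, image_size, fps, class_map) {
  if (is.null(image_size) || is.null(fps))
    stop_config("yolo_txt_dir requires image_size and fps")
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop_parse("%s: no .txt frame files", path)
  idx <- suppressWarnings(
    as.integer(sub(".*?([0-9]+)\\.txt$", "\\1", basename(files))))
  if (anyNA(idx))
    stop_parse("%s: frame file names must contain a frame number", path)
  label_of <- setNames(names(class_map), as.integer(class_map))
  w <- image_size[1]; h <- image_size[2]
  frames <- lapply(order(idx), function(i) {
    txt <- readLines(files[i], warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt)) {
      parts <- lapply(seq_along(txt), function(j) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(txt[j]), "[[:space:]]+")[[1]]))
        if (length(v) < 5 || anyNA(v[1:5]))
          stop_parse("%s:%d: malformed YOLO row", files[i], j)
        v
      })
      cls <- vapply(parts, `[`, numeric(1), 1)
      lab <- label_of[as.character(as.integer(cls))]
      if (anyNA(lab))
        stop_parse("%s: unknown YOLO class id %s", files[i],
                   paste(unique(cls[is.na(lab)]), collapse = ","))
      cx <- vapply(parts, `[`, numeric(1), 2) * w
      cy <- vapply(parts, `[`, numeric(1), 3) * h
      bw <- vapply(parts, `[`, numeric(1), 4) * w
      bh <- vapply(parts, `[`, numeric(1), 5) * h
      conf <- vapply(parts, function(v) if (length(v) >= 6) v[6] else 1, numeric(1))
      d <- quick_df(list(label = unname(lab),
                         x_min = cx - bw / 2, y_min = cy - bh / 2,
                         x_max = cx + bw / 2, y_max = cy + bh / 2,
                         confidence = conf))
    } else d <- empty_detections()
    frame_record(idx[i], d, image_size, fps = fps)
  })
  detection_stream(frames, fps = fps)
}

write_stream_yolo <- function(stream, path, class_map) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (f in stream$frames) {
    d <- f$detections
    w <- f$image_size[1]; h <- f$image_size[2]
    lines <- character(0)
    if (nrow(d)) {
      cls <- unname(class_map[d$label])
      lines <- sprintf("%d %.10f %.10f %.10f %.10f %.6f", cls,
                       (d$x_min + d$x_max) / 2 / w, (d$y_min + d$y_max) / 2 / h,
                       (d$x_max - d$x_min) / w, (d$y_max - d$y_min) / h,
                       d$confidence)
    }
    writeLines(lines, file.path(path, yolo_frame_file(f$frame_index)))
  }
}

# ---- cage records -----------------------------------------------------------

#' Write cage records to CSV
#'
#' Columns `cage_id`, `max_count`, `key_frame_index`, `timestamp_s`, one row
#' per cage in traversal order; timestamps serialized with 3-decimal seconds.
#'
#' @param records a cage-record `data.frame` from [count_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cage_records <- function(records, path) {
  out <- data.frame(cage_id = records$cage_id,
                    max_count = records$max_count,
                    key_frame_index = records$key_frame_index,
                    timestamp_s = sprintf("%.3f", records$timestamp_s))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cage records from CSV
#'
#' @param path CSV written by [write_cage_records()].
#' @return cage-record `data.frame`.
#' @export
read_cage_records <- function(path) {
  if (!file.exists(path)) stop_config("input path does not exist: %s", path)
  df <- read.csv(path)
  df$timestamp_s <- as.numeric(df$timestamp_s)
  df
}
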