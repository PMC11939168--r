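# Stream-level evaluation: compares a prediction stream against a ground
# truth stream of the same shape, per class and pooled.

#' Evaluate a prediction stream against ground truth
#'
#' Per class: greedy per-frame matching at `iou_threshold` gives TP/FP/FN and
#' precision/recall/F1; `ap50` and `ap_50_95` come from the pooled
#' precision-recall curve.  `overall` micro-averages the counts across
#' classes and macro-averages the AP values (the usual mAP convention).
#'
#' @param pred,truth [detection_stream()] objects covering the same frames.
#' @param iou_threshold IoU used for the P/R/F1 operating point (default 0.5).
#' @param labels classes to evaluate; defaults to all present in either
#'   stream.
#' @return list of class `detection_eval` with one entry per class and an
#'   `overall` entry.
#' @export
evaluate_streams <- function(pred, truth, iou_threshold = 0.5, labels = NULL) {
  pdf <- stream_to_df(pred)
  tdf <- stream_to_df(truth)
  labels <- labels %||% sort(union(unique(pdf$label), unique(tdf$label)))
  per_class <- list()
  tot <- c(tp = 0, fp = 0, fn = 0)
  aps50 <- numeric(0); aps5095 <- numeric(0)
  for (lab in labels) {
    p <- pdf[pdf$label == lab, , drop = FALSE]
    t <- tdf[tdf$label == lab, , drop = FALSE]
    counts <- c(tp = 0, fp = 0, fn = 0)
    for (fr in union(unique(p$frame_index), unique(t$frame_index))) {
      m <- match_detections(p[p$frame_index == fr, , drop = FALSE],
                            t[t$frame_index == fr, , drop = FALSE],
                            iou_threshold)
      counts <- counts + c(tp = m$tp, fp = m$fp, fn = m$fn)
    }
    P <- as.numeric(precision(counts["tp"], counts["fp"]))
    R <- as.numeric(recall(counts["tp"], counts["fn"]))
    ap50 <- as.numeric(average_precision(p, t, 0.5))
    ap5095 <- ap_50_95(p, t)
    per_class[[lab]] <- list(tp = unname(counts["tp"]), fp = unname(counts["fp"]),
                             fn = unname(counts["fn"]),
                             precision = P, recall = R,
                             f1 = as.numeric(f1_score(P, R)),
                             ap50 = ap50, ap_50_95 = ap5095)
    tot <- tot + counts
    aps50 <- c(aps50, ap50); aps5095 <- c(aps5095, ap5095)
  }
  P <- as.numeric(precision(tot["tp"], tot["fp"]))
  R <- as.numeric(recall(tot["tp"], tot["fn"]))
  out <- c(per_class,
           list(overall = list(tp = unname(tot["tp"]), fp = unname(tot["fp"]),
                               fn = unname(tot["fn"]),
                               precision = P, recall = R,
                               f1 = as.numeric(f1_score(P, R)),
                               map50 = mean(aps50), map_50_95 = mean(aps5095))))
  structure(out, class = "detection_eval", iou_threshold = iou_threshold)
}

#' @export
print.detection_eval <- function(x, ...) {
  for (lab in names(x)) {
    e <- x[[lab]]
    ap <- e$ap_50_95 %||% e$map_50_95
    cat(sprintf("%-14s P=%5.1f%% R=%5.1f%% F1=%5.1f%% AP50:95=%5.1f%%\n",
                lab, 100 * e$precision, 100 * e$recall, 100 * e$f1, 100 * ap))
  }
  invisible(x)
}
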