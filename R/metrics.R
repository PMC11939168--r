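# Detection and counting evaluation statistics.
#
# Detection metrics follow standard practice: greedy confidence-ordered
# one-to-one matching at an IoU threshold, precision/recall/F1 from the
# resulting TP/FP/FN counts, and average precision as the area under the
# 101-point interpolated precision-recall curve, averaged over IoU
# thresholds 0.50:0.05:0.95 for AP50:95.  Zero denominators yield 0 with an
# `undefined` attribute (batch evaluation must not abort).

flag_undefined <- function(value) structure(value, undefined = TRUE)

check_counts <- function(...) {
  v <- c(...)
  if (any(v < 0) || anyNA(v)) stop_contract("counts must be non-negative")
  invisible(v)
}

#' Precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 P R / (P + R)`.  A zero denominator returns 0 carrying attribute
#' `undefined = TRUE`.
#'
#' @param tp,fp,fn non-negative counts.
#' @param p,r precision and recall in `[0, 1]`.
#' @return a fraction in `[0, 1]`.
#' @export
precision <- function(tp, fp) {
  check_counts(tp, fp)
  if (tp + fp == 0) return(flag_undefined(0))
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  check_counts(tp, fn)
  if (tp + fn == 0) return(flag_undefined(0))
  tp / (tp + fn)
}

#' @rdname precision
#' @export
f1_score <- function(p, r) {
  if (any(c(p, r) < 0) || any(c(p, r) > 1))
    stop_contract("p and r must be in [0, 1]")
  if (p + r == 0) return(flag_undefined(0))
  2 * p * r / (p + r)
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x_min, y_min, x_max, y_max)`.
#' @return IoU in `[0, 1]`; 0 when disjoint.
#' @export
box_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IoU matrix between prediction and truth boxes given as 4-column matrices.
iou_matrix <- function(p, t) {
  np <- nrow(p); nt <- nrow(t)
  if (!np || !nt) return(matrix(0, np, nt))
  iw <- outer(p[, 3], t[, 3], pmin) - outer(p[, 1], t[, 1], pmax)
  ih <- outer(p[, 4], t[, 4], pmin) - outer(p[, 2], t[, 2], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  pa <- (p[, 3] - p[, 1]) * (p[, 4] - p[, 2])
  ta <- (t[, 3] - t[, 1]) * (t[, 4] - t[, 2])
  inter / (outer(pa, ta, `+`) - inter)
}

boxes_matrix <- function(df) {
  cbind(df$x_min, df$y_min, df$x_max, df$y_max)
}

#' Match predictions to ground truth in one frame
#'
#' Greedy matching in descending confidence: each prediction claims the
#' highest-IoU still-unmatched truth with IoU at or above the threshold;
#' matching is one-to-one.
#'
#' @param preds,truths detection `data.frame`s from the same frame and class.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return list of class `match_result` with `tp`, `fp`, `fn`,
#'   `matched_pairs` (prediction row, truth row, IoU), `sorted_confidences`,
#'   and `is_tp` flags aligned with `sorted_confidences`.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  np <- nrow(preds); nt <- nrow(truths)
  ord <- order(-preds$confidence)
  iou <- iou_matrix(boxes_matrix(preds), boxes_matrix(truths))
  taken <- logical(nt)
  is_tp <- logical(np)
  pairs <- list()
  for (k in seq_len(np)) {
    i <- ord[k]
    if (!nt) break
    cand <- which(!taken & iou[i, ] >= iou_threshold)
    if (length(cand)) {
      j <- cand[which.max(iou[i, cand])]
      taken[j] <- TRUE
      is_tp[k] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(pred = i, truth = j, iou = iou[i, j])
    }
  }
  mp <- if (length(pairs)) as.data.frame(do.call(rbind, pairs)) else
    data.frame(pred = integer(), truth = integer(), iou = numeric())
  structure(list(tp = sum(is_tp), fp = np - sum(is_tp), fn = nt - sum(taken),
                 matched_pairs = mp,
                 sorted_confidences = preds$confidence[ord],
                 is_tp = is_tp),
            class = "match_result")
}

# Pool per-frame greedy matches into a global (confidence, tp) table.
pool_matches <- function(preds, truths, iou_threshold) {
  frames <- union(unique(preds$frame_index), unique(truths$frame_index))
  conf <- numeric(0); tp <- logical(0); n_truth <- 0L
  for (fr in frames) {
    p <- preds[preds$frame_index == fr, , drop = FALSE]
    t <- truths[truths$frame_index == fr, , drop = FALSE]
    n_truth <- n_truth + nrow(t)
    if (nrow(p)) {
      m <- match_detections(p, t, iou_threshold)
      conf <- c(conf, m$sorted_confidences)
      tp <- c(tp, m$is_tp)
    }
  }
  list(conf = conf, tp = tp, n_truth = n_truth)
}

#' Average precision over a multi-frame detection set
#'
#' Area under the 101-point interpolated precision-recall curve (the COCO
#' convention implied by the AP50:95 name): predictions are pooled over
#' frames, sorted by descending confidence, and precision is interpolated as
#' the running maximum to the right before sampling at recalls 0, 0.01, ...,
#' 1.  `ap_50_95` averages AP over IoU thresholds 0.50 to 0.95 in steps of
#' 0.05.
#'
#' @param preds,truths detection `data.frame`s with a `frame_index` column
#'   (single class).
#' @param iou_threshold IoU threshold for `average_precision`.
#' @return a fraction in `[0, 1]`; 0 with attribute `undefined` when there
#'   are no ground-truth objects.
#' @export
average_precision <- function(preds, truths, iou_threshold = 0.5) {
  if (is.null(preds$frame_index)) preds$frame_index <- 0L
  if (is.null(truths$frame_index)) truths$frame_index <- 0L
  pm <- pool_matches(preds, truths, iou_threshold)
  if (pm$n_truth == 0) return(flag_undefined(0))
  if (!length(pm$conf)) return(0)
  ord <- order(-pm$conf)
  tp <- pm$tp[ord]
  cum_tp <- cumsum(tp)
  rec <- cum_tp / pm$n_truth
  prec <- cum_tp / seq_along(tp)
  envelope <- rev(cummax(rev(prec)))
  rpts <- seq(0, 1, by = 0.01)
  # sample the envelope at the first operating point with recall >= r
  ap <- vapply(rpts, function(r) {
    i <- which(rec >= r - 1e-12)
    if (length(i)) envelope[i[1]] else 0
  }, numeric(1))
  mean(ap)
}

#' @rdname average_precision
#' @export
ap_50_95 <- function(preds, truths) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thresholds, function(thr)
    as.numeric(average_precision(preds, truths, thr)), numeric(1))
  mean(aps)
}

# ---- counting rates ---------------------------------------------------------

#' Counting-pipeline rates
#'
#' The three rates summarizing the threshold-processing pipeline:
#' * sample selection rate = samples kept after threshold processing /
#'   samples with a complete cage in view;
#' * chicken selection rate = heads assigned to the cage after threshold
#'   processing / heads detected in the image;
#' * chicken recognition rate = heads detected / actual birds present.
#'
#' @param after count after threshold processing.
#' @param complete count of complete-cage samples.
#' @param detected detected head count.
#' @param actual manually verified bird count.
#' @return fraction (not percentage); 0 with attribute `undefined` on a zero
#'   denominator.
#' @export
sample_selection_rate <- function(after, complete) {
  check_counts(after, complete)
  if (complete == 0) return(flag_undefined(0))
  after / complete
}

#' @rdname sample_selection_rate
#' @export
chicken_selection_rate <- function(after, detected) {
  check_counts(after, detected)
  if (detected == 0) return(flag_undefined(0))
  after / detected
}

#' @rdname sample_selection_rate
#' @export
chicken_recognition_rate <- function(detected, actual) {
  check_counts(detected, actual)
  if (actual == 0) return(flag_undefined(0))
  detected / actual
}

#' Assemble a counting report
#'
#' @param initial_samples,complete_cage_samples,samples_after_threshold
#'   sample counts.
#' @param actual_chickens,detected_chickens,chickens_after_threshold bird
#'   counts.
#' @return list of class `counting_report` with the raw counts, the three
#'   rates as fractions, and `percent` (rates as one-decimal percentages).
#' @export
counting_report <- function(initial_samples, complete_cage_samples,
                            samples_after_threshold, actual_chickens,
                            detected_chickens, chickens_after_threshold) {
  rates <- list(
    sample_selection_rate =
      as.numeric(sample_selection_rate(samples_after_threshold,
                                       complete_cage_samples)),
    chicken_selection_rate =
      as.numeric(chicken_selection_rate(chickens_after_threshold,
                                        detected_chickens)),
    chicken_recognition_rate =
      as.numeric(chicken_recognition_rate(detected_chickens,
                                          actual_chickens)))
  structure(c(list(initial_samples = initial_samples,
                   complete_cage_samples = complete_cage_samples,
                   samples_after_threshold = samples_after_threshold,
                   actual_chickens = actual_chickens,
                   detected_chickens = detected_chickens,
                   chickens_after_threshold = chickens_after_threshold),
              rates,
              list(percent = lapply(rates, as_percent))),
            class = "counting_report")
}

#' Deterministic dataset split counts
#'
#' Allocates `n` items to groups proportionally to `ratios` using largest
#' remainders, so the counts are integers summing to `n` (6500 images at
#' 8:1:1 give 5200/650/650).
#'
#' @param n total item count.
#' @param ratios positive weights, e.g. `c(train = 8, val = 1, test = 1)`.
#' @return named integer vector summing to `n`.
#' @export
dataset_split <- function(n, ratios = c(train = 8, val = 1, test = 1)) {
  if (n < 0 || any(ratios <= 0)) stop_contract("n >= 0 and ratios > 0 required")
  exact <- n * ratios / sum(ratios)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(ratios))
}
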