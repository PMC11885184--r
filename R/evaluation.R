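# ---- matching --------------------------------------------------------------

#' Match detections to ground-truth cells
#'
#' Greedy one-to-one matching: all (blob, truth) candidate pairs are sorted
#' by center distance (ties broken lexicographically by blob index then
#' truth index) and accepted in order when the distance is within the match
#' threshold and neither member is already matched. The threshold is either
#' a fixed pixel distance or, with `match_dist = "radius"`, each truth
#' cell's own annotated radius.
#'
#' @param blobs Blob data frame (`x`, `y`, ...).
#' @param truth Ground-truth data frame (`x`, `y`, and `radius` when
#'   `match_dist = "radius"`).
#' @param match_dist Either a positive number of pixels, or `"radius"`.
#'   Default 10.
#' @return List with counts `tp`, `fp`, `fn` and `pairs`, a data frame of
#'   matched (blob_index, truth_index, distance).
#' @export
match_detections <- function(blobs, truth, match_dist = 10) {
  nb <- nrow(blobs); nt <- nrow(truth)
  no_pairs <- data.frame(blob_index = integer(0), truth_index = integer(0),
                         distance = numeric(0))
  if (nb == 0L || nt == 0L) {
    return(list(tp = 0L, fp = nb, fn = nt, pairs = no_pairs))
  }
  use_radius <- identical(match_dist, "radius")
  if (!use_radius && (!is.numeric(match_dist) || match_dist <= 0)) {
    stop('match_dist must be a positive distance or "radius"', call. = FALSE)
  }

  bi <- rep(seq_len(nb), times = nt)
  ti <- rep(seq_len(nt), each = nb)
  dist <- sqrt((blobs$x[bi] - truth$x[ti])^2 + (blobs$y[bi] - truth$y[ti])^2)
  lim <- if (use_radius) truth$radius[ti] else match_dist
  cand <- which(dist <= lim)
  ord <- cand[order(dist[cand], bi[cand], ti[cand])]

  b_used <- logical(nb); t_used <- logical(nt)
  keep <- integer(0)
  for (k in ord) {
    if (!b_used[bi[k]] && !t_used[ti[k]]) {
      b_used[bi[k]] <- TRUE; t_used[ti[k]] <- TRUE
      keep <- c(keep, k)
    }
  }
  pairs <- data.frame(blob_index = bi[keep], truth_index = ti[keep],
                      distance = dist[keep])
  list(tp = length(keep), fp = nb - length(keep), fn = nt - length(keep),
       pairs = pairs)
}

# ---- metrics ---------------------------------------------------------------

#' Detection metrics from matched counts
#'
#' Computes precision = tp/(tp+fp), recall = tp/(tp+fn), F-measure =
#' harmonic mean of the two, and detection accuracy = tp/(tp+fp+fn) (a
#' detection task has no natural true-negative count, so accuracy is the
#' Jaccard-style agreement between the detected and annotated sets). Any
#' metric with a zero denominator is reported as `NA` (undefined), never
#' coerced to 0 or 1.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return An `eval_report` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_measure`, `accuracy` (fractions in \[0, 1\] or `NA`).
#' @export
compute_metrics <- function(tp, fp, fn) {
  counts <- c(tp = tp, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, fn must be non-negative integers", call. = FALSE)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall    <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_measure <- if (!is.na(precision) && !is.na(recall) &&
                   precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision, recall = recall,
                 f_measure = f_measure, accuracy = accuracy),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "N/A" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("tp=%d fp=%d fn=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("precision %s  recall %s  F-measure %s  accuracy %s\n",
              pct(x$precision), pct(x$recall), pct(x$f_measure),
              pct(x$accuracy)))
  invisible(x)
}

#' Evaluate detections against ground truth in one call
#'
#' @inheritParams match_detections
#' @return An `eval_report` (see [compute_metrics()]) with the matched
#'   `pairs` attached.
#' @export
evaluate_detections <- function(blobs, truth, match_dist = 10) {
  m <- match_detections(blobs, truth, match_dist)
  rep <- compute_metrics(m$tp, m$fp, m$fn)
  rep$pairs <- m$pairs
  rep
}

#' Per-frame detection and extraction counts
#'
#' @param frame_results List of per-frame results, each with `frame_index`,
#'   `n_cells` (blobs detected) and `n_segments` (crops surviving the edge
#'   clipping rule); `n_segments <= n_cells` always.
#' @return Data frame `frame_index`, `n_cells`, `n_segments`, one row per
#'   frame.
#' @export
per_frame_counts <- function(frame_results) {
  out <- data.frame(
    frame_index = vapply(frame_results, function(f) as.integer(f$frame_index),
                         integer(1)),
    n_cells = vapply(frame_results, function(f) as.integer(f$n_cells),
                     integer(1)),
    n_segments = vapply(frame_results, function(f) as.integer(f$n_segments),
                        integer(1))
  )
  stopifnot(all(out$n_segments <= out$n_cells))
  out
}
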