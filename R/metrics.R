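# Cycle-level evaluation: recognized / missed / false counts per label and
# the derived sensitivity and precision.

#' Cycle-level sensitivity
#'
#' `TP / (TP + FN)`: the fraction of cycles carrying the sound in which it
#' was recognized. Undefined (returned as `NA`) when no cycle carries the
#' sound.
#'
#' @param tp,fn non-negative counts.
#' @return A fraction in \[0, 1\], or `NA_real_`.
#' @export
sensitivity <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' Cycle-level precision
#'
#' `TP / (TP + FP)`: the fraction of emitted detections that match a true
#' event. Undefined (returned as `NA`) when nothing was detected.
#'
#' @param tp,fp non-negative counts.
#' @return A fraction in \[0, 1\], or `NA_real_`.
#' @export
precision <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' Score detections against ground truth, cycle by cycle
#'
#' For each label (S3, S4) and each cardiac cycle: a true event matched by a
#' detection within `tol_ms` counts as recognized (TP); a true event with no
#' matching detection as missed (FN); a detection in a cycle without the
#' true event - or farther than the tolerance from it - as false (FP). At
#' most one TP and one FP per label per cycle are counted, so the counting
#' is at cycle level, not at sample level. A detection mislabelled relative
#' to truth counts as FP for the emitted label only.
#'
#' @param detected an [annotation_set()] with `source = "detected"`.
#' @param truth an [annotation_set()] with `source = "truth"`.
#' @param tol_ms onset matching tolerance within a cycle (default 50).
#' @param labels labels to score (default S3 and S4).
#' @return An object of class `"score_table"`: list with `per_label` (data
#'   frame `label`, `tp`, `fn`, `fp`, `sensitivity`, `precision`),
#'   `per_record` (the same counts split by record id) and `tol_ms`.
#' @export
score_cycles <- function(detected, truth, tol_ms = 50,
                         labels = c("S3", "S4")) {
  stopifnot(inherits(detected, "annotation_set"),
            inherits(truth, "annotation_set"))
  rid_d <- unique(detected$record_id)
  rid_t <- unique(truth$record_id)
  if (length(rid_d) && length(rid_t) &&
      !any(rid_d %in% rid_t) && !any(rid_t %in% rid_d))
    stop("detected and truth annotations carry different record ids")
  recs <- union(rid_t, rid_d)
  tol <- tol_ms / 1000
  per_rec <- list()
  for (rid in recs) {
    d <- detected[detected$record_id == rid, , drop = FALSE]
    tr <- truth[truth$record_id == rid, , drop = FALSE]
    for (lb in labels) {
      dl <- d[d$label == lb, , drop = FALSE]
      tl <- tr[tr$label == lb, , drop = FALSE]
      tp <- fn <- fp <- 0L
      for (k in union(tl$cycle, dl$cycle)) {
        dt <- dl$onset_s[dl$cycle == k]
        tt <- tl$onset_s[tl$cycle == k]
        if (length(tt)) {
          hit <- length(dt) > 0 && min(abs(outer(dt, tt, "-"))) <= tol
          if (hit) tp <- tp + 1L else {
            fn <- fn + 1L
            if (length(dt)) fp <- fp + 1L  # detection present but far
          }
        } else if (length(dt)) fp <- fp + 1L
      }
      per_rec[[length(per_rec) + 1L]] <- data.frame(
        record_id = rid, label = lb, tp = tp, fn = fn, fp = fp,
        stringsAsFactors = FALSE)
    }
  }
  per_record <- do.call(rbind, per_rec)
  agg <- stats::aggregate(cbind(tp, fn, fp) ~ label, data = per_record, sum)
  agg <- agg[match(labels, agg$label), , drop = FALSE]
  agg$sensitivity <- mapply(sensitivity, agg$tp, agg$fn)
  agg$precision <- mapply(precision, agg$tp, agg$fp)
  rownames(agg) <- NULL
  structure(list(per_label = agg, per_record = per_record, tol_ms = tol_ms),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Cycle-level scores (tolerance %g ms)\n", x$tol_ms))
  cat(sprintf("  %-4s %11s %7s %6s %12s %10s\n", "", "recognized",
              "missed", "false", "sensitivity", "precision"))
  for (r in seq_len(nrow(x$per_label))) {
    row <- x$per_label[r, ]
    fmt <- function(v) if (is.na(v)) "   --" else sprintf("%.1f%%", 100 * v)
    cat(sprintf("  %-4s %11d %7d %6d %12s %10s\n", row$label, row$tp,
                row$fn, row$fp, fmt(row$sensitivity), fmt(row$precision)))
  }
  if (length(unique(x$per_record$record_id)) > 1) {
    cat("  per record:\n")
    pr <- x$per_record
    for (r in seq_len(nrow(pr))) {
      if (pr$tp[r] + pr$fn[r] + pr$fp[r] == 0) next
      cat(sprintf("    %-10s %-4s recognized=%d missed=%d false=%d\n",
                  pr$record_id[r], pr$label[r], pr$tp[r], pr$fn[r],
                  pr$fp[r]))
    }
  }
  invisible(x)
}
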