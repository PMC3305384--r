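# S3 methods and report export for "s34_detection".

#' @export
print.s34_detection <- function(x, ...) {
  n3 <- sum(x$events$label == "S3")
  n4 <- sum(x$events$label == "S4")
  cat(sprintf("S3/S4 detection for record '%s'\n", x$record_id))
  cat(sprintf("  %d cycles segmented; S3 in %d, S4 in %d (%d candidate%s rejected)\n",
              x$n_cycles, n3, n4, x$n_rejected,
              if (x$n_rejected == 1) "" else "s"))
  if (nrow(x$events) > 0) {
    ev <- x$events
    cat(sprintf("  %-3s cycle %2d  onset %7.3f s  latency %5.0f ms  (%s)\n",
                ev$label, ev$cycle, ev$onset_s, 1000 * ev$latency_s,
                ev$provenance), sep = "")
  }
  invisible(x)
}

#' @export
summary.s34_detection <- function(object, ...) {
  ev <- object$events
  out <- lapply(c("S3", "S4"), function(lb) {
    e <- ev[ev$label == lb, , drop = FALSE]
    data.frame(label = lb, n_cycles = object$n_cycles, n_detected = nrow(e),
               n_recovered = sum(e$provenance == "recovered"),
               median_latency_ms = if (nrow(e)) 1000 *
                 stats::median(e$latency_s) else NA_real_,
               median_magnitude = if (nrow(e))
                 stats::median(e$magnitude) else NA_real_)
  })
  out <- do.call(rbind, out)
  class(out) <- c("summary.s34_detection", "data.frame")
  out
}

#' @export
print.summary.s34_detection <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.s34_detection <- function(x, ...) x$events

#' Diagnostic plot of a detection
#'
#' Two panels: the per-cycle table as event marks over the smoothed Shannon
#' energy with the segmented S1/S2 peaks, and the diastolic
#' frequency-magnitude scatter coloured by cluster group.
#'
#' @param x an `"s34_detection"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.s34_detection <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  se <- attr(x$segmentation, "se")
  tt <- (seq_along(se$values) - 1) / se$fs
  graphics::plot(tt, se$values, type = "l", xlab = "time (s)",
                 ylab = "Shannon energy", main = x$record_id, ...)
  graphics::abline(v = x$segmentation$s1_times, col = "grey40", lty = 3)
  graphics::abline(v = x$segmentation$s2_times, col = "grey70", lty = 3)
  if (nrow(x$events)) {
    cols <- ifelse(x$events$label == "S3", "red", "blue")
    graphics::points(x$events$onset_s, rep(max(se$values) * 0.9,
                                           nrow(x$events)),
                     pch = 25, bg = cols, col = cols)
    graphics::legend("topright", legend = c("S3", "S4"), pt.bg =
                       c("red", "blue"), pch = 25, bty = "n")
  }
  pts <- x$points
  cols <- c(normal = "grey60", uncertain = "orange", abnormal = "red")
  graphics::plot(pts$freq_hz, pts$magnitude,
                 col = cols[as.character(x$assignment$labels)], pch = 16,
                 cex = 0.5, xlab = "instantaneous frequency (Hz)",
                 ylab = "magnitude")
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Export a detection report as JSON
#'
#' Writes the record id, seed, configuration echo, per-cycle rows and the
#' event list. The output is a deterministic function of the detection
#' object: identical record, config and seed give byte-identical files.
#'
#' @param det an `"s34_detection"`.
#' @param path output path; `NULL` returns the JSON string instead.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_report <- function(det, path = NULL) {
  stopifnot(inherits(det, "s34_detection"))
  cyc <- det$cycles
  payload <- list(
    record_id = det$record_id,
    seed = det$seed,
    fs = det$fs,
    n_cycles = det$n_cycles,
    n_rejected = det$n_rejected,
    config = unclass(det$config),
    cycles = cyc,
    events = det$events
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
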