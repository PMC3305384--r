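# Recognition: pool diastolic ridge points, cluster the frequency-magnitude
# distribution, project the abnormal group to time, classify S3 vs S4, and
# enforce periodicity with iterative recovery of missed events.

#' Pool ridge points from the diastolic intervals
#'
#' Collects the (time, frequency, magnitude) ridge samples whose times fall
#' inside the diastolic interval of each cycle, decimated by `decimate`,
#' tagged with the cycle index. Margins after the S2 peak and before the
#' next S1 peak keep the skirts of the segmenting bursts out of the pooled
#' set; without them the high-amplitude S1/S2 tails dominate the cluster
#' structure and mask the diastolic sounds.
#'
#' @param ridge a `"ridge_track"`.
#' @param seg a `"cycle_segmentation"` with at least one diastole.
#' @param decimate sampling stride (default 8, i.e. 1 ms at 8000 Hz).
#' @param trim_after_s2_ms,trim_before_s1_ms margins in ms (defaults 70 and
#'   60) excluded at the start and end of each diastole.
#' @return An object of class `"freq_mag_points"`: data frame with columns
#'   `time_s`, `freq_hz`, `magnitude`, `cycle`.
#' @export
extract_diastolic_points <- function(ridge, seg, decimate = 8L,
                                     trim_after_s2_ms = 70,
                                     trim_before_s1_ms = 60) {
  stopifnot(inherits(ridge, "ridge_track"),
            inherits(seg, "cycle_segmentation"))
  cyc <- seg$cycles[!is.na(seg$cycles$dia_start), , drop = FALSE]
  if (nrow(cyc) == 0) stop("segmentation contains no diastolic interval")
  fs <- ridge$fs
  n <- length(ridge$freq_hz)
  out <- vector("list", nrow(cyc))
  for (r in seq_len(nrow(cyc))) {
    t0 <- cyc$dia_start[r] + trim_after_s2_ms / 1000
    t1 <- cyc$dia_end[r] - trim_before_s1_ms / 1000
    # first sample with time >= t0, last with time < t1 (epsilon guards
    # against floating-point fuzz on interval boundaries)
    i0 <- max(1L, as.integer(ceiling(t0 * fs - 1e-9)) + 1L)
    i1 <- min(n, as.integer(floor(t1 * fs - 1e-9)) + 1L)
    if (i1 < i0) next
    i <- seq(i0, i1, by = max(1L, as.integer(decimate)))
    out[[r]] <- data.frame(time_s = (i - 1L) / fs,
                           freq_hz = ridge$freq_hz[i],
                           magnitude = ridge$magnitude[i],
                           cycle = cyc$cycle[r])
  }
  pts <- do.call(rbind, out)
  if (is.null(pts) || nrow(pts) == 0)
    stop("no ridge points fall inside the (trimmed) diastolic intervals")
  rownames(pts) <- NULL
  structure(pts, class = c("freq_mag_points", "data.frame"))
}

#' Cluster the frequency-magnitude distribution into three groups
#'
#' Frequencies and magnitudes are standardized per dimension (they are
#' incommensurate) and partitioned by k-means with k = 3 and seeded random
#' restarts. The group with the fewest members is the abnormal one (extra
#' diastolic sounds are sparse relative to the baseline); among the
#' remaining two, the group whose standardized centroid is closest to the
#' origin is the normal baseline (low amplitude and frequency) and the
#' other is uncertain. Size ties for the fewest group go to the group with
#' the higher mean standardized magnitude.
#'
#' @param pts a `"freq_mag_points"` data frame (>= 3 distinct points).
#' @param seed integer seed making the restarts reproducible.
#' @param restarts number of k-means restarts (default 10).
#' @return An object of class `"cluster_assignment"`: list with `labels`
#'   (factor levels normal/uncertain/abnormal per point), `centroids`
#'   (3 x 2 standardized), `sizes`, and the standardization parameters.
#' @export
cluster_points <- function(pts, seed = 1L, restarts = 10L) {
  stopifnot(inherits(pts, "freq_mag_points"))
  X <- cbind(pts$freq_hz, pts$magnitude)
  if (nrow(unique(X)) < 3)
    stop("need at least 3 distinct points to form three clusters")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  set.seed(as.integer(seed))
  km <- stats::kmeans(Z, centers = 3, nstart = as.integer(restarts),
                      iter.max = 300)
  sizes <- as.integer(km$size)
  mean_mag <- km$centers[, 2]
  ab <- order(sizes, -mean_mag)[1]
  rest <- setdiff(1:3, ab)
  norms <- sqrt(rowSums(km$centers^2))
  nm <- rest[which.min(norms[rest])]
  un <- setdiff(rest, nm)
  lab <- character(3)
  lab[ab] <- "abnormal"; lab[nm] <- "normal"; lab[un] <- "uncertain"
  structure(list(
    labels = factor(lab[km$cluster],
                    levels = c("normal", "uncertain", "abnormal")),
    centroids = km$centers, sizes = sizes,
    group_of_cluster = lab, center = ctr, scale = scl),
    class = "cluster_assignment")
}

#' Project abnormal cluster points to candidate event times
#'
#' Abnormal points are sorted by time and split into runs wherever the gap
#' to the next point reaches `gap_ms`; each run becomes one candidate event
#' at the magnitude-weighted mean time, carrying the run's maximum
#' magnitude and its cycle index.
#'
#' @param assign a `"cluster_assignment"` for `pts`.
#' @param pts the `"freq_mag_points"` that were clustered.
#' @param seg the `"cycle_segmentation"` (for cycle sanity only).
#' @param gap_ms merge gap in ms (default 60).
#' @return Data frame with columns `onset_s`, `magnitude`, `cycle`,
#'   `n_points` (zero rows when no abnormal points exist).
#' @export
project_to_events <- function(assign, pts, seg, gap_ms = 60) {
  stopifnot(inherits(assign, "cluster_assignment"),
            inherits(pts, "freq_mag_points"))
  ab <- pts[assign$labels == "abnormal", , drop = FALSE]
  empty <- data.frame(onset_s = numeric(), magnitude = numeric(),
                      cycle = integer(), n_points = integer())
  if (nrow(ab) == 0) return(empty)
  ab <- ab[order(ab$time_s), , drop = FALSE]
  run <- cumsum(c(1, diff(ab$time_s) >= gap_ms / 1000))
  out <- lapply(split(ab, run), function(d) {
    data.frame(onset_s = stats::weighted.mean(d$time_s, d$magnitude),
               magnitude = max(d$magnitude),
               cycle = d$cycle[which.max(d$magnitude)],
               n_points = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify candidate events as S3 or S4 by their position in diastole
#'
#' S3 occurs in early diastole, shortly after S2 (the rapid-filling phase);
#' S4 occurs in late diastole, right before the next S1 (atrial
#' contraction). A candidate whose latency from the cycle's S2 falls in
#' `s3_window_ms` becomes an S3; one whose lead before the next S1 falls in
#' `s4_window_ms` becomes an S4; a candidate matching both is assigned to
#' the window whose centre it is nearer (in units of the window half-width);
#' candidates matching neither are rejected. At most one event per label per
#' cycle is kept, the one with the largest magnitude.
#'
#' @param cands candidate data frame from [project_to_events()].
#' @param seg a `"cycle_segmentation"`.
#' @param s3_window_ms latency window after S2, default `c(80, 250)`.
#' @param s4_window_ms lead window before next S1, default `c(40, 200)`.
#' @return Data frame with columns `label`, `onset_s`, `cycle`,
#'   `latency_s`, `magnitude`, `provenance`; attribute `n_rejected`.
#' @export
classify_events <- function(cands, seg, s3_window_ms = c(80, 250),
                            s4_window_ms = c(40, 200)) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  empty <- event_frame()
  if (is.null(cands) || nrow(cands) == 0) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  cyc <- seg$cycles
  rows <- list()
  n_rejected <- 0L
  for (r in seq_len(nrow(cands))) {
    k <- match(cands$cycle[r], cyc$cycle)
    if (is.na(k) || is.na(cyc$dia_start[k])) { n_rejected <- n_rejected + 1L; next }
    lat_ms <- (cands$onset_s[r] - cyc$s2[k]) * 1000
    lead_ms <- (cyc$dia_end[k] - cands$onset_s[r]) * 1000
    in3 <- lat_ms >= s3_window_ms[1] && lat_ms <= s3_window_ms[2]
    in4 <- lead_ms >= s4_window_ms[1] && lead_ms <= s4_window_ms[2]
    if (in3 && in4) {
      d3 <- abs(lat_ms - mean(s3_window_ms)) / (diff(s3_window_ms) / 2)
      d4 <- abs(lead_ms - mean(s4_window_ms)) / (diff(s4_window_ms) / 2)
      if (d4 < d3) in3 <- FALSE else in4 <- FALSE
    }
    if (in3) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = "S3", onset_s = cands$onset_s[r], cycle = cands$cycle[r],
        latency_s = lat_ms / 1000, magnitude = cands$magnitude[r],
        provenance = "clustered", stringsAsFactors = FALSE)
    } else if (in4) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = "S4", onset_s = cands$onset_s[r], cycle = cands$cycle[r],
        latency_s = lead_ms / 1000, magnitude = cands$magnitude[r],
        provenance = "clustered", stringsAsFactors = FALSE)
    } else n_rejected <- n_rejected + 1L
  }
  ev <- if (length(rows)) do.call(rbind, rows) else empty
  # at most one event per label per cycle: strongest magnitude wins
  if (nrow(ev) > 1) {
    keep <- unlist(lapply(split(seq_len(nrow(ev)),
                                paste(ev$label, ev$cycle)), function(i) {
      i[which.max(ev$magnitude[i])]
    }), use.names = FALSE)
    n_rejected <- n_rejected + nrow(ev) - length(keep)
    ev <- ev[sort(keep), , drop = FALSE]
  }
  rownames(ev) <- NULL
  attr(ev, "n_rejected") <- n_rejected
  ev
}

event_frame <- function() {
  data.frame(label = character(), onset_s = numeric(), cycle = integer(),
             latency_s = numeric(), magnitude = numeric(),
             provenance = character(), stringsAsFactors = FALSE)
}

# latency of an event under its label's convention: S3 from S2 forward,
# S4 backward from the closing S1
event_latency <- function(ev, cyc) {
  k <- match(ev$cycle, cyc$cycle)
  ifelse(ev$label == "S3", ev$onset_s - cyc$s2[k],
         cyc$dia_end[k] - ev$onset_s)
}

#' Iterative periodicity-based recognition
#'
#' Diastolic sounds recur at a stable position within the cycle, while noise
#' does not. For each label the median latency across cycles is computed
#' (S3: after S2; S4: before the next S1); events deviating from it by more
#' than `latency_tol_ms` are discarded as non-periodic. A label is deemed
#' present in the record when it was detected in at least `presence_frac` of
#' the cycles; detections of a label that is not present are discarded as
#' noise, while for present labels every cycle lacking the event is
#' re-searched within the median latency +/- tolerance, and the pooled ridge
#' point of maximal magnitude there is promoted to a recovered event if its
#' magnitude exceeds `recover_frac` times the median magnitude of the
#' label's detected events. The pass repeats until the event set is stable,
#' so the operation is idempotent.
#'
#' @param events event data frame from [classify_events()].
#' @param pts the pooled `"freq_mag_points"` (all groups, not only
#'   abnormal).
#' @param seg the `"cycle_segmentation"`.
#' @param latency_tol_ms periodicity tolerance (default 50).
#' @param presence_frac fraction of cycles required for presence (default
#'   0.5).
#' @param recover_frac magnitude fraction for recovery (default 0.6).
#' @param max_iter safety cap on passes (default 20).
#' @return The final event data frame, sorted by onset.
#' @export
iterative_recognition <- function(events, pts, seg, latency_tol_ms = 50,
                                  presence_frac = 0.5, recover_frac = 0.6,
                                  max_iter = 20L) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  cyc <- seg$cycles[!is.na(seg$cycles$dia_start), , drop = FALSE]
  n_cycles <- nrow(cyc)
  if (n_cycles < 2) return(events)
  tol <- latency_tol_ms / 1000
  ev <- events
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (lb in c("S3", "S4")) {
      sel <- which(ev$label == lb)
      if (length(sel) == 0) next
      lat <- event_latency(ev[sel, , drop = FALSE], cyc)
      med <- stats::median(lat)
      drop <- sel[abs(lat - med) > tol]
      if (length(drop)) {
        ev <- ev[-drop, , drop = FALSE]
        changed <- TRUE
        next  # recompute the median before recovering
      }
      if (length(sel) < presence_frac * n_cycles) {
        # the sound is not present in the record: its sparse detections are
        # noise, not a periodic component
        ev <- ev[-sel, , drop = FALSE]
        changed <- TRUE
        next
      }
      med_mag <- stats::median(ev$magnitude[sel])
      missing <- setdiff(cyc$cycle, ev$cycle[sel])
      for (k in missing) {
        r <- match(k, cyc$cycle)
        if (lb == "S3") {
          t0 <- cyc$s2[r] + med - tol; t1 <- cyc$s2[r] + med + tol
        } else {
          t0 <- cyc$dia_end[r] - med - tol; t1 <- cyc$dia_end[r] - med + tol
        }
        cand <- pts[pts$cycle == k & pts$time_s >= t0 & pts$time_s <= t1, ,
                    drop = FALSE]
        if (nrow(cand) == 0) next
        best <- cand[which.max(cand$magnitude), ]
        if (best$magnitude > recover_frac * med_mag) {
          lat_new <- if (lb == "S3") best$time_s - cyc$s2[r] else
            cyc$dia_end[r] - best$time_s
          ev <- rbind(ev, data.frame(
            label = lb, onset_s = best$time_s, cycle = k,
            latency_s = lat_new, magnitude = best$magnitude,
            provenance = "recovered", stringsAsFactors = FALSE))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect third and fourth heart sounds in a phonocardiogram
#'
#' Runs the full recognition pipeline on one record: zero-phase low-pass
#' filtering, Shannon-energy segmentation into cardiac cycles, empirical
#' mode decomposition with Hilbert spectral analysis of the filtered
#' signal, extraction of the maximal-amplitude frequency ridge, k-means
#' clustering of the pooled diastolic frequency-magnitude points,
#' projection of the abnormal group to candidate times, S3/S4
#' classification by position in diastole, and iterative periodicity-based
#' refinement.
#'
#' @param rec a [pcg_record()] (roughly 2 s minimum; several cycles are
#'   needed for the periodicity criterion to act).
#' @param config an [hs_config()].
#' @param seed integer seed for the k-means restarts; identical record,
#'   config and seed give an identical result.
#' @return An object of class `"s34_detection"`: list with `events` (data
#'   frame `label`, `onset_s`, `cycle`, `latency_s`, `magnitude`,
#'   `provenance`), `cycles` (per-cycle table with S3/S4 onsets or `NA`),
#'   `segmentation`, `ridge`, `points`, `assignment`, `n_rejected`,
#'   `record_id`, `fs`, `config`, `seed`.
#' @seealso [simulate_pcg()] to generate test records, [score_cycles()] to
#'   evaluate against ground truth, [write_report()] for JSON export.
#' @export
#' @examples
#' sim <- simulate_pcg(synth_config(n_cycles = 6, s3_present = TRUE,
#'                                  seed = 7))
#' det <- detect_s34(sim$record, seed = 7)
#' det
detect_s34 <- function(rec, config = hs_config(), seed = 1L) {
  stopifnot(inherits(rec, "pcg_record"))
  if (length(rec$samples) < 2 * rec$fs)
    warning("record shorter than 2 s; detection is unreliable")
  seg <- segment_cycles(rec, config)
  filt <- lowpass_filter(rec, config$lowpass$cutoff_hz, config$lowpass$order)
  decomp <- emd(filt$samples, filt$fs, config$emd$sd_tol,
                config$emd$max_sifts, config$emd$max_imfs,
                config$emd$boundary_extrema)
  if (ncol(decomp$imfs) == 0)
    stop("EMD produced no intrinsic mode functions; record may be constant")
  tracks <- hilbert_tracks(decomp)
  ridge <- max_amplitude_ridge(tracks, config$hht$ridge)
  pts <- extract_diastolic_points(ridge, seg, config$detect$decimate,
                                  config$detect$trim_after_s2_ms,
                                  config$detect$trim_before_s1_ms)
  assign <- cluster_points(pts, seed = seed,
                           restarts = config$kmeans$restarts)
  cands <- project_to_events(assign, pts, seg, config$detect$gap_ms)
  ev <- classify_events(cands, seg, config$detect$s3_window_ms,
                        config$detect$s4_window_ms)
  n_rejected <- attr(ev, "n_rejected")
  ev <- iterative_recognition(ev, pts, seg, config$detect$latency_tol_ms,
                              config$detect$presence_frac,
                              config$detect$recover_frac)
  cycles <- seg$cycles
  for (lb in c("S3", "S4")) {
    col_on <- paste0(tolower(lb), "_onset")
    col_pr <- paste0(tolower(lb), "_provenance")
    cycles[[col_on]] <- NA_real_
    cycles[[col_pr]] <- NA_character_
    sel <- ev$label == lb
    k <- match(ev$cycle[sel], cycles$cycle)
    cycles[[col_on]][k] <- ev$onset_s[sel]
    cycles[[col_pr]][k] <- ev$provenance[sel]
  }
  structure(list(
    record_id = rec$record_id, fs = rec$fs, events = ev, cycles = cycles,
    n_cycles = nrow(seg$cycles), segmentation = seg, ridge = ridge,
    points = pts, assignment = assign, n_rejected = n_rejected,
    config = config, seed = as.integer(seed)),
    class = "s34_detection")
}

#' Convert a detection to an [annotation_set()]
#'
#' @param det an `"s34_detection"`.
#' @return An `"annotation_set"` with `source = "detected"`.
#' @export
as_annotations <- function(det) {
  stopifnot(inherits(det, "s34_detection"))
  annotation_set(det$events$label, det$events$onset_s, det$events$cycle,
                 det$record_id, source = "detected")
}
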