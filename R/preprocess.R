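# Preprocessing: low-pass filtering, analytic-signal envelope, normalization,
# Shannon energy, and segmentation of the record into S1/S2/systole/diastole.

#' Zero-phase Butterworth low-pass filter
#'
#' Heart-sound energy lies almost entirely below 600 Hz; stethoscope
#' recordings carry broadband noise above that. The filter is applied
#' forward and backward ([signal::filtfilt()]) so that peak timing used by
#' the segmentation is not shifted.
#'
#' @param rec a [pcg_record()].
#' @param cutoff_hz cutoff frequency in Hz, strictly below Nyquist.
#' @param order Butterworth order (of the single pass; the zero-phase
#'   response is the squared magnitude).
#' @return A filtered `"pcg_record"` of the same length.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 600, order = 6L) {
  stopifnot(inherits(rec, "pcg_record"))
  if (cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "low")
  x <- rec$samples
  n <- length(x)
  # odd-symmetric edge padding suppresses the start-up transients of the
  # forward and backward passes
  pad <- min(n - 1L, as.integer(ceiling(25 * rec$fs / cutoff_hz)))
  ext <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, ext)[pad + seq_len(n)]
  pcg_record(y, rec$fs, rec$record_id)
}

#' Analytic-signal envelope
#'
#' Forms the analytic signal x + iH\{x\} (H the Hilbert transform, computed
#' by FFT) and returns its modulus, the instantaneous envelope of the
#' record.
#'
#' @param rec a [pcg_record()].
#' @return An object of class `"envelope_signal"`: list with nonnegative
#'   `values` (same length as the record) and `fs`.
#' @export
envelope <- function(rec) {
  stopifnot(inherits(rec, "pcg_record"))
  structure(list(values = Mod(analytic_signal(rec$samples)), fs = rec$fs),
            class = "envelope_signal")
}

#' Analytic signal via FFT
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x` (one-sided spectrum
#' construction).
#'
#' @param x numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n0 <- length(x)
  if (n0 == 0) return(complex(0))
  if (n0 == 1) return(complex(real = x, imaginary = 0))
  # pad to a 2-3-5-smooth length: R's mixed-radix FFT is O(n^2) for lengths
  # with large prime factors; mirror padding keeps the extension continuous
  m <- stats::nextn(n0, c(2L, 3L, 5L))
  if (m > n0) {
    pad <- m - n0
    ext <- x[n0 - seq_len(pad)]          # reflect the tail
    x <- c(x, ext)
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  z[seq_len(n0)]
}

#' Normalize an envelope to unit maximum
#'
#' Divides by the maximum absolute value so the result lies in \[-1, 1\]
#' with maximum exactly 1.
#'
#' @param env an `"envelope_signal"` (or numeric vector with `fs` attr
#'   supplied via `fs`).
#' @param fs sampling rate, required only when `env` is a bare vector.
#' @return An object of class `"normalized_signal"`.
#' @export
normalize <- function(env, fs = NULL) {
  if (inherits(env, "envelope_signal")) {
    v <- env$values; fs <- env$fs
  } else {
    v <- as.numeric(env)
    if (is.null(fs)) stop("fs required for bare numeric input")
  }
  m <- max(abs(v))
  if (m == 0) stop("cannot normalize an all-zero signal")
  structure(list(values = v / m, fs = fs), class = "normalized_signal")
}

#' Shannon energy
#'
#' `SE = -x^2 log(x^2)` with the limit convention `0 log 0 = 0`. For inputs
#' bounded by 1 in magnitude the output lies in \[0, 1/e\], with the maximum
#' attained at `|x| = exp(-1/2)`; the transform suppresses low-amplitude
#' content while compressing the largest peaks, which makes burst picking
#' robust to noise.
#'
#' @param norm a `"normalized_signal"` (or numeric vector with
#'   `max(abs(.)) <= 1`).
#' @param fs sampling rate for bare numeric input.
#' @return An object of class `"shannon_energy"`.
#' @export
shannon_energy <- function(norm, fs = NULL) {
  if (inherits(norm, "normalized_signal")) {
    v <- norm$values; fs <- norm$fs
  } else {
    v <- as.numeric(norm)
    if (is.null(fs)) stop("fs required for bare numeric input")
  }
  if (max(abs(v)) > 1 + 1e-9)
    stop("shannon_energy input must satisfy |x| <= 1")
  u <- pmin(v * v, 1)
  se <- ifelse(u == 0, 0, -u * log(u))
  structure(list(values = se, fs = fs), class = "shannon_energy")
}

# centred moving average with shrinking windows at the record edges
smooth_ma <- function(x, fs, window_ms) {
  w <- max(1L, round(fs * window_ms / 1000))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1L || length(x) < 2) return(x)
  half <- (w - 1L) / 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# strict local maxima with plateau-midpoint rule
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  if (all(d != 0)) {              # fast path: no plateaus
    up <- d > 0
    return(which(up[-(n - 1L)] & !up[-1L]) + 1L)
  }
  s <- sign(d)
  # carry the last nonzero slope across plateaus
  pos <- cummax(ifelse(s != 0, seq_along(s), 0L))
  filled <- ifelse(pos > 0L, s[pmax(pos, 1L)], 0)
  m <- length(filled)
  trans <- which(filled[-m] == 1 & filled[-1] == -1) + 1L
  out <- integer(length(trans))
  for (k in seq_along(trans)) {
    i <- trans[k]
    j <- i
    while (j > 1 && x[j - 1] == x[i]) j <- j - 1L  # back across the plateau
    out[k] <- as.integer(floor((i + j) / 2))
  }
  unique(out)
}

#' Pick the major Shannon-energy peaks
#'
#' Local maxima of the (smoothed) Shannon energy above
#' `threshold_frac * max(SE)` are candidate S1/S2 positions. Peaks closer
#' than `merge_ms` belong to one sound: candidates are processed in order of
#' decreasing energy and a candidate is kept only if no already-kept peak
#' lies within `merge_ms` of it. This rule is deterministic and independent
#' of detection order, and on any group of mutually close peaks it keeps the
#' group's energy maximum.
#'
#' @param se a `"shannon_energy"` (values are used as-is; smooth first for
#'   per-sample envelopes, see [segment_cycles()]).
#' @param threshold_frac fraction of the global maximum (default 0.70).
#' @param merge_ms minimum spacing between surviving peaks (default 50).
#' @return Numeric vector of peak times in seconds (sorted).
#' @export
pick_major_peaks <- function(se, threshold_frac = 0.70, merge_ms = 50) {
  stopifnot(inherits(se, "shannon_energy"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  v <- se$values
  idx <- local_maxima(v)
  idx <- idx[v[idx] > threshold_frac * max(v)]
  if (length(idx) == 0)
    stop("no Shannon-energy peak above threshold; segmentation impossible")
  keep <- merge_close_peaks(idx, v[idx], se$fs * merge_ms / 1000)
  sort((keep - 1) / se$fs)
}

# canonical order-independent elimination: descending energy, keep if no
# stronger kept peak within min_gap samples; ties broken by earlier time
merge_close_peaks <- function(idx, energy, min_gap) {
  o <- order(-energy, idx)
  kept <- integer(0)
  for (i in o) {
    if (length(kept) == 0 || all(abs(idx[kept] - idx[i]) >= min_gap))
      kept <- c(kept, i)
  }
  sort(idx[kept])
}

#' Label inter-peak intervals as systolic, diastolic or uncertain
#'
#' Systole (S1 to S2) is shorter than the diastole that follows it, so an
#' interval shorter than its reference neighbour is labelled systolic and a
#' longer one diastolic. Intervals whose relative difference from the
#' reference is below `tie_tol` are ambiguous, and intervals longer than
#' `gap_factor` times the median interval are flagged as likely containing a
#' missed peak; both are labelled `uncertain` and handed to
#' [recover_missed_peaks()]. Peaks flanking each systolic interval are
#' labelled (S1, S2) and cycles are assembled as S1 onset, S2 onset,
#' diastole start (= S2) and diastole end (= next S1).
#'
#' @param peaks sorted numeric vector of peak times in seconds (>= 3).
#' @param tie_tol relative-difference tolerance for ambiguity (default 0.10).
#' @param gap_factor multiple of the median interval above which an interval
#'   is uncertain (default 1.5).
#' @return An object of class `"cycle_segmentation"`: list with `s1_times`,
#'   `s2_times`, `intervals` (data frame `start`, `end`, `label`), `cycles`
#'   (data frame `cycle`, `s1`, `s2`, `dia_start`, `dia_end`) and `peaks`.
#' @export
label_intervals <- function(peaks, tie_tol = 0.10, gap_factor = 1.5) {
  peaks <- sort(as.numeric(peaks))
  if (length(peaks) < 3)
    stop("at least 3 peaks are required to label intervals")
  len <- diff(peaks)
  m <- length(len)
  med <- stats::median(len)
  lab <- character(m)
  for (i in seq_len(m)) {
    ref <- if (i == 1) len[2] else len[i - 1]
    reldiff <- abs(len[i] - ref) / max(len[i], ref)
    if (len[i] > gap_factor * med) {
      lab[i] <- "uncertain"
    } else if (reldiff < tie_tol) {
      lab[i] <- "uncertain"
    } else if (len[i] < ref) {
      lab[i] <- "systolic"
    } else {
      lab[i] <- "diastolic"
    }
  }
  build_segmentation(peaks, lab)
}

build_segmentation <- function(peaks, lab) {
  m <- length(lab)
  intervals <- data.frame(start = peaks[-length(peaks)], end = peaks[-1],
                          label = lab, stringsAsFactors = FALSE)
  s1 <- peaks[which(lab == "systolic")]
  s2 <- peaks[which(lab == "systolic") + 1L]
  cyc <- list()
  k <- 0L
  for (i in which(lab == "systolic")) {
    if (i + 1L <= m && lab[i + 1L] == "diastolic") {
      cyc[[length(cyc) + 1L]] <- data.frame(
        cycle = k, s1 = peaks[i], s2 = peaks[i + 1L],
        dia_start = peaks[i + 1L], dia_end = peaks[i + 2L])
    } else {
      cyc[[length(cyc) + 1L]] <- data.frame(
        cycle = k, s1 = peaks[i], s2 = peaks[i + 1L],
        dia_start = NA_real_, dia_end = NA_real_)
    }
    k <- k + 1L
  }
  cycles <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(cycle = integer(), s1 = numeric(), s2 = numeric(),
               dia_start = numeric(), dia_end = numeric())
  structure(list(s1_times = s1, s2_times = s2, intervals = intervals,
                 cycles = cycles, peaks = peaks),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  n_unc <- sum(x$intervals$label == "uncertain")
  cat(sprintf(
    "Cycle segmentation: %d peaks, %d S1, %d S2, %d cycles (%d uncertain interval%s)\n",
    length(x$peaks), length(x$s1_times), length(x$s2_times),
    nrow(x$cycles), n_unc, if (n_unc == 1) "" else "s"))
  invisible(x)
}

#' Recover peaks missed at the primary threshold
#'
#' Inside every uncertain interval a secondary, lower threshold is applied
#' to find an S1 or S2 whose energy fell below the primary threshold
#' (typically a weak S2). Recovered candidates are merged with the existing
#' peaks under the same minimum-spacing rule and the intervals are
#' relabelled.
#'
#' @param se the (smoothed) `"shannon_energy"` used for the original peaks.
#' @param seg a `"cycle_segmentation"`.
#' @param secondary_frac secondary threshold as a fraction of the global
#'   Shannon-energy maximum; must be below the primary threshold.
#' @param merge_ms,tie_tol,gap_factor as in [pick_major_peaks()] and
#'   [label_intervals()].
#' @return A relabelled `"cycle_segmentation"` (unchanged when nothing is
#'   recovered).
#' @export
recover_missed_peaks <- function(se, seg, secondary_frac = 0.50,
                                 merge_ms = 50, tie_tol = 0.10,
                                 gap_factor = 1.5) {
  stopifnot(inherits(se, "shannon_energy"),
            inherits(seg, "cycle_segmentation"))
  unc <- seg$intervals[seg$intervals$label == "uncertain", , drop = FALSE]
  if (nrow(unc) == 0) return(seg)
  v <- se$values
  thr <- secondary_frac * max(v)
  new_idx <- integer(0)
  for (r in seq_len(nrow(unc))) {
    i0 <- max(1L, floor(unc$start[r] * se$fs) + 1L)
    i1 <- min(length(v), ceiling(unc$end[r] * se$fs) + 1L)
    cand <- local_maxima(v[i0:i1]) + i0 - 1L
    new_idx <- c(new_idx, cand[v[cand] > thr])
  }
  if (length(new_idx) == 0) return(seg)
  all_idx <- unique(c(round(seg$peaks * se$fs) + 1L, new_idx))
  keep <- merge_close_peaks(all_idx, v[all_idx], se$fs * merge_ms / 1000)
  label_intervals(sort((keep - 1) / se$fs), tie_tol = tie_tol,
                  gap_factor = gap_factor)
}

#' Segment a record into cardiac cycles
#'
#' Composition of the preprocessing chain: low-pass filter, analytic
#' envelope, normalization, Shannon energy, moving-average smoothing, peak
#' picking, interval labelling and secondary-threshold recovery. Peak times
#' are refined to the local maximum of the normalized envelope within half
#' the merge window of each Shannon-energy peak; the Shannon energy of a
#' normalized envelope vanishes where the envelope touches 1, so its argmax
#' is biased off the burst centre while the envelope maximum is not.
#'
#' @param rec a [pcg_record()].
#' @param config an [hs_config()].
#' @return A `"cycle_segmentation"` with the smoothed Shannon energy
#'   attached as attribute `"se"` and the normalized envelope as `"env"`.
#' @export
segment_cycles <- function(rec, config = hs_config()) {
  stopifnot(inherits(rec, "pcg_record"))
  filt <- lowpass_filter(rec, config$lowpass$cutoff_hz, config$lowpass$order)
  env <- normalize(envelope(filt))
  se <- shannon_energy(env)
  se$values <- smooth_ma(se$values, se$fs, config$se$smooth_ms)
  peaks <- pick_major_peaks(se, config$seg$threshold_frac,
                            config$seg$merge_ms)
  peaks <- refine_peak_times(peaks, env, config$seg$merge_ms / 2)
  seg <- label_intervals(peaks, config$seg$tie_tol, config$seg$gap_factor)
  if (any(seg$intervals$label == "uncertain")) {
    seg2 <- recover_missed_peaks(se, seg, config$seg$secondary_frac,
                                 config$seg$merge_ms, config$seg$tie_tol,
                                 config$seg$gap_factor)
    if (length(seg2$peaks) > length(seg$peaks)) {
      seg <- label_intervals(
        refine_peak_times(seg2$peaks, env, config$seg$merge_ms / 2),
        config$seg$tie_tol, config$seg$gap_factor)
    }
  }
  attr(seg, "se") <- se
  attr(seg, "env") <- env
  seg
}

# move each peak to the envelope maximum within +/- win_ms
refine_peak_times <- function(peaks, env, win_ms) {
  half <- max(1L, round(env$fs * win_ms / 1000))
  n <- length(env$values)
  vapply(peaks, function(p) {
    i <- round(p * env$fs) + 1L
    lo <- max(1L, i - half); hi <- min(n, i + half)
    (lo - 1L + which.max(env$values[lo:hi]) - 1L) / env$fs
  }, numeric(1))
}
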