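# Synthetic phonocardiogram generator: periodic S1/S2 tone bursts with
# optional low-amplitude, low-frequency S3/S4, cycle-to-cycle timing jitter
# and additive noise at a configurable SNR, plus exact ground truth.

#' Gaussian-windowed tone burst
#'
#' The elementary heart-sound model: a cosine carrier under a Gaussian
#' window spanning `dur` seconds (+/- 3 standard deviations), centred so the
#' window peak coincides with a carrier extremum and the waveform's peak
#' magnitude equals `amp` exactly.
#'
#' @param f0 carrier frequency in Hz (< fs/2).
#' @param dur burst duration in seconds (0 gives an empty waveform).
#' @param amp peak amplitude.
#' @param fs sampling rate in Hz.
#' @return Numeric waveform of `round(dur * fs)` samples.
#' @export
tone_burst <- function(f0, dur, amp, fs) {
  if (f0 >= fs / 2) stop("f0 must be below the Nyquist frequency")
  n <- round(dur * fs)
  if (n <= 0) return(numeric(0))
  t <- (seq_len(n) - ceiling(n / 2)) / fs  # a sample lies exactly at t = 0
  sigma <- dur / 6
  amp * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t)
}

#' Synthetic phonocardiogram configuration
#'
#' Defaults describe a typical adult recording: 75 bpm, S1/S2 tone bursts at
#' 40/60 Hz, and (when enabled) diastolic sounds in the physiologic regime
#' reported for S3 and S4 - frequencies below 100 Hz and amplitudes well
#' under the S1/S2 level (here 20% and 15% of S1). Timing jitter is applied
#' multiplicatively (truncated Gaussian, fraction of each nominal duration)
#' to the cycle length and the intra-cycle latencies.
#'
#' @param fs sampling rate in Hz (default 8000).
#' @param n_cycles number of complete cardiac cycles (default 10); a closing
#'   S1 is placed after the last cycle so its diastole is bounded.
#' @param heart_rate_bpm mean heart rate (default 75).
#' @param timing_jitter standard deviation of the multiplicative jitter
#'   (default 0.03, truncated at 3 sigma).
#' @param s1,s2,s3,s4 component descriptors: lists with `f0` (Hz), `dur_ms`,
#'   `amp`, and the timing field (`delay_ms` after S1 for S2, `latency_ms`
#'   after S2 for S3, `lead_ms` before the next S1 for S4).
#' @param s3_present,s4_present logical, or a probability in (0, 1) applied
#'   independently per cycle.
#' @param snr_db signal-to-noise ratio of the added noise in dB (default
#'   20); `Inf` adds no noise.
#' @param noise `"white"` (Gaussian) or `"pink"` (1/f-shaped Gaussian).
#' @param lead_in_s silence before the first S1 centre (default 0.3).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(fs = 8000, n_cycles = 10L, heart_rate_bpm = 75,
                         timing_jitter = 0.03,
                         s1 = list(f0 = 40, dur_ms = 120, amp = 1.0),
                         s2 = list(f0 = 60, dur_ms = 100, amp = 0.8,
                                   delay_ms = 300),
                         s3 = list(f0 = 35, dur_ms = 80, amp = 0.2,
                                   latency_ms = 150),
                         s4 = list(f0 = 30, dur_ms = 80, amp = 0.15,
                                   lead_ms = 90),
                         s3_present = FALSE, s4_present = FALSE,
                         snr_db = 20, noise = c("white", "pink"),
                         lead_in_s = 0.3, seed = NULL) {
  noise <- match.arg(noise)
  cfg <- list(fs = fs, n_cycles = as.integer(n_cycles),
              heart_rate_bpm = heart_rate_bpm,
              timing_jitter = timing_jitter, s1 = s1, s2 = s2, s3 = s3,
              s4 = s4, s3_present = s3_present, s4_present = s4_present,
              snr_db = snr_db, noise = noise, lead_in_s = lead_in_s,
              seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  cycle_ms <- 60000 / cfg$heart_rate_bpm
  for (nm in c("s1", "s2", "s3", "s4")) {
    comp <- cfg[[nm]]
    if (comp$amp <= 0) stop(nm, " amplitude must be positive")
    if (comp$dur_ms >= cycle_ms)
      stop(nm, " duration must be shorter than the cycle length")
  }
  if (cfg$s3$amp >= min(cfg$s1$amp, cfg$s2$amp) ||
      cfg$s4$amp >= min(cfg$s1$amp, cfg$s2$amp))
    stop("S3/S4 amplitudes must be smaller than S1 and S2")
  # feasibility on the +/-2 sigma burst cores (dur spans +/-3 sigma); the
  # 3-sigma skirts are at ~1% amplitude and may touch without overlap
  core <- function(comp) comp$dur_ms / 3  # 2 sigma in ms
  s2_c <- cfg$s2$delay_ms
  s3_c <- s2_c + cfg$s3$latency_ms
  s4_c <- cycle_ms - cfg$s4$lead_ms
  ends <- c(0 + core(cfg$s1), s2_c - core(cfg$s2))
  if (ends[1] >= ends[2]) stop("S1 and S2 overlap with these timings")
  if (s2_c + core(cfg$s2) >= s3_c - core(cfg$s3))
    stop("S2 and S3 overlap with these timings")
  comp_on <- function(flag) isTRUE(flag) || (is.numeric(flag) && flag > 0)
  s3_on <- comp_on(cfg$s3_present)
  s4_on <- comp_on(cfg$s4_present)
  lim <- if (s4_on) s4_c - core(cfg$s4) else cycle_ms - core(cfg$s1)
  if (s3_on && s3_c + core(cfg$s3) >= lim)
    stop("S3 runs into the late-diastolic components")
  if (s4_on && s4_c + core(cfg$s4) >= cycle_ms - core(cfg$s1))
    stop("S4 and the next S1 overlap with these timings")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic PCG: %d cycles at %g bpm, fs %g Hz, SNR %g dB, jitter %g\n",
    x$n_cycles, x$heart_rate_bpm, x$fs, x$snr_db, x$timing_jitter))
  cat(sprintf("  S3 %s, S4 %s\n",
              format(x$s3_present), format(x$s4_present)))
  invisible(x)
}

# truncated standard normal draw times jitter fraction
jit <- function(n, frac) {
  if (frac == 0) return(rep(1, n))
  e <- pmax(pmin(stats::rnorm(n), 3), -3)
  1 + frac * e
}

#' Generate a synthetic phonocardiogram with ground truth
#'
#' Places S1/S2 (and optionally S3/S4) tone bursts on a jittered periodic
#' timing grid, adds noise scaled to the requested SNR (clean signal power
#' over noise power), and returns the record together with the exact
#' component onsets. A closing S1 is placed after the last cycle so that
#' every cycle has a bounded diastole; ground-truth onsets are the burst
#' centres.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `"synth_pcg"`: `record` (a [pcg_record()]),
#'   `truth` (an [annotation_set()]), `clean` and `noise` (numeric vectors
#'   summing to `record$samples`), and `cfg`.
#' @export
simulate_pcg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  fs <- cfg$fs
  cycle_s <- 60 / cfg$heart_rate_bpm
  nc <- cfg$n_cycles

  cyc_len <- cycle_s * jit(nc, cfg$timing_jitter)
  s1_c <- cfg$lead_in_s + c(0, cumsum(cyc_len))          # nc + 1 centres
  s2_c <- s1_c[seq_len(nc)] + cfg$s2$delay_ms / 1000 * jit(nc, cfg$timing_jitter)
  s3_c <- s2_c + cfg$s3$latency_ms / 1000 * jit(nc, cfg$timing_jitter)
  s4_c <- s1_c[-1] - cfg$s4$lead_ms / 1000 * jit(nc, cfg$timing_jitter)

  present <- function(flag) {
    if (is.logical(flag)) rep(isTRUE(flag), nc)
    else stats::runif(nc) < flag
  }
  has3 <- present(cfg$s3_present)
  has4 <- present(cfg$s4_present)

  dur_s <- s1_c[nc + 1] + cfg$s1$dur_ms / 2000 + 0.2
  n <- ceiling(dur_s * fs)
  clean <- numeric(n)
  add_burst <- function(x, centre, comp) {
    w <- tone_burst(comp$f0, comp$dur_ms / 1000, comp$amp, fs)
    i0 <- round(centre * fs) + 1L - floor(length(w) / 2)
    idx <- seq(i0, length.out = length(w))
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + w[ok]
    x
  }
  for (k in seq_len(nc)) {
    clean <- add_burst(clean, s1_c[k], cfg$s1)
    clean <- add_burst(clean, s2_c[k], cfg$s2)
    if (has3[k]) clean <- add_burst(clean, s3_c[k], cfg$s3)
    if (has4[k]) clean <- add_burst(clean, s4_c[k], cfg$s4)
  }
  clean <- add_burst(clean, s1_c[nc + 1], cfg$s1)

  if (is.finite(cfg$snr_db)) {
    nz <- if (cfg$noise == "white") stats::rnorm(n) else pink_noise(n)
    p_sig <- mean(clean^2)
    nz <- nz * sqrt(p_sig / 10^(cfg$snr_db / 10) / mean(nz^2))
  } else nz <- numeric(n)

  lab <- c(rep("S1", nc + 1), rep("S2", nc),
           rep("S3", sum(has3)), rep("S4", sum(has4)))
  ons <- c(s1_c, s2_c, s3_c[has3], s4_c[has4])
  cyc <- c(0:nc, seq_len(nc) - 1L, which(has3) - 1L, which(has4) - 1L)
  truth <- annotation_set(lab, ons, cyc, record_id = "synthetic",
                          source = "truth")
  structure(list(
    record = pcg_record(clean + nz, fs, "synthetic"),
    truth = truth, clean = clean, noise = nz, cfg = cfg),
    class = "synth_pcg")
}

# Gaussian noise with 1/f spectral shaping (FFT filter)
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' @export
print.synth_pcg <- function(x, ...) {
  print(x$record)
  cat(sprintf("  truth: %d events (%s)\n", nrow(x$truth),
              paste(names(table(x$truth$label)), table(x$truth$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
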