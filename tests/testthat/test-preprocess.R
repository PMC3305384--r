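test_that("low-pass filter passes DC and the heart-sound band, kills 2 kHz", {
  fs <- 8000
  t <- seq(0, 2, by = 1 / fs)

  dc <- pcg_record(rep(0.5, length(t)), fs)
  expect_lt(max(abs(lowpass_filter(dc)$samples - 0.5)), 1e-9)

  tone100 <- pcg_record(sin(2 * pi * 100 * t), fs)
  y <- lowpass_filter(tone100)$samples
  i <- interior(length(t), 0.1)
  gain <- sqrt(mean(y[i]^2) / mean(tone100$samples[i]^2))
  expect_lt(abs(gain - 1), 0.01)

  tone2k <- pcg_record(sin(2 * pi * 2000 * t), fs)
  y2 <- lowpass_filter(tone2k, 600, 6L)$samples
  att_db <- -20 * log10(sqrt(mean(y2[i]^2) / mean(tone2k$samples[i]^2)))
  # analytic magnitude of the bilinear-designed Butterworth at 2 kHz
  r <- tan(pi * 2000 / fs) / tan(pi * 600 / fs)
  oracle_db <- 10 * log10(1 + r^12)      # single pass
  expect_gte(oracle_db, 60)
  expect_gte(att_db, 60)
  expect_gte(att_db, oracle_db)          # zero-phase pass squares the response

  expect_error(lowpass_filter(dc, cutoff_hz = 4000), "fs/2")
})

test_that("analytic-signal envelope recovers tone and AM modulation", {
  fs <- 1000
  t <- (0:1999) / fs
  rec <- pcg_record(cos(2 * pi * 50 * t), fs)
  env <- envelope(rec)
  expect_true(all(env$values >= 0))
  expect_length(env$values, length(t))
  i <- interior(length(t), 0.05)
  expect_lt(max(abs(env$values[i] - 1)), 1e-3)

  # envelope dominates |x| pointwise
  expect_true(all(env$values - abs(rec$samples) >= -1e-12))

  am <- (1 + 0.5 * cos(2 * pi * 2 * t)) * cos(2 * pi * 100 * t)
  env_am <- envelope(pcg_record(am, fs))
  expect_lt(max(abs(env_am$values[i] - (1 + 0.5 * cos(2 * pi * 2 * t))[i])),
            0.02)
})

test_that("normalization scales to unit maximum, is idempotent, guards zero", {
  env <- structure(list(values = c(0.5, 2.5, 1), fs = 10),
                   class = "envelope_signal")
  nm <- normalize(env)
  expect_equal(max(abs(nm$values)), 1)
  expect_equal(nm$values, c(0.2, 1, 0.4))
  expect_equal(normalize(nm$values, fs = 10)$values, nm$values)
  expect_error(normalize(numeric(5), fs = 10), "all-zero")
})

test_that("Shannon energy has the exact bounds and extremum", {
  se <- shannon_energy(c(0, 1, -1, exp(-0.5), -exp(-0.5)), fs = 1)
  expect_equal(se$values[1], 0)            # 0 log 0 convention
  expect_equal(se$values[2], 0)            # log 1 = 0
  expect_equal(se$values[3], 0)
  expect_equal(se$values[4], exp(-1))      # global maximum 1/e
  expect_equal(se$values[5], exp(-1))
  x <- seq(-1, 1, by = 0.001)
  v <- shannon_energy(x, fs = 1)$values
  expect_true(all(v >= 0 & v <= exp(-1) + 1e-12))
  expect_error(shannon_energy(c(0, 1.01), fs = 1), "<= 1")
})

make_se <- function(times_s, energies, fs = 1000, dur_s = 2) {
  v <- numeric(dur_s * fs + 1)
  v[round(times_s * fs) + 1] <- energies
  structure(list(values = v, fs = fs), class = "shannon_energy")
}

test_that("peak picking thresholds, merges close pairs, keeps cluster max", {
  # two peaks 40 ms apart: lower one eliminated
  se <- make_se(c(0.5, 0.54, 1.2), c(0.3, 0.2, 0.25))
  pk <- pick_major_peaks(se, threshold_frac = 0.5, merge_ms = 50)
  expect_equal(pk, c(0.5, 1.2))

  # four well-separated bursts survive
  se4 <- make_se(c(0.2, 0.6, 1.0, 1.4), c(0.3, 0.28, 0.32, 0.29))
  expect_length(pick_major_peaks(se4, 0.7, 50), 4)

  # clustered triple within 50 ms: only the global max survives
  se3 <- make_se(c(0.5, 0.53, 0.545), c(0.22, 0.35, 0.28))
  expect_equal(pick_major_peaks(se3, 0.5, 50), 0.53)

  # nothing above threshold
  expect_error(pick_major_peaks(make_se(1, 0), 0.7), "no Shannon-energy peak")
})

# brute force: explore every order of "drop the lower peak of a violating
# pair" and collect all reachable final survivor sets
all_elimination_outcomes <- function(t_ms, e, merge = 50) {
  outcomes <- list()
  recurse <- function(keep) {
    pairs <- which(outer(t_ms[keep], t_ms[keep],
                         function(a, b) abs(a - b)) < merge &
                   upper.tri(diag(length(keep))), arr.ind = TRUE)
    if (nrow(pairs) == 0) {
      outcomes[[length(outcomes) + 1]] <<- sort(t_ms[keep])
      return()
    }
    for (r in seq_len(nrow(pairs))) {
      i <- keep[pairs[r, 1]]; j <- keep[pairs[r, 2]]
      drop <- if (e[i] < e[j]) i else j
      recurse(setdiff(keep, drop))
    }
  }
  recurse(seq_along(t_ms))
  unique(outcomes)
}

test_that("peak elimination is order-independent and matches reachable
           brute-force outcomes", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    t_ms <- sort(sample(0:300, n))  # on the 1 ms sample grid
    e <- stats::runif(n, 0.25, 1)
    se <- make_se(t_ms / 1000, e, fs = 1000, dur_s = 1)
    got <- pick_major_peaks(se, threshold_frac = 0.2, merge_ms = 50) * 1000
    # input-order invariance: shuffle by perturbing construction order
    perm <- sample(n)
    se_p <- make_se(t_ms[perm] / 1000, e[perm], fs = 1000, dur_s = 1)
    got_p <- pick_major_peaks(se_p, 0.2, 50) * 1000
    expect_equal(got, got_p)
    # the survivor set is reachable by some pair-elimination order
    outs <- all_elimination_outcomes(t_ms, e, 50)
    expect_true(any(vapply(outs, function(o)
      isTRUE(all.equal(o, got)), logical(1))))
    # when elimination is confluent the implementation must agree with it
    if (length(outs) == 1) expect_equal(got, outs[[1]])
  }
})

test_that("interval labelling follows the shorter/longer rule with ties and
           long gaps uncertain", {
  # alternating 300/500 ms
  pk <- cumsum(c(0.1, rep(c(0.3, 0.5), 4)))
  seg <- label_intervals(pk)
  labs <- seg$intervals$label
  expect_true(all(labs[seq(1, 8, 2)] == "systolic"))
  expect_true(all(labs[seq(2, 8, 2)] == "diastolic"))
  expect_equal(nrow(seg$cycles), 4)
  expect_true(all(seg$cycles$dia_end - seg$cycles$dia_start > 0))

  # all equal: every interval uncertain
  seg_eq <- label_intervals(seq(0, 2, by = 0.4))
  expect_true(all(seg_eq$intervals$label == "uncertain"))

  # 800 ms gap between two 300 ms intervals flagged uncertain
  seg_gap <- label_intervals(cumsum(c(0.1, 0.3, 0.8, 0.3)))
  expect_equal(seg_gap$intervals$label, c("systolic", "uncertain",
                                          "systolic"))
  expect_error(label_intervals(c(0, 1)), "3 peaks")
})

test_that("secondary threshold recovers a weak S2 inside an uncertain gap", {
  fs <- 1000
  # S1 peaks at 0.1/0.9/1.7, S2 at 0.4/1.2/2.0; the middle S2 at 55% energy
  t_pk <- c(0.1, 0.4, 0.9, 1.2, 1.7, 2.0)
  e_pk <- c(0.35, 0.30, 0.35, 0.19, 0.35, 0.30)  # 0.19 < 0.7*0.35 threshold
  se <- make_se(t_pk, e_pk, fs = fs, dur_s = 2.2)
  pk1 <- pick_major_peaks(se, 0.7, 50)
  expect_false(any(abs(pk1 - 1.2) < 0.01))       # missed at primary
  seg1 <- label_intervals(pk1)
  expect_true(any(seg1$intervals$label == "uncertain"))
  seg2 <- recover_missed_peaks(se, seg1, secondary_frac = 0.5)
  expect_true(any(abs(seg2$peaks - 1.2) < 0.01)) # recovered at secondary
  expect_equal(nrow(seg2$cycles), 3)

  # nothing above the secondary threshold: unchanged
  e_pk2 <- e_pk; e_pk2[4] <- 0.05
  se_low <- make_se(t_pk, e_pk2, fs = fs, dur_s = 2.2)
  pk_low <- pick_major_peaks(se_low, 0.7, 50)
  seg_low <- label_intervals(pk_low)
  seg_same <- recover_missed_peaks(se_low, seg_low, secondary_frac = 0.5)
  expect_identical(seg_same$peaks, seg_low$peaks)
})

test_that("a recovered peak within the merge window is absorbed by the
           stronger existing peak", {
  fs <- 1000
  t_pk <- c(0.1, 0.4, 0.9, 1.2, 1.7, 2.0, 1.23)
  e_pk <- c(0.35, 0.30, 0.35, 0.19, 0.35, 0.30, 0.16)
  se <- make_se(t_pk, e_pk, fs = fs, dur_s = 2.2)
  seg1 <- label_intervals(pick_major_peaks(se, 0.7, 50))
  seg2 <- recover_missed_peaks(se, seg1, secondary_frac = 0.4)
  # both 1.2 and 1.23 cross the secondary threshold; only 1.2 survives
  expect_true(any(abs(seg2$peaks - 1.2) < 0.005))
  expect_false(any(abs(seg2$peaks - 1.23) < 0.005))
})

test_that("segment_cycles returns non-overlapping intervals tiling the span", {
  sim <- quick_sim(11, s3 = TRUE, s4 = TRUE)
  seg <- segment_cycles(sim$record)
  iv <- seg$intervals
  expect_true(all(diff(as.vector(rbind(iv$start, iv$end))) >= 0))
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])  # contiguous tiling
  expect_equal(min(iv$start), min(seg$peaks))
  expect_equal(max(iv$end), max(seg$peaks))
})
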