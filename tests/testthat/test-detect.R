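# helpers building small segmentations and ridge tracks in code

toy_seg <- function(n_cycles = 5, cycle_s = 1.0, sys_s = 0.3, t0 = 0.1) {
  s1 <- t0 + (0:n_cycles) * cycle_s
  peaks <- sort(c(s1, s1[seq_len(n_cycles)] + sys_s))
  label_intervals(peaks, tie_tol = 0.1)
}

toy_ridge <- function(dur_s, fs = 8000, freq = 30, mag = 0.01) {
  n <- round(dur_s * fs)
  structure(list(freq_hz = rep(freq, n), magnitude = rep(mag, n), fs = fs,
                 imf_index = rep(1L, n)), class = "ridge_track")
}

test_that("diastolic point extraction counts, strides and membership", {
  seg <- toy_seg(5, cycle_s = 0.8, sys_s = 0.3)  # diastole 0.5 s
  ridge <- toy_ridge(0.1 + 5 * 0.8 + 0.2)
  pts <- extract_diastolic_points(ridge, seg, decimate = 8,
                                  trim_after_s2_ms = 0,
                                  trim_before_s1_ms = 0)
  expect_equal(nrow(pts), 5 * 500)

  pts1 <- extract_diastolic_points(ridge, seg, decimate = 1,
                                   trim_after_s2_ms = 0,
                                   trim_before_s1_ms = 0)
  expect_equal(nrow(pts1), 5 * 4000)

  # brute-force membership: every point lies inside a diastole of its cycle
  # (1 ns tolerance for floating-point representation of interval bounds)
  cyc <- seg$cycles
  for (r in seq_len(nrow(pts))) {
    k <- match(pts$cycle[r], cyc$cycle)
    expect_true(pts$time_s[r] >= cyc$dia_start[k] - 1e-9 &&
                pts$time_s[r] < cyc$dia_end[k] + 1e-9)
  }

  # trims shrink the member interval accordingly
  ptr <- extract_diastolic_points(ridge, seg, decimate = 1,
                                  trim_after_s2_ms = 70,
                                  trim_before_s1_ms = 60)
  k <- match(ptr$cycle, cyc$cycle)
  expect_true(all(ptr$time_s >= cyc$dia_start[k] + 0.07 - 1e-9))
  expect_true(all(ptr$time_s <= cyc$dia_end[k] - 0.06 + 1e-9))
})

fmp <- function(time_s, freq_hz, magnitude, cycle = 0L) {
  structure(data.frame(time_s = time_s, freq_hz = freq_hz,
                       magnitude = magnitude, cycle = cycle),
            class = c("freq_mag_points", "data.frame"))
}

test_that("clustering separates planted blobs and flags the smallest as
           abnormal, the low-amplitude/low-frequency one as normal", {
  set.seed(1)
  blob <- function(n, f, m) cbind(stats::rnorm(n, f, 1),
                                  stats::rnorm(n, m, 0.002))
  X <- rbind(blob(100, 25, 0.01), blob(30, 300, 0.012), blob(5, 35, 0.18))
  pts <- fmp(seq_len(nrow(X)) / 1000, X[, 1], X[, 2])
  a <- cluster_points(pts, seed = 9)
  expect_equal(sum(a$labels == "abnormal"), 5)
  expect_true(all(a$labels[131:135] == "abnormal"))
  expect_true(all(a$labels[1:100] == "normal"))
  expect_true(all(a$labels[101:130] == "uncertain"))
})

test_that("k-means partition on a tiny set attains the exhaustive-search
           optimum", {
  set.seed(4)
  pts <- fmp(1:6 / 100, c(1, 1.2, 5, 5.3, 9, 9.1),
             c(0.01, 0.012, 0.05, 0.052, 0.1, 0.102))
  a <- cluster_points(pts, seed = 2, restarts = 25)
  Z <- scale(cbind(pts$freq_hz, pts$magnitude))

  # enumerate all assignments of 6 points to 3 non-empty groups
  best <- Inf; best_part <- NULL
  for (code in 0:(3^6 - 1)) {
    g <- (code %/% 3^(0:5)) %% 3
    if (length(unique(g)) != 3) next
    w <- sum(vapply(0:2, function(k) {
      Zk <- Z[g == k, , drop = FALSE]
      sum(scale(Zk, scale = FALSE)^2)
    }, numeric(1)))
    if (w < best - 1e-12) { best <- w; best_part <- g }
  }
  # compare as unordered partitions
  canon <- function(g) {
    m <- match(g, unique(g))
    paste(m, collapse = "")
  }
  got <- as.integer(factor(as.character(a$labels),
                           levels = unique(as.character(a$labels))))
  expect_identical(canon(got), canon(best_part))
})

test_that("clustering is invariant to duplicating every point", {
  set.seed(7)
  X <- rbind(cbind(stats::rnorm(40, 20, 2), stats::rnorm(40, 0.01, 0.001)),
             cbind(stats::rnorm(20, 200, 5), stats::rnorm(20, 0.01, 0.001)),
             cbind(stats::rnorm(8, 30, 2), stats::rnorm(8, 0.15, 0.01)))
  pts <- fmp(seq_len(nrow(X)) / 100, X[, 1], X[, 2])
  dup <- fmp(rep(pts$time_s, 2), rep(X[, 1], 2), rep(X[, 2], 2))
  a1 <- cluster_points(pts, seed = 3, restarts = 20)
  a2 <- cluster_points(dup, seed = 3, restarts = 20)
  expect_identical(as.character(a1$labels),
                   as.character(a2$labels[seq_len(nrow(X))]))
  expect_identical(as.character(a1$labels),
                   as.character(a2$labels[nrow(X) + seq_len(nrow(X))]))
  expect_error(cluster_points(fmp(1:2, c(1, 1), c(2, 2))), "distinct")
})

test_that("projection merges runs by gap and uses the magnitude-weighted
           mean onset", {
  seg <- toy_seg(2)
  # 10 points spanning 30 ms: one candidate
  pts <- fmp(0.5 + seq(0, 0.03, length.out = 10), 30, 0.1, 0L)
  a <- structure(list(labels = factor(rep("abnormal", 10),
                                      levels = c("normal", "uncertain",
                                                 "abnormal"))),
                 class = "cluster_assignment")
  ev <- project_to_events(a, pts, seg, gap_ms = 60)
  expect_equal(nrow(ev), 1)

  # two bursts 300 ms apart: two candidates
  pts2 <- fmp(c(0.5, 0.505, 0.8, 0.805), 30, 0.1, 0L)
  a2 <- structure(list(labels = factor(rep("abnormal", 4),
                                       levels = c("normal", "uncertain",
                                                  "abnormal"))),
                  class = "cluster_assignment")
  ev2 <- project_to_events(a2, pts2, seg, gap_ms = 60)
  expect_equal(nrow(ev2), 2)

  # hand-checked weighted mean on a 4-point run
  pts3 <- fmp(c(1.000, 1.010, 1.020, 1.030), 30, c(1, 2, 3, 4), 0L)
  a3 <- a2
  ev3 <- project_to_events(a3, pts3, seg, gap_ms = 60)
  expect_equal(ev3$onset_s,
               sum(c(1.000, 1.010, 1.020, 1.030) * (1:4)) / sum(1:4))
  expect_equal(ev3$magnitude, 4)

  # empty abnormal set
  a0 <- structure(list(labels = factor(rep("normal", 4),
                                       levels = c("normal", "uncertain",
                                                  "abnormal"))),
                  class = "cluster_assignment")
  expect_equal(nrow(project_to_events(a0, pts3, seg, 60)), 0)
})

test_that("candidates classify as S3 after S2, S4 before next S1, or are
           rejected", {
  seg <- toy_seg(3)  # S1 at 0.1+k, S2 at 0.4+k, diastole 0.4..1.1
  cands <- data.frame(
    onset_s = c(0.4 + 0.150,   # 150 ms after S2 -> S3
                1.1 + 1 - 0.080,  # 80 ms before next S1 (cycle 1) -> S4
                0.4 + 0.350),  # mid-diastole, outside both windows
    magnitude = c(0.1, 0.1, 0.1),
    cycle = c(0L, 1L, 0L), n_points = 5L)
  ev <- classify_events(cands, seg)
  expect_equal(ev$label, c("S3", "S4"))
  expect_equal(attr(ev, "n_rejected"), 1L)
  expect_equal(ev$latency_s, c(0.150, 0.080), tolerance = 1e-9)

  # two S3 candidates in one cycle: the stronger wins
  cands2 <- data.frame(onset_s = c(0.52, 0.58), magnitude = c(0.05, 0.2),
                       cycle = 0L, n_points = 5L)
  ev2 <- classify_events(cands2, seg)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$onset_s, 0.58)
})

test_that("iterative recognition recovers a periodic miss, removes an
           aperiodic spurious event, and is idempotent", {
  seg <- toy_seg(5)  # S2 at 0.4+k, diastole to 1.1+k
  # events in cycles 0-3 at ~160 ms latency; cycle 4 missing
  ev <- data.frame(label = "S3", onset_s = 0.4 + 0:3 + 0.160, cycle = 0:3,
                   latency_s = 0.160, magnitude = c(0.2, 0.21, 0.19, 0.2),
                   provenance = "clustered", stringsAsFactors = FALSE)
  # ridge points: cycle 4 has a sub-threshold bump at 158 ms latency
  pts <- fmp(c(0.4 + 4 + 0.158, 0.4 + 4 + 0.3), 30, c(0.15, 0.01),
             c(4L, 4L))
  out <- iterative_recognition(ev, pts, seg, latency_tol_ms = 50,
                               presence_frac = 0.5, recover_frac = 0.6)
  expect_equal(nrow(out), 5)
  rec <- out[out$provenance == "recovered", ]
  expect_equal(rec$cycle, 4L)
  expect_equal(rec$onset_s, 4.558)

  # idempotence
  out2 <- iterative_recognition(out, pts, seg, 50, 0.5, 0.6)
  expect_identical(out, out2)

  # a single spurious event with no counterparts is removed
  seg8 <- toy_seg(8)
  lone <- data.frame(label = "S4", onset_s = 1.0, cycle = 0L,
                     latency_s = 0.1, magnitude = 0.3,
                     provenance = "clustered", stringsAsFactors = FALSE)
  out3 <- iterative_recognition(lone, fmp(numeric(0), numeric(0),
                                          numeric(0), integer(0)),
                                seg8, 50, 0.5, 0.6)
  expect_equal(nrow(out3), 0)
})

test_that("full detection is deterministic and events stay inside diastoles", {
  sim <- quick_sim(21, s3 = TRUE, s4 = TRUE)
  det1 <- detect_s34(sim$record, seed = 21)
  det2 <- detect_s34(sim$record, seed = 21)
  expect_identical(write_report(det1), write_report(det2))

  cyc <- det1$cycles
  for (r in seq_len(nrow(det1$events))) {
    k <- match(det1$events$cycle[r], cyc$cycle)
    expect_true(det1$events$onset_s[r] > cyc$dia_start[k])
    expect_true(det1$events$onset_s[r] < cyc$dia_end[k])
  }
  # at most one S3 and one S4 per cycle
  tab <- table(det1$events$label, det1$events$cycle)
  expect_true(all(tab <= 1))
})
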