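# s34detect

Detection of the third and fourth heart sounds (S3, S4) in single-channel
phonocardiogram (PCG) recordings.

S3 and S4 are faint, low-frequency diastolic sounds: S3 appears in the
rapid-filling phase of early diastole shortly after the second heart sound
(S2), S4 in late diastole just before the first heart sound (S1). In
adults both are markers of ventricular dysfunction, but their low amplitude
and their cycle-to-cycle variability in both amplitude and frequency make
them hard to detect with fixed-basis time-frequency methods. This package
is for researchers and engineers working on automated auscultation who need
an adaptive, fully scriptable S3/S4 detector together with a controlled
synthetic test bench.

## Method

The pipeline runs in three stages on a record `x[n]` sampled at `fs` Hz
(8000 Hz in the intended setting):

1. **Preprocessing and segmentation.** A zero-phase Butterworth low-pass
   filter (600 Hz) removes out-of-band noise. The analytic signal
   `x + iH{x}` gives the envelope, which is normalized to `[-1, 1]` and
   transformed to Shannon energy `SE = -x² log x²`, a map that suppresses
   low-amplitude content and compresses the dominant peaks. Smoothed-SE
   peaks above 70% of the maximum, cleaned by a 50 ms minimum-spacing rule,
   mark S1 and S2; each inter-peak interval shorter than its neighbour is a
   systole, longer a diastole, and ambiguous or overlong intervals are
   re-examined at a secondary threshold to recover weak S2 peaks.
2. **Hilbert-Huang transform.** The filtered signal is decomposed by
   empirical mode decomposition (sifting with natural cubic-spline
   envelopes) into intrinsic mode functions `c_i(t)` with residual `r_k`,
   such that `x = Σ c_i + r_k` exactly. Each IMF's analytic signal yields
   instantaneous amplitude `a_i(t)` and frequency `f_i(t)`; at every sample
   the IMF with the largest amplitude contributes its `(f, a)` pair to a
   single dominant-component *ridge*.
3. **Clustering and recognition.** Ridge points from all diastolic
   intervals of the record are pooled in the frequency-magnitude plane,
   standardized, and split by k-means into three groups: normal (low
   amplitude and frequency), uncertain, and abnormal - the group with the
   fewest members. Abnormal points are projected back to time, merged into
   candidate events, and classified by their position in diastole: S3 in a
   latency window after S2, S4 in a lead window before the next S1. An
   iterative periodicity criterion then discards events that do not recur
   at a stable latency, and re-searches cycles where a periodic event is
   missing.

Detections are scored per cardiac cycle: `sensitivity = TP/(TP+FN)` and
`precision = TP/(TP+FP)`, where a cycle counts as a true positive when the
detected onset falls within 50 ms of the true event in that cycle.

The synthetic generator (`simulate_pcg()`) produces Gaussian-windowed tone
bursts on a jittered periodic grid - S1/S2 at 40/60 Hz with optional
S3/S4 at 35/30 Hz and 20%/15% of the S1 amplitude - plus white (or pink)
noise at a configurable SNR, with exact ground-truth annotations.

## Worked example

```r
library(s34detect)

sim <- simulate_pcg(synth_config(n_cycles = 8, s3_present = TRUE,
                                 s4_present = TRUE, seed = 42))
det <- detect_s34(sim$record, seed = 42)
det
#> S3/S4 detection for record 'synthetic'
#>   8 cycles segmented; S3 in 8, S4 in 8 (0 candidates rejected)
#>   S3  cycle  0  onset   0.763 s  latency   148 ms  (clustered)
#>   S4  cycle  0  onset   1.035 s  latency   100 ms  (clustered)
#>   S3  cycle  1  onset   1.571 s  latency   139 ms  (clustered)
#>   ...

summary(det)
#>  label n_cycles n_detected n_recovered median_latency_ms median_magnitude
#>     S3        8          8           0            145.27          0.14021
#>     S4        8          8           0             89.91          0.08543

score_cycles(as_annotations(det), sim$truth)
#> Cycle-level scores (tolerance 50 ms)
#>        recognized  missed  false  sensitivity  precision
#>   S3            8       0      0       100.0%     100.0%
#>   S4            8       0      0       100.0%     100.0%
```

The detection latencies (S3 ~145 ms after S2, S4 ~90 ms before the next
S1) recover the planted timing model; `plot(det)` shows the Shannon-energy
segmentation with event marks and the clustered frequency-magnitude
scatter. Real recordings enter through `read_wav()`, and a thin
command-line front end wraps the same functions:

```sh
Rscript inst/cli/pcg-s34.R simulate --seed 5 --s3 --out rec.wav --truth truth.csv
Rscript inst/cli/pcg-s34.R detect rec.wav --out report.json --annotations det.csv
Rscript inst/cli/pcg-s34.R evaluate --detected det.csv --truth truth.csv
```

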