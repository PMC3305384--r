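# Hilbert-Huang transform: empirical mode decomposition by sifting with
# natural cubic-spline envelopes, Hilbert spectral attributes per IMF, and
# the maximal-amplitude frequency ridge.

# indices and values of local extrema; strict comparisons, plateau midpoints
find_extrema <- function(x) {
  mx <- local_maxima(x)
  mn <- local_maxima(-x)
  list(max = mx, min = mn)
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' The upper envelope interpolates the local maxima and the lower envelope
#' the local minima with natural cubic splines; their pointwise average is
#' the local-mean curve subtracted at each sifting step. To tame end swings,
#' the outermost `boundary_extrema` maxima and minima are mirrored across
#' each record end before fitting.
#'
#' @param x numeric signal.
#' @param boundary_extrema number of extrema mirrored at each end.
#' @return Numeric mean curve of `length(x)`, or `NULL` when the signal has
#'   fewer than two maxima or two minima (sifting must stop).
#' @export
envelope_mean <- function(x, boundary_extrema = 2L) {
  ex <- find_extrema(x)
  if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
  n <- length(x)
  up <- mirror_knots(ex$max, x[ex$max], n, boundary_extrema)
  lo <- mirror_knots(ex$min, x[ex$min], n, boundary_extrema)
  fu <- stats::splinefun(up$i, up$v, method = "natural")
  fl <- stats::splinefun(lo$i, lo$v, method = "natural")
  s <- seq_len(n)
  (fu(s) + fl(s)) / 2
}

# reflect up to nb extrema about each record end
mirror_knots <- function(idx, val, n, nb) {
  k <- min(nb, length(idx))
  m <- length(idx)
  left_i <- 2L - idx[k:1]                 # ascending, left of sample 1
  left_v <- val[k:1]
  right_i <- 2L * n - idx[m:(m - k + 1L)] # ascending, right of sample n
  right_v <- val[m:(m - k + 1L)]
  i <- c(left_i, idx, right_i)
  v <- c(left_v, val, right_v)
  keep <- !duplicated(i)
  list(i = i[keep], v = v[keep])
}

#' Extract one IMF candidate by sifting
#'
#' Repeatedly subtracts the envelope-mean curve, `h <- h - m(h)`, until both
#' the Cauchy-type criterion `sum((h_prev - h)^2) / sum(h_prev^2) < sd_tol`
#' is met and the extrema and zero-crossing counts of `h` differ by at most
#' one (the defining property of an intrinsic mode function), or the
#' iteration cap is reached.
#'
#' @param x numeric signal admitting an envelope mean.
#' @param sd_tol stopping tolerance (default 0.2, the standard value).
#' @param max_sifts iteration cap (default 100; reaching it sets a flag).
#' @param boundary_extrema see [envelope_mean()].
#' @return List with `h` (the candidate IMF), `n_sifts`, and `capped`
#'   (TRUE when the iteration cap was hit).
#' @export
sift <- function(x, sd_tol = 0.2, max_sifts = 100L, boundary_extrema = 2L) {
  h <- x
  capped <- TRUE
  n_sifts <- 0L
  for (it in seq_len(max_sifts)) {
    m <- envelope_mean(h, boundary_extrema)
    if (is.null(m)) { capped <- FALSE; break }
    h2 <- h - m
    sd <- sum(m * m) / sum(h * h)
    h <- h2
    n_sifts <- it
    if (sd < sd_tol) {
      # accept only once the extrema and zero-crossing counts agree to
      # within one, the defining property of an intrinsic mode function
      cnt <- imf_counts(h)
      if (abs(cnt[["extrema"]] - cnt[["zero_crossings"]]) <= 1L) {
        capped <- FALSE
        break
      }
    }
  }
  if (capped) warning("sifting iteration cap reached")
  list(h = h, n_sifts = n_sifts, capped = capped)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by repeated
#' sifting: the first IMF is sifted out of the signal, subtracted to form a
#' residual, and the process repeats on the residual until it has fewer than
#' two maxima or two minima (a monotonic or near-constant remainder) or its
#' energy is negligible. The components satisfy the exact reconstruction
#' identity `sum(imfs) + residual == x` because each residual is formed by
#' subtraction.
#'
#' @param x numeric signal (length >= 16 for a meaningful decomposition).
#' @param fs sampling rate in Hz, stored for downstream spectral analysis.
#' @param sd_tol,max_sifts,max_imfs,boundary_extrema decomposition controls;
#'   see [hs_config()] (`emd` section).
#' @return An object of class `"imf_set"`: list with `imfs` (a
#'   `length(x) x k` matrix, possibly zero columns), `residual`, `fs`,
#'   `n_sifts` per IMF and `capped` flags.
#' @export
emd <- function(x, fs, sd_tol = 0.2, max_sifts = 100L, max_imfs = 12L,
                boundary_extrema = 2L) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  r <- x
  imfs <- list()
  n_sifts <- integer(0)
  capped <- logical(0)
  e0 <- sum(x * x)
  for (k in seq_len(max_imfs)) {
    ex <- find_extrema(r)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
    if (e0 > 0 && sum(r * r) < 1e-10 * e0) break
    s <- suppressWarnings(sift(r, sd_tol, max_sifts, boundary_extrema))
    imfs[[k]] <- s$h
    n_sifts <- c(n_sifts, s$n_sifts)
    capped <- c(capped, s$capped)
    r <- r - s$h
  }
  out <- structure(list(
    imfs = if (length(imfs)) do.call(cbind, imfs) else
      matrix(numeric(0), nrow = length(x), ncol = 0),
    residual = r, fs = fs, n_sifts = n_sifts, capped = capped),
    class = "imf_set")
  if (isTRUE(getOption("s34detect.check_reconstruction"))) {
    recon <- if (ncol(out$imfs)) rowSums(out$imfs) + out$residual else
      out$residual
    rel <- sqrt(sum((recon - x)^2) / max(sum(x^2), .Machine$double.xmin))
    if (rel >= 1e-8)
      stop("EMD reconstruction identity violated: relative error ", rel)
  }
  out
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("EMD: %d IMF%s + residual (%d samples at %g Hz)\n",
              ncol(x$imfs), if (ncol(x$imfs) == 1) "" else "s",
              nrow(x$imfs), x$fs))
  invisible(x)
}

# extrema and zero-crossing counts, used to check the IMF property
imf_counts <- function(h) {
  ex <- find_extrema(h)
  zc <- sum(diff(sign(h[h != 0])) != 0)
  c(extrema = length(ex$max) + length(ex$min), zero_crossings = zc)
}

#' Instantaneous amplitude, phase and frequency of an IMF
#'
#' Forms the analytic signal of the IMF; the instantaneous amplitude is its
#' modulus, the phase its unwrapped argument, and the instantaneous
#' frequency the phase derivative (central differences, one-sided at the
#' ends) divided by 2*pi. Negative frequency estimates, which arise only at
#' record boundaries or where the amplitude is negligible, are clamped to
#' zero and counted.
#'
#' @param imf numeric IMF.
#' @param fs sampling rate in Hz.
#' @return An object of class `"inst_track"`: list with `amplitude`,
#'   `phase`, `freq_hz`, `fs`, `n_clamped`.
#' @export
analytic_attrs <- function(imf, fs) {
  z <- analytic_signal(imf)
  a <- Mod(z)
  th <- signal::unwrap(Arg(z))
  n <- length(th)
  f <- numeric(n)
  if (n >= 3) f[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / 2
  if (n >= 2) { f[1] <- th[2] - th[1]; f[n] <- th[n] - th[n - 1] }
  f <- f * fs / (2 * pi)
  n_clamped <- sum(f < 0)
  f[f < 0] <- 0
  structure(list(amplitude = a, phase = th, freq_hz = f, fs = fs,
                 n_clamped = n_clamped), class = "inst_track")
}

#' Maximal-amplitude frequency ridge
#'
#' At each sample the IMF with the largest instantaneous amplitude is
#' selected and its (frequency, amplitude) pair retained: the single
#' dominant time-frequency component of the record at that instant. Ties go
#' to the lowest IMF index. With `mode = "max_frequency"` the IMF with the
#' highest instantaneous frequency is selected instead (provided for
#' comparison; the amplitude reading is the default).
#'
#' @param tracks list of `"inst_track"` objects of equal length.
#' @param mode `"max_amplitude"` (default) or `"max_frequency"`.
#' @return An object of class `"ridge_track"`: list with `freq_hz`,
#'   `magnitude`, `fs`, `imf_index`.
#' @export
max_amplitude_ridge <- function(tracks, mode = c("max_amplitude",
                                                 "max_frequency")) {
  mode <- match.arg(mode)
  if (length(tracks) == 0) stop("at least one instantaneous track required")
  lens <- vapply(tracks, function(t) length(t$amplitude), integer(1))
  if (length(unique(lens)) != 1) stop("tracks must have equal length")
  A <- vapply(tracks, `[[`, numeric(lens[1]), "amplitude")
  Fq <- vapply(tracks, `[[`, numeric(lens[1]), "freq_hz")
  A <- matrix(A, nrow = lens[1])
  Fq <- matrix(Fq, nrow = lens[1])
  sel <- max.col(if (mode == "max_amplitude") A else Fq,
                 ties.method = "first")
  n <- lens[1]
  structure(list(freq_hz = Fq[cbind(seq_len(n), sel)],
                 magnitude = A[cbind(seq_len(n), sel)],
                 fs = tracks[[1]]$fs, imf_index = sel),
            class = "ridge_track")
}

#' Hilbert spectral tracks of an IMF set
#'
#' Convenience wrapper: [analytic_attrs()] applied to every IMF.
#'
#' @param decomp an `"imf_set"`.
#' @return List of `"inst_track"` objects (possibly empty).
#' @export
hilbert_tracks <- function(decomp) {
  stopifnot(inherits(decomp, "imf_set"))
  lapply(seq_len(ncol(decomp$imfs)),
         function(i) analytic_attrs(decomp$imfs[, i], decomp$fs))
}

#' Export a frequency ridge as CSV
#'
#' Diagnostic dump of the maximal-amplitude ridge, one row per sample:
#' `sample`, `time_s`, `freq_hz`, `magnitude`.
#'
#' @param ridge a `"ridge_track"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ridge_csv <- function(ridge, path) {
  stopifnot(inherits(ridge, "ridge_track"))
  n <- length(ridge$freq_hz)
  utils::write.csv(data.frame(sample = seq_len(n),
                              time_s = (seq_len(n) - 1) / ridge$fs,
                              freq_hz = ridge$freq_hz,
                              magnitude = ridge$magnitude),
                   path, row.names = FALSE)
  invisible(path)
}
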