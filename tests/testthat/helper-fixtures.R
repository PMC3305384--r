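# Shared fixtures: small tone records and a quick synthetic generator.

tone_record <- function(f0, dur_s = 2, fs = 1000, amp = 1,
                        record_id = "tone") {
  t <- seq(0, dur_s, by = 1 / fs)
  pcg_record(amp * cos(2 * pi * f0 * t), fs, record_id)
}

# interior index range excluding a fraction at each edge
interior <- function(n, frac = 0.05) {
  k <- max(1L, floor(n * frac))
  (k + 1L):(n - k)
}

quick_sim <- function(seed, s3 = TRUE, s4 = FALSE, n_cycles = 10L, ...) {
  simulate_pcg(synth_config(n_cycles = n_cycles, s3_present = s3,
                            s4_present = s4, seed = seed, ...))
}

# natural cubic spline by direct tridiagonal solve (independent oracle)
natural_spline_eval <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  # second derivatives M_i: natural BCs M_1 = M_n = 0
  if (n > 2) {
    a <- h[-(n - 1)]
    b <- 2 * (h[-1] + h[-(n - 1)])
    cc <- h[-1]
    d <- 6 * diff(diff(yk) / h)
    # Thomas algorithm
    m <- length(b)
    for (i in seq_len(m - 1)) {
      w <- a[i + 1] / b[i]
      b[i + 1] <- b[i + 1] - w * cc[i]
      d[i + 1] <- d[i + 1] - w * d[i]
    }
    M_in <- numeric(m)
    M_in[m] <- d[m] / b[m]
    for (i in (m - 1):1) M_in[i] <- (d[i] - cc[i] * M_in[i + 1]) / b[i]
    M <- c(0, M_in, 0)
  } else M <- c(0, 0)
  vapply(xout, function(x) {
    i <- findInterval(x, xk, all.inside = TRUE)
    dx <- xk[i + 1] - xk[i]
    A <- (xk[i + 1] - x) / dx
    B <- (x - xk[i]) / dx
    A * yk[i] + B * yk[i + 1] +
      ((A^3 - A) * M[i] + (B^3 - B) * M[i + 1]) * dx^2 / 6
  }, numeric(1))
}
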