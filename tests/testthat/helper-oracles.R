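# Independent brute-force oracles, kept deliberately naive: straight loops
# over the stated definitions, sharing no code with the implementation.

# editing rule: an interval is retained iff both bounding beats are N;
# returns the retained interval list and the original index of each
oracle_edit <- function(times, labels) {
  keep_rr <- numeric(0)
  keep_i <- integer(0)
  for (i in seq_len(length(times) - 1L)) {
    if (labels[i] == "N" && labels[i + 1L] == "N") {
      keep_rr <- c(keep_rr, times[i + 1L] - times[i])
      keep_i <- c(keep_i, i)
    }
  }
  list(rr = keep_rr, idx = keep_i)
}

# one filtering pass over every window of five mutually contiguous
# intervals, comparing and replacing with original (pre-pass) values
oracle_filter <- function(rr, idx, threshold = 0.20) {
  out <- rr
  n <- length(rr)
  if (n >= 5) {
    for (c in 3:(n - 2L)) {
      window <- (c - 2L):(c + 2L)
      if (any(diff(idx[window]) != 1L)) next  # spans an editing gap
      avg <- mean(rr[window[-3]])
      if (rr[c] > 1.2 * avg || rr[c] < 0.8 * avg) out[c] <- avg
    }
  }
  out
}

oracle_pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# direct-from-definition time-domain statistics on a fully contiguous series
oracle_time_domain <- function(rr, x_ms = 50) {
  d <- diff(rr)
  list(sdnn = oracle_pop_sd(rr),
       rmssd = sqrt(sum(d^2) / length(d)),
       nnx = sum(abs(d) > x_ms),
       pnnx = sum(abs(d) > x_ms) / length(d),
       mean_hr = mean(60000 / rr),
       sd_hr = oracle_pop_sd(60000 / rr))
}

oracle_poincare <- function(rr) {
  x1 <- rr[-length(rr)]
  x2 <- rr[-1]
  list(sd1 = oracle_pop_sd((x2 - x1) / sqrt(2)),
       sd2 = oracle_pop_sd((x2 + x1) / sqrt(2)))
}

# O(n^2) double-loop sample entropy match counts
oracle_sampen_counts <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

# random labeled beat series with ectopy and occasional interval spikes
random_beat_series <- function(n, p_ect = 0.15, p_spike = 0.1) {
  rr <- round(stats::runif(n - 1, 700, 1300))
  spikes <- stats::runif(n - 1) < p_spike
  rr[spikes] <- round(rr[spikes] * sample(c(0.4, 1.8), sum(spikes), replace = TRUE))
  labels <- sample(c("N", "V", "S", "U"), n, replace = TRUE,
                   prob = c(1 - p_ect, p_ect / 2, p_ect / 4, p_ect / 4))
  beat_series(cumsum(c(0, rr)), labels)
}

# contiguous nn_series from bare intervals
make_nn <- function(rr) nn_series(rr)
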