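# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Exhaustive sample-entropy template counting: plain nested loops over all
# unordered template pairs (i < j) among the n - m templates that have an
# (m+1)-length continuation; Chebyshev distance, self-matches excluded.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  np <- n - m
  A <- 0L; B <- 0L
  if (np < 2) return(list(A = 0L, B = 0L))
  for (i in 1:(np - 1)) {
    for (j in (i + 1):np) {
      dm <- 0
      for (k in 0:(m - 1)) {
        dk <- abs(x[i + k] - x[j + k])
        if (dk > dm) dm <- dk
      }
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B)
}

# Direct DFT power by explicit summation (no FFT): |X_k|^2 for k = 0..n/2.
dft_power_oracle <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  vapply(0:(n %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * j / n)))^2
  }, numeric(1))
}

# A bounded-noise stationary tachogram that the 2-SD ectopic rule never
# flags: a single sinusoid (max deviation = sqrt(2) * SD) plus small uniform
# noise.
clean_tachogram <- function(n, mean_rr = 100, amp = 5, freq = 0.05,
                            unif_half_width = 0.5, seed = 1) {
  set.seed(seed)
  i <- seq_len(n) - 1
  mean_rr + amp * sin(2 * pi * freq * i) +
    stats::runif(n, -unif_half_width, unif_half_width)
}
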