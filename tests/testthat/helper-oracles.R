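# Independent oracles used across test files. None of these call the package
# code paths they are used to check.

# Brute-force OLS by nested grid refinement over (slope, intercept); no lm().
grid_search_ols <- function(x, y, iters = 40) {
  s_lo <- -100; s_hi <- 100; b_lo <- -100; b_hi <- 100
  for (i in seq_len(iters)) {
    ss <- seq(s_lo, s_hi, length.out = 21)
    bs <- seq(b_lo, b_hi, length.out = 21)
    sse <- outer(ss, bs, Vectorize(function(s, b) sum((y - s * x - b)^2)))
    k <- arrayInd(which.min(sse), dim(sse))
    s_best <- ss[k[1]]; b_best <- bs[k[2]]
    s_half <- (s_hi - s_lo) / 10; b_half <- (b_hi - b_lo) / 10
    s_lo <- s_best - s_half; s_hi <- s_best + s_half
    b_lo <- b_best - b_half; b_hi <- b_best + b_half
  }
  c(slope = s_best, intercept = b_best)
}

# Closed-form area delivered by the chord-baseline + trapezoid protocol for a
# single Gaussian band integrated over [lo, hi] on a continuous axis:
# truncated Gaussian mass minus the chord through the endpoint ordinates.
chord_protocol_area <- function(center, width, strength, lo, hi) {
  mass <- strength * width * sqrt(2 * pi) *
    (pnorm((hi - center) / width) - pnorm((lo - center) / width))
  g <- function(v) strength * exp(-(v - center)^2 / (2 * width^2))
  chord <- (g(lo) + g(hi)) / 2 * (hi - lo)
  mass - chord
}

# A clean (noise- and background-free) simulation configuration.
clean_cfg <- function(...) {
  sim_config(noise_sd = 0, baseline_offset = 0, baseline_slope = 0, ...)
}
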