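# Independent oracles used by the tests.  These deliberately do not
# reuse the package's integration or clustering code paths.

# Forward-Euler integration of the two-variable quadratic neuron at a
# very small step: reference for spike counts of the RK4 engine.
euler_spike_count <- function(params, I, duration, dt = 5e-4) {
  v <- params$v_r
  u <- 0
  n_steps <- round(duration / dt)
  count <- 0L
  for (s in seq_len(n_steps)) {
    dv <- (params$k * (v - params$v_r) * (v - params$v_t) - u + I) / params$C
    du <- params$a * (params$b * (v - params$v_r) - u)
    v <- v + dt * dv
    u <- u + dt * du
    if (v >= params$v_peak) {
      v <- params$c
      u <- u + params$d
      count <- count + 1L
    }
  }
  count
}

# Exhaustive best 2-partition by total within-cluster sum of squares
# (for small n): reference for the top split of bisecting k-means.
brute_force_best_bipartition <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 16)
  wss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(sweep(X[idx, , drop = FALSE], 2,
              colMeans(X[idx, , drop = FALSE]))^2)
  }
  best <- NULL
  best_val <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    a <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    b <- setdiff(seq_len(n), a)
    val <- wss(a) + wss(b)
    if (val < best_val) {
      best_val <- val
      best <- a
    }
  }
  best
}

# Default-calibration config with small overrides for fast tests.
test_config <- function(...) {
  network_config(...)
}
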