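# Independent, deliberately non-vectorized reference implementation of the
# network dynamics (scalar loops over neurons and synapses). Used to verify
# the vectorized simulator to machine precision.
oracle_simulate <- function(schedule, params, mask = NULL) {
  N <- params$N
  if (is.null(mask)) mask <- matrix(1, N, N)
  r <- numeric(N)
  W <- matrix(0, N, N)
  rates_trace <- matrix(0, schedule$n_steps, N)
  for (t in seq_len(schedule$n_steps)) {
    d <- schedule$day_of_step[t]
    eps <- schedule$epsilon_by_day[d, ]
    I <- params$I0
    for (i in 1:N) I <- I + params$I1 * r[i] + params$I2 * r[i]^2
    r_new <- numeric(N)
    for (i in 1:N) {
      rec <- 0
      for (j in 1:N) rec <- rec + W[i, j] * r[j]
      x <- schedule$drive[t] + rec - I
      f <- if (params$excitability_mode == "threshold") {
        max(x + eps[i], 0)
      } else {
        eps[i] * max(x, 0)
      }
      r_new[i] <- r[i] + params$dt / params$tau_r * (f - r[i])
    }
    r <- r_new
    W_new <- W
    for (i in 1:N) for (j in 1:N) {
      w <- W[i, j] + params$dt *
        (r[i] * r[j] / params$tau_W - W[i, j] / params$tau_decay)
      W_new[i, j] <- min(max(w, 0), params$c) * mask[i, j]
    }
    W <- W_new
    rates_trace[t, ] <- r
  }
  list(rates = rates_trace, W = W)
}

# small, fast parameter sets for unit tests
tiny_network <- function(...) network_params(N = 20, ...)
tiny_protocol <- function(...) {
  protocol_params(n_days = 4, Nrep = 2, T_rep = 50, IR = 20, ID = 100,
                  boost_blocks = default_boost_blocks(4, width = 4, N = 20),
                  ...)
}

# 4 x n pattern rows with an exactly prescribed correlation matrix
patterns_with_correlation <- function(R, n = 40, seed = 1) {
  k <- nrow(R)
  set.seed(seed)
  X <- matrix(rnorm(k * n), k, n)
  M <- qr.Q(qr(cbind(1, t(X))))[, 2:(k + 1)]  # orthonormal, mean-zero cols
  B <- t(M) * sqrt(n - 1)                     # rows: mean 0, sd 1, uncorrelated
  t(chol(R)) %*% B
}
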