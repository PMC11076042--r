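#' Global inhibition current
#'
#' The network-wide inhibitory current depends on the population activity:
#' `I = I0 + I1 * sum(r) + I2 * sum(r^2)`. With non-negative rates it is
#' always at least `I0`.
#'
#' @param rates Non-negative firing-rate vector.
#' @param params A [network_params()] object.
#' @return Scalar inhibition current.
#' @export
#' @examples
#' global_inhibition(rep(0, 50), network_params())  # I0 = 12
global_inhibition <- function(rates, params) {
  params$I0 + params$I1 * sum(rates) + params$I2 * sum(rates^2)
}

#' One Euler step of the rate dynamics
#'
#' Advances the firing rates by one step of
#' `tau_r * dr/dt + r = f`, where in threshold mode
#' `f_i = ReLU(drive_i + sum_j W_ij r_j - I + epsilon_i)` and in slope mode
#' `f_i = epsilon_i * ReLU(drive_i + sum_j W_ij r_j - I)`. With
#' `dt <= tau_r` the update keeps rates non-negative.
#'
#' @param rates Current rate vector.
#' @param drive Per-neuron external drive (scalar recycled).
#' @param epsilon Per-neuron excitability vector.
#' @param W Recurrent weight matrix (N x N).
#' @param I Scalar inhibition current (see [global_inhibition()]).
#' @param params A [network_params()] object.
#' @return Updated rate vector.
#' @export
rate_step <- function(rates, drive, epsilon, W, I, params) {
  if (!all(is.finite(rates))) stop("non-finite rates passed to rate_step")
  input <- drive + as.vector(W %*% rates) - I
  f <- if (params$excitability_mode == "threshold") {
    pmax(input + epsilon, 0)
  } else {
    epsilon * pmax(input, 0)
  }
  rates + (params$dt / params$tau_r) * (f - rates)
}

#' One Euler step of the Hebbian recurrent plasticity
#'
#' Advances every recurrent weight by
#' `dW_ij/dt = r_i * r_j / tau_W - W_ij / tau_decay`, then clips elementwise
#' to the hard bound `[0, c]`, then applies the structural sparsity mask
#' (a masked synapse stays exactly zero).
#'
#' @param rates Rate vector (length N).
#' @param W Weight matrix (N x N).
#' @param mask Binary N x N matrix; 1 = synapse present. Use
#'   `matrix(1, N, N)` for the dense network.
#' @param params A [network_params()] object.
#' @return Updated weight matrix.
#' @export
hebbian_weight_step <- function(rates, W, mask, params) {
  N <- length(rates)
  if (!all(dim(W) == c(N, N)) || !all(dim(mask) == c(N, N)))
    stop("W and mask must be N x N with N = length(rates)")
  W <- W + params$dt * (tcrossprod(rates) / params$tau_W - W / params$tau_decay)
  W <- pmin(pmax(W, 0), params$c)
  W * mask
}

#' Active neurons
#'
#' Indices of neurons whose rate strictly exceeds the active threshold
#' `theta`; boundary ties (`r == theta`) are not active.
#'
#' @param rates Rate vector.
#' @param theta Active threshold.
#' @return Integer vector of 1-based indices.
#' @export
active_neurons <- function(rates, theta) {
  if (theta < 0) stop("theta must be >= 0")
  which(rates > theta)
}

#' Draw the structural sparsity mask
#'
#' Each directed synapse is independently present with probability
#' `1 - sparsity`. The dense network gets an all-ones mask.
#'
#' @param params A [network_params()] object.
#' @return Binary N x N matrix.
#' @export
sample_mask <- function(params) {
  N <- params$N
  if (params$sparsity <= 0) return(matrix(1, N, N))
  matrix(stats::rbinom(N * N, 1L, 1 - params$sparsity), N, N)
}

#' Simulate the recurrent network over a stimulation schedule
#'
#' Runs the full Euler loop. Each step: (1) the global inhibition is
#' computed from the current rates; (2) the rates advance one step of the
#' leaky-ReLU dynamics using that day's excitability; (3) the recurrent
#' weights advance one Hebbian step using the new rates, are clipped to
#' `[0, c]` and masked. The network starts naive: `r(0) = 0`, `W(0) = 0`.
#' Optionally a read-out neuron (or two, in two-context mode) is integrated
#' concurrently with the same step.
#'
#' The returned record holds the full rate traces, the activity pattern
#' `V_d` (rates at the final step of each day's last repetition; one per
#' context in two-context mode), per-day weight-matrix snapshots taken at
#' the same step, and, when a read-out is attached, its weight/output
#' traces together with shuffled-weight control outputs drawn at each
#' pattern step.
#'
#' @param schedule A `stim_schedule` from [build_schedule()] or
#'   [build_two_context_schedule()].
#' @param params A [network_params()] object.
#' @param mask Binary N x N structural mask; defaults to dense. Pass the
#'   mask returned in a previous record to replay with identical structure.
#' @param readout Optional [readout_params()]; `NULL` disables the read-out.
#' @param record_rates If `FALSE`, the full rate trace is not stored
#'   (patterns and snapshots still are).
#' @return A `simulation_record` list: `rates` (T x N), `patterns`
#'   (n_days x N, or an `A`/`B` list), `W_snapshots` (list of N x N per
#'   day), `epsilon` (n_days x N), `active` (per-day active sets),
#'   `readout` (traces, shuffles, per-day weight snapshots) and the inputs
#'   needed to reproduce the run.
#' @export
simulate_network <- function(schedule, params, mask = NULL, readout = NULL,
                             record_rates = TRUE) {
  stopifnot(inherits(schedule, "stim_schedule"))
  N <- params$N
  if (ncol(schedule$epsilon_by_day) != N)
    stop("schedule and params disagree on N")
  if (is.null(mask)) mask <- matrix(1, N, N)
  if (!all(dim(mask) == c(N, N))) stop("mask must be N x N")

  n_steps <- schedule$n_steps
  r <- numeric(N)
  W <- matrix(0, N, N) * mask   # W(0) = 0; masked entries stay 0 throughout
  dt <- params$dt

  two_ctx <- isTRUE(schedule$two_context)
  n_days <- nrow(schedule$epsilon_by_day)
  pattern_steps <- schedule$pattern_steps
  n_ctx <- ncol(pattern_steps)

  rates_trace <- if (record_rates) matrix(0, n_steps, N) else NULL
  patterns <- array(0, c(n_days, n_ctx, N))
  W_snapshots <- vector("list", n_days)
  active <- vector("list", n_days)

  ro <- NULL
  if (!is.null(readout)) {
    K <- readout$n_outputs
    if (two_ctx && K != 2L)
      warning("two-context schedules are normally paired with n_outputs = 2")
    ro <- list(params = readout,
               W_out = matrix(readout$w0, N, K), # tiny seed weight; h(0) ~ 1
               y_trace = matrix(0, n_steps, K),
               h_trace = matrix(0, n_steps, K),
               W_out_snapshots = array(0, c(n_days, n_ctx, N, K)),
               y_at_patterns = array(0, c(n_days, n_ctx, K)),
               y_shuffle = array(0, c(n_days, n_ctx, readout$n_shuffle, K)))
  }

  # per-neuron drive indicator for context targeting
  ctx_members <- if (two_ctx) {
    list(schedule$context == 1L, schedule$context == 2L)
  } else NULL

  day_prev <- 0L
  eps <- NULL
  for (t in seq_len(n_steps)) {
    d <- schedule$day_of_step[t]
    if (d != day_prev) {
      eps <- schedule$epsilon_by_day[d, ]
      day_prev <- d
    }
    drive <- if (schedule$drive[t] > 0) {
      if (two_ctx) schedule$drive[t] * ctx_members[[schedule$target[t]]]
      else schedule$drive[t]
    } else 0

    I <- global_inhibition(r, params)
    r <- rate_step(r, drive, eps, W, I, params)
    if (!all(is.finite(r)))
      stop(sprintf("non-finite rates at step %d (inhibition explosion?)", t))
    W <- hebbian_weight_step(r, W, mask, params)

    if (!is.null(ro)) {
      beta <- if (!is.null(schedule$beta))
        readout$beta_amplitude * schedule$beta[t, seq_len(ncol(ro$W_out))]
      else rep(0, ncol(ro$W_out))
      st <- readout_step(list(W_out = ro$W_out), r, readout, beta,
                         dt = params$dt)
      ro$W_out <- st$W_out
      ro$y_trace[t, ] <- st$y
      ro$h_trace[t, ] <- st$h
    }

    if (record_rates) rates_trace[t, ] <- r

    hit <- which(pattern_steps == t, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      for (k in seq_len(nrow(hit))) {
        dd <- hit[k, 1]; cc <- hit[k, 2]
        patterns[dd, cc, ] <- r
        if (cc == n_ctx) {
          W_snapshots[[dd]] <- W
          active[[dd]] <- active_neurons(r, params$theta)
        }
        if (!is.null(ro)) {
          ro$W_out_snapshots[dd, cc, , ] <- ro$W_out
          ro$y_at_patterns[dd, cc, ] <- ro$y_trace[t, ]
          for (s in seq_len(readout$n_shuffle)) {
            for (kk in seq_len(ncol(ro$W_out))) {
              ws <- shuffle_output_weights(ro$W_out[, kk])
              ro$y_shuffle[dd, cc, s, kk] <- sum(ws * r)
            }
          }
        }
      }
    }
  }

  pat_out <- if (two_ctx) {
    list(A = matrix(patterns[, 1, ], n_days, N),
         B = matrix(patterns[, 2, ], n_days, N))
  } else {
    matrix(patterns[, 1, ], n_days, N)
  }

  rec <- list(rates = rates_trace, patterns = pat_out,
              W_snapshots = W_snapshots, active = active,
              epsilon = schedule$epsilon_by_day, mask = mask,
              schedule = schedule, params = params,
              readout = if (is.null(ro)) NULL else
                ro[c("W_out", "y_trace", "h_trace", "W_out_snapshots",
                     "y_at_patterns", "y_shuffle")],
              final_W = W, final_rates = r)
  class(rec) <- "simulation_record"
  rec
}

#' @export
print.simulation_record <- function(x, ...) {
  n_days <- nrow(x$epsilon)
  cat("<simulation_record>\n")
  cat(sprintf("  %d steps, N = %d, %d days%s%s\n", x$schedule$n_steps,
              x$params$N, n_days,
              if (isTRUE(x$schedule$two_context)) ", two contexts" else "",
              if (is.null(x$readout)) "" else ", with read-out"))
  for (d in seq_len(n_days))
    cat(sprintf("  day %d: %d active neurons\n", d, length(x$active[[d]])))
  invisible(x)
}

#' Run a fully seeded simulation
#'
#' Convenience wrapper fixing the whole RNG pipeline: seeds the session,
#' draws the structural mask, builds the schedule (which draws the per-day
#' excitability and, in two-context mode, the context halves), and runs
#' [simulate_network()]. Optionally also runs the baseline-excitability
#' replay (same mask, same baseline draws, boost removed), which supplies
#' the reference patterns for the day decoder. The same `(protocol,
#' network, seed)` always yields a bit-identical record.
#'
#' @inheritParams sample_excitability
#' @param seed Integer seed.
#' @param readout Optional [readout_params()].
#' @param with_baseline If `TRUE`, also run the baseline replay and attach
#'   it as `$baseline` (a second `simulation_record`).
#' @param record_rates Passed to [simulate_network()].
#' @return A `simulation_record`, with `$seed` set and optionally
#'   `$baseline`.
#' @export
run_simulation <- function(protocol, network, seed, readout = NULL,
                           with_baseline = FALSE, record_rates = TRUE) {
  set.seed(seed)
  mask <- sample_mask(network)
  schedule <- build_schedule(protocol, network)
  rec <- simulate_network(schedule, network, mask = mask, readout = readout,
                          record_rates = record_rates)
  rec$seed <- seed
  if (with_baseline) {
    rec$baseline <- simulate_network(baseline_replay(schedule), network,
                                     mask = mask, record_rates = FALSE)
  }
  rec
}
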