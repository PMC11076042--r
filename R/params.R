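#' Network parameters
#'
#' Constructs the constant set governing the recurrent rate network: neuron
#' count, time constants of rates and recurrent plasticity, the global
#' inhibition coefficients, stimulation drive amplitude, excitability-boost
#' amplitude, the active threshold, the hard weight bound, and structural
#' flags (excitability mode, synaptic sparsity).
#'
#' All quantities are in arbitrary units; one Euler step (`dt`) is one time
#' unit. Defaults reproduce the reference single-ensemble simulation; use
#' [variant_params()] for the slope-excitability, two-context and sparse
#' parameter columns.
#'
#' @param N Number of neurons.
#' @param tau_W Learning time constant of the recurrent weights.
#' @param tau_decay Decay time constant of the recurrent weights.
#' @param tau_r Decay time constant of the firing rates.
#' @param I0,I1,I2 Global inhibition coefficients: the inhibitory current is
#'   `I0 + I1 * sum(r) + I2 * sum(r^2)`.
#' @param delta Input current applied during stimulation repetitions.
#' @param E Amplitude of the excitability boost given to that day's block.
#' @param theta Active threshold: a neuron is "active" when `r > theta`.
#' @param c Hard upper bound on recurrent weights (lower bound is 0).
#' @param dt Euler integration step. Must satisfy `dt <= tau_r` so that rates
#'   stay non-negative.
#' @param excitability_mode `"threshold"`: excitability shifts the threshold
#'   of the ReLU input-output function. `"slope"`: excitability multiplies
#'   its slope.
#' @param sparsity Fraction of recurrent synapses structurally absent
#'   (masked to zero). 0 for the dense all-to-all network.
#'
#' @return An object of class `network_params` (a validated list).
#' @seealso [variant_params()], [protocol_params()], [simulate_network()]
#' @export
#' @examples
#' p <- network_params()
#' p$E
network_params <- function(N = 50, tau_W = 800, tau_decay = 1000, tau_r = 20,
                           I0 = 12, I1 = 0.5, I2 = 0.05,
                           delta = 15, E = 1.5, theta = 5, c = 1, dt = 1,
                           excitability_mode = c("threshold", "slope"),
                           sparsity = 0) {
  excitability_mode <- match.arg(excitability_mode)
  p <- list(N = as.integer(N), tau_W = tau_W, tau_decay = tau_decay,
            tau_r = tau_r, I0 = I0, I1 = I1, I2 = I2, delta = delta, E = E,
            theta = theta, c = c, dt = dt,
            excitability_mode = excitability_mode, sparsity = sparsity)
  class(p) <- "network_params"
  validate_network_params(p)
  p
}

validate_network_params <- function(p) {
  stopifnot(is.list(p))
  if (p$N < 2) stop("N must be >= 2")
  for (nm in c("tau_W", "tau_decay", "tau_r", "dt")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a positive number", nm))
  }
  if (p$c <= 0) stop("weight cap 'c' must be positive")
  if (p$sparsity < 0 || p$sparsity >= 1)
    stop("'sparsity' must lie in [0, 1)")
  if (p$dt > p$tau_r)
    stop("dt must not exceed tau_r (Euler step would make rates negative)")
  if (p$theta < 0) stop("'theta' must be >= 0")
  if (p$delta < 0) stop("'delta' must be >= 0")
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  cat(sprintf("  N = %d, mode = %s, sparsity = %g\n",
              x$N, x$excitability_mode, x$sparsity))
  cat(sprintf("  tau_W = %g, tau_decay = %g, tau_r = %g, dt = %g\n",
              x$tau_W, x$tau_decay, x$tau_r, x$dt))
  cat(sprintf("  I0 = %g, I1 = %g, I2 = %g\n", x$I0, x$I1, x$I2))
  cat(sprintf("  delta = %g, E = %g, theta = %g, c = %g\n",
              x$delta, x$E, x$theta, x$c))
  invisible(x)
}

#' Stimulation-protocol parameters
#'
#' Describes the multi-day stimulation protocol: each "day" consists of an
#' inter-day delay of `ID` silent steps followed by `Nrep` repetitions of
#' `T_rep` driven steps, each repetition trailed by an `IR`-step delay. On
#' day `d`, the neurons of `boost_blocks[[d]]` receive an excitability boost
#' of amplitude `E` on top of their baseline draw `|Normal(epsilon_mean,
#' epsilon_sd)|`, resampled independently each day.
#'
#' @param n_days Number of stimulation days.
#' @param Nrep Stimulation repetitions per day.
#' @param T_rep Duration (steps) of each repetition.
#' @param IR Inter-repetition delay (steps).
#' @param ID Inter-day delay (steps) preceding each day's stimulation.
#' @param boost_blocks List of length `n_days`: integer vectors of 1-based
#'   neuron indices receiving the `+E` boost on each day. The default rotates
#'   through neurons 11:20, 21:30, 31:40, 41:50.
#' @param epsilon_mean,epsilon_sd Parameters of the baseline excitability
#'   distribution `|Normal(epsilon_mean, epsilon_sd)|`. The slope-mode
#'   variant uses mean 0.4, sd 0.2.
#' @param two_context If `TRUE`, each day a random half of the neurons
#'   (context A) is stimulated first and the other half (context B) second;
#'   the halves are drawn once per simulation.
#'
#' @return An object of class `protocol_params`.
#' @seealso [build_schedule()], [variant_params()]
#' @export
protocol_params <- function(n_days = 4, Nrep = 10, T_rep = 100, IR = 100,
                            ID = 1000,
                            boost_blocks = default_boost_blocks(n_days),
                            epsilon_mean = 0, epsilon_sd = 1,
                            two_context = FALSE) {
  p <- list(n_days = as.integer(n_days), Nrep = as.integer(Nrep),
            T_rep = as.integer(T_rep), IR = as.integer(IR),
            ID = as.integer(ID), boost_blocks = boost_blocks,
            epsilon_mean = epsilon_mean, epsilon_sd = epsilon_sd,
            two_context = isTRUE(two_context))
  class(p) <- "protocol_params"
  if (p$n_days < 1) stop("n_days must be >= 1")
  if (any(c(p$Nrep, p$T_rep) < 1) || any(c(p$IR, p$ID) < 0))
    stop("durations must be positive (delays non-negative)")
  if (length(p$boost_blocks) != p$n_days)
    stop("boost_blocks must have one index vector per day")
  if (p$epsilon_sd < 0) stop("epsilon_sd must be >= 0")
  p
}

#' Default rotating boost blocks
#'
#' Day `d` boosts the block of `width` neurons starting (0-based) at
#' `d * width`, wrapped modulo `N`: with the defaults this is neurons 11:20,
#' 21:30, 31:40, 41:50 on days 1-4.
#'
#' @param n_days Number of days.
#' @param width Block width (neurons per day).
#' @param N Neuron count (used for wrap-around when blocks overrun).
#' @return List of integer index vectors (1-based).
#' @export
default_boost_blocks <- function(n_days = 4, width = 10, N = 50) {
  lapply(seq_len(n_days), function(d) {
    idx0 <- (d * width):((d + 1L) * width - 1L) %% N
    sort(idx0) + 1L
  })
}

#' @export
print.protocol_params <- function(x, ...) {
  cat("<protocol_params>\n")
  cat(sprintf("  %d days; Nrep = %d x (T = %d, IR = %d); ID = %d%s\n",
              x$n_days, x$Nrep, x$T_rep, x$IR, x$ID,
              if (x$two_context) "; two contexts" else ""))
  cat(sprintf("  baseline epsilon ~ |N(%g, %g)|\n",
              x$epsilon_mean, x$epsilon_sd))
  invisible(x)
}

#' Read-out neuron parameters
#'
#' The read-out unit is a linear neuron `y = sum_i Wout_i r_i + beta` whose
#' weights follow a Hebbian rule gated by a homeostatic factor
#' `h = max(0, 1 - sum(Wout))`, so learning stops once the summed weight
#' reaches 1 and thereafter weights only decay.
#'
#' @param tau_out_plus Learning time constant of the output weights.
#' @param tau_out_minus Decay time constant of the output weights.
#' @param beta_amplitude Supervision current added to an output neuron while
#'   its assigned context is being stimulated on day 1 (two-context mode).
#' @param n_outputs Number of read-out neurons (1, or 2 for the two-context
#'   experiment).
#' @param n_shuffle Number of weight shuffles drawn at each recorded time
#'   point for the shuffled-weight control and the quality index.
#' @param w0 Initial output weight per synapse. The Hebbian update is
#'   proportional to the output rate itself, so an exactly-zero start can
#'   never learn; a tiny uniform seed weight (default `1e-3`, giving
#'   `h(0) = 0.95` for 50 neurons, i.e. effectively "1 before learning")
#'   bootstraps it.
#' @return An object of class `readout_params`.
#' @export
readout_params <- function(tau_out_plus = 200, tau_out_minus = 1000,
                           beta_amplitude = 0.1, n_outputs = 1,
                           n_shuffle = 10, w0 = 1e-3) {
  p <- list(tau_out_plus = tau_out_plus, tau_out_minus = tau_out_minus,
            beta_amplitude = beta_amplitude,
            n_outputs = as.integer(n_outputs),
            n_shuffle = as.integer(n_shuffle), w0 = w0)
  if (w0 < 0) stop("w0 must be >= 0")
  class(p) <- "readout_params"
  if (tau_out_plus <= 0 || tau_out_minus <= 0)
    stop("read-out time constants must be positive")
  if (!p$n_outputs %in% c(1L, 2L)) stop("n_outputs must be 1 or 2")
  p
}

#' Parameter presets for the published simulation variants
#'
#' Returns the `network_params`/`protocol_params` pair for one of the named
#' simulation variants: `"default"` (single drifting ensemble,
#' threshold-mode excitability), `"slope"` (excitability rescales the slope
#' of the activation function; tau_W = 700, tau_decay = 800, I0 = 4,
#' I1 = 0.7, E = 0.5, theta = 1, c = 0.5, baseline epsilon ~ |N(0.4, 0.2)|),
#' `"two_context"` (two interleaved ensembles; tau_decay = 4000, I0 = 8,
#' I1 = 0.8, delta = 12) and `"sparse"` (50% of synapses masked; I0 = 7,
#' I1 = 0.8, delta = 20).
#'
#' @param variant One of `"default"`, `"slope"`, `"two_context"`, `"sparse"`.
#' @param ... Overrides forwarded to [network_params()].
#' @return List with elements `network` and `protocol`.
#' @export
variant_params <- function(variant = c("default", "slope", "two_context",
                                       "sparse"), ...) {
  variant <- match.arg(variant)
  net <- switch(variant,
    default = network_params(...),
    slope = network_params(tau_W = 700, tau_decay = 800, I0 = 4, I1 = 0.7,
                           E = 0.5, theta = 1, c = 0.5,
                           excitability_mode = "slope", ...),
    two_context = network_params(tau_decay = 4000, I0 = 8, I1 = 0.8,
                                 delta = 12, ...),
    sparse = network_params(I0 = 7, I1 = 0.8, delta = 20, sparsity = 0.5,
                            ...)
  )
  proto <- switch(variant,
    slope = protocol_params(epsilon_mean = 0.4, epsilon_sd = 0.2),
    two_context = protocol_params(two_context = TRUE),
    protocol_params()
  )
  list(network = net, protocol = proto)
}
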