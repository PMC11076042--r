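#' Sample one day's excitability vector
#'
#' Baseline excitability of every neuron is drawn as the absolute value of a
#' normal variate, `|Normal(epsilon_mean, epsilon_sd)|`, independently each
#' day; the neurons in that day's boost block additionally receive `+E`.
#' Draws use the current RNG state, so seed the session (or use
#' [run_simulation()]) for reproducibility.
#'
#' @param day Day index (1-based).
#' @param protocol A [protocol_params()] object.
#' @param network A [network_params()] object (supplies `N` and `E`).
#' @return List with `epsilon` (boosted vector, length `N`) and `baseline`
#'   (the same draws without the boost).
#' @export
sample_excitability <- function(day, protocol, network) {
  if (day < 1 || day > protocol$n_days) stop("'day' out of range")
  base <- abs(stats::rnorm(network$N, protocol$epsilon_mean,
                           protocol$epsilon_sd))
  eps <- base
  block <- protocol$boost_blocks[[day]]
  if (length(block) && (min(block) < 1 || max(block) > network$N))
    stop("boost block indices must lie within 1..N")
  eps[block] <- eps[block] + network$E
  list(epsilon = eps, baseline = base)
}

new_schedule <- function(n_steps, drive, target, day_of_step, day_windows,
                         pattern_steps, epsilon_by_day, epsilon_baseline,
                         context = NULL, beta = NULL, delta = NULL,
                         two_context = FALSE) {
  s <- list(n_steps = as.integer(n_steps), drive = drive,
            target = as.integer(target), day_of_step = as.integer(day_of_step),
            day_windows = day_windows, pattern_steps = pattern_steps,
            epsilon_by_day = epsilon_by_day,
            epsilon_baseline = epsilon_baseline,
            context = context, beta = beta, delta = delta,
            two_context = two_context)
  class(s) <- "stim_schedule"
  s
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("<stim_schedule>\n")
  cat(sprintf("  %d steps, %d days%s\n", x$n_steps, nrow(x$epsilon_by_day),
              if (x$two_context) ", two contexts" else ""))
  cat(sprintf("  driven steps: %d (drive = %g)\n", sum(x$drive > 0),
              x$delta))
  invisible(x)
}

# Place Nrep repetitions of T_rep driven steps (spaced by IR) starting at
# 0-based offset `start`; returns 1-based step indices of driven steps and
# the 1-based index of the final step of the last repetition.
rep_block_steps <- function(start, protocol) {
  T_rep <- protocol$T_rep; IR <- protocol$IR; Nrep <- protocol$Nrep
  driven <- integer(0)
  for (k in seq_len(Nrep)) {
    s0 <- start + (k - 1L) * (T_rep + IR)   # 0-based window start
    driven <- c(driven, (s0 + 1L):(s0 + T_rep))
  }
  last <- start + (Nrep - 1L) * (T_rep + IR) + T_rep
  list(driven = driven, pattern_step = last)
}

#' Build the multi-day stimulation schedule
#'
#' Lays out the full Euler-time schedule: for each day, `ID` silent delay
#' steps, then `Nrep` repetitions of `T_rep` steps at drive `delta` each
#' followed by `IR` silent steps. Under the defaults day-1 stimulation
#' occupies steps 1000-3000 and the whole 4-day protocol spans 12000 steps.
#' Per-day excitability (boosted and baseline) is drawn here via
#' [sample_excitability()] from the current RNG state.
#'
#' @inheritParams sample_excitability
#' @return A `stim_schedule` object carrying the per-step drive, per-day
#'   windows and pattern-extraction steps, and the per-day excitability
#'   matrices (`epsilon_by_day` boosted, `epsilon_baseline` without boost).
#' @seealso [build_two_context_schedule()], [baseline_replay()]
#' @export
build_schedule <- function(protocol, network) {
  if (protocol$two_context)
    return(build_two_context_schedule(protocol, network))
  day_len <- protocol$ID + protocol$Nrep * (protocol$T_rep + protocol$IR)
  n_steps <- protocol$n_days * day_len
  drive <- numeric(n_steps)
  day_of_step <- rep(seq_len(protocol$n_days), each = day_len)
  day_windows <- matrix(0L, protocol$n_days, 2,
                        dimnames = list(NULL, c("start", "end")))
  pattern_steps <- integer(protocol$n_days)
  eps <- base <- matrix(0, protocol$n_days, network$N)
  for (d in seq_len(protocol$n_days)) {
    off <- (d - 1L) * day_len
    blk <- rep_block_steps(off + protocol$ID, protocol)
    drive[blk$driven] <- network$delta
    day_windows[d, ] <- c(off, off + day_len)
    pattern_steps[d] <- blk$pattern_step
    e <- sample_excitability(d, protocol, network)
    eps[d, ] <- e$epsilon
    base[d, ] <- e$baseline
  }
  new_schedule(n_steps, drive, target = rep(0L, n_steps), day_of_step,
               day_windows, pattern_steps = matrix(pattern_steps, ncol = 1),
               epsilon_by_day = eps, epsilon_baseline = base,
               delta = network$delta, two_context = FALSE)
}

#' Build the two-context stimulation schedule
#'
#' A random half of the neurons is assigned to context A and the complement
#' to context B (drawn once per simulation). Each day consists of two
#' stimulation blocks, each preceded by an `ID` delay: first context A's
#' neurons are driven, then context B's. Under the defaults day-1 windows
#' are A at steps 1000-3000 and B at 4000-6000. During a context's block
#' only that context's neurons receive the drive.
#'
#' @inheritParams sample_excitability
#' @return A `stim_schedule` with `context` (per-neuron label 1 = A, 2 = B),
#'   a per-step `target` context, per-day-per-context pattern steps, and the
#'   day-1 supervision currents `beta` for the two read-out neurons.
#' @export
build_two_context_schedule <- function(protocol, network) {
  if (network$N %% 2L != 0L) stop("two-context protocol requires even N")
  half <- sample.int(network$N, network$N / 2L)
  context <- rep(2L, network$N)
  context[half] <- 1L

  block_len <- protocol$ID + protocol$Nrep * (protocol$T_rep + protocol$IR)
  day_len <- 2L * block_len
  n_steps <- protocol$n_days * day_len
  drive <- numeric(n_steps)
  target <- integer(n_steps)
  day_of_step <- rep(seq_len(protocol$n_days), each = day_len)
  day_windows <- matrix(0L, protocol$n_days, 2,
                        dimnames = list(NULL, c("start", "end")))
  pattern_steps <- matrix(0L, protocol$n_days, 2,
                          dimnames = list(NULL, c("A", "B")))
  eps <- base <- matrix(0, protocol$n_days, network$N)
  for (d in seq_len(protocol$n_days)) {
    off <- (d - 1L) * day_len
    for (ctx in 1:2) {
      blk <- rep_block_steps(off + (ctx - 1L) * block_len + protocol$ID,
                             protocol)
      drive[blk$driven] <- network$delta
      target[blk$driven] <- ctx
      pattern_steps[d, ctx] <- blk$pattern_step
    }
    day_windows[d, ] <- c(off, off + day_len)
    e <- sample_excitability(d, protocol, network)
    eps[d, ] <- e$epsilon
    base[d, ] <- e$baseline
  }
  # supervision: output k receives beta while its context is stimulated on
  # day 1 (steps 1000-3000 for A, 4000-6000 for B under defaults)
  beta <- matrix(0, n_steps, 2)
  for (ctx in 1:2) {
    a0 <- (ctx - 1L) * block_len + protocol$ID
    a1 <- a0 + protocol$Nrep * (protocol$T_rep + protocol$IR)
    beta[(a0 + 1L):a1, ctx] <- 1
  }
  new_schedule(n_steps, drive, target, day_of_step, day_windows,
               pattern_steps, epsilon_by_day = eps, epsilon_baseline = base,
               context = context, beta = beta, delta = network$delta,
               two_context = TRUE)
}

#' Baseline-excitability replay of a schedule
#'
#' Returns the same schedule with the `+E` boost removed from every day:
#' the baseline `|Normal|` draws (shared with the boosted schedule, same RNG
#' stream) are kept, so the only difference between the two runs is the
#' boost. Reference patterns for the day decoder are recorded under this
#' replay.
#'
#' @param schedule A `stim_schedule`.
#' @return A `stim_schedule` with `epsilon_by_day` set to the baseline draws.
#' @export
baseline_replay <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  schedule$epsilon_by_day <- schedule$epsilon_baseline
  schedule
}
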