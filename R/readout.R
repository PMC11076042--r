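#' Homeostatic gating factor of the read-out
#'
#' `h = 1 - sum(W_out)`, clamped below at 0. It equals 1 before learning
#' (zero weights) and 0 once the summed output weight reaches 1, at which
#' point Hebbian growth halts and the weights only decay.
#'
#' @param W_out Non-negative output-weight vector.
#' @return Scalar in `[0, 1]`.
#' @export
homeostatic_factor <- function(W_out) {
  max(0, 1 - sum(W_out))
}

#' One Euler step of the read-out neuron
#'
#' The output rate is `y_k = sum_i W_out[i, k] * r_i + beta_k`; each weight
#' then advances one step of
#' `dW_out[i, k]/dt = h(W_out[, k]) * r_i * y_k / tau_out_plus -
#' W_out[i, k] / tau_out_minus`, floored at 0.
#'
#' @param state List with `W_out`: an N x K matrix (or length-N vector for a
#'   single output).
#' @param rates Network rate vector (length N).
#' @param params A [readout_params()] object.
#' @param beta Per-output supervision current (scalar recycled; 0 when
#'   unsupervised).
#' @param dt Euler step; 1 by default, matching the network integration.
#' @return List with updated `W_out` (N x K matrix), `y` (length K) and `h`
#'   (length K, the gating factor used for this step).
#' @export
readout_step <- function(state, rates, params, beta = 0, dt = 1) {
  W_out <- state$W_out
  if (is.null(dim(W_out))) W_out <- matrix(W_out, ncol = 1)
  if (nrow(W_out) != length(rates))
    stop("W_out and rates disagree on N")
  if (!all(is.finite(W_out)) || !all(is.finite(rates)))
    stop("non-finite read-out state")
  K <- ncol(W_out)
  beta <- rep_len(beta, K)
  y <- as.vector(crossprod(W_out, rates)) + beta
  h <- pmax(0, 1 - colSums(W_out))
  dW <- outer(rates, h * y) / params$tau_out_plus - W_out / params$tau_out_minus
  W_out <- pmax(W_out + dt * dW, 0)
  list(W_out = W_out, y = y, h = h)
}

#' Read-out quality index
#'
#' `Q` compares the real output to the shuffled-weight control at the end of
#' the last repetition of days 2 onward:
#' `Q = < sum_d y_d / y_d^shuffle >` averaged over the shuffle replicates.
#' `Q = n_days - 1` when real and shuffled outputs are equal; larger values
#' mean the read-out tracks the drifting ensemble better than chance.
#'
#' @param y_by_day Real output at the per-day pattern steps (length
#'   `n_days`).
#' @param y_shuffled_by_day Matrix of shuffled-control outputs,
#'   `n_shuffle` rows x `n_days` columns.
#' @return Scalar Q. Shuffle replicates containing a zero denominator on
#'   days 2+ are excluded with a warning.
#' @export
readout_quality <- function(y_by_day, y_shuffled_by_day) {
  n_days <- length(y_by_day)
  if (n_days < 2) stop("readout_quality needs at least 2 days")
  if (ncol(y_shuffled_by_day) != n_days)
    stop("y_shuffled_by_day must have one column per day")
  dd <- 2:n_days
  per_shuffle <- apply(y_shuffled_by_day, 1, function(ys) {
    if (any(ys[dd] == 0)) return(NA_real_)
    sum(y_by_day[dd] / ys[dd])
  })
  if (anyNA(per_shuffle)) {
    warning("excluding shuffle replicates with zero output")
    per_shuffle <- per_shuffle[!is.na(per_shuffle)]
  }
  if (length(per_shuffle) == 0) stop("all shuffle replicates degenerate")
  mean(per_shuffle)
}

#' Center of mass of the output-weight distribution
#'
#' First moment of the weight vector over neuron indices (1-based):
#' `sum(i * W_out_i) / sum(W_out_i)`. Tracks which part of the network the
#' read-out currently listens to.
#'
#' @param W_out Non-negative weight vector with positive sum.
#' @return Scalar index (fractional).
#' @export
weight_center_of_mass <- function(W_out) {
  s <- sum(W_out)
  if (s <= 0) stop("center of mass undefined for all-zero weights")
  sum(seq_along(W_out) * W_out) / s
}

#' Shuffle the output weights
#'
#' Uniform random permutation of the weight vector entries (the multiset of
#' weights is preserved). Used for the chance-level control of the read-out
#' response.
#'
#' @param W_out Weight vector.
#' @return Permuted vector.
#' @export
shuffle_output_weights <- function(W_out) {
  W_out[sample.int(length(W_out))]
}
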