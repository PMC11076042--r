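#' Activity-pattern set
#'
#' Bundles the per-day activity patterns of a simulation: `V` holds the
#' rates at the end of each day's last stimulation repetition (rows = days),
#' and `V0` the corresponding patterns recorded under the
#' baseline-excitability replay (boost removed), which serve as the day
#' decoder's references.
#'
#' @param V `n_days` x N matrix of patterns (non-negative).
#' @param V0 Optional matching matrix of baseline-replay patterns.
#' @param context Optional label (`"A"`/`"B"`) for two-context runs.
#' @return A `pattern_set` object.
#' @export
pattern_set <- function(V, V0 = NULL, context = NULL) {
  V <- as.matrix(V)
  if (nrow(V) < 2) stop("pattern decoding needs at least 2 days")
  if (any(V < 0)) stop("patterns must be non-negative")
  if (!is.null(V0)) {
    V0 <- as.matrix(V0)
    if (!all(dim(V0) == dim(V))) stop("V and V0 must have the same shape")
  }
  structure(list(V = V, V0 = V0, context = context), class = "pattern_set")
}

#' Extract the pattern set from a simulation record
#'
#' @param record A `simulation_record`, typically from
#'   [run_simulation()] with `with_baseline = TRUE` so that `V0` is
#'   available.
#' @param context For two-context records, which ensemble to extract
#'   (`"A"` or `"B"`).
#' @return A [pattern_set()].
#' @export
get_patterns <- function(record, context = c("A", "B")) {
  if (isTRUE(record$schedule$two_context)) {
    context <- match.arg(context)
    V <- record$patterns[[context]]
    V0 <- if (!is.null(record$baseline)) record$baseline$patterns[[context]]
    pattern_set(V, V0, context = context)
  } else {
    V0 <- if (!is.null(record$baseline)) record$baseline$patterns
    pattern_set(record$patterns, V0)
  }
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d days x %d neurons%s%s\n", nrow(x$V),
              ncol(x$V), if (is.null(x$V0)) "" else " (+ baseline refs)",
              if (is.null(x$context)) "" else paste0(", context ", x$context)))
  invisible(x)
}

#' Pearson correlation between two activity patterns
#'
#' Plain Pearson correlation, with an explicit error (condition class
#' `driftnet_zero_variance`) when either pattern has zero variance — a dead
#' or saturated network — instead of a silent `NA`.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pattern_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("patterns must have equal length >= 2")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop(structure(class = c("driftnet_zero_variance", "error", "condition"),
                   list(message = "zero-variance pattern: correlation undefined",
                        call = sys.call(-1))))
  stats::cor(a, b)
}

# correlation matrix between rows of two pattern matrices
pattern_cor_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- pattern_correlation(A[i, ], B[j, ])
  out
}

#' Day decoder
#'
#' Infers, for each day `d`, the day of an activity pattern by maximizing
#' the Pearson correlation of the baseline-replay reference `V0_d` against
#' the patterns `V_d'` of all days: `d_inf = argmax_d' corr(V0_d, V_d')`.
#' The error is `d_inf - d`. Ties in the argmax are broken towards the
#' earliest day and flagged.
#'
#' @param patterns A [pattern_set()] with `V0` present, or a matrix `V`
#'   combined with the `V0` argument.
#' @param V0 Reference matrix if `patterns` is a plain matrix.
#' @return Data frame with columns `day`, `inferred`, `error`, `tie`.
#' @export
day_decode <- function(patterns, V0 = NULL) {
  if (inherits(patterns, "pattern_set")) {
    V <- patterns$V; V0 <- patterns$V0
  } else V <- as.matrix(patterns)
  if (is.null(V0)) stop("day decoding needs baseline reference patterns V0")
  C <- pattern_cor_matrix(as.matrix(V0), V)
  n_days <- nrow(V)
  inferred <- integer(n_days); tie <- logical(n_days)
  for (d in seq_len(n_days)) {
    mx <- max(C[d, ])
    hits <- which(C[d, ] >= mx - 1e-12)
    inferred[d] <- hits[1]
    tie[d] <- length(hits) > 1
  }
  data.frame(day = seq_len(n_days), inferred = inferred,
             error = inferred - seq_len(n_days), tie = tie)
}

#' Shuffle day labels per neuron
#'
#' For each neuron (column) independently, permutes its values across days
#' uniformly at random; each neuron's multiset of per-day rates is
#' preserved. This is the null used for both temporal decoders.
#'
#' @param V `n_days` x N pattern matrix.
#' @return Matrix of the same shape.
#' @export
shuffle_day_labels <- function(V) {
  V <- as.matrix(V)
  apply(V, 2, function(col) col[sample.int(length(col))])
}

#' All permutations of 1..n
#'
#' @param n Number of elements (n! rows are returned; keep n small).
#' @return Integer matrix, one permutation per row; the first row is the
#'   identity.
#' @export
permutations_of <- function(n) {
  if (n > 8) stop("refusing to enumerate more than 8! permutations")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in n:1) {  # insert n at each position; identity row comes first
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Ordinal time decoder
#'
#' Scores every permutation `p` of the days by the summed Pearson
#' correlation of consecutive patterns,
#' `S(p) = sum_i corr(V[p_i], V[p_{i+1}])`, and compares the real (identity)
#' order against the distribution of all `n_days!` scores with a one-sample
#' t-statistic `t = (S(p_real) - mu) / (sigma / sqrt(n_perm))`, where `mu`
#' and `sigma` are the mean and SD of all scores (the real permutation
#' included). Because Pearson correlation is symmetric, every score is
#' shared by a permutation and its reversal, so the argmax set always has
#' at least two members.
#'
#' @param patterns A [pattern_set()] or a plain `n_days` x N matrix.
#' @return An `ordinal_result` list: `perms` (matrix of permutations),
#'   `scores` (vector of `S(p)`), `S_real`, `t_value`, `real_is_max`
#'   (whether `S(p_real)` attains the maximum, at tolerance 1e-12) and
#'   `mu`, `sigma`.
#' @export
ordinal_decode <- function(patterns) {
  V <- if (inherits(patterns, "pattern_set")) patterns$V else
    as.matrix(patterns)
  n_days <- nrow(V)
  C <- pattern_cor_matrix(V, V)
  perms <- permutations_of(n_days)
  scores <- apply(perms, 1, function(p)
    sum(C[cbind(p[-n_days], p[-1])]))
  S_real <- scores[1]  # identity permutation is the first row
  mu <- mean(scores); sigma <- stats::sd(scores)
  t_value <- if (sigma == 0) NA_real_ else
    (S_real - mu) / (sigma / sqrt(length(scores)))
  if (sigma == 0) warning("degenerate score distribution: t undefined")
  structure(list(perms = perms, scores = scores, S_real = S_real,
                 mu = mu, sigma = sigma, t_value = t_value,
                 real_is_max = S_real >= max(scores) - 1e-12),
            class = "ordinal_result")
}

#' @export
print.ordinal_result <- function(x, ...) {
  cat(sprintf("<ordinal_result> %d permutations; S(real) = %.3f, t = %.2f%s\n",
              length(x$scores), x$S_real, x$t_value,
              if (x$real_is_max) " (real order maximal)" else ""))
  invisible(x)
}

#' Drift rate
#'
#' Total decorrelation of the ensemble relative to its day-1 pattern:
#' `sum_{d >= 2} (1 - corr(V_1, V_d))`. Zero when the ensemble is stable;
#' up to `2 * (n_days - 1)` for anti-correlated drift.
#'
#' @param patterns A [pattern_set()] or `n_days` x N matrix.
#' @return Scalar drift rate.
#' @export
drift_rate <- function(patterns) {
  V <- if (inherits(patterns, "pattern_set")) patterns$V else
    as.matrix(patterns)
  n_days <- nrow(V)
  sum(vapply(2:n_days, function(d)
    1 - pattern_correlation(V[1, ], V[d, ]), numeric(1)))
}
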