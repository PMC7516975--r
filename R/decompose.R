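# evaluate a cost at every subset; returns vector indexed as
# all_subsets_bits(n) rows (row i+1 = integer i). Direct evaluation, no
# ledger: used by the exhaustive structural checks below.
all_costs <- function(cost) {
  n <- cost$ground$n
  m <- all_subsets_bits(n)
  vapply(seq_len(nrow(m)), function(i) as.double(cost$eval(m[i, ])),
         numeric(1))
}

# for each subset: the minimum cost over its lower neighbours (one feature
# removed) and over its upper neighbours (one feature added). Inf where a
# subset has no neighbour on that side.
neighbour_minima <- function(costs, n) {
  N <- length(costs)
  idx <- 0:(N - 1)
  lowmin <- rep(Inf, N)
  upmin <- rep(Inf, N)
  for (j in seq_len(n)) {
    d <- 2^(n - j)
    has <- bitwAnd(idx, d) != 0L
    wi <- which(has)
    lowmin[wi] <- pmin(lowmin[wi], costs[wi - d])
    wo <- which(!has)
    upmin[wo] <- pmin(upmin[wo], costs[wo + d])
  }
  list(low = lowmin, up = upmin)
}

#' Test whether a cost function decomposes into U-shaped curves
#'
#' A cost function decomposes into U-shaped curves when for every chain
#' triple \eqn{X_1 \subseteq X_2 \subseteq X_3} it holds that
#' \eqn{c(X_2) \le \max\{c(X_1), c(X_3)\}}: along any chain the costs dip
#' and then rise, never spiking in the middle. Checking triples of
#' *consecutive* cardinality suffices — a violation on a wider chain
#' implies one on some consecutive triple along it.
#'
#' The check enumerates the whole lattice, so it is restricted to small
#' ground sets.
#'
#' @param cost A [cost_fn()].
#' @param guard Maximum ground-set size accepted (default 14).
#' @return Logical scalar.
#' @examples
#' inst <- gen_subset_sum_instance(6, seed = 1)
#' is_u_decomposable(cost_subset_sum(inst))  # TRUE by construction
#' @export
is_u_decomposable <- function(cost, guard = 14L) {
  n <- cost$ground$n
  if (n > guard) {
    abort(paste0("exhaustive U-curve check limited to n <= ", guard,
                 " features (got n = ", n, ")"))
  }
  costs <- all_costs(cost)
  nb <- neighbour_minima(costs, n)
  low <- ifelse(is.finite(nb$low), nb$low, costs)
  up <- ifelse(is.finite(nb$up), nb$up, costs)
  !any(cost_lt(low, costs) & cost_lt(up, costs))
}

#' Count oscillations of a cost function
#'
#' An oscillation is an ordered chain triple \eqn{X_1 \subset X_2 \subset
#' X_3} with consecutive cardinalities where \eqn{c(X_2) >
#' \max\{c(X_1), c(X_3)\}} — a spike violating the U-curve property.
#' Real-data criteria exhibit oscillations; the subset-sum cost has none.
#' The per-element oscillation ratio is `count / 2^n`.
#'
#' @param cost A [cost_fn()].
#' @param guard Maximum ground-set size accepted (default 20).
#' @return Integer (as double) count of oscillating triples.
#' @seealso [oscillation_ratio()]
#' @export
count_oscillations <- function(cost, guard = 20L) {
  n <- cost$ground$n
  if (n > guard) {
    abort(paste0("oscillation count limited to n <= ", guard,
                 " features (got n = ", n, ")"))
  }
  costs <- all_costs(cost)
  N <- length(costs)
  idx <- 0:(N - 1)
  nlow <- numeric(N)
  nup <- numeric(N)
  for (j in seq_len(n)) {
    d <- 2^(n - j)
    has <- bitwAnd(idx, d) != 0L
    wi <- which(has)
    nlow[wi] <- nlow[wi] + cost_lt(costs[wi - d], costs[wi])
    wo <- which(!has)
    nup[wo] <- nup[wo] + cost_lt(costs[wo + d], costs[wo])
  }
  sum(nlow * nup)
}

#' Per-element oscillation ratio
#'
#' Oscillation count divided by the lattice size \eqn{2^n}; a scale-free
#' measure of how far an instance departs from the U-curve assumption.
#'
#' @inheritParams count_oscillations
#' @return Non-negative double.
#' @export
oscillation_ratio <- function(cost, guard = 20L) {
  count_oscillations(cost, guard) / 2^cost$ground$n
}
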