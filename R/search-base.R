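# Guard against accidentally enumerating huge lattices. Instances with up
# to 25 features are the "small" regime where optimal solvers are viable;
# beyond that the exhaustive solvers refuse unless forced.
SMALL_INSTANCE_MAX <- 25L

check_guard <- function(n, guard, force, what) {
  if (n > guard && !force) {
    abort(paste0(what, " refuses n = ", n, " > ", guard,
                 " features; pass force = TRUE to override"))
  }
}

#' Exhaustive search
#'
#' Evaluates every one of the \eqn{2^n} subsets through the memoized
#' ledger and returns all global minimizers. The distinct-call count is
#' exactly \eqn{2^n} on a fresh ledger.
#'
#' @param cost A [cost_fn()].
#' @param ledger Optional shared [evaluation_ledger()]; defaults to a
#'   fresh one.
#' @param guard Refuse ground sets larger than this (default 25).
#' @param force Set `TRUE` to override the guard.
#' @return A `feature_search` object.
#' @examples
#' inst <- gen_subset_sum_instance(7, seed = 1)
#' glance(search_exhaustive(cost_subset_sum(inst)))  # 128 cost calls
#' @export
search_exhaustive <- function(cost, ledger = NULL, guard = SMALL_INSTANCE_MAX,
                              force = FALSE) {
  lg <- ledger %||% evaluation_ledger()
  es_core(cost, lg, guard, force)
  new_feature_search("es", cost, lg)
}

# Search cores: the traversal logic without result packaging. `lg = NULL`
# skips the solver-local memo — used when the cost already memoizes into a
# shared ledger (PUCS inner lattices), halving the per-evaluation cost.
core_evalf <- function(cost, lg) {
  if (is.null(lg)) cost$eval else function(bits) eval_cost_bits(cost, lg, bits)
}

es_core <- function(cost, lg, guard = SMALL_INSTANCE_MAX, force = FALSE) {
  n <- cost$ground$n
  check_guard(n, guard, force, "exhaustive search")
  ev <- core_evalf(cost, lg)
  m <- all_subsets_bits(n)
  for (i in seq_len(nrow(m))) {
    ev(m[i, ])
  }
  invisible(lg)
}

#' U-curve branch-and-bound (UBB)
#'
#' A simple optimal solver for costs that decompose into U-shaped curves.
#' The power set is enumerated as a spanning tree rooted at the empty set:
#' the children of a subset append only features with index greater than
#' the subset's highest selected index, so every subset is generated
#' exactly once. When expanding a child \eqn{X \cup \{s\}}, if
#' \eqn{c(X) < c(X \cup \{s\})} the whole subtree below the child — which
#' lies inside the interval \eqn{[X \cup \{s\}, S]} — is pruned, which
#' loses no minima on a U-decomposable cost (costs above a strict increase
#' can only stay above \eqn{c(X)}).
#'
#' @inheritParams search_exhaustive
#' @return A `feature_search` object; on U-decomposable costs the minima
#'   are globally optimal.
#' @export
search_ubb <- function(cost, ledger = NULL, guard = SMALL_INSTANCE_MAX,
                       force = FALSE) {
  lg <- ledger %||% evaluation_ledger()
  ubb_core(cost, lg, guard, force)
  new_feature_search("ubb", cost, lg)
}

ubb_core <- function(cost, lg, guard = SMALL_INSTANCE_MAX, force = FALSE) {
  n <- cost$ground$n
  check_guard(n, guard, force, "UBB")
  ev <- core_evalf(cost, lg)
  root <- integer(n)
  c0 <- ev(root)
  rec <- function(bits, cx, from) {
    for (j in from:n) {
      child <- bits
      child[j] <- 1L
      cc <- ev(child)
      if (!cost_lt(cx, cc) && j < n) rec(child, cc, j + 1L)
    }
  }
  if (n >= 1L) rec(root, c0, 1L)
  invisible(lg)
}

#' Sequential forward selection (SFS)
#'
#' Greedy bottom-up search: starting from the empty set, repeatedly add
#' the single feature whose addition gives the lowest cost (ties broken by
#' lowest feature index), stopping as soon as no addition strictly
#' improves the best cost seen. Suboptimal but cheap; also usable as the
#' PUCS base algorithm on big instances.
#'
#' @inheritParams search_exhaustive
#' @return A `feature_search` object.
#' @export
search_sfs <- function(cost, ledger = NULL) {
  lg <- ledger %||% evaluation_ledger()
  sfs_core(cost, lg)
  new_feature_search("sfs", cost, lg)
}

sfs_core <- function(cost, lg) {
  n <- cost$ground$n
  ev <- core_evalf(cost, lg)
  bits <- integer(n)
  best <- ev(bits)
  repeat {
    open <- which(bits == 0L)
    if (!length(open)) break
    cand <- vapply(open, function(j) {
      b <- bits
      b[j] <- 1L
      ev(b)
    }, numeric(1))
    k <- open[which.min(cand)]     # which.min takes the lowest index on ties
    if (!cost_lt(min(cand), best)) break
    bits[k] <- 1L
    best <- min(cand)
  }
  invisible(lg)
}

#' Sequential forward floating selection (SFFS)
#'
#' Floating variant of [search_sfs()]: after each forward step (best single
#' addition), backward steps remove a feature while doing so strictly
#' improves the best cost recorded at the smaller cardinality. The search
#' halts once the current cardinality exceeds the cardinality of the best
#' subset found so far by more than `delta`.
#'
#' @inheritParams search_exhaustive
#' @param delta Non-negative integer exploration margin (default 3).
#' @return A `feature_search` object.
#' @export
search_sffs <- function(cost, ledger = NULL, delta = 3L) {
  lg <- ledger %||% evaluation_ledger()
  sffs_core(cost, lg, delta)
  new_feature_search("sffs", cost, lg, params = list(delta = delta))
}

sffs_core <- function(cost, lg, delta = 3L) {
  if (delta < 0L) abort("delta must be non-negative")
  n <- cost$ground$n
  ev <- core_evalf(cost, lg)
  bits <- integer(n)
  cur <- ev(bits)
  best_at <- rep(Inf, n + 1L)      # best cost recorded per cardinality
  best_at[1L] <- cur
  best_cost <- cur
  best_card <- 0L
  note <- function(card, v) {
    if (cost_lt(v, best_at[card + 1L])) best_at[card + 1L] <<- v
    if (cost_lt(v, best_cost)) {
      best_cost <<- v
      best_card <<- card
    }
  }
  repeat {
    open <- which(bits == 0L)
    if (!length(open)) break
    cand <- vapply(open, function(j) {
      b <- bits
      b[j] <- 1L
      ev(b)
    }, numeric(1))
    k <- open[which.min(cand)]
    bits[k] <- 1L
    cur <- min(cand)
    note(sum(bits), cur)
    # conditional backward steps
    while (sum(bits) > 2L) {
      inn <- which(bits == 1L)
      back <- vapply(inn, function(j) {
        b <- bits
        b[j] <- 0L
        ev(b)
      }, numeric(1))
      r <- inn[which.min(back)]
      card <- sum(bits) - 1L
      if (cost_lt(min(back), best_at[card + 1L])) {
        bits[r] <- 0L
        cur <- min(back)
        note(card, cur)
      } else {
        break
      }
    }
    if (sum(bits) > best_card + delta) break
  }
  invisible(lg)
}
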