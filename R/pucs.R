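# ---- PUCS: the pruning walk on the outer lattice and the parallel
# ---- solving of the surviving inner lattices.

#' Floor and ceiling probes of an outer-lattice element
#'
#' The two full-lattice evaluations the pruning rules compare: the
#' *floor* \eqn{c(X)} (free coordinates all 0) and the *ceiling*
#' \eqn{c(X \cup \bar{S'})} (free coordinates all 1), both memoized into
#' the shared ledger.
#'
#' @param x Outer element: bit string / vector over the fixed coordinates.
#' @param part A [make_partition()].
#' @param cost A [cost_fn()] over the full ground set.
#' @param ledger Shared [evaluation_ledger()].
#' @return Named numeric vector `c(floor = ..., ceiling = ...)`.
#' @export
probe_costs <- function(x, part, cost, ledger) {
  xb <- as_bits(x, length(part$fixed_idx))
  fl <- outer_to_full(part, xb, 0L)
  ce <- outer_to_full(part, xb, 1L)
  c(floor = eval_cost_bits(cost, ledger, fl),
    ceiling = eval_cost_bits(cost, ledger, ce))
}

#' Pruning decision for an adjacent outer-lattice pair
#'
#' Applies the pruning rules to a pair of adjacent outer elements `x`, `y`
#' (Hamming distance 1 on the fixed coordinates), testing the branches
#' strictly in order. With \eqn{X \subseteq Y}: a strict ceiling decrease
#' prunes the downset \eqn{[\emptyset, X \cup \bar{S'}]} and moves the
#' walk to `y`; otherwise a strict floor increase prunes the upset
#' \eqn{[Y, S]} and the walk stays. The two symmetric branches apply when
#' \eqn{Y \subseteq X}; if no strict inequality fires, the walk moves to
#' `y` without pruning. Removed full-lattice intervals translate to
#' outer-lattice removals: \eqn{[Y, S]} removes outer \eqn{[Y, S']},
#' \eqn{[\emptyset, A \cup \bar{S'}]} removes outer \eqn{[\emptyset, A]} —
#' sound because the whole inner lattice of a removed outer element lies
#' inside the pruned interval.
#'
#' @param x,y Adjacent outer elements (bit strings / vectors over the
#'   fixed coordinates).
#' @param probes List with numeric entries `x` and `y`, each as returned
#'   by [probe_costs()].
#' @return A list: `action` (one of `"prune_lower_move"`,
#'   `"prune_upper_stay"`, `"prune_upper_move"`, `"prune_lower_stay"`,
#'   `"move"`), `move` (logical), and `remove` (`NULL` or the outer
#'   interval to delete, as `list(lower, upper)` bit vectors).
#' @export
adjacency_case <- function(x, y, probes) {
  d <- if (is.character(x)) nchar(x) else length(x)
  xb <- as_bits(x, d)
  yb <- as_bits(y, d)
  if (sum(xb != yb) != 1L) {
    abort("adjacency_case requires outer elements at Hamming distance 1")
  }
  px <- probes$x
  py <- probes$y
  ones <- rep(1L, d)
  zeros <- integer(d)
  if (all(xb <= yb)) {
    if (cost_gt(px[["ceiling"]], py[["ceiling"]])) {
      list(action = "prune_lower_move", move = TRUE,
           remove = list(lower = zeros, upper = xb))
    } else if (cost_lt(px[["floor"]], py[["floor"]])) {
      list(action = "prune_upper_stay", move = FALSE,
           remove = list(lower = yb, upper = ones))
    } else {
      list(action = "move", move = TRUE, remove = NULL)
    }
  } else {
    if (cost_lt(py[["floor"]], px[["floor"]])) {
      list(action = "prune_upper_move", move = TRUE,
           remove = list(lower = xb, upper = ones))
    } else if (cost_gt(py[["ceiling"]], px[["ceiling"]])) {
      list(action = "prune_lower_stay", move = FALSE,
           remove = list(lower = zeros, upper = yb))
    } else {
      list(action = "move", move = TRUE, remove = NULL)
    }
  }
}

# simple explicit set of outer bit strings (the explored collection E):
# interval removals must delete from E too, so it keeps explicit members
eset_new <- function() new.env(parent = emptyenv())
eset_add <- function(e, key) assign(key, TRUE, envir = e)
eset_members <- function(e) sort(ls(e, all.names = TRUE))
eset_remove_interval <- function(e, lower, upper, d) {
  for (k in ls(e, all.names = TRUE)) {
    b <- bits_from_string(k, d)
    if (all(lower <= b) && all(b <= upper)) rm(list = k, envir = e)
  }
}

outer_neighbours <- function(bits) {
  lapply(seq_along(bits), function(j) {
    b <- bits
    b[j] <- 1L - b[j]
    b
  })
}

# the pruned full-lattice interval spans the whole inner lattice of every
# removed outer element: lower endpoint with free bits 0, upper with 1
prune_record <- function(part, rule, at, lower, upper) {
  list(
    rule = rule,
    at = bits_to_string(at),
    outer_lower = bits_to_string(lower),
    outer_upper = bits_to_string(upper),
    full_lower = bits_to_string(outer_to_full(part, lower, 0L)),
    full_upper = bits_to_string(outer_to_full(part, upper, 1L))
  )
}

#' Walk the outer Boolean lattice, pruning intervals
#'
#' The coordinator phase of PUCS. The store `U` starts as the full outer
#' lattice; walks pop a random start element, explore adjacent elements in
#' seeded-random order, apply [adjacency_case()] to each pair, remove the
#' justified intervals from both `U` and the explored set `E`, and replace
#' the walking element when a move fires. The walk ends when `U` is empty;
#' the surviving explored elements anchor the inner lattices still to be
#' solved.
#'
#' @param part A [make_partition()].
#' @param cost A [cost_fn()] over the full ground set.
#' @param ledger Shared [evaluation_ledger()] collecting the probe costs.
#' @param rng Seeded RNG stream (or `seed` to create one).
#' @param seed Seed used when `rng` is not supplied.
#' @return A list: `explored` (character vector of surviving outer
#'   elements) and `prune_log` (tibble of pruning events with the fired
#'   rule and the removed outer/full intervals).
#' @export
outer_walk <- function(part, cost, ledger = evaluation_ledger(),
                       rng = NULL, seed = 1L) {
  rng <- rng %||% rng_new(seed)
  d <- length(part$fixed_idx)
  U <- store_full(d)
  E <- eset_new()
  log <- list()
  probe <- function(b) probe_costs(b, part, cost, ledger)
  drop_interval <- function(lower, upper) {
    store_remove_interval(U, lower, upper)
    eset_remove_interval(E, lower, upper, d)
  }
  while (!store_is_empty(U)) {
    X <- store_pop(U, rng)
    eset_add(E, bits_to_string(X))
    repeat {
      nbrs <- Filter(function(b) store_contains(U, b),
                     rng_shuffle(rng, outer_neighbours(X)))
      if (!length(nbrs)) break
      moved <- FALSE
      for (Y in nbrs) {
        if (!store_contains(U, Y)) next
        dec <- adjacency_case(X, Y, list(x = probe(X), y = probe(Y)))
        if (!is.null(dec$remove)) {
          log[[length(log) + 1L]] <-
            prune_record(part, dec$action, X, dec$remove$lower,
                         dec$remove$upper)
          drop_interval(dec$remove$lower, dec$remove$upper)
        }
        if (dec$move) {
          # Y becomes the walking element: out of U, into E (after any
          # removal, so the new X survives the interval it fired)
          store_remove_interval(U, Y, Y)
          X <- Y
          eset_add(E, bits_to_string(X))
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }
  prune_log <- if (length(log)) {
    dplyr::bind_rows(lapply(log, as_tibble))
  } else {
    tibble(rule = character(0), at = character(0),
           outer_lower = character(0), outer_upper = character(0),
           full_lower = character(0), full_upper = character(0))
  }
  list(explored = eset_members(E), prune_log = prune_log)
}

# solve the inner lattice anchored at one outer element; evaluations flow
# into `ledger` through the projected cost
solve_inner <- function(xstr, part, cost, ledger, base, p, l, level, seed) {
  d <- length(part$fixed_idx)
  xb <- bits_from_string(xstr, d)
  k <- length(part$free_idx)
  if (k == 0L) {
    fl <- outer_to_full(part, xb, 0L)
    eval_cost_bits(cost, ledger, fl)
    return(invisible(NULL))
  }
  pc <- cost_project(cost, part, xb, ledger)
  if (level < l && k > 1L) {
    pucs_run(pc, p = p, l = l, base = base, level = level + 1L,
             seed = rng_child_seed(seed, bits_fold(xb)), workers = 1L)
  } else {
    base_dispatch(base, pc)
  }
  invisible(NULL)
}

# deterministic numeric fold of a bit word (any width) for child seeds
bits_fold <- function(bits) {
  k <- 0
  for (b in bits) k <- (k * 2 + b) %% 2147483647
  k
}

base_dispatch <- function(base, cost) {
  # the projected cost already memoizes into the shared ledger, so the
  # solver-local memo is redundant (lg = NULL)
  lg <- NULL
  switch(base,
    es = es_core(cost, lg, force = TRUE),
    ubb = ubb_core(cost, lg, force = TRUE),
    sfs = sfs_core(cost, lg),
    sffs = sffs_core(cost, lg),
    abort(paste0("unknown base algorithm \"", base,
                 "\"; use one of es, ubb, sfs, sffs"))
  )
}

# one full PUCS pass at a given recursion level; returns ledger + log
pucs_run <- function(cost, p, l, base, level, seed, workers, fixed = NULL) {
  n <- cost$ground$n
  rng <- rng_new(seed)
  ledger <- evaluation_ledger()
  if (n == 0L) return(list(ledger = ledger, prune_log = NULL))
  part <- make_partition(cost$ground, p = p, fixed = fixed, rng = rng)
  walk <- outer_walk(part, cost, ledger, rng = rng)
  solve_one <- function(xstr) {
    # per-worker ledger, merged afterwards; the merged distinct-call count
    # is the size of the union of the memo maps
    lg <- evaluation_ledger()
    solve_inner(xstr, part, cost, lg, base, p, l, level,
                rng_child_seed(seed, bits_fold(bits_from_string(xstr, length(part$fixed_idx)))))
    lg
  }
  xs <- walk$explored
  ledgers <- if (workers > 1L && length(xs) > 1L) {
    parallel::mclapply(xs, solve_one, mc.cores = workers)
  } else {
    lapply(xs, solve_one)
  }
  for (lg in ledgers) ledger_absorb(ledger, lg)
  list(ledger = ledger, prune_log = walk$prune_log, partition = part)
}

#' Parallel U-Curve Search (PUCS)
#'
#' Minimizes a cost function over the Boolean lattice of feature subsets
#' by partitioning the lattice: a walk on the outer lattice of the fixed
#' points prunes whole intervals of the search space wherever a strict
#' cost inequality licenses it, and the inner lattices anchored at the
#' surviving outer elements are solved independently — recursively by PUCS
#' down to depth `l`, then by the base algorithm — optionally in parallel
#' worker processes. With an optimal base algorithm and a cost that
#' decomposes into U-shaped curves the returned minima are global.
#'
#' Defaults follow the small/big instance regimes: up to 25 features,
#' `p = 0.5` with the optimal UBB base; above that, `p = 10/n` with the
#' SFS base. The fixed-set size is \eqn{\lceil p\,n \rceil}.
#'
#' @param cost A [cost_fn()].
#' @param p Fixed-point proportion in \eqn{(0, 1]}; `NULL` picks the
#'   regime default.
#' @param l Maximum recursion depth (>= 1).
#' @param base Base algorithm at depth `l`: `"ubb"`, `"es"`, `"sfs"` or
#'   `"sffs"`; `NULL` picks the regime default.
#' @param seed Integer seed driving every random choice (partition, walk
#'   order); fixed seed + `workers = 1` reproduces a run exactly, and the
#'   minima are invariant to the worker count.
#' @param workers Number of worker processes for solving inner lattices.
#' @param fixed Optional character vector naming the fixed points,
#'   overriding the random choice.
#' @return A `feature_search` object with the minima over all evaluated
#'   elements, the merged evaluation ledger, and the pruning-event log.
#' @examples
#' inst <- gen_subset_sum_instance(8, seed = 42)
#' fit <- search_pucs(cost_subset_sum(inst), seed = 1)
#' glance(fit)
#' @export
search_pucs <- function(cost, p = NULL, l = 1L, base = NULL, seed = 1L,
                        workers = 1L, fixed = NULL) {
  n <- cost$ground$n
  if (n < 1L) abort("the ground set must have at least one feature")
  l <- as.integer(l)
  if (is.na(l) || l < 1L) abort("l must be an integer >= 1")
  workers <- max(1L, as.integer(workers))
  if (is.null(p)) p <- if (n <= SMALL_INSTANCE_MAX) 0.5 else 10 / n
  if (is.null(base)) base <- if (n <= SMALL_INSTANCE_MAX) "ubb" else "sfs"
  base <- match.arg(base, c("ubb", "es", "sfs", "sffs"))
  run <- pucs_run(cost, p = p, l = l, base = base, level = 1L,
                  seed = seed, workers = workers, fixed = fixed)
  new_feature_search("pucs", cost, run$ledger,
                     params = list(p = p, l = l, base = base, seed = seed,
                                   workers = workers),
                     prune_log = run$prune_log)
}
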