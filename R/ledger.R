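# Cost comparisons: strict inequalities drive the pruning rules, so they
# must not flip on floating-point noise. Integer-valued costs compare
# exactly; real-valued costs get a 1e-12 relative tolerance.
COST_TOL <- 1e-12

cost_lt <- function(a, b) {
  r <- a < b - COST_TOL * pmax(1, abs(a), abs(b))
  # infinite sentinels (e.g. "no cost recorded yet") make the slack NaN
  bad <- is.na(r) & !is.na(a) & !is.na(b)
  if (any(bad)) r[bad] <- (a < b)[bad]
  r
}
cost_gt <- function(a, b) cost_lt(b, a)
cost_eq <- function(a, b) abs(a - b) <= COST_TOL * pmax(1, abs(a), abs(b))

#' Construct a cost function
#'
#' A cost function maps every subset of its ground set to a non-negative
#' real number. `fn` receives the subset as an integer 0/1 vector aligned
#' with the ground set's lexicographic feature order.
#'
#' @param fn Function of one argument (integer bit vector) returning a
#'   single non-negative number; must be deterministic.
#' @param ground The [ground_set()] the function is defined over.
#' @param name Identifier used in printouts and reports.
#' @return An object of class `ucurve_cost`.
#' @export
cost_fn <- function(fn, ground, name = "cost") {
  stopifnot(is.function(fn), inherits(ground, "ucurve_ground"))
  structure(list(eval = fn, ground = ground, name = name),
            class = "ucurve_cost")
}

#' @export
print.ucurve_cost <- function(x, ...) {
  cat("<cost function \"", x$name, "\" over ", x$ground$n, " features>\n",
      sep = "")
  invisible(x)
}

#' Evaluation ledger
#'
#' The memo of all cost evaluations made during a search (the record of
#' computed elements). A repeat query is served from the memo and does not
#' count as a new call; `ledger_calls()` therefore counts *distinct*
#' evaluations, the hardware-independent work measure used throughout the
#' package.
#'
#' @return An empty ledger of class `ucurve_ledger`.
#' @export
evaluation_ledger <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- utils::hashtab("identical")
  class(e) <- "ucurve_ledger"
  e
}

#' @export
print.ucurve_ledger <- function(x, ...) {
  cat("<evaluation ledger:", ledger_calls(x), "distinct evaluations>\n")
  invisible(x)
}

#' Number of distinct cost evaluations recorded
#' @param ledger An [evaluation_ledger()].
#' @return Integer count.
#' @export
ledger_calls <- function(ledger) {
  utils::numhash(ledger$map)
}

#' Memoized cost evaluation
#'
#' Evaluates `cost` at subset `x`, recording the value in `ledger`. The
#' first evaluation of a subset reaches the underlying function and
#' increments the distinct-call count; repeats are memo hits.
#'
#' @param cost A [cost_fn()].
#' @param ledger An [evaluation_ledger()].
#' @param x Subset: an `ucurve_fset`, a bit string, or an integer 0/1
#'   vector over the cost's ground set.
#' @return The cost value (non-negative scalar).
#' @export
eval_cost <- function(cost, ledger, x) {
  bits <- as_bits(x, cost$ground$n)
  eval_cost_bits(cost, ledger, bits)
}

# Memo keys: the bit word packed into numeric chunks of <= 45 bits (each
# exact in double precision) — a scalar double for ordinary widths, a
# short double vector beyond 45 features. Numeric keys go straight into a
# C-level hash table; nothing is ever interned in R's string cache, which
# keeps garbage collection flat over millions of evaluations.
KEY_CHUNK <- 45L

# power-of-two tables per width, computed once
POW2 <- local({
  cache <- new.env(parent = emptyenv())
  function(width) {
    k <- as.character(width)
    p <- get0(k, envir = cache, inherits = FALSE)
    if (is.null(p)) {
      p <- 2^((width - 1L):0)
      assign(k, p, envir = cache)
    }
    p
  }
})

bits_key <- function(bits) {
  n <- length(bits)
  if (n <= KEY_CHUNK) {
    return(sum(bits * POW2(n)))
  }
  starts <- seq(1L, n, by = KEY_CHUNK)
  vapply(starts, function(s) {
    b <- bits[s:min(s + KEY_CHUNK - 1L, n)]
    sum(b * POW2(length(b)))
  }, numeric(1))
}

key_to_string <- function(key, width) {
  widths <- rep(KEY_CHUNK, length(key))
  widths[length(key)] <- width - KEY_CHUNK * (length(key) - 1L)
  paste(unlist(lapply(seq_along(key), function(i) {
    (key[i] %/% 2^((widths[i] - 1L):0)) %% 2
  })), collapse = "")
}

# vectorized decode of a list of keys into canonical bit strings
keys_to_strings <- function(keys, width) {
  if (width <= KEY_CHUNK) {
    v <- unlist(keys, use.names = FALSE)
    m <- matrix(0L, length(v), width)
    for (j in seq_len(width)) {
      m[, j] <- (v %/% 2^(width - j)) %% 2
    }
    return(do.call(paste0, as.data.frame(m)))
  }
  vapply(keys, key_to_string, character(1), width = width,
         USE.NAMES = FALSE)
}

# all (key, cost) pairs currently memoized
ledger_pairs <- function(ledger) {
  n <- utils::numhash(ledger$map)
  keys <- vector("list", n)
  costs <- numeric(n)
  i <- 0L
  utils::maphash(ledger$map, function(k, v) {
    i <<- i + 1L
    keys[[i]] <<- k
    costs[i] <<- v
  })
  list(keys = keys, costs = costs)
}

# fast internal path: caller may supply the precomputed key
eval_cost_bits <- function(cost, ledger, bits, key = bits_key(bits)) {
  v <- utils::gethash(ledger$map, key)
  if (!is.null(v)) return(v)
  if (is.null(ledger$width)) ledger$width <- length(bits)
  v <- cost$eval(bits)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
    abort(paste0("cost function \"", cost$name,
                 "\" returned an invalid value at subset ", bits_to_string(bits)))
  }
  v <- as.double(v)
  utils::sethash(ledger$map, key, v)
  v
}

#' Ledger contents as a tibble
#'
#' @param ledger An [evaluation_ledger()].
#' @return A tibble with columns `subset` (canonical bit string) and
#'   `cost`, sorted by subset string.
#' @export
ledger_tbl <- function(ledger) {
  p <- ledger_pairs(ledger)
  if (!length(p$costs)) {
    return(tibble(subset = character(0), cost = numeric(0)))
  }
  subsets <- keys_to_strings(p$keys, ledger$width)
  o <- order(subsets, method = "radix")
  tibble(subset = subsets[o], cost = p$costs[o])
}

#' Best cost recorded so far
#' @param ledger An [evaluation_ledger()].
#' @return Minimum recorded cost, or `Inf` for an empty ledger.
#' @export
ledger_best <- function(ledger) {
  if (!utils::numhash(ledger$map)) return(Inf)
  best <- Inf
  utils::maphash(ledger$map, function(k, v) {
    if (v < best) best <<- v
  })
  best
}

ledger_clone <- function(ledger) {
  out <- evaluation_ledger()
  out$width <- ledger$width
  utils::maphash(ledger$map, function(k, v) utils::sethash(out$map, k, v))
  out
}

# union of memo maps; overlapping keys carry equal values (deterministic
# costs), so a plain overwrite merge is the set union
ledger_absorb <- function(target, source) {
  if (is.null(target$width)) target$width <- source$width
  utils::maphash(source$map, function(k, v) utils::sethash(target$map, k, v))
  invisible(target)
}

# minima among all evaluated elements (ties within COST_TOL of the
# minimum); only the argmin keys are decoded back to bit strings
ledger_minima <- function(ledger) {
  p <- ledger_pairs(ledger)
  if (!length(p$costs)) return(list(minima = character(0), best = Inf))
  best <- min(p$costs)
  keep <- cost_eq(p$costs, best) | p$costs <= best
  list(minima = sort(keys_to_strings(p$keys[keep], ledger$width)),
       best = best)
}
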