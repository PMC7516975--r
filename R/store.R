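#' Compressed subset-family store
#'
#' A store holding a family of fixed-width bit words — the collection of
#' outer-lattice elements still unexplored and unpruned during a search.
#' Its semantics are always those of an explicit set of words, but the
#' representation is a reduced ordered binary decision diagram (ROBDD), so
#' the initial state — the full family of \eqn{2^{dimension}} words — costs
#' O(1) and interval removals are BDD conjunctions with a negated cube,
#' never an enumeration.
#'
#' @param dimension Word width (number of fixed coordinates), >= 0.
#' @return An object of class `ucurve_store` containing all
#'   `2^dimension` words.
#' @examples
#' s <- store_full(20)
#' store_contains(s, strrep("01", 10))   # no enumeration involved
#' @export
store_full <- function(dimension) {
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 0L) {
    abort("dimension must be a non-negative integer")
  }
  s <- new.env(parent = emptyenv())
  s$dim <- dimension
  s$m <- bdd_manager(dimension)
  s$root <- BDD_T
  class(s) <- "ucurve_store"
  s
}

#' @export
print.ucurve_store <- function(x, ...) {
  cat("<subset-family store: width", x$dim, "holding", store_size(x),
      "words>\n")
  invisible(x)
}

store_bits <- function(store, w) {
  as_bits(w, store$dim)
}

#' @rdname store_full
#' @param store An `ucurve_store`.
#' @param w A word: bit string or integer 0/1 vector of the store's width.
#' @export
store_contains <- function(store, w) {
  bits <- store_bits(store, w)
  bdd_contains(store$m, store$root, bits)
}

#' @rdname store_full
#' @export
store_is_empty <- function(store) {
  store$root == BDD_F
}

#' @rdname store_full
#' @export
store_size <- function(store) {
  bdd_satcount(store$m, store$root)
}

#' Remove a whole interval from a store
#'
#' Deletes every word `w` with `lower` \eqn{\subseteq} `w`
#' \eqn{\subseteq} `upper` (bitwise) from the family; all other words are
#' untouched. This is the primitive behind interval pruning: the interval
#' predicate is a cube, and the removal is one conjunction with its
#' negation.
#'
#' @param store An `ucurve_store`.
#' @param lower,upper Words of the store's width with `lower`
#'   \eqn{\subseteq} `upper`.
#' @return The store, invisibly (modified in place).
#' @export
store_remove_interval <- function(store, lower, upper) {
  lo <- store_bits(store, lower)
  up <- store_bits(store, upper)
  if (any(lo > up)) abort("interval endpoints must satisfy lower ⊆ upper")
  cube <- bdd_interval_cube(store$m, lo, up)
  store$root <- bdd_and(store$m, store$root, bdd_not(store$m, cube))
  invisible(store)
}

#' Remove and return one word from a store
#'
#' Pops a uniformly random member, drawn with the search's own seeded RNG
#' stream so runs are reproducible; the word is removed from the family.
#'
#' @param store A non-empty `ucurve_store`.
#' @param rng An internal RNG stream (created per search from its seed).
#' @return Integer 0/1 vector of the popped word.
#' @export
store_pop <- function(store, rng) {
  if (store_is_empty(store)) abort("cannot pop from an empty store")
  bits <- bdd_pick(store$m, store$root, rng)
  store_remove_interval(store, bits, bits)
  bits
}
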