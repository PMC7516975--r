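#' Partition a ground set into fixed and free points
#'
#' Splits the ground set \eqn{S} into a fixed set \eqn{S'} and its
#' complement, the free set. The subsets of \eqn{S'} form the *outer*
#' Boolean lattice; each outer element anchors an *inner* Boolean lattice
#' isomorphic to \eqn{P(\bar{S'})}, and the \eqn{2^{|S'|}} inner lattices
#' are pairwise disjoint with union \eqn{P(S)}. The fixed-set size is
#' \eqn{\lceil p \, n \rceil}; which features become fixed is drawn
#' uniformly at random with the search's seeded stream unless `fixed`
#' names them explicitly.
#'
#' @param ground A [ground_set()].
#' @param p Proportion of features to fix, in \eqn{(0, 1]} (default 0.5).
#' @param seed Integer seed used when choosing fixed points at random.
#' @param fixed Optional character vector of feature names to fix,
#'   overriding the random choice (`p` is then ignored).
#' @param rng Internal: an existing RNG stream to draw from.
#' @return An object of class `ucurve_partition` with integer index
#'   vectors `fixed_idx` and `free_idx` into the lexicographic feature
#'   order.
#' @examples
#' part <- make_partition(ground_set(letters[1:5]), p = 0.4, seed = 1)
#' n_inner_lattices(part)   # 4: fixing 2 of 5 features
#' @export
make_partition <- function(ground, p = 0.5, seed = 1L, fixed = NULL,
                           rng = NULL) {
  stopifnot(inherits(ground, "ucurve_ground"))
  n <- ground$n
  if (!is.null(fixed)) {
    unknown <- setdiff(fixed, ground$features)
    if (length(unknown)) {
      abort(paste0("unknown feature name(s): ",
                   paste(unknown, collapse = ", ")))
    }
    fixed_idx <- sort(match(unique(fixed), ground$features))
  } else {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
      abort("p must lie in (0, 1]")
    }
    k <- as.integer(ceiling(p * n))
    rng <- rng %||% rng_new(seed)
    fixed_idx <- sort(rng_eval(rng, function() sample.int(n, k)))
  }
  structure(
    list(ground = ground, fixed_idx = fixed_idx,
         free_idx = setdiff(seq_len(n), fixed_idx)),
    class = "ucurve_partition"
  )
}

#' @export
print.ucurve_partition <- function(x, ...) {
  cat("<partition: ", length(x$fixed_idx), " fixed / ",
      length(x$free_idx), " free points; ",
      format(n_inner_lattices(x), big.mark = ","),
      " inner lattices>\n", sep = "")
  cat("  fixed: ", paste(x$ground$features[x$fixed_idx], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname make_partition
#' @param part An `ucurve_partition`.
#' @export
n_inner_lattices <- function(part) {
  stopifnot(inherits(part, "ucurve_partition"))
  2^length(part$fixed_idx)
}

# embed outer-lattice bits (over fixed coords) into a full-lattice bit
# vector, free coordinates set to `free_fill`
outer_to_full <- function(part, outer_bits, free_fill = 0L) {
  full <- integer(part$ground$n)
  full[part$fixed_idx] <- outer_bits
  if (free_fill == 1L) full[part$free_idx] <- 1L
  full
}
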