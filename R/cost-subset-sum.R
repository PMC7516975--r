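#' Subset-sum instance
#'
#' A subset-sum instance: one non-negative integer weight per feature and a
#' non-negative integer target \eqn{t}. The induced cost
#' \eqn{c(X) = |t - \sum_{x \in X} w_x|} decomposes into U-shaped curves on
#' every instance, which makes these the canonical "hard but well-behaved"
#' synthetic instances for U-curve solvers.
#'
#' @param weights Named numeric vector of non-negative integer weights; the
#'   names are the feature names.
#' @param target Non-negative integer target.
#' @return An object of class `ucurve_ssinst`.
#' @seealso [cost_subset_sum()], [gen_subset_sum_instance()]
#' @export
subset_sum_instance <- function(weights, target) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("weights must be a fully named vector (one weight per feature)")
  }
  w <- as.double(weights)
  if (anyNA(w) || any(w < 0) || any(w != floor(w))) {
    abort("weights must be non-negative integers")
  }
  target <- as.double(target)
  if (length(target) != 1L || is.na(target) || target < 0 ||
      target != floor(target)) {
    abort("target must be a single non-negative integer")
  }
  ground <- ground_set(names(weights))
  structure(
    list(weights = setNames(w[match(ground$features, names(weights))],
                            ground$features),
         target = target, ground = ground),
    class = "ucurve_ssinst"
  )
}

#' @export
print.ucurve_ssinst <- function(x, ...) {
  cat("<subset-sum instance: n =", x$ground$n, " target =", x$target, ">\n")
  invisible(x)
}

#' Subset-sum cost function
#'
#' The absolute deviation of the selected weights' sum from the target:
#' \eqn{c(X) = |t - \sum_{x \in X} w_x|}. Integer-valued, zero exactly on
#' subsets that hit the target.
#'
#' @param inst A [subset_sum_instance()].
#' @return A [cost_fn()] over the instance's features.
#' @examples
#' inst <- subset_sum_instance(c(a = 2, b = 3, c = 5), target = 8)
#' cost <- cost_subset_sum(inst)
#' eval_cost(cost, evaluation_ledger(), feature_set(c("b", "c"), inst$ground))
#' @export
cost_subset_sum <- function(inst) {
  stopifnot(inherits(inst, "ucurve_ssinst"))
  w <- unname(inst$weights)
  t <- inst$target
  cost_fn(function(bits) abs(t - sum(w * bits)),
          inst$ground, name = "subset-sum")
}

#' Read / write a subset-sum instance as JSON
#'
#' The serialized form is `{"weights": {"name": w, ...}, "target": t}`.
#'
#' @param path File path.
#' @return `read_subset_sum()` returns a [subset_sum_instance()];
#'   `write_subset_sum()` returns `path` invisibly.
#' @export
read_subset_sum <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$weights) || is.null(x$target)) {
    abort("subset-sum JSON must have fields \"weights\" and \"target\"")
  }
  subset_sum_instance(unlist(x$weights), x$target)
}

#' @rdname read_subset_sum
#' @param inst A [subset_sum_instance()].
#' @export
write_subset_sum <- function(inst, path) {
  stopifnot(inherits(inst, "ucurve_ssinst"))
  jsonlite::write_json(
    list(weights = as.list(inst$weights), target = inst$target),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Explicit-table cost function
#'
#' A cost function given by an exhaustive lookup table, mainly for building
#' hand-crafted fixtures (U-decomposable or deliberately oscillating).
#'
#' @param values Named numeric vector: one non-negative cost per canonical
#'   bit string, covering all \eqn{2^n} subsets.
#' @param ground A [ground_set()] of matching width.
#' @return A [cost_fn()].
#' @examples
#' g <- ground_set(c("a", "b"))
#' cost <- cost_table(c("00" = 1, "01" = 0, "10" = 3, "11" = 1), g)
#' is_u_decomposable(cost)  # FALSE: spike at {a}
#' @export
cost_table <- function(values, ground) {
  stopifnot(inherits(ground, "ucurve_ground"))
  n <- ground$n
  if (is.null(names(values))) abort("values must be named by bit strings")
  keys <- vapply(seq_len(2^n) - 1L, function(i) {
    bits_to_string(bitwAnd(i %/% 2^(n - seq_len(n)), 1L))
  }, character(1))
  missing <- setdiff(keys, names(values))
  if (length(missing)) {
    abort(paste0("cost table is missing subset(s): ",
                 paste(head(missing, 5L), collapse = ", "),
                 if (length(missing) > 5L) " ..." else ""))
  }
  if (any(values < 0)) abort("costs must be non-negative")
  tab <- values
  cost_fn(function(bits) unname(tab[[bits_to_string(bits)]]),
          ground, name = "table")
}

#' Projected (wrapper) cost on an inner Boolean lattice
#'
#' Given a partition of the ground set into fixed and free points, the cost
#' of an element \eqn{Y} of the inner lattice anchored at the outer element
#' \eqn{X} is the base cost of the union, \eqn{c_X(Y) = c(X \cup Y)}. All
#' evaluations flow through the shared `ledger`, so work is counted once
#' across inner lattices.
#'
#' @param base A [cost_fn()] over the full ground set.
#' @param part A [make_partition()] of that ground set.
#' @param anchor Outer-lattice element: bit string / bit vector over the
#'   partition's fixed coordinates, or an `ucurve_fset` over the full
#'   ground set supported on the fixed points only.
#' @param ledger Shared [evaluation_ledger()] receiving all evaluations.
#' @return A [cost_fn()] over the free features.
#' @export
cost_project <- function(base, part, anchor, ledger = evaluation_ledger()) {
  stopifnot(inherits(part, "ucurve_partition"))
  n <- base$ground$n
  if (inherits(anchor, "ucurve_fset")) {
    check_same_ground(anchor, list(ground = base$ground))
    if (any(anchor$bits[part$free_idx] == 1L)) {
      abort("anchor must be supported on the fixed points only")
    }
    abits <- anchor$bits[part$fixed_idx]
  } else {
    abits <- as_bits(anchor, length(part$fixed_idx))
  }
  full <- integer(n)
  full[part$fixed_idx] <- abits
  free_idx <- part$free_idx
  fn <- if (n <= KEY_CHUNK) {
    # hot path: the memo key of X ∪ Y is the anchor's packed value plus
    # the free bits' contribution, so no full-width repacking per call
    base_key <- sum(full * POW2(n))
    pow_free <- POW2(n)[free_idx]
    map <- ledger$map
    base_eval <- base$eval
    function(bits) {
      key <- base_key + sum(bits * pow_free)
      v <- utils::gethash(map, key)
      if (!is.null(v)) return(v)
      fb <- full
      fb[free_idx] <- bits
      if (is.null(ledger$width)) ledger$width <- n
      v <- as.double(base_eval(fb))
      if (!is.finite(v) || v < 0) {
        abort(paste0("cost function \"", base$name,
                     "\" returned an invalid value at subset ",
                     bits_to_string(fb)))
      }
      utils::sethash(map, key, v)
      v
    }
  } else {
    function(bits) {
      fb <- full
      fb[free_idx] <- bits
      eval_cost_bits(base, ledger, fb)
    }
  }
  cost_fn(fn, ground_set(base$ground$features[free_idx]),
          name = paste0(base$name, "|", bits_to_string(abits)))
}
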