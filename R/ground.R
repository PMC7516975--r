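#' Ground feature set
#'
#' The ground set \eqn{S} of a feature-selection instance: the full set of
#' candidate features, held in lexicographic order. All subsets are encoded
#' as fixed-width bit strings whose leftmost digit corresponds to the first
#' feature in this order, e.g. over \eqn{S = \{c, b, e, d, a\}} (sorted to
#' `a, b, c, d, e`) the subset `{b, e}` is the string `"01001"`.
#'
#' @param features Character vector of unique feature names.
#' @return An object of class `ucurve_ground` with fields `features`
#'   (sorted names) and `n`.
#' @examples
#' g <- ground_set(c("c", "b", "e", "d", "a"))
#' g$features
#' @export
ground_set <- function(features) {
  features <- as.character(features)
  if (length(features) < 1L) {
    abort("a ground set needs at least one feature")
  }
  if (anyNA(features)) abort("feature names must not be NA")
  if (anyDuplicated(features)) {
    abort(paste0(
      "duplicated feature name(s): ",
      paste(unique(features[duplicated(features)]), collapse = ", ")
    ))
  }
  features <- sort(features, method = "radix")
  structure(list(features = features, n = length(features)),
            class = "ucurve_ground")
}

#' @export
print.ucurve_ground <- function(x, ...) {
  cat("<ground set of", x$n, "features>\n")
  cat(" ", paste(head(x$features, 10L), collapse = ", "),
      if (x$n > 10L) "..." else "", "\n")
  invisible(x)
}

same_ground <- function(a, b) {
  identical(a$features, b$features)
}

#' Encode a feature subset as a bit string
#'
#' Encodes a set of feature names over a ground set as a fixed-width binary
#' word: bit \eqn{i} is 1 iff the \eqn{i}-th feature in lexicographic order
#' belongs to the subset.
#'
#' @param names Character vector of feature names (possibly empty).
#' @param ground A [ground_set()].
#' @return An object of class `ucurve_fset`.
#' @examples
#' g <- ground_set(c("c", "b", "e", "d", "a"))
#' feature_set(c("b", "e"), g)   # "01001"
#' @export
feature_set <- function(names, ground) {
  names <- as.character(names)
  unknown <- setdiff(names, ground$features)
  if (length(unknown)) {
    abort(paste0("unknown feature name(s): ", paste(unknown, collapse = ", ")))
  }
  new_fset(as.integer(ground$features %in% names), ground)
}

new_fset <- function(bits, ground) {
  structure(list(bits = as.integer(bits), ground = ground),
            class = "ucurve_fset")
}

#' Parse a canonical bit string into a feature subset
#'
#' @param string A string of `0`/`1` digits of width `ground$n`.
#' @param ground A [ground_set()].
#' @return An `ucurve_fset`.
#' @examples
#' g <- ground_set(letters[1:5])
#' feature_members(parse_subset("01001", g))
#' @export
parse_subset <- function(string, ground) {
  bits <- bits_from_string(string, ground$n)
  new_fset(bits, ground)
}

bits_from_string <- function(string, width) {
  stopifnot(is.character(string), length(string) == 1L)
  if (nchar(string) != width) {
    abort(paste0("expected a bit string of width ", width,
                 ", got \"", string, "\""))
  }
  bits <- as.integer(strsplit(string, "", fixed = TRUE)[[1]])
  if (anyNA(bits) || any(bits > 1L)) {
    abort(paste0("not a binary string: \"", string, "\""))
  }
  bits
}

bits_to_string <- function(bits) {
  paste(bits, collapse = "")
}

# accept fset | bit string | integer bits, return integer bits of given width
as_bits <- function(x, width) {
  if (inherits(x, "ucurve_fset")) x <- x$bits
  if (is.character(x)) x <- bits_from_string(x, width)
  x <- as.integer(x)
  if (length(x) != width) {
    abort(paste0("bit width mismatch: expected ", width, ", got ", length(x)))
  }
  if (anyNA(x) || any(x < 0L | x > 1L)) abort("bits must be 0 or 1")
  x
}

#' @export
format.ucurve_fset <- function(x, ...) bits_to_string(x$bits)

#' @export
print.ucurve_fset <- function(x, ...) {
  cat("<subset ", bits_to_string(x$bits), ">  {",
      paste(feature_members(x), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
as.character.ucurve_fset <- function(x, ...) bits_to_string(x$bits)

#' Feature names present in a subset
#' @param x An `ucurve_fset`.
#' @return Character vector of member names.
#' @export
feature_members <- function(x) {
  stopifnot(inherits(x, "ucurve_fset"))
  x$ground$features[x$bits == 1L]
}

check_same_ground <- function(a, b) {
  if (!same_ground(a$ground, b$ground)) {
    abort("feature sets are defined over different ground sets")
  }
  invisible(TRUE)
}

#' Subset relation between two feature sets
#'
#' Bitwise containment test: `is_subset_of(a, b)` is `TRUE` iff every
#' feature of `a` is also in `b`.
#'
#' @param a,b `ucurve_fset` objects over the same ground set.
#' @return Logical scalar.
#' @export
is_subset_of <- function(a, b) {
  check_same_ground(a, b)
  all(a$bits <= b$bits)
}

#' Lattice interval \eqn{[X, Y]}
#'
#' The interval \eqn{[X, Y] = \{A : X \subseteq A \subseteq Y\}} of the
#' Boolean lattice, the unit in which the search space is pruned.
#'
#' @param lower,upper `ucurve_fset` objects with `lower` contained in
#'   `upper`.
#' @return An object of class `ucurve_interval`.
#' @export
interval <- function(lower, upper) {
  check_same_ground(lower, upper)
  if (!all(lower$bits <= upper$bits)) {
    abort("interval endpoints must satisfy lower ⊆ upper")
  }
  structure(list(lower = lower, upper = upper), class = "ucurve_interval")
}

#' @export
print.ucurve_interval <- function(x, ...) {
  cat("<interval [", bits_to_string(x$lower$bits), ", ",
      bits_to_string(x$upper$bits), "]>\n", sep = "")
  invisible(x)
}

#' Interval membership
#'
#' @param iv An [interval()].
#' @param a An `ucurve_fset` over the same ground set.
#' @return `TRUE` iff `lower` \eqn{\subseteq} `a` \eqn{\subseteq} `upper`.
#' @examples
#' g <- ground_set(letters[1:5])
#' iv <- interval(parse_subset("01001", g), parse_subset("11111", g))
#' interval_contains(iv, parse_subset("00001", g))  # FALSE
#' @export
interval_contains <- function(iv, a) {
  check_same_ground(iv$lower, a)
  all(iv$lower$bits <= a$bits) && all(a$bits <= iv$upper$bits)
}

# bit matrix of all 2^n subsets, row i+1 = binary digits of i,
# leftmost column = first lexicographic feature (most significant digit)
all_subsets_bits <- function(n) {
  stopifnot(n >= 0L, n <= 25L)
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  idx <- 0:(2^n - 1)
  m <- matrix(0L, nrow = length(idx), ncol = n)
  for (j in seq_len(n)) {
    m[, j] <- bitwAnd(idx %/% 2^(n - j), 1L)
  }
  m
}

# row index (1-based) of a bit vector in all_subsets_bits(n)
bits_to_index <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1)) + 1
}
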