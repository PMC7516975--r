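# ---- sample tables -------------------------------------------------------
# A sample table is a data frame of discrete feature columns plus a label
# column (default "label") and an optional "multiplicity" column counting
# repeated samples. Feature order is always the lexicographic order of the
# column names, matching the canonical bit-string encoding.

sample_table_parts <- function(data, label = "label") {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  if (!nrow(data)) abort("the sample table is empty")
  if (!label %in% names(data)) {
    abort(paste0("label column \"", label, "\" not found"))
  }
  mult_col <- "multiplicity" %in% names(data)
  feat <- setdiff(names(data), c(label, if (mult_col) "multiplicity"))
  if (!length(feat)) abort("the sample table has no feature columns")
  ground <- ground_set(feat)
  m <- matrix(0L, nrow = nrow(data), ncol = ground$n)
  for (j in seq_len(ground$n)) {
    col <- data[[ground$features[j]]]
    codes <- as.integer(factor(col))
    if (anyNA(codes)) {
      abort(paste0("feature \"", ground$features[j],
                   "\" has missing values; features must be discrete"))
    }
    m[, j] <- codes - 1L
  }
  y <- as.integer(factor(data[[label]]))
  labels <- levels(factor(data[[label]]))
  mult <- if (mult_col) as.double(data[["multiplicity"]]) else rep(1, nrow(data))
  if (any(mult < 1) || any(mult != floor(mult))) {
    abort("multiplicities must be integers >= 1")
  }
  list(ground = ground, m = m, y = y, labels = labels, mult = mult,
       total = sum(mult), card = apply(m, 2, max) + 1L)
}

# combine selected feature columns into one realization id per row;
# mixed-radix when it fits in a double, string paste otherwise
realization_ids <- function(parts, sel) {
  t <- nrow(parts$m)
  if (!length(sel)) return(rep.int(1L, t))
  card <- parts$card[sel]
  if (prod(card) < 2^52) {
    key <- numeric(t)
    r <- 1
    for (k in seq_along(sel)) {
      key <- key + parts$m[, sel[k]] * r
      r <- r * card[k]
    }
  } else {
    key <- do.call(paste, c(lapply(sel, function(j) parts$m[, j]), sep = "\r"))
  }
  match(key, unique(key))
}

#' Project a sample table onto a feature subset
#'
#' Aggregates the samples by the realization of the selected features,
#' giving the empirical per-label counts for every observed realization —
#' the empirical distribution the mean-conditional-entropy criterion is
#' built on. Projecting onto no features yields a single realization with
#' the full label histogram.
#'
#' @param data A sample table: data frame with discrete feature columns, a
#'   label column, and an optional `multiplicity` column.
#' @param features Character vector of feature names to project onto (may
#'   be empty).
#' @param label Name of the label column (default `"label"`).
#' @return A tibble with the selected feature columns, `label`, and the
#'   aggregated count `n`; `sum(n)` equals the total sample count.
#' @examples
#' tab <- tibble::tibble(f1 = c(0, 0, 1), f2 = c(0, 1, 0),
#'                       label = c("y0", "y1", "y0"))
#' project_counts(tab, "f1")
#' @export
project_counts <- function(data, features, label = "label") {
  parts <- sample_table_parts(data, label)
  features <- as.character(features)
  unknown <- setdiff(features, parts$ground$features)
  if (length(unknown)) {
    abort(paste0("unknown feature name(s): ", paste(unknown, collapse = ", ")))
  }
  sel <- which(parts$ground$features %in% features)
  ids <- realization_ids(parts, sel)
  key <- (ids - 1) * (max(parts$y) + 1L) + parts$y
  agg <- rowsum(parts$mult, key)
  kv <- as.numeric(rownames(agg))
  rid <- (kv - 1) %/% (max(parts$y) + 1L) + 1
  yid <- kv - (rid - 1) * (max(parts$y) + 1L)
  first_row <- match(rid, ids)
  out <- tibble(.rows = length(kv))
  for (j in sel) {
    out[[parts$ground$features[j]]] <- data[[parts$ground$features[j]]][first_row]
  }
  out[[label]] <- parts$labels[yid]
  out$n <- as.vector(agg)
  dplyr::arrange(out, dplyr::across(dplyr::everything()))
}

#' Conditional entropy of a label histogram
#'
#' Shannon entropy of the empirical label distribution given one
#' realization, \eqn{-\sum_y p_y \log_{|L|} p_y}, with the logarithm taken
#' in base \eqn{|L|} (the number of classes) so that the uniform
#' distribution has entropy exactly 1. Zero counts contribute nothing
#' (\eqn{0 \log 0 \equiv 0}).
#'
#' @param counts Non-negative numeric vector of per-label counts; must not
#'   be all zero.
#' @param n_labels Number of classes \eqn{|L|} (at least 2).
#' @return Entropy in \eqn{[0, 1]}.
#' @examples
#' conditional_entropy(c(3, 1), 2)   # 0.8113
#' @export
conditional_entropy <- function(counts, n_labels) {
  counts <- as.double(counts)
  if (anyNA(counts) || any(counts < 0)) abort("counts must be non-negative")
  tot <- sum(counts)
  if (tot < 1) abort("counts must sum to at least 1")
  if (n_labels < 2L) abort("n_labels must be at least 2")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = n_labels))
}

# core penalized-MCE evaluation given precomputed table parts and a
# selected-column index vector
mce_eval <- function(parts, sel) {
  ids <- realization_ids(parts, sel)
  nlab <- max(parts$y)
  key <- (ids - 1) * (nlab + 1L) + parts$y
  cnt <- rowsum(parts$mult, key)[, 1L]
  kv <- as.numeric(names(cnt))
  rid <- (kv - 1) %/% (nlab + 1L) + 1
  tot <- rowsum(cnt, rid)[, 1L]
  tot_of <- tot[match(as.character(rid), names(tot))]
  t <- parts$total
  nclasses <- max(2L, length(parts$labels))
  singleton <- tot_of == 1
  N <- sum(cnt[singleton])
  keep <- !singleton
  if (!any(keep)) return(N / t)
  # H(Y|x) * P(x) summed over realizations seen at least twice; expanding
  # the per-label terms lets the realization weights tot/t distribute in
  p <- cnt[keep] / tot_of[keep]
  h <- -p * log(p, base = nclasses)
  N / t + sum(h * tot_of[keep]) / t
}

#' Penalized mean conditional entropy of a feature subset
#'
#' The mean conditional entropy (MCE) of the label given the selected
#' features, estimated from the sample table, with a penalty for
#' underrepresented realizations: a realization observed exactly once is
#' charged the maximal entropy 1 (as if its label were uniform), so the
#' singletons contribute \eqn{N/t} in total, where \eqn{N} is the number of
#' samples whose realization occurs once and \eqn{t} the sample count.
#' Realizations observed at least twice contribute their empirical
#' conditional entropy weighted by their empirical probability:
#' \deqn{c(X) = N/t + \sum_{x : \hat{P}(x) > 1/t}
#'   \hat{H}(Y \mid X = x)\, \hat{P}(x).}
#' With the base-\eqn{|L|} logarithm the value always lies in \eqn{[0, 1]}.
#'
#' @inheritParams project_counts
#' @return Cost in \eqn{[0, 1]}.
#' @examples
#' tab <- tibble::tibble(f1 = c(0, 0, 1, 1), label = c(0, 1, 0, 0))
#' penalized_mce(tab, "f1")   # 0.5
#' @export
penalized_mce <- function(data, features, label = "label") {
  parts <- sample_table_parts(data, label)
  features <- as.character(features)
  unknown <- setdiff(features, parts$ground$features)
  if (length(unknown)) {
    abort(paste0("unknown feature name(s): ", paste(unknown, collapse = ", ")))
  }
  mce_eval(parts, which(parts$ground$features %in% features))
}

#' Penalized-MCE cost function over a sample table
#'
#' Packages [penalized_mce()] as a [cost_fn()] over the table's features,
#' ready for any of the search algorithms.
#'
#' @inheritParams project_counts
#' @return A [cost_fn()] named `"mce"`.
#' @export
cost_mce <- function(data, label = "label") {
  parts <- sample_table_parts(data, label)
  cost_fn(function(bits) mce_eval(parts, which(bits == 1L)),
          parts$ground, name = "mce")
}
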