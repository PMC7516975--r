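new_feature_search <- function(algorithm, cost, ledger, params = list(),
                               prune_log = NULL) {
  mm <- ledger_minima(ledger)
  structure(
    list(
      algorithm = algorithm,
      cost_name = cost$name,
      ground = cost$ground,
      minima = mm$minima,
      best_cost = mm$best,
      ledger = ledger,
      params = params,
      prune_log = prune_log
    ),
    class = "feature_search"
  )
}

#' @export
print.feature_search <- function(x, ...) {
  cat("U-curve feature search (", x$algorithm, ", cost = ", x$cost_name,
      ")\n", sep = "")
  cat("  features:       ", x$ground$n, "\n")
  cat("  best cost:      ", format(x$best_cost, digits = 10), "\n")
  cat("  minima found:   ", length(x$minima), "  e.g. ",
      head(x$minima, 1L), "\n", sep = "")
  cat("  cost calls:     ", ledger_calls(x$ledger), " of ",
      2^x$ground$n, " subsets\n", sep = "")
  if (!is.null(x$prune_log) && nrow(x$prune_log)) {
    cat("  pruning events: ", nrow(x$prune_log), "\n")
  }
  invisible(x)
}

#' Tidy the minima of a feature search
#'
#' One row per minimum-cost subset found, with the canonical bit string,
#' the member features, the subset size, and the cost.
#'
#' @param x A `feature_search` object.
#' @param ... Unused.
#' @return A tibble with columns `subset`, `features`, `size`, `cost`.
#' @method tidy feature_search
#' @export
tidy.feature_search <- function(x, ...) {
  tibble(
    subset = x$minima,
    features = vapply(x$minima, function(s) {
      paste(feature_members(parse_subset(s, x$ground)), collapse = ",")
    }, character(1), USE.NAMES = FALSE),
    size = vapply(x$minima, function(s) {
      sum(bits_from_string(s, x$ground$n))
    }, integer(1), USE.NAMES = FALSE),
    cost = x$best_cost
  )
}

#' One-row summary of a feature search
#'
#' @param x A `feature_search` object.
#' @param ... Unused.
#' @return A tibble with the algorithm, problem size, best cost, number of
#'   minima, distinct cost-function calls, and pruning-event count.
#' @method glance feature_search
#' @export
glance.feature_search <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    cost = x$cost_name,
    n_features = x$ground$n,
    best_cost = x$best_cost,
    n_minima = length(x$minima),
    cost_calls = ledger_calls(x$ledger),
    prune_events = if (is.null(x$prune_log)) 0L else nrow(x$prune_log)
  )
}

#' Plot the evaluated landscape of a feature search
#'
#' Scatter of every evaluated subset's cost against its cardinality, with
#' the minima highlighted — the U-shape (or its violations) made visible.
#'
#' @param object A `feature_search` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_search
#' @export
autoplot.feature_search <- function(object, ...) {
  tb <- ledger_tbl(object$ledger)
  tb$size <- vapply(tb$subset, function(s) sum(bits_from_string(s, object$ground$n)),
                    integer(1), USE.NAMES = FALSE)
  tb$minimum <- tb$subset %in% object$minima
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$size, y = .data$cost)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.4,
                         ggplot2::aes(colour = .data$minimum)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "subset cardinality", y = "cost",
                  colour = "minimum",
                  title = paste0("Evaluated subsets (", object$algorithm,
                                 ", ", object$cost_name, ")")) +
    ggplot2::theme_minimal()
}
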