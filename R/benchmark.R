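# dispatch a named algorithm on a cost function
run_algorithm <- function(algorithm, cost, seed = 1L, params = list()) {
  switch(algorithm,
    es = search_exhaustive(cost, force = TRUE),
    ubb = search_ubb(cost, force = TRUE),
    sfs = search_sfs(cost),
    sffs = search_sffs(cost, delta = params$delta %||% 3L),
    pucs = search_pucs(cost,
                       p = params$p, l = params$l %||% 1L,
                       base = params$base, seed = seed,
                       workers = params$workers %||% 1L),
    abort(paste0("unknown algorithm \"", algorithm, "\""))
  )
}

#' Benchmark search algorithms on a set of instances
#'
#' Runs each algorithm on each instance and reports, per (algorithm,
#' instance) cell: the best cost found, the distinct cost-function calls
#' (the hardware-independent work measure, taken from the merged ledger),
#' the wall time, and — when the exhaustive oracle is feasible — whether
#' the algorithm hit the global optimum.
#'
#' @param instances A list of [cost_fn()] objects and/or
#'   [subset_sum_instance()]s (coerced with [cost_subset_sum()]).
#' @param algorithms Character vector among `"pucs"`, `"es"`, `"ubb"`,
#'   `"sfs"`, `"sffs"`.
#' @param seed Integer seed; each (algorithm, instance) cell gets a
#'   deterministic child seed.
#' @param oracle_max Run the exhaustive oracle (for the `optimal` flag)
#'   only when the instance has at most this many features; larger
#'   instances get `optimal = NA`.
#' @param params Named list of per-algorithm parameter lists, e.g.
#'   `list(pucs = list(p = 0.5, base = "ubb"))`.
#' @return A tibble of class `ucurve_benchmark`: columns `instance`,
#'   `algorithm`, `n_features`, `best_cost`, `cost_calls`, `seconds`,
#'   `optimal`.
#' @examples
#' insts <- lapply(1:3, function(i) gen_subset_sum_instance(6, seed = i))
#' run_benchmark(insts, c("pucs", "sfs"), seed = 1)
#' @export
run_benchmark <- function(instances, algorithms = c("pucs", "sfs"),
                          seed = 1L, oracle_max = 16L, params = list()) {
  if (!length(instances)) abort("no instances supplied")
  costs <- lapply(instances, function(x) {
    if (inherits(x, "ucurve_ssinst")) cost_subset_sum(x)
    else if (inherits(x, "ucurve_cost")) x
    else abort("instances must be cost functions or subset-sum instances")
  })
  rows <- list()
  for (i in seq_along(costs)) {
    cost <- costs[[i]]
    n <- cost$ground$n
    oracle_best <- if (n <= oracle_max) {
      search_exhaustive(cost, force = TRUE)$best_cost
    } else {
      NA_real_
    }
    for (alg in algorithms) {
      t0 <- proc.time()[["elapsed"]]
      fit <- run_algorithm(alg, cost, seed = rng_child_seed(seed, i),
                           params = params[[alg]] %||% list())
      el <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1L]] <- tibble(
        instance = i,
        algorithm = alg,
        n_features = n,
        best_cost = fit$best_cost,
        cost_calls = ledger_calls(fit$ledger),
        seconds = el,
        optimal = if (is.na(oracle_best)) NA else
          cost_eq(fit$best_cost, oracle_best)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ucurve_benchmark", class(out))
  out
}

#' Summarize a benchmark: best-solution proportions
#'
#' For each algorithm: the proportion of instances on which it found the
#' best solution among all benchmarked algorithms, the optimal-hit
#' proportion (where the oracle ran), and mean calls/time.
#'
#' @param report A [run_benchmark()] tibble.
#' @return A tibble with one row per algorithm.
#' @export
summarize_benchmark <- function(report) {
  best_by_inst <- report |>
    dplyr::group_by(.data$instance) |>
    dplyr::mutate(found_best = cost_eq(.data$best_cost,
                                       min(.data$best_cost))) |>
    dplyr::ungroup()
  best_by_inst |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      n_instances = dplyr::n(),
      best_solution_prop = mean(.data$found_best),
      optimal_prop = if (all(is.na(.data$optimal))) NA_real_ else
        mean(.data$optimal, na.rm = TRUE),
      mean_calls = mean(.data$cost_calls),
      mean_seconds = mean(.data$seconds),
      .groups = "drop"
    )
}

#' Write a benchmark report to TSV and JSON
#'
#' @param report A [run_benchmark()] tibble.
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_benchmark <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    readr::write_tsv(report, tsv, progress = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}

#' Plot a benchmark report
#'
#' Distinct cost-function calls per algorithm across instances, on a log
#' scale — the hardware-independent cost of each search.
#'
#' @param object A [run_benchmark()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ucurve_benchmark
#' @export
autoplot.ucurve_benchmark <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$algorithm, y = .data$cost_calls,
                               colour = .data$algorithm)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "distinct cost-function calls") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
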