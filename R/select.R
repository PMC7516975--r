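#' Select features from a labelled sample table
#'
#' The front door of the package: takes a data frame of discrete features
#' plus a label column, scores subsets with the penalized mean conditional
#' entropy criterion, and minimizes it with the chosen search algorithm
#' (PUCS by default). Results carry the full evaluation ledger and support
#' [tidy()], [glance()] and [autoplot()].
#'
#' @param data Data frame: discrete feature columns, a label column, and
#'   an optional `multiplicity` count column.
#' @param label Name of the label column (default `"label"`).
#' @param algorithm `"pucs"` (default), `"es"`, `"ubb"`, `"sfs"` or
#'   `"sffs"`.
#' @param cost `"mce"` (default) or a ready-made [cost_fn()] whose ground
#'   set matches the feature columns.
#' @param seed Integer seed for the randomized choices.
#' @param ... Passed to the search: `p`, `l`, `base`, `workers`, `fixed`
#'   for PUCS; `delta` for SFFS; `force` for the exhaustive solvers.
#' @return A `feature_search` object.
#' @examples
#' tab <- gen_mce_dataset(n = 6, k = 2, t = 300, noise_rate = 0.1, seed = 7)
#' fit <- select_features(tab, algorithm = "pucs", seed = 1)
#' tidy(fit)
#' @export
select_features <- function(data, label = "label",
                            algorithm = c("pucs", "es", "ubb", "sfs", "sffs"),
                            cost = "mce", seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  cf <- if (inherits(cost, "ucurve_cost")) {
    cost
  } else if (identical(cost, "mce")) {
    cost_mce(data, label = label)
  } else {
    abort("cost must be \"mce\" or a cost_fn object")
  }
  dots <- list(...)
  switch(algorithm,
    pucs = search_pucs(cf, p = dots$p, l = dots$l %||% 1L,
                       base = dots$base, seed = seed,
                       workers = dots$workers %||% 1L, fixed = dots$fixed),
    es = search_exhaustive(cf, force = isTRUE(dots$force)),
    ubb = search_ubb(cf, force = isTRUE(dots$force)),
    sfs = search_sfs(cf),
    sffs = search_sffs(cf, delta = dots$delta %||% 3L)
  )
}
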