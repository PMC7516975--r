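#' Read a whitespace-separated sample table (.dat)
#'
#' Reads the plain benchmarking format for discrete labelled samples: one
#' sample per line, whitespace-separated integer feature values followed by
#' the integer class label (labels `0..K`) in the last column. Features are
#' named `f01, f02, ...` in column order, which is also their lexicographic
#' order.
#'
#' @param path File path.
#' @return A tibble with integer feature columns and a `label` column.
#' @seealso [read_sample_csv()], [write_sample_dat()]
#' @export
read_sample_dat <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) < 2L) abort("a .dat sample table needs >= 1 feature + label")
  storage.mode(m) <- "integer"
  n <- ncol(m) - 1L
  out <- as_tibble(as.data.frame(m[, seq_len(n), drop = FALSE]))
  names(out) <- sprintf("f%0*d", max(2L, nchar(n)), seq_len(n))
  out$label <- m[, n + 1L]
  out
}

#' @rdname read_sample_dat
#' @param data Sample table (data frame with feature columns and `label`).
#' @param label Name of the label column.
#' @export
write_sample_dat <- function(data, path, label = "label") {
  parts <- sample_table_parts(data, label)
  cols <- lapply(parts$ground$features, function(f) {
    v <- data[[f]]
    if (is.numeric(v)) as.integer(v) else as.integer(factor(v)) - 1L
  })
  y <- data[[label]]
  y <- if (is.numeric(y)) as.integer(y) else as.integer(factor(y)) - 1L
  m <- cbind(do.call(cbind, cols), y)
  m <- m[rep(seq_len(nrow(m)), times = parts$mult), , drop = FALSE]
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a CSV sample table
#'
#' CSV with a header; the label column must be named `label`; every other
#' column (except an optional `multiplicity`) is a discrete feature.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"label" %in% names(out)) {
    abort("CSV sample tables must have a column named \"label\"")
  }
  out
}
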