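#' Generate a random subset-sum instance
#'
#' Draws \eqn{n + 1} random integers: \eqn{n} weights uniform on
#' \eqn{\{0, \ldots, 10n\}} and a target uniform on
#' \eqn{\{0, \ldots, \sum w\}}. The induced cost \eqn{|t - \sum_{x \in X}
#' w_x|} decomposes into U-shaped curves on every instance, giving hard
#' but well-behaved synthetic benchmarks whose optimum is neither the
#' empty nor the full set systematically.
#'
#' @param n Number of features (>= 1).
#' @param seed Integer seed; a fixed seed reproduces the instance bit for
#'   bit.
#' @return A [subset_sum_instance()].
#' @export
gen_subset_sum_instance <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("n must be a positive integer")
  rng <- rng_new(seed)
  w <- rng_uint(rng, n, 10L * n)
  t <- rng_eval(rng, function() sample.int(sum(w) + 1L, 1L) - 1L)
  width <- max(2L, nchar(n))
  subset_sum_instance(setNames(w, sprintf("f%0*d", width, seq_len(n))), t)
}

#' Generate a noisy discrete classification table
#'
#' Emulates training data whose label is a Boolean function of a planted
#' subset of binary features, corrupted by label-flip noise — the same
#' regime as binary images covered with uniformly distributed
#' salt-and-pepper noise. Feature vectors are uniform random bits; the
#' label is `rule` applied to the `k` planted features, then flipped with
#' probability `noise_rate` (default 0.3, the 30% corruption regime).
#'
#' @param n Number of binary features.
#' @param k Number of planted (informative) features, `1 <= k <= n`.
#' @param t Number of samples.
#' @param noise_rate Label-flip probability in `[0, 0.5)`.
#' @param rule `"parity"` (default; fully multivariate, invisible to any
#'   proper subset of the planted features) or `"majority"`.
#' @param seed Integer seed.
#' @return A tibble with binary feature columns and a `label` column; the
#'   planted feature names are attached as attribute `"planted"`.
#' @examples
#' tab <- gen_mce_dataset(n = 6, k = 2, t = 200, noise_rate = 0, seed = 1)
#' penalized_mce(tab, attr(tab, "planted"))   # 0 when noise-free
#' @export
gen_mce_dataset <- function(n, k, t, noise_rate = 0.3,
                            rule = c("parity", "majority"), seed = 1L) {
  rule <- match.arg(rule)
  n <- as.integer(n)
  k <- as.integer(k)
  t <- as.integer(t)
  if (is.na(n) || n < 1L) abort("n must be a positive integer")
  if (is.na(k) || k < 1L || k > n) abort("k must satisfy 1 <= k <= n")
  if (is.na(t) || t < 1L) abort("t must be a positive integer")
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 0.5) {
    abort("noise_rate must lie in [0, 0.5)")
  }
  rng <- rng_new(seed)
  width <- max(2L, nchar(n))
  feats <- sprintf("f%0*d", width, seq_len(n))
  planted <- sort(rng_eval(rng, function() sample(feats, k)))
  m <- matrix(rng_uint(rng, n * t, 1L), nrow = t, ncol = n,
              dimnames = list(NULL, feats))
  sums <- rowSums(m[, planted, drop = FALSE])
  y <- if (rule == "parity") sums %% 2L else as.integer(sums > k / 2)
  flip <- rng_runif(rng, t) < noise_rate
  y <- as.integer(xor(y == 1L, flip))
  out <- as_tibble(as.data.frame(m))
  out$label <- y
  attr(out, "planted") <- planted
  attr(out, "rule") <- rule
  out
}
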