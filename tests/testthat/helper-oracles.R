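# Independent oracles used across the suite. These deliberately use the
# dumbest possible representations so they cannot share a bug with the
# package's compressed / incremental implementations.

# all subsets of width d as canonical bit strings
all_words <- function(d) {
  if (d == 0L) return("")
  apply(expand.grid(rep(list(0:1), d))[, d:1, drop = FALSE], 1,
        paste, collapse = "")
}

word_bits <- function(w) as.integer(strsplit(w, "")[[1]])

# explicit-set oracle mirroring the subset-family store contract
oracle_full <- function(d) {
  e <- new.env(parent = emptyenv())
  e$d <- d
  e$members <- all_words(d)
  e
}

oracle_remove_interval <- function(o, lower, upper) {
  keep <- vapply(o$members, function(w) {
    b <- word_bits(w)
    !(all(lower <= b) && all(b <= upper))
  }, logical(1))
  o$members <- o$members[keep]
  invisible(o)
}

oracle_contains <- function(o, w) w %in% o$members

oracle_remove_word <- function(o, w) {
  o$members <- setdiff(o$members, w)
  invisible(o)
}

# brute-force count of consecutive-cardinality chain triples X1 c X2 c X3
# with c(X2) > max(c(X1), c(X3)); explicit triple loops, no shared code
brute_oscillations <- function(cost) {
  n <- cost$ground$n
  words <- all_words(n)
  costs <- vapply(words, function(w) cost$eval(word_bits(w)), numeric(1))
  names(costs) <- words
  count <- 0L
  for (w2 in words) {
    b2 <- word_bits(w2)
    ones <- which(b2 == 1L)
    zeros <- which(b2 == 0L)
    for (i in ones) {
      b1 <- b2
      b1[i] <- 0L
      w1 <- paste(b1, collapse = "")
      for (j in zeros) {
        b3 <- b2
        b3[j] <- 1L
        w3 <- paste(b3, collapse = "")
        if (costs[[w2]] > max(costs[[w1]], costs[[w3]]) + 1e-12) {
          count <- count + 1L
        }
      }
    }
  }
  count
}

# full-chain U-curve check: scans ALL chain triples X1 c X2 c X3 (any
# cardinality gap), not only consecutive ones
full_chain_u_check <- function(cost) {
  n <- cost$ground$n
  words <- all_words(n)
  bits <- lapply(words, word_bits)
  costs <- vapply(bits, cost$eval, numeric(1))
  N <- length(words)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j || !all(bits[[i]] <= bits[[j]])) next
      for (k in seq_len(N)) {
        if (k == j || !all(bits[[j]] <= bits[[k]])) next
        if (costs[j] > max(costs[i], costs[k]) + 1e-12) return(FALSE)
      }
    }
  }
  TRUE
}

# a small explicit cost table with a single oscillation on two features
oscillating_table_2 <- function() {
  g <- ground_set(c("a", "b"))
  cost_table(c("00" = 1, "10" = 3, "01" = 0, "11" = 1), g)
}

# random explicit cost table over `letters[1:n]`
random_cost_table <- function(n, seed) {
  g <- ground_set(letters[seq_len(n)])
  words <- all_words(n)
  set.seed(seed)
  cost_table(setNames(round(stats::runif(length(words), 0, 10), 3), words), g)
}

# subset-sum instance guaranteed to contain a subset summing to the target
planted_zero_instance <- function(n, seed) {
  set.seed(seed)
  w <- sample(0:(10 * n), n, replace = TRUE)
  names(w) <- sprintf("f%02d", seq_len(n))
  size <- sample(seq_len(n), 1L)
  subset_sum_instance(w, sum(w[sample(seq_len(n), size)]))
}

# does any subset inside the full-lattice interval [lower, upper] have a
# cost strictly below `best`? checked against the exhaustive cost vector
interval_beats_best <- function(m, costs, lower, upper, best) {
  lo <- word_bits(lower)
  up <- word_bits(upper)
  inside <- (m %*% lo == sum(lo)) & (m %*% (1L - up) == 0L)
  any(costs[inside] < best - 1e-12)
}
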