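# Reduced ordered binary decision diagrams, the compressed representation
# behind the search-space store. Variables are the bit positions 1..nvars
# (leftmost bit = variable 1); terminals are node 1 (FALSE) and node 2
# (TRUE), carried at pseudo-level nvars + 1. Nodes are hash-consed through
# a unique table, so equal functions share one node and node ids are
# stable, which lets the satcount memo survive root changes.

BDD_F <- 1L
BDD_T <- 2L

bdd_manager <- function(nvars) {
  m <- new.env(parent = emptyenv())
  m$nvars <- as.integer(nvars)
  m$var <- c(nvars + 1L, nvars + 1L)
  m$lo <- c(0L, 0L)
  m$hi <- c(0L, 0L)
  m$unique <- new.env(parent = emptyenv())
  m$and_memo <- new.env(parent = emptyenv())
  m$not_memo <- new.env(parent = emptyenv())
  m$cnt_memo <- new.env(parent = emptyenv())
  m
}

bdd_mk <- function(m, v, lo, hi) {
  if (lo == hi) return(lo)
  key <- paste(v, lo, hi)
  id <- get0(key, envir = m$unique, inherits = FALSE)
  if (!is.null(id)) return(id)
  id <- length(m$var) + 1L
  m$var[id] <- v
  m$lo[id] <- lo
  m$hi[id] <- hi
  assign(key, id, envir = m$unique)
  id
}

bdd_not <- function(m, a) {
  if (a == BDD_F) return(BDD_T)
  if (a == BDD_T) return(BDD_F)
  key <- as.character(a)
  r <- get0(key, envir = m$not_memo, inherits = FALSE)
  if (!is.null(r)) return(r)
  r <- bdd_mk(m, m$var[a], bdd_not(m, m$lo[a]), bdd_not(m, m$hi[a]))
  assign(key, r, envir = m$not_memo)
  r
}

bdd_and <- function(m, a, b) {
  if (a == BDD_F || b == BDD_F) return(BDD_F)
  if (a == BDD_T) return(b)
  if (b == BDD_T) return(a)
  if (a == b) return(a)
  key <- if (a < b) paste(a, b) else paste(b, a)
  r <- get0(key, envir = m$and_memo, inherits = FALSE)
  if (!is.null(r)) return(r)
  va <- m$var[a]
  vb <- m$var[b]
  v <- min(va, vb)
  a0 <- if (va == v) m$lo[a] else a
  a1 <- if (va == v) m$hi[a] else a
  b0 <- if (vb == v) m$lo[b] else b
  b1 <- if (vb == v) m$hi[b] else b
  r <- bdd_mk(m, v, bdd_and(m, a0, b0), bdd_and(m, a1, b1))
  assign(key, r, envir = m$and_memo)
  r
}

# the cube (conjunction of literals) of an interval [lower, upper]:
# variables forced to 1 where lower = 1, forced to 0 where upper = 0,
# free elsewhere
bdd_interval_cube <- function(m, lower, upper) {
  node <- BDD_T
  for (v in rev(seq_len(m$nvars))) {
    if (lower[v] == 1L) {
      node <- bdd_mk(m, v, BDD_F, node)
    } else if (upper[v] == 0L) {
      node <- bdd_mk(m, v, node, BDD_F)
    }
  }
  node
}

bdd_contains <- function(m, root, bits) {
  id <- root
  while (id > BDD_T) {
    id <- if (bits[m$var[id]] == 1L) m$hi[id] else m$lo[id]
  }
  id == BDD_T
}

# number of satisfying assignments of variables var(id)..nvars at node id
bdd_scount <- function(m, id) {
  if (id == BDD_F) return(0)
  if (id == BDD_T) return(1)
  key <- as.character(id)
  r <- get0(key, envir = m$cnt_memo, inherits = FALSE)
  if (!is.null(r)) return(r)
  v <- m$var[id]
  lo <- m$lo[id]
  hi <- m$hi[id]
  r <- bdd_scount(m, lo) * 2^(m$var[lo] - v - 1) +
    bdd_scount(m, hi) * 2^(m$var[hi] - v - 1)
  assign(key, r, envir = m$cnt_memo)
  r
}

bdd_satcount <- function(m, root) {
  bdd_scount(m, root) * 2^(m$var[root] - 1)
}

# draw one satisfying assignment uniformly at random (seeded rng stream)
bdd_pick <- function(m, root, rng) {
  if (root == BDD_F) abort("cannot pick from an empty family")
  n <- m$nvars
  bits <- integer(n)
  id <- root
  pos <- 1L
  while (pos <= n) {
    v <- if (id > BDD_T) m$var[id] else n + 1L
    while (pos < v && pos <= n) {
      # both branches identical: free variable, fair coin
      bits[pos] <- if (rng_runif(rng) < 0.5) 1L else 0L
      pos <- pos + 1L
    }
    if (pos > n) break
    lo <- m$lo[id]
    hi <- m$hi[id]
    w0 <- bdd_scount(m, lo) * 2^(m$var[lo] - v - 1)
    w1 <- bdd_scount(m, hi) * 2^(m$var[hi] - v - 1)
    take1 <- rng_runif(rng) < w1 / (w0 + w1)
    bits[pos] <- if (take1) 1L else 0L
    id <- if (take1) hi else lo
    pos <- pos + 1L
  }
  bits
}
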