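test_that("partitions fix ceiling(p * n) features", {
  g <- ground_set(letters[1:5])
  part <- make_partition(g, p = 0.5, seed = 1)
  expect_length(part$fixed_idx, 3L)        # ceiling(2.5)
  expect_length(part$free_idx, 2L)
  part2 <- make_partition(g, fixed = c("a", "d"))
  expect_equal(n_inner_lattices(part2), 4)
  expect_equal(n_inner_lattices(make_partition(g, p = 1, seed = 1)), 32)
  expect_error(make_partition(g, p = 0), "p must lie")
  expect_error(make_partition(g, p = 1.2), "p must lie")
  expect_error(make_partition(g, fixed = "zz"), "unknown feature")
  for (n in c(1, 4, 9, 13)) {
    gg <- ground_set(sprintf("v%02d", seq_len(n)))
    for (p in c(0.2, 0.5, 0.9, 1)) {
      expect_length(make_partition(gg, p = p, seed = n)$fixed_idx,
                    ceiling(p * n))
    }
  }
})

test_that("inner lattices partition the full power set", {
  for (s in 1:5) {
    n <- 4 + s
    g <- ground_set(sprintf("v%02d", seq_len(n)))
    part <- make_partition(g, p = 0.4, seed = s)
    d <- length(part$fixed_idx)
    anchors <- vapply(all_words(n), function(w) {
      paste(word_bits(w)[part$fixed_idx], collapse = "")
    }, character(1))
    counts <- table(anchors)
    expect_equal(length(counts), 2^d)                  # union exhaustive
    expect_true(all(counts == 2^(n - d)))              # pairwise disjoint
  }
})

test_that("probe costs are the anchored floor and ceiling, memoized", {
  inst <- gen_subset_sum_instance(6, seed = 11)
  co <- cost_subset_sum(inst)
  part <- make_partition(co$ground, p = 0.5, seed = 3)
  lg <- evaluation_ledger()
  pr <- probe_costs(integer(3), part, co, lg)
  expect_equal(unname(pr["floor"]), co$eval(integer(6)))
  expect_equal(unname(pr["ceiling"]),
               co$eval(as.integer(seq_len(6) %in% part$free_idx)))
  before <- ledger_calls(lg)
  probe_costs(integer(3), part, co, lg)
  expect_equal(ledger_calls(lg), before)     # memo: no new distinct calls
  # cross-check every outer element against the closed form
  for (w in all_words(3)) {
    pr <- probe_costs(w, part, co, lg)
    fl <- integer(6); fl[part$fixed_idx] <- word_bits(w)
    ce <- fl; ce[part$free_idx] <- 1L
    expect_equal(unname(pr["floor"]), abs(inst$target - sum(inst$weights[fl == 1L])))
    expect_equal(unname(pr["ceiling"]), abs(inst$target - sum(inst$weights[ce == 1L])))
  }
})

test_that("adjacency cases fire in the pseudocode's order", {
  pr <- function(fx, cx, fy, cy) {
    list(x = c(floor = fx, ceiling = cx), y = c(floor = fy, ceiling = cy))
  }
  # walking up with a ceiling drop: prune the downset below X, move
  d1 <- adjacency_case("00110", "00111", pr(5, 4, 5, 3))
  expect_equal(d1$action, "prune_lower_move")
  expect_true(d1$move)
  expect_equal(d1$remove$upper, word_bits("00110"))
  expect_equal(d1$remove$lower, integer(5))
  # walking up with a floor rise: prune the upset above Y, stay
  d2 <- adjacency_case("00001", "01001", pr(1, 4, 3, 4))
  expect_equal(d2$action, "prune_upper_stay")
  expect_false(d2$move)
  expect_equal(d2$remove$lower, word_bits("01001"))
  expect_equal(d2$remove$upper, rep(1L, 5))
  # both conditions true: the ceiling test precedes the floor test
  d3 <- adjacency_case("00", "01", pr(1, 9, 3, 2))
  expect_equal(d3$action, "prune_lower_move")
  # downward neighbours, floor drop: prune upset above X, move to Y
  d4 <- adjacency_case("11", "01", pr(5, 5, 2, 5))
  expect_equal(d4$action, "prune_upper_move")
  expect_equal(d4$remove$lower, word_bits("11"))
  # downward neighbours, ceiling rise at Y: prune downset below Y, stay
  d5 <- adjacency_case("11", "10", pr(5, 5, 5, 9))
  expect_equal(d5$action, "prune_lower_stay")
  expect_equal(d5$remove$upper, word_bits("10"))
  # no strict inequality: move without pruning
  d6 <- adjacency_case("00", "10", pr(2, 2, 2, 2))
  expect_equal(d6$action, "move")
  expect_null(d6$remove)
  expect_error(adjacency_case("00", "11", pr(1, 1, 1, 1)), "Hamming")
})

test_that("the outer walk empties U and never prunes a minimal anchor", {
  for (s in 1:12) {
    n <- 5 + (s %% 4)
    co <- cost_subset_sum(gen_subset_sum_instance(n, seed = 70 + s))
    part <- make_partition(co$ground, p = 0.5, seed = s)
    lg <- evaluation_ledger()
    walk <- outer_walk(part, co, lg, seed = s)
    es <- search_exhaustive(co)
    # anchor of each global minimum must have survived the walk
    for (m in es$minima) {
      anchor <- paste(word_bits(m)[part$fixed_idx], collapse = "")
      expect_true(anchor %in% walk$explored)
    }
    # every pruning event was justified: nothing in a pruned interval
    # beats the global minimum on a U-decomposable instance
    mm <- all_subsets_bits(n)
    costs <- vapply(seq_len(nrow(mm)), function(i) co$eval(mm[i, ]),
                    numeric(1))
    for (r in seq_len(nrow(walk$prune_log))) {
      expect_false(interval_beats_best(
        mm, costs, walk$prune_log$full_lower[r],
        walk$prune_log$full_upper[r], es$best_cost))
    }
  }
})

test_that("a one-bit outer lattice explores at most two elements", {
  co <- cost_subset_sum(gen_subset_sum_instance(4, seed = 1))
  part <- make_partition(co$ground, fixed = co$ground$features[1])
  walk <- outer_walk(part, co, seed = 5)
  expect_lte(length(walk$explored), 2L)
})

test_that("PUCS with an optimal base matches the exhaustive minimum", {
  for (s in 1:40) {
    n <- 4 + (s %% 9)
    co <- cost_subset_sum(gen_subset_sum_instance(n, seed = 300 + s))
    fit <- search_pucs(co, seed = s)
    es <- search_exhaustive(co)
    expect_equal(fit$best_cost, es$best_cost)
  }
})

test_that("single-feature and p = 1 degeneracies still run", {
  g1 <- ground_set("a")
  co1 <- cost_fn(function(bits) 2 - sum(bits), g1)
  fit <- search_pucs(co1, seed = 1)
  expect_equal(fit$best_cost, 1)
  expect_equal(fit$minima, "1")
  co <- cost_subset_sum(gen_subset_sum_instance(5, seed = 6))
  fit2 <- search_pucs(co, p = 1, seed = 2)
  expect_equal(fit2$best_cost, search_exhaustive(co)$best_cost)
})

test_that("an exhaustive base on the inner lattices evaluates them fully", {
  co <- cost_subset_sum(gen_subset_sum_instance(6, seed = 13))
  part_fixed <- co$ground$features[1:2]
  fit <- search_pucs(co, base = "es", seed = 3, fixed = part_fixed)
  # surviving outer elements have their whole 2^4 inner lattice evaluated
  walkE <- unique(vapply(fit$minima, function(m) {
    paste(word_bits(m)[1:2], collapse = "")
  }, character(1)))
  tb <- ledger_tbl(fit$ledger)
  for (a in walkE) {
    inner <- tb$subset[substr(tb$subset, 1, 2) == a]
    expect_equal(length(inner), 16L)
  }
})

test_that("minima are invariant to the worker count", {
  for (s in c(4, 9)) {
    co <- cost_subset_sum(gen_subset_sum_instance(8, seed = 400 + s))
    f1 <- search_pucs(co, seed = s, workers = 1)
    f2 <- search_pucs(co, seed = s, workers = 2)
    f4 <- search_pucs(co, seed = s, workers = 4)
    expect_equal(f1$best_cost, f2$best_cost)
    expect_equal(f1$best_cost, f4$best_cost)
    expect_setequal(f1$minima, f2$minima)
    expect_setequal(f1$minima, f4$minima)
  }
})

test_that("deeper recursion preserves optimality with an optimal base", {
  for (s in 1:6) {
    co <- cost_subset_sum(gen_subset_sum_instance(9, seed = 500 + s))
    f1 <- search_pucs(co, l = 1, seed = s)
    f2 <- search_pucs(co, l = 2, seed = s)
    expect_equal(f2$best_cost, f1$best_cost)
  }
})

test_that("runs are reproducible for a fixed seed", {
  co <- cost_subset_sum(gen_subset_sum_instance(8, seed = 77))
  f1 <- search_pucs(co, seed = 123)
  f2 <- search_pucs(co, seed = 123)
  expect_identical(f1$minima, f2$minima)
  expect_identical(f1$prune_log, f2$prune_log)
  expect_equal(ledger_calls(f1$ledger), ledger_calls(f2$ledger))
})

test_that("oscillating costs keep internal consistency", {
  # pruning soundness is only promised under the U-curve assumption; on
  # oscillating costs the result still equals the ledger minimum and
  # never beats the true optimum
  for (s in 1:8) {
    co <- random_cost_table(5, seed = 600 + s)
    fit <- search_pucs(co, seed = s)
    expect_equal(fit$best_cost, min(ledger_tbl(fit$ledger)$cost))
    es <- search_exhaustive(co)
    expect_gte(fit$best_cost, es$best_cost - 1e-12)
  }
})

test_that("select_features drives MCE selection end to end", {
  tab <- gen_mce_dataset(n = 6, k = 2, t = 400, noise_rate = 0.05, seed = 31)
  fit <- select_features(tab, algorithm = "pucs", seed = 2)
  expect_s3_class(fit, "feature_search")
  expect_equal(fit$cost_name, "mce")
  td <- tidy(fit)
  expect_true(all(td$cost <= 1))
  # the exhaustive reference finds the same criterion value
  es <- select_features(tab, algorithm = "es")
  expect_equal(fit$best_cost, es$best_cost)
})
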