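test_that("subset-sum cost is the absolute deviation from the target", {
  inst <- subset_sum_instance(c(a = 2, b = 3, c = 5), 8)
  co <- cost_subset_sum(inst)
  lg <- evaluation_ledger()
  expect_equal(eval_cost(co, lg, feature_set(c("b", "c"), inst$ground)), 0)
  expect_equal(eval_cost(co, lg, "000"), 8)
  expect_equal(eval_cost(co, lg, feature_set("a", inst$ground)), 6)
})

test_that("subset-sum instances round-trip through JSON", {
  inst <- gen_subset_sum_instance(9, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_subset_sum(inst, path)
  back <- read_subset_sum(path)
  expect_identical(back$weights, inst$weights)
  expect_identical(back$target, inst$target)
})

test_that("projection aggregates per-label counts correctly", {
  tab <- tibble::tibble(f1 = c(0, 0, 1), f2 = c(0, 1, 0),
                        label = c("y0", "y1", "y0"))
  # onto nothing: single realization holding the full label histogram
  p0 <- project_counts(tab, character(0))
  expect_equal(nrow(p0), 2L)
  expect_equal(sum(p0$n), 3)
  expect_equal(p0$n[p0$label == "y0"], 2)
  # onto the first feature: hand aggregation
  p1 <- project_counts(tab, "f1")
  expect_equal(p1$n[p1$f1 == 0 & p1$label == "y0"], 1)
  expect_equal(p1$n[p1$f1 == 0 & p1$label == "y1"], 1)
  expect_equal(p1$n[p1$f1 == 1 & p1$label == "y0"], 1)
  # identity projection: one entry per distinct full vector
  p2 <- project_counts(tab, c("f1", "f2"))
  expect_equal(nrow(p2), 3L)
  expect_error(project_counts(tab[0, ], "f1"), "empty")
  expect_error(project_counts(tab, "nope"), "unknown feature")
})

test_that("multiplicities weigh into projections and totals", {
  tab <- tibble::tibble(f1 = c(0, 1), label = c(0, 1),
                        multiplicity = c(3, 2))
  p <- project_counts(tab, "f1")
  expect_equal(sum(p$n), 5)
  expect_equal(p$n[p$f1 == 0], 3)
})

test_that("conditional entropy uses the |L|-ary logarithm", {
  expect_equal(conditional_entropy(c(1, 1), 2), 1)
  expect_equal(conditional_entropy(c(5, 0), 2), 0)
  expect_equal(conditional_entropy(c(3, 1), 2), 0.8113, tolerance = 1e-4)
  # uniform over three classes is maximal in base 3
  expect_equal(conditional_entropy(c(2, 2, 2), 3), 1)
  expect_error(conditional_entropy(c(0, 0), 2), "at least 1")
  expect_error(conditional_entropy(c(1, 1), 1), "n_labels")
})

test_that("penalized MCE matches hand computations", {
  # (0,y0) (0,y1) (1,y0) (1,y0): realization 0 has H = 1 and weight 1/2;
  # realization 1 is pure; no singletons
  tab <- tibble::tibble(f1 = c(0, 0, 1, 1), label = c(0, 1, 0, 0))
  expect_equal(penalized_mce(tab, "f1"), 0.5)
  # every projected realization unique: penalty term only
  tab2 <- tibble::tibble(f1 = 1:4, label = c(0, 1, 0, 1))
  expect_equal(penalized_mce(tab2, "f1"), 1)
  # projecting onto nothing with t >= 2: the empirical label entropy
  tab3 <- tibble::tibble(f1 = c(0, 1, 0, 1), label = c(0, 0, 0, 1))
  expect_equal(penalized_mce(tab3, character(0)),
               conditional_entropy(c(3, 1), 2))
})

test_that("penalized MCE stays within [0, 1] on random tables", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    t <- sample(5:60, 1)
    tab <- tibble::as_tibble(as.data.frame(matrix(sample(0:2, n * t, TRUE),
                                                  nrow = t)))
    names(tab) <- sprintf("f%d", seq_len(n))
    tab$label <- sample(0:2, t, TRUE)
    feats <- sample(names(tab)[seq_len(n)], sample(0:n, 1))
    v <- penalized_mce(tab, feats)
    expect_gte(v, 0)
    expect_lte(v, 1 + 1e-12)
  }
})

test_that("projected cost evaluates the base at the anchored union", {
  g <- ground_set(letters[1:5])
  words <- all_words(5)
  vals <- setNames(seq_along(words) / 10, words)
  base <- cost_table(vals, g)
  lg <- evaluation_ledger()
  part <- make_partition(g, fixed = c("a", "b"))
  pc <- cost_project(base, part, "11", lg)
  # anchor 11000 with free-set element 00100 evaluates the base at 11100
  got <- pc$eval(c(1L, 0L, 0L))
  expect_equal(got, unname(vals[["11100"]]))
  expect_true("11100" %in% ledger_tbl(lg)$subset)
  # empty anchor: identity wrapper
  pc0 <- cost_project(base, part, "00", lg)
  expect_equal(pc0$eval(c(0L, 1L, 0L)), unname(vals[["00010"]]))
  # anchors supported on free points are rejected
  bad <- feature_set("c", g)
  expect_error(cost_project(base, part, bad, lg), "fixed points")
})

test_that("projected evaluations stay inside the anchored inner lattice", {
  g <- ground_set(letters[1:6])
  inst <- gen_subset_sum_instance(6, seed = 9)
  base <- cost_subset_sum(inst)
  part <- make_partition(base$ground, p = 0.5, seed = 2)
  lg <- evaluation_ledger()
  anchor <- c(1L, 0L, 1L)
  pc <- cost_project(base, part, anchor, lg)
  for (w in all_words(3)) pc$eval(word_bits(w))
  tb <- ledger_tbl(lg)
  for (s in tb$subset) {
    b <- word_bits(s)
    expect_identical(b[part$fixed_idx], anchor)
  }
})

test_that("explicit cost tables delegate and validate", {
  g <- ground_set(letters[1:3])
  zero <- cost_table(setNames(rep(0, 8), all_words(3)), g)
  expect_equal(zero$eval(c(1L, 1L, 0L)), 0)
  expect_error(cost_table(c("000" = 1), g), "missing subset")
  expect_false(is_u_decomposable(oscillating_table_2()))
  # a table built from a subset-sum instance agrees with the closed form
  inst <- gen_subset_sum_instance(6, seed = 3)
  co <- cost_subset_sum(inst)
  words <- all_words(6)
  tab <- cost_table(setNames(vapply(words, function(w) co$eval(word_bits(w)),
                                    numeric(1)), words), inst$ground)
  for (w in words) expect_equal(tab$eval(word_bits(w)), co$eval(word_bits(w)))
})

test_that("sample tables round-trip through .dat and CSV", {
  tab <- gen_mce_dataset(n = 4, k = 2, t = 40, noise_rate = 0.2, seed = 5)
  dat <- withr::local_tempfile(fileext = ".dat")
  write_sample_dat(tab, dat)
  back <- read_sample_dat(dat)
  expect_equal(dim(back), dim(tab))
  expect_equal(back$label, tab$label)
  expect_equal(unname(as.matrix(back[1:4])), unname(as.matrix(tab[1:4])))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, csv)
  back2 <- read_sample_csv(csv)
  expect_equal(back2$label, tab$label)
  nolabel <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab[1:4], nolabel)
  expect_error(read_sample_csv(nolabel), "label")
})
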