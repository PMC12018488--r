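# subgroup_tree: split search, greedy fitting, group assignment, rule text.

test_that("6-value best-split worked example gives SSE reduction 24.0 exactly", {
  tau <- c(1, 1, 2, 5, 5, 6)
  x <- c(0, 0, 0, 1, 1, 1)
  res <- best_split(tau, x)
  expect_equal(res$reduction, 24.0)
  expect_equal(res$rule$kind, "ordinal-threshold")
  expect_equal(res$rule$threshold, 0.5)

  # constant target: no-split sentinel
  res0 <- best_split(rep(2, 6), x)
  expect_null(res0$rule)
  expect_identical(res0$reduction, 0)

  # min_leaf can forbid every split
  res1 <- best_split(tau, x, min_leaf = 4)
  expect_null(res1$rule)
})

test_that("greedy single split matches brute force on random small instances", {
  # 150 instances here; the 1000-instance sweep backs the acceptance criterion
  set.seed(71)
  for (i in 1:150) {
    n <- sample(10:50, 1)
    covs <- data.frame(
      a = rnorm(n),
      b = sample(0:2, n, replace = TRUE),
      c = factor(sample(letters[1:4], n, replace = TRUE)),
      d = factor(sample(c("lo", "mid", "hi"), n, replace = TRUE),
                 levels = c("lo", "mid", "hi"), ordered = TRUE)
    )[, seq_len(sample(1:4, 1)), drop = FALSE]
    tau <- rnorm(n)
    min_leaf <- sample(1:3, 1)
    t1 <- fit_tree(tau, covs, max_depth = 1, min_leaf = min_leaf)
    got <- if (t1$root$is_leaf) 0 else t1$root$reduction
    expect_equal(got, brute_force_best(tau, covs, min_leaf = min_leaf),
                 tolerance = 1e-9)
  }
})

test_that("depth-2 fit on the planted 4-cell scenario recovers the cells exactly", {
  cfg <- small_sim(n = 2000, seed = 73)
  d <- simulate_trial(cfg)
  oc <- oracle_cate(d)
  rec <- apply_recoding(d, default_rules())[d$retained == 1L, ]
  tree <- fit_tree(oc, rec, max_depth = 2, min_leaf = 50)
  rt <- rules_text(tree)
  expect_identical(nrow(rt), 4L)
  expect_true(all(lengths(strsplit(rt$rule, " AND ")) == 2))
  expect_true(all(grepl("hist_cvd|hist_mi", rt$rule)))

  g <- assign_groups(tree, rec)
  expect_identical(length(g), nrow(rec))
  expect_identical(sum(table(g)), nrow(rec))
  # leaf membership = planted cells, ordered by ascending planted effect
  cells <- d$oracle_cell[d$retained == 1L]
  expect_identical(unname(vapply(split(cells, g), function(z)
    length(unique(z)), 0L)), rep(1L, 4))
  cell_order <- names(sort(cfg$cell_effects))
  expect_identical(unname(vapply(1:4, function(k) unique(cells[g == k]), "")),
                   cell_order)
  # group means ascend
  expect_identical(order(rt$mean_tau), 1:4)
})

test_that("max_depth 0 gives one all-subjects leaf; weighted/unit fits coincide", {
  d <- simulate_trial(small_sim(n = 300, seed = 79))
  oc <- oracle_cate(d)
  rec <- apply_recoding(d, default_rules())[d$retained == 1L, ]
  t0 <- fit_tree(oc, rec, max_depth = 0)
  expect_identical(length(t0$leaves), 1L)
  expect_equal(t0$leaves[[1]]$mean_tau, mean(oc$tau_hat))
  expect_identical(rules_text(t0)$rule, "all subjects")

  tw <- fit_tree(oc, rec, max_depth = 2, min_leaf = 30,
                 weights = rep(1, nrow(rec)))
  tu <- fit_tree(oc, rec, max_depth = 2, min_leaf = 30)
  expect_identical(rules_text(tw), rules_text(tu))

  expect_error(fit_tree(oc, rec[, "subject_id", drop = FALSE], max_depth = 2),
               class = "pragsub_config_error")
})

test_that("fitted trees are invariant to subject order", {
  d <- simulate_trial(small_sim(n = 800, seed = 83))
  oc <- oracle_cate(d)
  rec <- apply_recoding(d, default_rules())[d$retained == 1L, ]
  t1 <- fit_tree(oc, rec, max_depth = 2, min_leaf = 40)
  set.seed(84)
  perm <- sample(nrow(rec))
  t2 <- fit_tree(oc, rec[perm, ], max_depth = 2, min_leaf = 40)
  expect_identical(rules_text(t1), rules_text(t2))
  # assignment follows the permutation
  g1 <- assign_groups(t1, rec)
  g2 <- assign_groups(t2, rec[perm, ])
  expect_identical(as.integer(g1)[perm], as.integer(g2))
})

test_that("ordered factors split on order-respecting thresholds", {
  lev <- c("< 7", "7-8.9", "≥ 9")
  x <- factor(rep(lev, times = c(30, 30, 30)), levels = lev, ordered = TRUE)
  tau <- rep(c(0.00, 0.10, 0.12), times = c(30, 30, 30))
  res <- best_split(tau, x, min_leaf = 10)
  expect_equal(res$rule$kind, "ordinal-threshold")
  expect_identical(res$rule$left_levels, "< 7")   # contiguous prefix
  t1 <- fit_tree(tau, data.frame(hba1c_cat = x), max_depth = 1, min_leaf = 10)
  expect_match(rules_text(t1)$rule[1], "≤ '< 7'|> '< 7'")
})

test_that("unordered factors split on mean-ordered level subsets; unseen levels flagged", {
  x <- factor(rep(c("a", "b", "c"), times = c(20, 20, 20)))
  tau <- rep(c(0.0, 0.5, 0.1), times = c(20, 20, 20))
  res <- best_split(tau, x, min_leaf = 5)
  expect_equal(res$rule$kind, "level-subset")
  expect_setequal(res$rule$left_levels, c("a", "c"))  # low-mean side

  covs <- data.frame(g = x)
  tr <- fit_tree(tau, covs, max_depth = 1, min_leaf = 5)
  new <- data.frame(g = factor(c("a", "zzz"), levels = c("a", "zzz")))
  g <- assign_groups(tr, new)
  expect_identical(length(g), 2L)
  routing <- attr(g, "routing")
  expect_identical(routing$level, "zzz")
  # unseen level goes to the complement (right/high) side
  expect_identical(g[2], max(g))
})
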