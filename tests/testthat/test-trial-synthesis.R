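# trial_synthesis: generator contracts, oracle exposure, round-trip I/O.

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_sim(n = 300, seed = 7)
  d1 <- simulate_trial(cfg)
  d2 <- simulate_trial(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_trial(small_sim(n = 300, seed = 8))
  expect_false(identical(d1$outcome, d3$outcome))
})

test_that("randomization, event rate and censoring hit their targets", {
  d <- simulate_trial(sim_config(n_subjects = 10000, scenario = "null",
                                 covariate_names = c("age", "hba1c"),
                                 seed = 21))
  expect_lt(abs(mean(d$treatment) - 0.5), 0.02)

  # event rate: null effects, no censoring, baseline risk 0.13
  d2 <- simulate_trial(sim_config(n_subjects = 20000, scenario = "null",
                                  censoring_rate = 0,
                                  covariate_names = c("age", "hba1c"),
                                  seed = 22))
  ev <- mean(d2$outcome == 0L)
  expect_lt(abs(ev - 0.13), 3 * sqrt(0.13 * 0.87 / 20000))
  expect_true(all(d2$retained == 1L))

  # censoring control at the configured marginal rate
  d3 <- simulate_trial(small_sim(n = 20000, seed = 23))
  expect_lt(abs(mean(d3$retained) - 0.938), 3 * sqrt(0.062 * 0.938 / 20000))
  expect_true(all(is.na(d3$outcome[d3$retained == 0L])))
  expect_true(all(!is.na(d3$outcome[d3$retained == 1L])))
})

test_that("treatment is independent of covariates (chi-square null across seeds)", {
  reject <- vapply(1:200, function(s) {
    d <- simulate_trial(small_sim(n = 400, seed = 1000 + s, scenario = "null",
                                  censoring_rate = 0))
    suppressWarnings(
      stats::chisq.test(table(d$treatment, d$hist_cvd), correct = FALSE)$p.value
    ) < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("planted cell effects are recovered by difference-in-means per cell", {
  cfg <- small_sim(n = 20000, seed = 31, censoring_rate = 0)
  d <- simulate_trial(cfg)
  for (cell in names(cfg$cell_effects)) {
    rows <- d$oracle_cell == cell
    y <- d$outcome[rows]; a <- d$treatment[rows]
    est <- mean(y[a == 1]) - mean(y[a == 0])
    se <- sqrt(var(y[a == 1]) / sum(a == 1) + var(y[a == 0]) / sum(a == 0))
    expect_lt(abs(est - cfg$cell_effects[[cell]]), 3 * se)
  }
})

test_that("oracle_cate returns the planted effects exactly", {
  d0 <- simulate_trial(small_sim(n = 200, seed = 5, scenario = "null"))
  expect_true(all(oracle_cate(d0)$tau_hat == 0))

  cfg <- small_sim(n = 500, seed = 6)
  d <- simulate_trial(cfg)
  oc <- oracle_cate(d)
  keep <- d$retained == 1L
  expect_identical(oc$subject_id, d$subject_id[keep])
  expect_equal(oc$tau_hat, unname(cfg$cell_effects[d$oracle_cell[keep]]))
  # mean oracle effect = empirical cell-frequency-weighted average (exact)
  freq <- table(d$oracle_cell[keep]) / sum(keep)
  expect_equal(mean(oc$tau_hat),
               sum(freq * cfg$cell_effects[names(freq)]))
  expect_equal(attr(oc, "provenance")$type, "oracle")

  # non-simulated data carries no oracle
  manual <- make_trial(c(0, 1), c(1, 0))
  expect_error(oracle_cate(manual), class = "pragsub_unsupported_input")
})

test_that("invalid configurations are rejected with the offending cell named", {
  expect_error(
    sim_config(cell_effects = c(cvd0_mi0 = 0.95, cvd0_mi1 = 0, cvd1_mi0 = 0,
                                cvd1_mi1 = 0)),
    "cvd0_mi0", class = "pragsub_config_error")
  expect_error(sim_config(treatment_probability = 1), "treatment_probability")
  expect_error(sim_config(censoring_rate = 0.7), "censoring_rate")
  expect_error(sim_config(scenario = "step_subgroups",
                          cell_effects = c(a = 0.1)), "cell effects named")
})

test_that("write/read round-trips datasets losslessly", {
  d <- simulate_trial(small_sim(n = 150, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(as.data.frame(d), as.data.frame(d2))
  expect_identical(attr(d, "kinds"), attr(d2, "kinds"))

  # n = 0: header-only file, empty dataset back
  d0 <- simulate_trial(small_sim(n = 0, seed = 1))
  path0 <- tempfile(fileext = ".csv")
  write_dataset(d0, path0)
  expect_identical(nrow(read_dataset(path0)), 0L)

  # delimiter escaping: a categorical level containing a comma
  tricky <- make_trial(
    treatment = c(0, 1, 0, 1),
    outcome = c(1, 1, 0, 1),
    covariates = data.frame(
      grp = factor(c("a, plus", "b", "a, plus", "b"),
                   levels = c("a, plus", "b"))),
    kinds = c(grp = "categorical"))
  patht <- tempfile(fileext = ".csv")
  write_dataset(tricky, patht)
  back <- read_dataset(patht)
  expect_identical(levels(back$grp), c("a, plus", "b"))
  expect_equal(as.data.frame(back), as.data.frame(tricky))

  expect_error(write_dataset(d, file.path(tempdir(), "no/such/dir/x.csv")),
               class = "pragsub_io_error")
})
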