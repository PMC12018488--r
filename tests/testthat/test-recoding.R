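# interpretable_recoding: ruleset validation, half-open categorization,
# partition/monotonicity properties.

test_that("shipped ruleset turns the 47-covariate roster into 42 interpretable covariates", {
  d <- simulate_trial(sim_config(n_subjects = 400, seed = 12))
  expect_identical(length(attr(d, "kinds")), 47L)
  rec <- apply_recoding(d, default_rules())
  expect_identical(ncol(rec) - 1L, 42L)   # minus subject_id
  expect_false("urine_albumin" %in% names(rec))
  expect_false("sf36_pcs" %in% names(rec))
  # kept binaries are bitwise unchanged
  expect_identical(rec$hist_cvd, d$hist_cvd)
  expect_identical(rec$race_ethnicity, d$race_ethnicity)
})

test_that("half-open boundary convention maps values as printed", {
  d <- make_trial(
    treatment = rep(c(0, 1), 3),
    outcome = rep(1L, 6),
    covariates = data.frame(hba1c = c(5.69, 5.7, 6.5, 6.95, 7.0, 10.0),
                            age = c(59.9, 60, 61, 45, 50, 80)),
    kinds = c(hba1c = "continuous", age = "continuous"))
  rec <- apply_recoding(d, default_rules())
  expect_equal(as.character(rec$hba1c),
               c("< 5.7", "5.7–6.3", "6.4–6.9", "6.4–6.9", "7.0–7.9", "≥ 10"))
  expect_equal(as.character(rec$age),
               c("< 60", "≥ 60", "≥ 60", "< 60", "< 60", "≥ 60"))
  expect_true(is.ordered(rec$hba1c))
})

test_that("rule and ruleset invariants are enforced", {
  expect_error(recoding_rule("hba1c", "categorize", cutpoints = c(7, 5.7)),
               "strictly increasing", class = "pragsub_validation_error")
  expect_error(recoding_rule("x", "categorize", cutpoints = c(1, 2),
                             labels = c("a", "b")),
               "3 labels", class = "pragsub_validation_error")
  expect_error(recoding_rule("x", "categorize", cutpoints = 1,
                             labels = c("a", "a")),
               "unique", class = "pragsub_validation_error")
  expect_error(recoding_rule("x", "remove", cutpoints = 1),
               class = "pragsub_validation_error")
  expect_error(
    recoding_ruleset(list(recoding_rule("x", "keep"), recoding_rule("x", "remove"))),
    "more than one rule", class = "pragsub_validation_error")

  # categorize on a non-continuous covariate is a type error
  d <- make_trial(c(0, 1), c(1, 1),
                  covariates = data.frame(g = factor(c("a", "b"))),
                  kinds = c(g = "categorical"))
  rs <- recoding_ruleset(list(recoding_rule("g", "categorize", cutpoints = 1)))
  expect_error(apply_recoding(d, rs), class = "pragsub_type_error")
})

test_that("empty ruleset with keep policy is the identity; missing values propagate", {
  d <- simulate_trial(small_sim(n = 100, seed = 3))
  rec <- apply_recoding(d, recoding_ruleset(list(), unlisted_policy = "keep"))
  expect_identical(rec[, -1], as.data.frame(d)[, names(attr(d, "kinds"))])

  dm <- make_trial(c(0, 1, 0), c(1, 1, 0),
                   covariates = data.frame(hba1c = c(6.5, NA, 8.2)),
                   kinds = c(hba1c = "continuous"))
  recm <- apply_recoding(dm, default_rules())
  expect_identical(is.na(recm$hba1c), c(FALSE, TRUE, FALSE))

  rs_err <- recoding_ruleset(list(), unlisted_policy = "error")
  expect_error(apply_recoding(dm, rs_err), "no rule",
               class = "pragsub_validation_error")
})

test_that("validate_rules reports missing variables and empty categories only", {
  d <- make_trial(c(0, 1, 0, 1), c(1, 1, 0, 1),
                  covariates = data.frame(hba1c = c(6.0, 7.2, 8.4, 9.1)),
                  kinds = c(hba1c = "continuous"))
  rep1 <- validate_rules(default_rules(), d)
  expect_true("missing_variable" %in% rep1$issue)    # e.g. bmi has a rule
  expect_true(any(rep1$issue == "empty_category" &
                    rep1$variable == "hba1c" & grepl("≥ 10", rep1$detail)))

  # fully consistent ruleset -> empty report
  rs <- recoding_ruleset(list(recoding_rule("hba1c", "categorize",
                                            cutpoints = 7,
                                            labels = c("< 7", "≥ 7"))))
  rep2 <- validate_rules(rs, d)
  expect_identical(nrow(rep2), 0L)

  # removed variables are reported informationally
  rs3 <- recoding_ruleset(list(recoding_rule("hba1c", "remove")))
  expect_identical(validate_rules(rs3, d)$issue, "removed")
})

test_that("categories partition the reals and are monotone in the raw value", {
  rules <- default_rules()
  grid <- seq(-10, 600, by = 0.37)
  for (nm in c("hba1c", "bmi", "sbp", "beck_depression", "triglycerides")) {
    rule <- rules$rules[[nm]]
    got <- pragsub:::cut_halfopen(grid, rule)
    expect_false(anyNA(got))                       # exhaustive
    expect_true(all(diff(as.integer(got)) >= 0))   # monotone
    expect_setequal(levels(got), rule$labels)
  }
})
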