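# calibration_metrics: Qini curve/coefficient and C-for-benefit.

test_that("4-subject Qini worked example reproduces exactly", {
  # descending-tau order: (A,Y) = (1,1), (0,0), (0,1), (1,0), unit weights
  d <- make_trial(treatment = c(1, 0, 0, 1), outcome = c(1, 0, 1, 0))
  est <- cate_estimate(d$subject_id, c(0.4, 0.3, 0.2, 0.1))
  q <- qini_curve(est, d, grid = c(0.5, 1.0))
  expect_equal(q$curve$fraction, c(0, 0.5, 1.0))
  expect_equal(q$curve$uplift, c(0, 1, 0))
  expect_equal(q$coefficient, 0.5)
  expect_equal(qini_coefficient(q), 0.5)
})

test_that("constant tau with equal arm outcome rates gives coefficient 0", {
  # arms perfectly interleaved with identical outcome patterns: every prefix
  # has equal weighted outcome rates, so the curve sits on its baseline
  d <- make_trial(treatment = rep(c(1, 0), 20),
                  outcome = rep(c(1, 1, 0, 0), 10))
  est <- cate_estimate(d$subject_id, rep(0.05, 40))
  q <- qini_curve(est, d, grid = seq(0.05, 1, by = 0.05))
  expect_equal(q$coefficient, 0, tolerance = 1e-12)
})

test_that("reversed ranking flips the coefficient on balanced prefixes", {
  # interleaved arms + equal per-arm outcome totals + grid on even prefixes:
  # the W1/W0 ratio is 1 at every grid point, so antisymmetry is exact
  set.seed(41)
  n <- 60
  y_half <- rbinom(n / 2, 1, 0.5)
  # treated outcomes y_half in order, control outcomes the same multiset
  # reversed: equal per-arm totals, non-trivial prefix differences
  d <- make_trial(treatment = rep(c(1, 0), n / 2),
                  outcome = as.integer(rbind(y_half, rev(y_half))))
  tau <- sort(rnorm(n), decreasing = TRUE) / 10
  grid <- seq(2, n, by = 2) / n
  q_fwd <- qini_curve(cate_estimate(d$subject_id, tau), d, grid = grid)
  q_rev <- qini_curve(cate_estimate(d$subject_id, -tau), d, grid = grid)
  expect_equal(q_rev$coefficient, -q_fwd$coefficient, tolerance = 1e-10)
})

test_that("randomly permuted tau centers the Qini coefficient at zero across replicates", {
  # On a single fixed dataset the permutation mean carries a small (~1 count)
  # dataset-conditional bias from the W1/W0 ratio correction, so the null
  # centering is assessed across freshly drawn replicates, one permutation
  # each (see the methods vignette).
  set.seed(44)
  coefs <- vapply(1:200, function(i) {
    d <- simulate_trial(small_sim(n = 600, seed = 9000 + i, censoring_rate = 0))
    tau <- oracle_cate(d)$tau_hat
    qini_curve(cate_estimate(d$subject_id, sample(tau)), d)$coefficient
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(length(coefs)))
})

test_that("qini input contracts hold", {
  d1 <- make_trial(treatment = rep(1, 10), outcome = rep(1, 10))
  est <- cate_estimate(d1$subject_id, seq(0.1, 1, 0.1) / 2)
  expect_error(qini_curve(est, d1), class = "pragsub_unsupported_input")

  degen <- structure(list(curve = data.frame(fraction = 0, uplift = 0,
                                             baseline = 0)),
                     class = "qini_result")
  expect_error(qini_coefficient(degen), class = "pragsub_degenerate_input")

  # per-subject scale divides by total weight but keeps the sign
  d <- simulate_trial(small_sim(n = 400, seed = 47, censoring_rate = 0))
  oc <- oracle_cate(d)
  q_counts <- qini_curve(oc, d, scale = "counts")
  q_ps <- qini_curve(oc, d, scale = "per-subject")
  expect_equal(q_ps$coefficient, q_counts$coefficient / nrow(d), tolerance = 1e-12)
})

test_that("3-pair C-for-benefit worked examples reproduce exactly", {
  # pairs (observed, predicted): (1, 0.3), (0, 0.1), (-1, -0.2)
  d <- make_trial(treatment = c(1, 1, 1, 0, 0, 0),
                  outcome = c(1, 0, 0, 0, 0, 1))
  est1 <- cate_estimate(d$subject_id, c(0.4, 0.2, -0.1, 0.2, 0.0, -0.3))
  r1 <- c_for_benefit(est1, d, n_boot = 0)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$n_pairs, 3L)
  expect_equal(sort(r1$pairs$observed), c(-1, 0, 1))

  # same observed benefits, predictions reversed -> all discordant
  est2 <- cate_estimate(d$subject_id, c(-0.3, 0.0, 0.2, -0.1, 0.2, 0.4))
  # re-pair: treated sorted (0.2, 0, -0.3) vs control (0.4, 0.2, -0.1)
  r2 <- c_for_benefit(est2, d, n_boot = 0)
  expect_equal(r2$statistic, 0)

  # identical predictions -> every comparison ties -> exactly 1/2
  est3 <- cate_estimate(d$subject_id, rep(0.1, 6))
  expect_equal(c_for_benefit(est3, d, n_boot = 0)$statistic, 0.5)
})

test_that("C-for-benefit is invariant to strictly increasing transforms of tau", {
  d <- simulate_trial(small_sim(n = 500, seed = 53, censoring_rate = 0))
  set.seed(54)
  keep <- d$retained == 1L
  tau <- rnorm(sum(keep), sd = 0.05)
  s1 <- c_for_benefit(cate_estimate(d$subject_id[keep], tau), d, n_boot = 0)$statistic
  s2 <- c_for_benefit(cate_estimate(d$subject_id[keep], plogis(5 * tau) * 2 - 1),
                      d, n_boot = 0)$statistic
  expect_equal(s1, s2)
})

test_that("degenerate and single-arm inputs are flagged", {
  d <- make_trial(treatment = c(1, 1, 0, 0), outcome = c(1, 1, 1, 1))
  est <- cate_estimate(d$subject_id, c(0.2, 0.1, 0.15, 0.05))
  r <- c_for_benefit(est, d, n_boot = 0)
  expect_true(r$degenerate)
  expect_true(is.na(r$statistic))

  d1 <- make_trial(treatment = rep(1, 4), outcome = c(1, 0, 1, 0))
  expect_error(c_for_benefit(cate_estimate(d1$subject_id, 1:4 / 10), d1),
               class = "pragsub_unsupported_input")
})

test_that("bootstrap CI is seeded, ordered, and covers the large-sample value", {
  d <- simulate_trial(small_sim(n = 800, seed = 59, censoring_rate = 0))
  oc <- oracle_cate(d)
  r1 <- c_for_benefit(oc, d, n_boot = 60, seed = 9)
  r2 <- c_for_benefit(oc, d, n_boot = 60, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$statistic)
  expect_gte(r1$ci[2], r1$statistic)

  # loose coverage check (percentile bootstrap is approximate): pseudo-truth
  # from one large replicate, 40 small replicates at level 0.95
  big <- simulate_trial(small_sim(n = 20000, seed = 61, censoring_rate = 0))
  truth <- c_for_benefit(oracle_cate(big), big, n_boot = 0)$statistic
  covered <- vapply(1:40, function(s) {
    ds <- simulate_trial(small_sim(n = 500, seed = 7000 + s, censoring_rate = 0))
    ci <- c_for_benefit(oracle_cate(ds), ds, n_boot = 100, seed = s)$ci
    ci[1] <= truth && truth <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})
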