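## calibration_metrics: predictive-accuracy diagnostics for a CATE model.
## The Qini curve tracks the cumulative (weighted) excess of event-free
## outcomes in the treated arm as subjects are taken in decreasing order of
## predicted benefit; its signed area above the random-ordering baseline is
## the Qini coefficient. C-for-benefit is the concordance probability between
## predicted and observed benefit over rank-matched treated-control pairs.
## Qini coefficient > 0 and C-for-benefit > 0.5 indicate calibration better
## than chance.

align_estimate <- function(estimate, dataset) {
  assert_that(inherits(estimate, "cate_estimate"), "estimate must be a cate_estimate")
  assert_that(inherits(dataset, "trial_data"), "dataset must be a trial_data")
  keep <- dataset$retained == 1L
  ids <- dataset$subject_id[keep]
  pos <- match(ids, estimate$subject_id)
  assert_that(!anyNA(pos),
              "every retained subject needs a CATE estimate; missing: ",
              paste(head(ids[is.na(pos)], 5), collapse = ", "))
  list(ids = ids,
       tau = estimate$tau_hat[pos],
       mu0 = estimate$mu0_hat[pos],
       mu1 = estimate$mu1_hat[pos],
       treatment = dataset$treatment[keep],
       outcome = as.numeric(dataset$outcome[keep]))
}

#' Qini curve of a CATE estimate
#'
#' Retained subjects are sorted by predicted effect, highest predicted benefit
#' first (ties broken by subject id). At each grid fraction phi, with prefix
#' size k = round(phi * n), the uplift is the weighted count of event-free
#' outcomes among the treated in the prefix minus the control count rescaled
#' to the treated weight total:
#' `uplift(k) = sum_{i<=k, A=1} w_i Y_i - sum_{i<=k, A=0} w_i Y_i * W1(k)/W0(k)`.
#' Prefixes with no control weight are omitted. The baseline is the straight
#' line from (0, 0) to (1, total uplift) — the expected curve under random
#' ordering.
#'
#' @param estimate A [cate_estimate()].
#' @param dataset The `trial_data` it refers to.
#' @param weights Optional [fit_censoring_weights()]; `NULL` = unit weights.
#' @param grid Increasing sample fractions in (0, 1] at which to evaluate the
#'   curve; default 100 evenly spaced fractions ending at 1.
#' @param scale `"counts"` (default; y in weighted outcome counts) or
#'   `"per-subject"` (y divided by the total weight, making the coefficient
#'   scale-free in n).
#' @return A `qini_result`: list with `curve` (data.frame fraction, uplift,
#'   baseline), `coefficient`, `scale`, `total_uplift`.
#' @export
qini_curve <- function(estimate, dataset, weights = NULL, grid = NULL,
                       scale = c("counts", "per-subject")) {
  scale <- match.arg(scale)
  al <- align_estimate(estimate, dataset)
  if (length(unique(al$treatment)) < 2) {
    stop_ps("Qini curve needs both arms present",
            class = "pragsub_unsupported_input")
  }
  w <- retained_weights(dataset, weights)
  n <- length(al$tau)
  if (is.null(grid)) grid <- seq_len(100) / 100
  assert_that(all(diff(grid) > 0) && all(grid > 0 & grid <= 1) &&
                abs(grid[length(grid)] - 1) < 1e-12,
              "grid must be strictly increasing fractions in (0, 1] ending at 1")

  ord <- order(-al$tau, al$ids)
  A <- al$treatment[ord]
  wy <- (w * al$outcome)[ord]
  ws <- w[ord]
  cum_wy1 <- cumsum(wy * (A == 1))
  cum_wy0 <- cumsum(wy * (A == 0))
  cum_w1 <- cumsum(ws * (A == 1))
  cum_w0 <- cumsum(ws * (A == 0))

  ks <- pmax(1L, pmin(n, as.integer(round(grid * n))))
  keep_pt <- cum_w0[ks] > 0
  uplift <- cum_wy1[ks] - cum_wy0[ks] * ifelse(cum_w0[ks] > 0,
                                               cum_w1[ks] / cum_w0[ks], NA)
  denom <- if (scale == "per-subject") sum(ws) else 1
  curve <- data.frame(fraction = c(0, grid[keep_pt]),
                      uplift = c(0, uplift[keep_pt]) / denom)
  total <- curve$uplift[nrow(curve)]
  curve$baseline <- total * curve$fraction

  res <- structure(list(curve = curve, total_uplift = total, scale = scale,
                        weighted = !is.null(weights)),
                   class = "qini_result")
  res$coefficient <- qini_coefficient(res)
  res
}

#' Qini coefficient: signed area between curve and baseline
#'
#' Trapezoidal area under the Qini curve minus the area under the random
#' -ordering baseline; x in sample-fraction units, y on the curve's scale.
#'
#' @param result A `qini_result` from [qini_curve()].
#' @return Signed area (numeric scalar).
#' @export
qini_coefficient <- function(result) {
  assert_that(inherits(result, "qini_result"), "result must be a qini_result")
  cv <- result$curve
  if (nrow(cv) < 2) {
    stop_ps("Qini curve has fewer than 2 points", class = "pragsub_degenerate_input")
  }
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  trap(cv$fraction, cv$uplift) - trap(cv$fraction, cv$baseline)
}

#' @export
print.qini_result <- function(x, ...) {
  cat(sprintf("<qini_result> coefficient %.4f (%s scale, %sweighted, %d curve points)\n",
              x$coefficient, x$scale, if (x$weighted) "IPCW-" else "un",
              nrow(x$curve)))
  invisible(x)
}

## Concordance between two groups of predicted benefits: pairs are scored
## against every pair in a lower observed-benefit group; strict concordance
## counts 1, ties 1/2. Counting uses sorted vectors + findInterval, O(n log n).
concordance_counts <- function(p_low, p_high) {
  s <- sort(p_low)
  le <- findInterval(p_high, s)                    # #(p_low <= p)
  lt <- findInterval(p_high, s, left.open = TRUE)  # #(p_low <  p)
  conc <- sum(lt)
  ties <- sum(le - lt)
  c(conc = conc, ties = ties, total = length(p_low) * length(p_high))
}

cbenefit_statistic <- function(tau_t, y_t, tau_c, y_c) {
  ## rank-match: j-th highest-predicted treated with j-th highest control;
  ## surplus lowest-ranked subjects of the larger arm are dropped
  m <- min(length(tau_t), length(tau_c))
  if (m == 0) return(list(statistic = NA_real_, pairs = NULL, degenerate = TRUE))
  ot <- order(-tau_t)[seq_len(m)]
  oc <- order(-tau_c)[seq_len(m)]
  observed <- y_t[ot] - y_c[oc]                 # in {-1, 0, 1}
  predicted <- (tau_t[ot] + tau_c[oc]) / 2
  groups <- split(predicted, factor(observed, levels = c(-1, 0, 1)))
  conc <- 0; ties <- 0; total <- 0
  lv <- c("-1", "0", "1")
  for (i in 1:2) for (j in (i + 1):3) {
    lo <- groups[[lv[i]]]; hi <- groups[[lv[j]]]
    if (length(lo) && length(hi)) {
      cc <- concordance_counts(lo, hi)
      conc <- conc + cc["conc"]; ties <- ties + cc["ties"]; total <- total + cc["total"]
    }
  }
  if (total == 0) {
    return(list(statistic = NA_real_, degenerate = TRUE,
                pairs = data.frame(observed = observed, predicted = predicted)))
  }
  list(statistic = unname((conc + ties / 2) / total), degenerate = FALSE,
       pairs = data.frame(observed = observed, predicted = predicted))
}

#' C-for-benefit with bootstrap confidence interval
#'
#' Treated and control subjects are each ranked by predicted effect and
#' matched by rank (the j-th treated with the j-th control; the surplus
#' lowest-ranked subjects of the larger arm are dropped). A pair's observed
#' benefit is `Y_treated - Y_control` (in -1/0/1), its predicted benefit the
#' mean of the two predicted effects. The statistic is, over all pairs of
#' pairs with unequal observed benefit, the fraction in which the pair with
#' the larger observed benefit also has the strictly larger predicted benefit,
#' with predicted ties counted 1/2 — the probability that prediction and
#' observation agree about who benefits more. The confidence interval is a
#' percentile interval over subject-level bootstrap resamples drawn within
#' arm and re-paired each time.
#'
#' @param estimate A [cate_estimate()].
#' @param dataset The `trial_data` it refers to.
#' @param n_boot Bootstrap replicates (default 200); 0 skips the interval.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A `cbenefit_result`: list with `statistic`, `ci`, `n_pairs`,
#'   `pairs` (data.frame of observed/predicted pair benefits), `degenerate`.
#' @export
c_for_benefit <- function(estimate, dataset, n_boot = 200, level = 0.95,
                          seed = 1L) {
  al <- align_estimate(estimate, dataset)
  t_idx <- which(al$treatment == 1L)
  c_idx <- which(al$treatment == 0L)
  if (length(t_idx) == 0 || length(c_idx) == 0) {
    stop_ps("C-for-benefit needs both arms present",
            class = "pragsub_unsupported_input")
  }
  base <- cbenefit_statistic(al$tau[t_idx], al$outcome[t_idx],
                             al$tau[c_idx], al$outcome[c_idx])
  ci <- c(NA_real_, NA_real_)
  boots <- numeric(0)
  if (!base$degenerate && n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      ti <- sample(t_idx, length(t_idx), replace = TRUE)
      cj <- sample(c_idx, length(c_idx), replace = TRUE)
      cbenefit_statistic(al$tau[ti], al$outcome[ti],
                         al$tau[cj], al$outcome[cj])$statistic
    }, numeric(1)))
    alpha <- (1 - level) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  }
  structure(list(statistic = base$statistic,
                 ci = ci, level = level, n_boot = n_boot, seed = seed,
                 n_pairs = nrow(base$pairs) %||% 0L,
                 pairs = base$pairs,
                 degenerate = isTRUE(base$degenerate)),
            class = "cbenefit_result")
}

#' @export
print.cbenefit_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<cbenefit_result> degenerate: no pair-of-pairs with unequal observed benefit\n")
  } else {
    cat(sprintf("<cbenefit_result> %.4f (%d%% CI %.4f-%.4f; %d pairs, %d bootstrap reps)\n",
                x$statistic, round(100 * x$level), x$ci[1], x$ci[2],
                x$n_pairs, x$n_boot))
  }
  invisible(x)
}
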