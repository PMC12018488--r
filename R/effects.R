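## group_effects: AIPW validation of discovered subgroups. The influence
## values are computed once, globally, from the arm-specific outcome
## predictions and the known (or supplied) propensity, then aggregated per
## subgroup with the IPCW weights. With a known randomization probability the
## estimator is unbiased regardless of the outcome model (double robustness).

#' Per-subject AIPW influence values
#'
#' Computes, for every retained subject,
#' `psi_i = mu1(x_i) - mu0(x_i) + A_i (Y_i - mu1(x_i)) / e
#'          - (1 - A_i)(Y_i - mu0(x_i)) / (1 - e)`,
#' whose (weighted) mean over any subgroup estimates that subgroup's average
#' treatment effect on the risk-difference scale. When `estimate` carries no
#' arm predictions (e.g. the oracle), zeros are substituted, which reduces
#' psi to the IPW difference-in-means contribution.
#'
#' @param dataset A `trial_data`.
#' @param estimate A [cate_estimate()]; arm predictions are used when present.
#' @param propensity Treatment probability `e` in (0, 1); in a randomized
#'   trial this is the known randomization share (default 0.5).
#' @param weights Optional [fit_censoring_weights()]; its IPCW weight rides
#'   along each influence value for aggregation.
#' @return An `aipw_scores` object: data.frame with `subject_id`, `psi`,
#'   `weight` for the retained subjects.
#' @export
aipw_scores <- function(dataset, estimate, propensity = 0.5, weights = NULL) {
  assert_that(is.numeric(propensity) && length(propensity) == 1L &&
                propensity > 0 && propensity < 1,
              "propensity must lie strictly inside (0, 1)",
              class = "pragsub_config_error")
  al <- align_estimate(estimate, dataset)
  w <- retained_weights(dataset, weights)
  mu0 <- al$mu0 %||% rep(0, length(al$tau))
  mu1 <- al$mu1 %||% rep(0, length(al$tau))
  A <- al$treatment
  Y <- al$outcome
  psi <- mu1 - mu0 +
    A * (Y - mu1) / propensity -
    (1 - A) * (Y - mu0) / (1 - propensity)
  structure(data.frame(subject_id = al$ids, psi = psi, weight = w,
                       stringsAsFactors = FALSE),
            propensity = propensity,
            class = c("aipw_scores", "data.frame"))
}

#' Group-specific AIPW risk differences
#'
#' Aggregates influence values per discovered subgroup: the weighted mean of
#' psi (reported in percentage points), its standard error (weighted standard
#' deviation over the square root of the Kish effective sample size) and the
#' normal-approximation 95\% interval, plus an `all` row computed identically
#' on the whole sample. Groups of size < 2 are reported with an undefined CI
#' and flagged.
#'
#' @param scores [aipw_scores()] result.
#' @param groups Group labels aligned with `scores` rows (any atomic vector),
#'   e.g. from [assign_groups()].
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `group`, `n`, `rd_pp`, `se_pp`,
#'   `ci_lower`, `ci_upper`, `flagged`.
#' @export
group_ate_table <- function(scores, groups, level = 0.95) {
  assert_that(inherits(scores, "aipw_scores"), "scores must come from aipw_scores()")
  assert_that(length(groups) == nrow(scores),
              "groups must label every influence value")
  assert_that(!anyNA(groups), "group labels contain NA")
  z <- qnorm(1 - (1 - level) / 2)

  one_row <- function(label, idx) {
    psi <- scores$psi[idx]
    w <- scores$weight[idx]
    n <- length(idx)
    est <- wmean(psi, w)
    if (n < 2) {
      return(data.frame(group = label, n = n, rd_pp = 100 * est,
                        se_pp = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    se <- sqrt(wvar(psi, w) / effective_n(w))
    data.frame(group = label, n = n,
               rd_pp = 100 * est, se_pp = 100 * se,
               ci_lower = 100 * (est - z * se), ci_upper = 100 * (est + z * se),
               flagged = FALSE, stringsAsFactors = FALSE)
  }

  labs <- sort(unique(groups))
  out <- do.call(rbind, c(
    list(one_row("all", seq_len(nrow(scores)))),
    lapply(labs, function(g) one_row(as.character(g), which(groups == g)))
  ))
  rownames(out) <- NULL
  out
}
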