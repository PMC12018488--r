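## IPCW: inverse probability of censoring weighting. Retention is modelled
## with a main-effects logistic regression on treatment and covariates (MAR),
## and retained subjects are reweighted by 1 / P(retained | A, X).

#' Fit inverse-probability-of-censoring weights
#'
#' Fits a main-effects logistic model of the retention indicator on treatment
#' and the (raw) covariates, using all subjects, and converts fitted retention
#' probabilities into weights `1/p` for the retained subjects. Weights are
#' truncated from above at the stated quantile of the retained-subject weight
#' distribution, a standard positivity safeguard.
#'
#' If the model cannot be fit (no variation in retention, or complete
#' separation / non-convergence), the fit falls back to an intercept-only
#' model, which yields the constant weight `n / n_retained`; the fallback is
#' recorded in the metadata.
#'
#' @param dataset A `trial_data`.
#' @param truncation_quantile Upper quantile at which weights are capped
#'   (default 0.99).
#' @param covariates Character vector of covariate names entering the model
#'   alongside treatment; `NULL` (default) uses all declared covariates;
#'   `character(0)` requests the intercept-only fit.
#' @return A `censoring_weights` object: list with `probability` (all
#'   subjects), `weight` (NA for non-retained), `truncation_quantile`,
#'   `metadata`.
#' @export
fit_censoring_weights <- function(dataset, truncation_quantile = 0.99,
                                  covariates = NULL) {
  assert_that(inherits(dataset, "trial_data"), "dataset must be a trial_data")
  assert_that(is_prob(truncation_quantile),
              "truncation_quantile must be a probability")
  retained <- dataset$retained
  n <- length(retained)
  kinds <- attr(dataset, "kinds")
  if (is.null(covariates)) covariates <- names(kinds)

  meta <- list(model = "logistic", fallback = FALSE,
               n = n, n_retained = sum(retained))
  fit_intercept_only <- function() {
    p <- rep(mean(retained), n)
    meta$model <<- "intercept-only"
    p
  }

  if (all(retained == 1L) || all(retained == 0L) ) {
    probability <- rep(mean(retained), n)
    meta$model <- "degenerate"
  } else if (length(covariates) == 0) {
    probability <- fit_intercept_only()
  } else {
    df <- as.data.frame(dataset)[, c("treatment", covariates), drop = FALSE]
    df$..retained <- retained
    fit <- tryCatch(
      suppressWarnings(glm(..retained ~ ., data = df, family = binomial())),
      error = function(e) NULL
    )
    bad <- is.null(fit) || !fit$converged ||
      any(!is.finite(predict(fit, type = "response")))
    if (bad) {
      probability <- fit_intercept_only()
      meta$fallback <- TRUE
    } else {
      probability <- as.numeric(predict(fit, type = "response"))
    }
  }

  probability <- pmin(pmax(probability, 1e-12), 1)
  weight <- ifelse(retained == 1L, 1 / probability, NA_real_)
  cap <- quantile(weight[retained == 1L], truncation_quantile,
                  na.rm = TRUE, names = FALSE, type = 7)
  meta$truncation_cap <- cap
  meta$n_truncated <- sum(weight > cap, na.rm = TRUE)
  weight <- pmin(weight, cap)

  structure(list(probability = probability,
                 weight = weight,
                 subject_id = dataset$subject_id,
                 truncation_quantile = truncation_quantile,
                 metadata = meta),
            class = "censoring_weights")
}

#' @export
print.censoring_weights <- function(x, ...) {
  w <- x$weight[!is.na(x$weight)]
  cat(sprintf("<censoring_weights> %s model; %d retained of %d; weights %.3f-%.3f (%d truncated at %.3f)\n",
              x$metadata$model, x$metadata$n_retained, x$metadata$n,
              min(w), max(w), x$metadata$n_truncated, x$metadata$truncation_cap))
  invisible(x)
}

## Weights for the retained subjects, in dataset order; unit weights when
## `weights` is NULL (the no-censoring case).
retained_weights <- function(dataset, weights) {
  keep <- dataset$retained == 1L
  if (is.null(weights)) return(rep(1, sum(keep)))
  assert_that(inherits(weights, "censoring_weights"),
              "weights must come from fit_censoring_weights()")
  assert_that(identical(weights$subject_id, dataset$subject_id),
              "weights were fit on a different dataset (subject ids differ)")
  weights$weight[keep]
}
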