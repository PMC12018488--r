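## cate_estimation: per-subject CATEs on the risk-difference scale behind a
## pluggable estimator contract. The reference estimator is an honest
## T-learner: one honest weighted regression-tree ensemble per arm, tau =
## mu1 - mu0. Bayesian causal forest (or any other meta-learner) estimates
## can be imported instead via read_cate_estimates().

#' Construct a per-subject CATE estimate
#'
#' The common currency of the pipeline: per-subject estimated (or oracle, or
#' imported) treatment effects on the risk-difference scale, optionally with
#' the arm-specific event-free probability predictions needed downstream by
#' AIPW.
#'
#' @param subject_id Character vector of subject ids.
#' @param tau_hat Numeric vector in `[-1, 1]`, one per subject.
#' @param mu0_hat,mu1_hat Optional arm-specific predictions in `[0, 1]`.
#' @param provenance List describing where the estimate came from (e.g.
#'   `list(type = "honest_t_learner", ...)`, `"oracle"`, `"imported"`).
#' @return A `cate_estimate`: data.frame with attribute `provenance`.
#' @export
cate_estimate <- function(subject_id, tau_hat, mu0_hat = NULL, mu1_hat = NULL,
                          provenance = list(type = "unspecified")) {
  assert_that(length(subject_id) == length(tau_hat),
              "subject_id and tau_hat lengths differ")
  assert_that(!anyNA(tau_hat) && all(is.finite(tau_hat)),
              "tau_hat must be finite for every subject")
  assert_that(all(tau_hat >= -1 & tau_hat <= 1), "tau_hat must lie in [-1, 1]")
  assert_that(!anyDuplicated(subject_id), "subject_id must be unique")
  df <- data.frame(subject_id = as.character(subject_id), tau_hat = tau_hat,
                   stringsAsFactors = FALSE)
  if (!is.null(mu0_hat) || !is.null(mu1_hat)) {
    assert_that(!is.null(mu0_hat) && !is.null(mu1_hat),
                "supply both arm predictions or neither")
    assert_that(all(mu0_hat >= 0 & mu0_hat <= 1) && all(mu1_hat >= 0 & mu1_hat <= 1),
                "arm predictions must lie in [0, 1]")
    df$mu0_hat <- mu0_hat
    df$mu1_hat <- mu1_hat
  }
  structure(df, provenance = provenance,
            class = c("cate_estimate", "data.frame"))
}

#' @export
print.cate_estimate <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<cate_estimate> %d subjects, provenance: %s\n", nrow(x),
              prov$type %||% "unspecified"))
  cat(sprintf("  tau_hat: mean %+.4f, range [%+.4f, %+.4f]%s\n",
              mean(x$tau_hat), min(x$tau_hat), max(x$tau_hat),
              if (!is.null(x$mu0_hat)) "; arm predictions present" else ""))
  invisible(x)
}

## One-hot design matrix over the declared covariates. Factor levels are
## frozen into the schema at fit time so prediction can verify compatibility.
build_design <- function(covariates, kinds, schema = NULL) {
  cols <- list()
  for (nm in names(kinds)) {
    x <- covariates[[nm]]
    if (anyNA(x)) stop_ps("covariate '", nm, "' contains missing values; impute first")
    if (kinds[[nm]] == "categorical") {
      lev <- if (!is.null(schema)) schema$levels[[nm]]
             else if (is.factor(x)) levels(x)
             else sort(unique(as.character(x)))
      for (l in lev) cols[[paste0(nm, "=", l)]] <- as.numeric(as.character(x) == l)
    } else {
      cols[[nm]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  cat_names <- names(kinds)[kinds == "categorical"]
  lev_of <- function(nm) {
    x <- covariates[[nm]]
    if (!is.null(schema)) schema$levels[[nm]]
    else if (is.factor(x)) levels(x)
    else sort(unique(as.character(x)))
  }
  list(X = X,
       schema = list(columns = colnames(X),
                     covariates = names(kinds),
                     kinds = kinds,
                     levels = setNames(lapply(cat_names, lev_of), cat_names)))
}

#' Fit the reference CATE model (honest T-learner)
#'
#' Fits, per arm, an ensemble of `n_trees` honest weighted regression trees to
#' the reverse-coded outcome among retained subjects: each tree is grown on a
#' bootstrap draw whose first half chooses splits and whose second half
#' supplies leaf means. The CATE is the difference of the two arm ensembles,
#' `tau_hat(x) = mu1_hat(x) - mu0_hat(x)`. IPCW weights (when supplied) enter
#' both the split criterion and the leaf means. The model is fit on all
#' retained subjects (no sample splitting), so in-sample calibration metrics
#' carry the usual optimism caveat.
#'
#' @param dataset A `trial_data`.
#' @param weights Optional [fit_censoring_weights()] result; `NULL` = unit
#'   weights.
#' @param n_trees Trees per arm (default 200).
#' @param min_leaf Minimum subjects per leaf in the split sample (default 20).
#' @param honest Use disjoint split/estimation halves (default TRUE); FALSE
#'   gives the adaptive (non-honest) ensemble, kept for diagnostics.
#' @param seed Integer seed for the bootstrap draws.
#' @return A `cate_model`.
#' @export
fit_cate_model <- function(dataset, weights = NULL, n_trees = 200,
                           min_leaf = 20, honest = TRUE, seed = 1L) {
  assert_that(inherits(dataset, "trial_data"), "dataset must be a trial_data")
  kinds <- attr(dataset, "kinds")
  keep <- dataset$retained == 1L
  w <- retained_weights(dataset, weights)
  dat <- as.data.frame(dataset)[keep, , drop = FALSE]
  design <- build_design(dat[, names(kinds), drop = FALSE], kinds)
  y <- as.numeric(dat$outcome)
  arms <- list(`0` = which(dat$treatment == 0L), `1` = which(dat$treatment == 1L))
  for (a in names(arms)) {
    if (length(arms[[a]]) < 2 * min_leaf) {
      stop_ps("arm ", a, " has ", length(arms[[a]]),
              " retained subjects; need at least ", 2 * min_leaf,
              class = "pragsub_insufficient_data")
    }
  }

  forests <- with_seed(seed, {
    lapply(arms, function(rows) {
      na <- length(rows)
      boot <- matrix(sample.int(na, na * n_trees, replace = TRUE),
                     nrow = na, ncol = n_trees)
      .hf_grow(design$X[rows, , drop = FALSE], y[rows], w[rows], boot,
               honest, as.integer(min_leaf))
    })
  })

  model <- structure(list(
    forests = forests,
    schema = design$schema,
    metadata = list(type = "honest_t_learner", n_trees = n_trees,
                    min_leaf = min_leaf, honest = honest, seed = seed,
                    weighted = !is.null(weights),
                    n_fit = sum(keep))
  ), class = "cate_model")
  model$training <- list(subject_id = dat$subject_id)
  model
}

#' @export
print.cate_model <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<cate_model> %s: %d trees/arm, min_leaf %d, %s, %sweighted, fit on %d subjects (seed %d)\n",
              m$type, m$n_trees, m$min_leaf,
              if (m$honest) "honest" else "adaptive",
              if (m$weighted) "IPCW-" else "un", m$n_fit, m$seed))
  invisible(x)
}

#' Predict per-subject treatment effects from a fitted CATE model
#'
#' @param model A `cate_model` from [fit_cate_model()].
#' @param newdata A `trial_data` or a covariate data.frame matching the
#'   training schema (plus `subject_id`).
#' @return A [cate_estimate()] with arm predictions, for the retained subjects
#'   when `newdata` is a `trial_data`.
#' @export
predict_effects <- function(model, newdata) {
  assert_that(inherits(model, "cate_model"), "model must be a cate_model")
  schema <- model$schema
  if (inherits(newdata, "trial_data")) {
    keep <- newdata$retained == 1L
    df <- as.data.frame(newdata)[keep, , drop = FALSE]
  } else {
    df <- as.data.frame(newdata)
  }
  missing <- setdiff(schema$covariates, names(df))
  extra <- setdiff(setdiff(names(df), schema$covariates),
                   c("subject_id", "treatment", "outcome", "retained",
                     "oracle_effect", "oracle_cell"))
  if (length(missing) || length(extra)) {
    stop_ps("covariate schema mismatch; missing: [",
            paste(missing, collapse = ", "), "], unexpected: [",
            paste(extra, collapse = ", "), "]",
            class = "pragsub_contract_error")
  }
  ## unseen categorical levels are a schema violation too
  for (nm in names(schema$levels)) {
    seen <- unique(as.character(df[[nm]]))
    unseen <- setdiff(seen[!is.na(seen)], schema$levels[[nm]])
    if (length(unseen)) {
      stop_ps("covariate '", nm, "' has levels unseen at fit time: ",
              paste(unseen, collapse = ", "), class = "pragsub_contract_error")
    }
  }
  design <- build_design(df[, schema$covariates, drop = FALSE], schema$kinds,
                         schema = schema)
  mu0 <- pmin(pmax(.hf_predict(model$forests[["0"]], design$X), 0), 1)
  mu1 <- pmin(pmax(.hf_predict(model$forests[["1"]], design$X), 0), 1)
  ids <- if ("subject_id" %in% names(df)) df$subject_id else
    sprintf("row%d", seq_len(nrow(df)))
  cate_estimate(subject_id = ids, tau_hat = mu1 - mu0,
                mu0_hat = mu0, mu1_hat = mu1,
                provenance = model$metadata)
}

#' Import externally produced CATE estimates
#'
#' Reads a CSV with columns `subject_id`, `tau_hat` and optionally `mu0_hat`,
#' `mu1_hat` — the hook for running, say, a Bayesian causal forest in another
#' environment and feeding its posterior-mean effects into Step 2.
#'
#' @param path CSV path.
#' @return A [cate_estimate()] with provenance `"imported"`.
#' @export
read_cate_estimates <- function(path) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "pragsub_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character"))
  assert_that(all(c("subject_id", "tau_hat") %in% names(df)),
              "CATE import needs columns subject_id, tau_hat")
  has_mu <- all(c("mu0_hat", "mu1_hat") %in% names(df))
  cate_estimate(df$subject_id, df$tau_hat,
                mu0_hat = if (has_mu) df$mu0_hat,
                mu1_hat = if (has_mu) df$mu1_hat,
                provenance = list(type = "imported", path = path))
}

#' Write CATE estimates as CSV
#' @param estimate A `cate_estimate`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cate_estimates <- function(estimate, path) {
  assert_that(inherits(estimate, "cate_estimate"), "not a cate_estimate")
  write.csv(as.data.frame(estimate), path, row.names = FALSE)
  invisible(path)
}
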