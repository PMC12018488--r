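# Shared fixtures: all synthetic, built in code at test time.

# Minimal hand-built trial for worked examples. Everyone retained unless
# stated; covariates default to a single standard-normal column.
make_trial <- function(treatment, outcome, covariates = NULL, retained = NULL,
                       kinds = NULL, oracle = NULL, seed = 99) {
  n <- length(treatment)
  if (is.null(covariates)) {
    covariates <- withr_seed_df(n, seed)
    kinds <- c(x = "continuous")
  }
  if (is.null(kinds)) {
    kinds <- vapply(covariates, function(col) {
      if (is.factor(col) || is.character(col)) "categorical"
      else if (all(col %in% c(0, 1))) "binary" else "continuous"
    }, "")
  }
  retained <- retained %||% rep(1L, n)
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   treatment = as.integer(treatment),
                   outcome = ifelse(retained == 1L, as.integer(outcome), NA_integer_),
                   retained = as.integer(retained),
                   stringsAsFactors = FALSE)
  df <- cbind(df, covariates)
  if (!is.null(oracle)) {
    df$oracle_effect <- oracle
    df$oracle_cell <- "manual"
  }
  pragsub:::new_trial_data(df, kinds)
}

withr_seed_df <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(x = rnorm(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduced-roster simulation config: fast to generate, keeps the planted
# scenario covariates plus a few prognostic/noise ones.
small_sim <- function(n = 800, seed = 1, scenario = "step_subgroups", ...) {
  sim_config(n_subjects = n, scenario = scenario, seed = seed,
             covariate_names = c("age", "hba1c", "bmi", "female", "sbp",
                                 "hist_cvd", "hist_mi"),
             ...)
}

# Difference-in-means ATE among retained subjects, optionally IPCW-weighted.
dim_ate <- function(d, w = NULL) {
  keep <- d$retained == 1L
  y <- d$outcome[keep]
  a <- d$treatment[keep]
  wt <- if (is.null(w)) rep(1, sum(keep)) else w$weight[keep]
  sum(wt * y * a) / sum(wt * a) - sum(wt * y * (1 - a)) / sum(wt * (1 - a))
}

# Exhaustive best-split search over all covariates of a small data.frame:
# every admissible binary partition (thresholds for numeric/ordered, all
# proper level subsets for unordered factors), honoring min_leaf. Returns the
# maximal weighted SSE reduction. Independent of the greedy implementation.
brute_force_best <- function(tau, covs, w = NULL, min_leaf = 1) {
  w <- w %||% rep(1, length(tau))
  sse <- function(v, wt) if (length(v)) sum(wt * (v - sum(wt * v) / sum(wt))^2) else 0
  total <- sse(tau, w)
  best <- 0
  for (nm in names(covs)) {
    x <- covs[[nm]]
    parts <- list()
    if (is.numeric(x) || is.ordered(x)) {
      xx <- if (is.ordered(x)) as.integer(x) else x
      for (t in sort(unique(xx))[-length(unique(xx))]) {
        parts[[length(parts) + 1]] <- xx <= t
      }
    } else {
      lev <- unique(as.character(x))
      if (length(lev) >= 2) {
        for (mask in 1:(2^length(lev) - 2)) {
          subset <- lev[bitwAnd(mask, 2^(seq_along(lev) - 1)) > 0]
          parts[[length(parts) + 1]] <- as.character(x) %in% subset
        }
      }
    }
    for (left in parts) {
      nl <- sum(left)
      if (nl < min_leaf || length(tau) - nl < min_leaf) next
      red <- total - sse(tau[left], w[left]) - sse(tau[!left], w[!left])
      if (red > best) best <- red
    }
  }
  best
}
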