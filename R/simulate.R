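## trial_synthesis: synthetic two-arm randomized trials with planted,
## subgroup-structured treatment-effect heterogeneity, binary (reverse-coded)
## outcomes and covariate-dependent (MAR) censoring.

#' Default covariate roster for the synthetic trial
#'
#' Returns the 47-covariate roster the generator emulates: 30 continuous,
#' 12 binary and 5 categorical variables whose names line up with the shipped
#' interpretable-recoding ruleset (clinical labs, blood pressure, SF-36
#' quality-of-life scales, depression score, histories and demographics of a
#' lifestyle-intervention diabetes trial).
#'
#' @return A data.frame with columns `name`, `kind`
#'   (`continuous`/`binary`/`categorical`) and list-columns of generation
#'   parameters.
#' @export
covariate_roster <- function() {
  cont <- function(name, mean, sd, lower = -Inf) {
    list(name = name, kind = "continuous", mean = mean, sd = sd, lower = lower)
  }
  bin <- function(name, p) list(name = name, kind = "binary", p = p)
  cat_ <- function(name, levels, probs) {
    list(name = name, kind = "categorical", levels = levels, probs = probs)
  }
  roster <- list(
    cont("age", 59, 7, lower = 45),
    cont("bmi", 36, 6, lower = 17),
    cont("alcohol_oz_wk", 1.2, 2.5, lower = 0),
    cont("fasting_glucose", 152, 45, lower = 40),
    cont("hba1c", 7.3, 1.2, lower = 4.5),
    cont("hdl", 44, 12, lower = 15),
    cont("ldl", 113, 32, lower = 30),
    cont("triglycerides", 180, 110, lower = 40),
    cont("urine_albumin", 3.5, 8, lower = 0),
    cont("urine_creatinine", 120, 60, lower = 10),
    cont("urine_acr", 35, 90, lower = 0),
    cont("sbp", 129, 17, lower = 80),
    cont("sf36_general_health", 50, 10),
    cont("sf36_mental_health", 53, 9),
    cont("sf36_bodily_pain", 49, 10),
    cont("sf36_physical_functioning", 47, 10),
    cont("sf36_role_emotional", 51, 10),
    cont("sf36_role_physical", 48, 10),
    cont("sf36_social_functioning", 51, 9),
    cont("sf36_vitality", 49, 10),
    cont("sf36_transition", 3, 1),
    cont("sf36_mcs", 54, 8),
    cont("sf36_pcs", 45, 8),
    cont("beck_depression", 8, 6, lower = 0),
    cont("dbp", 75, 10, lower = 40),
    cont("weight_kg", 101, 19, lower = 45),
    cont("waist_cm", 114, 14, lower = 70),
    cont("heart_rate", 72, 10, lower = 40),
    cont("diabetes_duration_yr", 7, 6, lower = 0),
    cont("serum_creatinine", 0.85, 0.2, lower = 0.3),
    bin("female", 0.58),
    bin("hist_cvd", 0.30),
    bin("hist_mi", 0.25),
    bin("hist_stroke", 0.03),
    bin("hypertension_dx", 0.74),
    bin("statin_use", 0.45),
    bin("insulin_use", 0.16),
    bin("metformin_use", 0.60),
    bin("current_smoker", 0.04),
    bin("family_hist_cvd", 0.38),
    bin("retinopathy", 0.08),
    bin("neuropathy", 0.20),
    cat_("race_ethnicity",
         c("white", "black", "hispanic", "asian_pacific", "other"),
         c(0.63, 0.16, 0.13, 0.05, 0.03)),
    cat_("education",
         c("lt_high_school", "high_school", "some_college", "college_plus"),
         c(0.07, 0.18, 0.35, 0.40)),
    cat_("marital_status", c("married", "previously_married", "never_married"),
         c(0.66, 0.24, 0.10)),
    cat_("employment", c("full_time", "part_time", "retired", "not_working"),
         c(0.52, 0.10, 0.27, 0.11)),
    cat_("clinic_region", c("northeast", "south", "midwest", "west"),
         c(0.22, 0.30, 0.24, 0.24))
  )
  roster
}

#' Simulation configuration for a synthetic two-arm trial
#'
#' Builds and validates the configuration consumed by [simulate_trial()]. The
#' defaults describe a "Look-AHEAD-like" trial: n = 4,600 subjects, 47
#' mixed-type covariates, 1:1 randomization, a binary 7-year outcome with a
#' 13\% event rate (reverse-coded so 1 = event-free and a higher treatment
#' effect means higher benefit) and ~6\% covariate-dependent loss to
#' follow-up.
#'
#' @param n_subjects Number of subjects.
#' @param treatment_probability Randomization probability for the treated arm,
#'   in (0, 1).
#' @param scenario Planted-heterogeneity scenario: `"null"` (no effect
#'   anywhere), `"step_subgroups"` (a 2x2 grid of cells over two binary
#'   covariates, each with its own constant risk-difference effect) or
#'   `"continuous_threshold"` (effect switches at a threshold of a continuous
#'   covariate).
#' @param cell_effects Named numeric vector of risk differences in `[-1, 1]`
#'   (probability of being event-free, treated minus control). For
#'   `step_subgroups`, names are `"cvd0_mi0"`, `"cvd0_mi1"`, `"cvd1_mi0"`,
#'   `"cvd1_mi1"` (cells of `hist_cvd` x `hist_mi`); defaults plant effects
#'   \{+0.08, +0.03, 0, -0.10\} so the span is 0.18. For
#'   `continuous_threshold`, names are `"below"`/`"above"` (HbA1c 7\%).
#' @param baseline_risk Marginal event risk in the control arm (default 0.13).
#' @param prognostic_strength Scale of the covariate effect on baseline risk;
#'   0 removes prognostic structure. The shift is bounded by construction so
#'   event probabilities stay inside `[0, 1]` (validated).
#' @param censoring_rate Target marginal probability of loss to follow-up, in
#'   `[0, 0.5]` (default 0.062).
#' @param censoring_coefficients Named log-odds coefficients of the censoring
#'   model on standardized covariates and treatment (MAR: never on the
#'   outcome). The intercept is calibrated so the marginal censoring rate hits
#'   `censoring_rate`.
#' @param covariate_names Optional subset of [covariate_roster()] names to
#'   generate (scenario covariates are added automatically); `NULL` = all 47.
#' @param seed Integer seed; the single source of randomness for the draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4600,
                       treatment_probability = 0.5,
                       scenario = c("step_subgroups", "null", "continuous_threshold"),
                       cell_effects = NULL,
                       baseline_risk = 0.13,
                       prognostic_strength = 1,
                       censoring_rate = 0.062,
                       censoring_coefficients = c(age = 0.6, hba1c = 0.5, treatment = -0.2),
                       covariate_names = NULL,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  assert_that(is.numeric(n_subjects) && n_subjects >= 0 &&
                n_subjects == round(n_subjects),
              "n_subjects must be a non-negative integer")
  assert_that(is_prob(treatment_probability) &&
                treatment_probability > 0 && treatment_probability < 1,
              "treatment_probability must lie strictly inside (0, 1)")
  assert_that(is_prob(baseline_risk), "baseline_risk must be a probability")
  assert_that(is_prob(censoring_rate) && censoring_rate <= 0.5,
              "censoring_rate must lie in [0, 0.5]")

  ## YAML round-trips named vectors as lists; accept both
  if (is.list(cell_effects)) cell_effects <- unlist(cell_effects)
  if (is.list(censoring_coefficients)) {
    censoring_coefficients <- unlist(censoring_coefficients)
  }
  if (is.null(cell_effects)) {
    cell_effects <- switch(scenario,
      null = c(all = 0),
      step_subgroups = c(cvd0_mi0 = 0.08, cvd0_mi1 = 0.03,
                         cvd1_mi0 = 0.00, cvd1_mi1 = -0.10),
      continuous_threshold = c(below = 0.06, above = -0.04)
    )
  }
  assert_that(all(abs(cell_effects) <= 1), "cell effects must lie in [-1, 1]")
  if (scenario == "step_subgroups") {
    need <- c("cvd0_mi0", "cvd0_mi1", "cvd1_mi0", "cvd1_mi1")
    assert_that(all(need %in% names(cell_effects)),
                "step_subgroups needs cell effects named ",
                paste(need, collapse = ", "))
  }
  if (scenario == "continuous_threshold") {
    assert_that(all(c("below", "above") %in% names(cell_effects)),
                "continuous_threshold needs cell effects named below, above")
  }

  ## invariant: baseline event-free probability plus every cell effect and the
  ## largest possible prognostic shift must stay inside [0, 1]
  p0 <- 1 - baseline_risk
  shift <- 0.04 * prognostic_strength  # max |prognostic shift|, by construction
  for (cell in names(cell_effects)) {
    p_hi <- p0 + shift + max(0, cell_effects[[cell]])
    p_lo <- p0 - shift + min(0, cell_effects[[cell]])
    if (p_hi > 1 || p_lo < 0) {
      stop_ps("cell '", cell, "' yields event-free probability outside [0, 1] ",
              sprintf("(range %.3f to %.3f)", p_lo, p_hi),
              class = "pragsub_config_error")
    }
  }

  roster <- covariate_roster()
  roster_names <- vapply(roster, `[[`, "", "name")
  if (!is.null(covariate_names)) {
    needed <- switch(scenario,
      step_subgroups = c("hist_cvd", "hist_mi"),
      continuous_threshold = "hba1c",
      character(0))
    covariate_names <- union(covariate_names, needed)
    missing <- setdiff(covariate_names, roster_names)
    assert_that(length(missing) == 0,
                "unknown covariate(s): ", paste(missing, collapse = ", "))
    roster <- roster[roster_names %in% covariate_names]
  }

  structure(list(
    n_subjects = as.integer(n_subjects),
    treatment_probability = treatment_probability,
    scenario = scenario,
    cell_effects = cell_effects,
    baseline_risk = baseline_risk,
    prognostic_strength = prognostic_strength,
    censoring_rate = censoring_rate,
    censoring_coefficients = censoring_coefficients,
    roster = roster,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## Bounded prognostic shift of the event-free probability. Uses plogis of the
## standardized covariate so the shift never exceeds +/- 0.04 *
## prognostic_strength regardless of covariate tails; this keeps the planted
## cell effects exact risk differences while making the outcome (and hence
## censoring, which shares the age/HbA1c coefficients) covariate-dependent.
prognostic_shift <- function(covariates, strength) {
  if (strength == 0) return(rep(0, nrow(covariates)))
  z_age <- if ("age" %in% names(covariates)) {
    (covariates$age - 59) / 7
  } else rep(0, nrow(covariates))
  z_a1c <- if ("hba1c" %in% names(covariates)) {
    (covariates$hba1c - 7.3) / 1.2
  } else rep(0, nrow(covariates))
  ## older / poorer glycemic control -> higher event risk (lower event-free)
  strength * (-0.05 * (plogis(z_age) - 0.5) - 0.03 * (plogis(z_a1c) - 0.5))
}

plant_effect <- function(config, covariates) {
  n <- nrow(covariates)
  switch(config$scenario,
    null = list(tau = rep(0, n), cell = rep("all", n)),
    step_subgroups = {
      cell <- sprintf("cvd%d_mi%d", covariates$hist_cvd, covariates$hist_mi)
      list(tau = unname(config$cell_effects[cell]), cell = cell)
    },
    continuous_threshold = {
      cell <- ifelse(covariates$hba1c < 7, "below", "above")
      list(tau = unname(config$cell_effects[cell]), cell = cell)
    }
  )
}

draw_covariates <- function(roster, n) {
  cols <- lapply(roster, function(r) {
    switch(r$kind,
      continuous = pmax(rnorm(n, r$mean, r$sd), r$lower),
      binary = rbinom(n, 1L, r$p),
      categorical = factor(sample(r$levels, n, replace = TRUE, prob = r$probs),
                           levels = r$levels)
    )
  })
  names(cols) <- vapply(roster, `[[`, "", "name")
  ## alcohol is zero-inflated: a point mass of non-drinkers
  if ("alcohol_oz_wk" %in% names(cols)) {
    drinks <- rbinom(n, 1L, 0.55)
    cols$alcohol_oz_wk <- ifelse(drinks == 1L,
                                 pmax(rlnorm(n, log(1.5), 0.9), 0.02), 0)
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

## Linear predictor of the censoring model on standardized covariates.
censoring_lp <- function(config, covariates, treatment) {
  lp <- rep(0, nrow(covariates))
  coefs <- config$censoring_coefficients
  for (nm in names(coefs)) {
    if (nm == "treatment") {
      lp <- lp + coefs[[nm]] * treatment
    } else if (nm %in% names(covariates)) {
      x <- covariates[[nm]]
      if (is.factor(x)) x <- as.integer(x)
      s <- sd(x)
      if (s > 0) lp <- lp + coefs[[nm]] * (x - mean(x)) / s
    }
  }
  lp
}

#' Simulate a synthetic two-arm randomized trial
#'
#' Draws covariates from the configured roster, assigns treatment
#' independently of covariates, generates the reverse-coded binary outcome
#' (1 = event-free at horizon) directly on the probability scale as baseline
#' event-free probability + prognostic shift + treatment x planted effect, and
#' draws loss to follow-up from a logistic model on treatment and covariates
#' (MAR; never on the outcome). The per-subject planted risk difference is
#' stored in the `oracle_effect` column, the generating cell in `oracle_cell`.
#'
#' @param config A [sim_config()].
#' @return A `trial_data` object: a data.frame with columns `subject_id`,
#'   `treatment`, `outcome` (NA when not retained), `retained`, the
#'   covariates, `oracle_effect` and `oracle_cell`; covariate kinds are kept
#'   in `attr(, "kinds")`.
#' @export
simulate_trial <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  n <- config$n_subjects
  kinds <- setNames(vapply(config$roster, `[[`, "", "kind"),
                    vapply(config$roster, `[[`, "", "name"))
  with_seed(config$seed, {
    covariates <- draw_covariates(config$roster, n)
    treatment <- rbinom(n, 1L, config$treatment_probability)
    planted <- plant_effect(config, covariates)
    p_eventfree <- (1 - config$baseline_risk) +
      prognostic_shift(covariates, config$prognostic_strength) +
      treatment * planted$tau
    if (n > 0 && (max(p_eventfree) > 1 || min(p_eventfree) < 0)) {
      bad <- planted$cell[which.max(pmax(p_eventfree - 1, -p_eventfree))]
      stop_ps("event probability outside [0, 1] in cell '", bad, "'",
              class = "pragsub_config_error")
    }
    outcome <- rbinom(n, 1L, p_eventfree)

    if (config$censoring_rate > 0 && n > 0) {
      lp <- censoring_lp(config, covariates, treatment)
      ## calibrate the intercept so the marginal censoring rate is as stated
      alpha <- uniroot(function(a) mean(plogis(a + lp)) - config$censoring_rate,
                       interval = c(-30, 30))$root
      censored <- rbinom(n, 1L, plogis(alpha + lp))
    } else {
      censored <- rep(0L, n)
    }
    retained <- 1L - censored
    outcome[retained == 0L] <- NA_integer_

    out <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      treatment = treatment,
      outcome = outcome,
      retained = retained,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, covariates)
    out$oracle_effect <- planted$tau
    out$oracle_cell <- planted$cell
    new_trial_data(out, kinds)
  })
}

new_trial_data <- function(df, kinds) {
  structure(df, kinds = kinds, class = c("trial_data", "data.frame"))
}

#' @export
print.trial_data <- function(x, ...) {
  kinds <- attr(x, "kinds")
  cat(sprintf("<trial_data> %d subjects, %d covariates (%d continuous, %d binary, %d categorical)\n",
              nrow(x), length(kinds),
              sum(kinds == "continuous"), sum(kinds == "binary"),
              sum(kinds == "categorical")))
  if (nrow(x) > 0) {
    cat(sprintf("  treated: %d | retained: %d | events (retained): %d\n",
                sum(x$treatment), sum(x$retained),
                sum(x$outcome[x$retained == 1L] == 0L)))
    if (!is.null(x$oracle_effect)) {
      cat("  oracle effects present (simulated data)\n")
    }
  }
  invisible(x)
}

#' Covariate columns of a trial dataset
#' @param dataset A `trial_data` object.
#' @return data.frame of covariates only.
#' @export
trial_covariates <- function(dataset) {
  kinds <- attr(dataset, "kinds")
  out <- as.data.frame(dataset)[, names(kinds), drop = FALSE]
  out
}

#' Oracle per-subject treatment effects of a simulated trial
#'
#' Returns the planted risk differences as a `cate_estimate` with provenance
#' `"oracle"`, for plugging into the downstream pipeline in place of a fitted
#' model. Arm predictions are not populated (the oracle is an effect, not an
#' outcome model).
#'
#' @param dataset A `trial_data` produced by [simulate_trial()].
#' @return A [cate_estimate()] for the retained subjects.
#' @export
oracle_cate <- function(dataset) {
  assert_that(inherits(dataset, "trial_data"), "dataset must be a trial_data")
  if (is.null(dataset$oracle_effect)) {
    stop_ps("dataset carries no oracle annotations (not produced by simulate_trial)",
            class = "pragsub_unsupported_input")
  }
  keep <- dataset$retained == 1L
  cate_estimate(subject_id = dataset$subject_id[keep],
                tau_hat = dataset$oracle_effect[keep],
                provenance = list(type = "oracle"))
}

#' Write / read a trial dataset as CSV plus a YAML schema sidecar
#'
#' The CSV holds one row per subject with a header; the sidecar records each
#' covariate's declared kind (and level order for categoricals) so the reader
#' can reconstruct the dataset losslessly, including empty (n = 0) datasets.
#'
#' @param dataset A `trial_data`.
#' @param path Output CSV path.
#' @param schema_path Sidecar path; defaults to `<path>.schema.yaml`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, schema_path = paste0(path, ".schema.yaml")) {
  assert_that(inherits(dataset, "trial_data"), "dataset must be a trial_data")
  kinds <- attr(dataset, "kinds")
  schema <- list(
    columns = lapply(names(kinds), function(nm) {
      entry <- list(name = nm, kind = unname(kinds[[nm]]))
      if (kinds[[nm]] == "categorical") entry$levels <- levels(dataset[[nm]])
      entry
    }),
    has_oracle = !is.null(dataset[["oracle_effect"]])
  )
  ok <- tryCatch(suppressWarnings({
    yaml::write_yaml(schema, schema_path)
    write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) stop_ps("cannot write dataset: ", conditionMessage(ok),
                           class = "pragsub_io_error")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, schema_path = paste0(path, ".schema.yaml")) {
  assert_that(file.exists(path), "no such file: ", path,
              class = "pragsub_io_error")
  assert_that(file.exists(schema_path), "no such schema sidecar: ", schema_path,
              class = "pragsub_io_error")
  schema <- yaml::read_yaml(schema_path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character"))
  kinds <- setNames(
    vapply(schema$columns, `[[`, "", "kind"),
    vapply(schema$columns, `[[`, "", "name")
  )
  for (col in schema$columns) {
    nm <- col$name
    if (nrow(df) == 0 && !nm %in% names(df)) df[[nm]] <- character(0)
    if (col$kind == "categorical") {
      df[[nm]] <- factor(df[[nm]], levels = col$levels)
    } else if (col$kind == "binary") {
      df[[nm]] <- as.integer(df[[nm]])
    } else {
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }
  ## empty-string NAs: re-establish outcome NA for non-retained rows
  if (nrow(df) > 0) {
    df$treatment <- as.integer(df$treatment)
    df$retained <- as.integer(df$retained)
    df$outcome <- suppressWarnings(as.integer(df$outcome))
  } else {
    for (nm in c("treatment", "outcome", "retained")) {
      if (!nm %in% names(df)) df[[nm]] <- integer(0)
    }
    if (!"subject_id" %in% names(df)) df$subject_id <- character(0)
  }
  base <- c("subject_id", "treatment", "outcome", "retained")
  extra <- if (isTRUE(schema$has_oracle)) c("oracle_effect", "oracle_cell") else character(0)
  if (length(extra) && nrow(df) > 0) {
    df$oracle_effect <- as.numeric(df$oracle_effect)
    df$oracle_cell <- as.character(df$oracle_cell)
  }
  new_trial_data(df[, c(base, names(kinds), intersect(extra, names(df))), drop = FALSE],
                 kinds)
}
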