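## subgroup_tree: depth-limited CART regression over interpretable covariates
## predicting the estimated CATE. Splits maximize the weighted squared-error
## reduction; leaves are the discovered subgroups, labelled group 1..G in
## ascending mean predicted effect (group 1 = lowest benefit). Written from
## first principles so tie-breaking is fully deterministic: larger reduction,
## then variable name (lexicographic, C locale), then lower threshold.

## Internal: a split candidate for one covariate. For numeric / ordered
## covariates only order-respecting thresholds are admissible; for unordered
## categoricals the levels are ordered by weighted mean of the target (exact
## for squared-error impurity) and thresholds are taken along that order,
## giving a level-subset rule.
split_candidates <- function(x, tau, w) {
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) < 2) return(NULL)
    list(kind = "ordinal-threshold",
         code = x,
         thresholds = (head(ux, -1) + tail(ux, -1)) / 2,
         boundary = head(ux, -1),  # last value on the left side
         levels = NULL)
  } else {
    f <- if (is.factor(x)) x else factor(x)
    present <- levels(f)[tabulate(f, nbins = nlevels(f)) > 0]
    if (length(present) < 2) return(NULL)
    if (is.ordered(f)) {
      code <- as.integer(factor(f, levels = present, ordered = TRUE))
      list(kind = "ordinal-threshold", code = code,
           thresholds = seq_len(length(present) - 1) + 0.5,
           boundary = head(present, -1), levels = present)
    } else {
      ## order levels by weighted mean tau; ties by level name for determinism
      wm <- vapply(present, function(l) wmean(tau[f == l], w[f == l]), 0)
      ord_levels <- present[order(wm, present)]
      code <- match(as.character(f), ord_levels)
      list(kind = "level-subset", code = code,
           thresholds = seq_len(length(ord_levels) - 1) + 0.5,
           boundary = NULL, levels = ord_levels)
    }
  }
}

node_sse <- function(tau, w) sum(w * (tau - wmean(tau, w))^2)

#' Best single split of one covariate
#'
#' Evaluates every admissible threshold of `covariate` against the target
#' `values` (per-subject estimated effects) and returns the split maximizing
#' the weighted SSE reduction, subject to `min_leaf` on both sides. Ordinal
#' (numeric / ordered factor) covariates admit only order-respecting
#' thresholds; unordered factors are scanned along the mean-ordered level
#' sequence, which is exact for squared-error impurity.
#'
#' @param values Numeric target vector (tau-hat).
#' @param covariate One covariate vector (numeric, factor or ordered factor).
#' @param weights Positive weights; `NULL` = unit.
#' @param min_leaf Minimum subjects per side (default 1).
#' @return A list `(rule, reduction, left)` where `rule` is a `split_rule`,
#'   or the no-split sentinel `list(rule = NULL, reduction = 0)` when no
#'   admissible split exists.
#' @export
best_split <- function(values, covariate, weights = NULL, min_leaf = 1L) {
  n <- length(values)
  assert_that(length(covariate) == n, "values and covariate lengths differ")
  w <- weights %||% rep(1, n)
  no_split <- list(rule = NULL, reduction = 0)
  if (n < 2 * min_leaf) return(no_split)
  if (!is.numeric(covariate) && !is.ordered(covariate)) {
    f <- if (is.factor(covariate)) covariate else factor(covariate)
    present <- levels(f)[tabulate(f, nbins = nlevels(f)) > 0]
    if (length(present) >= 2 && length(present) <= 8) {
      return(best_subset_split(values, f, w, min_leaf, present))
    }
  }
  cand <- split_candidates(covariate, values, w)
  if (is.null(cand)) return(no_split)

  ord <- order(cand$code)
  cw <- w[ord]; ct <- values[ord]; cc <- cand$code[ord]
  cw_sum <- cumsum(cw); cwt_sum <- cumsum(cw * ct)
  wtot <- cw_sum[n]; wttot <- cwt_sum[n]
  parent_term <- wttot^2 / wtot

  best <- no_split
  for (ti in seq_along(cand$thresholds)) {
    thr <- cand$thresholds[ti]
    k <- sum(cc <= thr)           # size of left side
    if (k < min_leaf || n - k < min_leaf) next
    wl <- cw_sum[k]; wr <- wtot - wl
    if (wl <= 0 || wr <= 0) next
    red <- cwt_sum[k]^2 / wl + (wttot - cwt_sum[k])^2 / wr - parent_term
    if (red > best$reduction + 1e-10) {
      rule <- if (cand$kind == "ordinal-threshold") {
        split_rule(variable = NA_character_, kind = "ordinal-threshold",
                   threshold = thr,
                   boundary = cand$boundary[ti],
                   levels = cand$levels,
                   left_levels = if (!is.null(cand$levels)) cand$levels[seq_len(ti)])
      } else {
        split_rule(variable = NA_character_, kind = "level-subset",
                   threshold = thr, levels = cand$levels,
                   left_levels = cand$levels[seq_len(ti)])
      }
      best <- list(rule = rule, reduction = red)
    }
  }
  best
}

## Exhaustive level-subset search for unordered factors with few levels.
## Under a min_leaf constraint the optimal subset need not be contiguous in
## the mean-ordered sequence, so for <= 8 levels every proper subset is
## scanned (the mean-ordered prefix scan remains the fallback above that).
## Levels are mean-ordered first and masks enumerated in increasing order
## with strict improvement only, making the chosen subset deterministic.
best_subset_split <- function(values, f, w, min_leaf, present) {
  wm <- vapply(present, function(l) wmean(values[f == l], w[f == l]), 0)
  lev <- present[order(wm, present)]
  L <- length(lev)
  code <- match(as.character(f), lev)
  n_l <- tabulate(code, nbins = L)
  w_l <- vapply(seq_len(L), function(k) sum(w[code == k]), 0)
  wt_l <- vapply(seq_len(L), function(k) sum((w * values)[code == k]), 0)
  wtot <- sum(w_l); wttot <- sum(wt_l)
  parent_term <- wttot^2 / wtot

  best <- list(rule = NULL, reduction = 0)
  bits <- 2^(seq_len(L) - 1)
  ## left subsets are those containing the lowest-mean level (bit 1), which
  ## enumerates each binary partition exactly once
  for (mask in seq.int(1, 2^L - 1, by = 2)) {
    inl <- bitwAnd(mask, bits) > 0
    if (all(inl)) next
    nl <- sum(n_l[inl])
    if (nl < min_leaf || sum(n_l) - nl < min_leaf) next
    wl <- sum(w_l[inl]); wr <- wtot - wl
    if (wl <= 0 || wr <= 0) next
    wyl <- sum(wt_l[inl])
    red <- wyl^2 / wl + (wttot - wyl)^2 / wr - parent_term
    if (red > best$reduction + 1e-10) {
      best <- list(rule = split_rule(variable = NA_character_,
                                     kind = "level-subset",
                                     threshold = mask, levels = lev,
                                     left_levels = lev[inl]),
                   reduction = red)
    }
  }
  best
}

split_rule <- function(variable, kind, threshold, boundary = NULL,
                       levels = NULL, left_levels = NULL) {
  structure(list(variable = variable, kind = kind, threshold = threshold,
                 boundary = boundary, levels = levels,
                 left_levels = left_levels),
            class = "split_rule")
}

## TRUE = go left. Unseen levels (not in rule$levels) go right (the
## complement side) and are reported by assign_groups.
route_left <- function(rule, x) {
  if (rule$kind == "ordinal-threshold" && is.null(rule$levels)) {
    as.numeric(x) <= rule$threshold
  } else {
    as.character(x) %in% rule$left_levels
  }
}

rule_text <- function(rule, left) {
  if (rule$kind == "ordinal-threshold" && is.null(rule$levels)) {
    if (left) sprintf("%s < %g", rule$variable, rule$threshold)
    else sprintf("%s ≥ %g", rule$variable, rule$threshold)
  } else if (rule$kind == "ordinal-threshold") {
    if (left) sprintf("%s ≤ '%s'", rule$variable, rule$boundary)
    else sprintf("%s > '%s'", rule$variable, rule$boundary)
  } else {
    side <- if (left) rule$left_levels else setdiff(rule$levels, rule$left_levels)
    sprintf("%s in {%s}", rule$variable, paste(side, collapse = ", "))
  }
}

#' Fit a depth-limited CART subgroup tree to estimated CATEs
#'
#' Greedy recursive partitioning of the retained subjects: at each node the
#' best split over all interpretable covariates is taken (ties broken by
#' variable name, then lower threshold), stopping at `max_depth`, `min_leaf`,
#' or zero achievable SSE reduction. Leaves are the discovered subgroups,
#' labelled `group 1..G` in ascending mean predicted effect, so group 1 is
#' the lowest-benefit subgroup. No pruning: the depth cap is the stated
#' complexity control.
#'
#' @param estimate A [cate_estimate()] (or bare numeric vector of effects).
#' @param covariates Interpretable covariate table from [apply_recoding()]
#'   (may include a `subject_id` column used for alignment).
#' @param max_depth Maximum splits on any root-to-leaf path (default 2).
#' @param min_leaf Minimum subjects per leaf (default 50).
#' @param weights Optional [fit_censoring_weights()] result or numeric vector
#'   aligned with rows.
#' @param dataset Optional `trial_data` used to align `estimate`, `weights`
#'   and `covariates` by subject id.
#' @return A `subgroup_tree`.
#' @export
fit_tree <- function(estimate, covariates, max_depth = 2, min_leaf = 50,
                     weights = NULL, dataset = NULL) {
  covs <- as.data.frame(covariates)
  ids <- covs$subject_id
  covs$subject_id <- NULL
  assert_that(ncol(covs) > 0, "empty covariate set",
              class = "pragsub_config_error")

  if (inherits(estimate, "cate_estimate")) {
    if (!is.null(ids)) {
      pos <- match(ids, estimate$subject_id)
      assert_that(!anyNA(pos), "covariate rows without a CATE estimate")
      tau <- estimate$tau_hat[pos]
    } else {
      assert_that(nrow(estimate) == nrow(covs),
                  "estimate and covariates lengths differ")
      tau <- estimate$tau_hat
      ids <- estimate$subject_id
    }
  } else {
    tau <- as.numeric(estimate)
    assert_that(length(tau) == nrow(covs), "estimate and covariates lengths differ")
  }
  assert_that(!anyNA(tau), "estimated effects contain NA")
  for (nm in names(covs)) {
    assert_that(!anyNA(covs[[nm]]),
                "interpretable covariate '", nm, "' contains missing values; impute first")
  }

  w <- if (is.null(weights)) rep(1, nrow(covs))
       else if (inherits(weights, "censoring_weights")) {
         assert_that(!is.null(ids), "subject ids required to align censoring weights")
         pos <- match(ids, weights$subject_id)
         assert_that(!anyNA(pos), "rows without a censoring weight")
         weights$weight[pos]
       } else as.numeric(weights)
  assert_that(all(is.finite(w) & w > 0), "weights must be positive and finite")

  var_names <- sort(names(covs))   # lexicographic tie-break order

  build <- function(rows, depth) {
    node <- list(n = length(rows),
                 mean = wmean(tau[rows], w[rows]),
                 sse = node_sse(tau[rows], w[rows]),
                 is_leaf = TRUE, members = rows)
    if (depth >= max_depth || length(rows) < 2 * min_leaf || node$sse <= 1e-12) {
      return(node)
    }
    ## var_names is sorted, and best_split returns the lowest threshold among
    ## within-covariate ties, so replacing only on strict improvement realizes
    ## the (reduction, variable name, threshold) tie-break order.
    best <- list(rule = NULL, reduction = 0)
    for (nm in var_names) {
      cand <- best_split(tau[rows], covs[[nm]][rows], w[rows], min_leaf)
      if (!is.null(cand$rule) && cand$reduction > best$reduction + 1e-10) {
        cand$rule$variable <- nm
        best <- cand
      }
    }
    if (is.null(best$rule)) return(node)
    go_left <- route_left(best$rule, covs[[best$rule$variable]][rows])
    node$is_leaf <- FALSE
    node$rule <- best$rule
    node$reduction <- best$reduction
    node$members <- NULL
    node$left <- build(rows[go_left], depth + 1)
    node$right <- build(rows[!go_left], depth + 1)
    node
  }

  root <- build(seq_len(nrow(covs)), 0)

  ## collect leaves and label them in ascending mean tau
  leaves <- list()
  walk <- function(node, conds) {
    if (node$is_leaf) {
      leaves[[length(leaves) + 1L]] <<- list(node = node, conds = conds)
    } else {
      walk(node$left, c(conds, rule_text(node$rule, TRUE)))
      walk(node$right, c(conds, rule_text(node$rule, FALSE)))
    }
  }
  walk(root, character(0))
  means <- vapply(leaves, function(l) l$node$mean, 0)
  ord <- order(means)                       # stable, so ties are deterministic
  dfs_to_group <- integer(length(ord))
  dfs_to_group[ord] <- seq_along(ord)
  leaf_tab <- lapply(seq_along(ord), function(g) {
    l <- leaves[[ord[g]]]
    list(group = g,
         conditions = if (length(l$conds)) l$conds else "all subjects",
         n = l$node$n, mean_tau = l$node$mean, members = l$node$members)
  })

  structure(list(root = root, leaves = leaf_tab, dfs_to_group = dfs_to_group,
                 max_depth = max_depth, min_leaf = min_leaf,
                 variables = names(covs),
                 schema = lapply(covs, function(x) {
                   if (is.factor(x)) levels(x) else class(x)
                 }),
                 subject_id = ids),
            class = "subgroup_tree")
}

#' Assign subjects to the discovered subgroups
#'
#' Routes each row of `covariates` down the fitted tree. Group labels carry
#' the ascending-benefit order from [fit_tree()]. Unseen categorical levels
#' are routed to the complement (right) side of the level-subset rule and
#' flagged in the `routing` attribute.
#'
#' @param tree A `subgroup_tree`.
#' @param covariates Interpretable covariate table with the training schema.
#' @return Integer vector of group ids (1 = lowest benefit) with attribute
#'   `routing` listing unseen-level incidents.
#' @export
assign_groups <- function(tree, covariates) {
  assert_that(inherits(tree, "subgroup_tree"), "tree must be a subgroup_tree")
  covs <- as.data.frame(covariates)
  covs$subject_id <- NULL
  missing <- setdiff(tree$variables, names(covs))
  assert_that(length(missing) == 0, "covariate schema mismatch; missing: ",
              paste(missing, collapse = ", "), class = "pragsub_contract_error")

  incidents <- list()
  out <- integer(nrow(covs))
  leaf_counter <- 0L
  ## left-first DFS visits leaves in the same order as fit time, so a running
  ## leaf counter indexes dfs_to_group directly
  route <- function(node, rows) {
    if (node$is_leaf) {
      leaf_counter <<- leaf_counter + 1L
      out[rows] <<- tree$dfs_to_group[leaf_counter]
      return(invisible(NULL))
    }
    x <- covs[[node$rule$variable]][rows]
    if (!is.null(node$rule$levels)) {
      unseen <- setdiff(unique(as.character(x)), node$rule$levels)
      if (length(unseen)) {
        incidents[[length(incidents) + 1L]] <<- data.frame(
          variable = node$rule$variable, level = unseen,
          stringsAsFactors = FALSE)
      }
    }
    go_left <- route_left(node$rule, x)
    route(node$left, rows[go_left])
    route(node$right, rows[!go_left])
  }
  route(tree$root, seq_len(nrow(covs)))
  attr(out, "routing") <- if (length(incidents)) do.call(rbind, incidents) else
    data.frame(variable = character(0), level = character(0),
               stringsAsFactors = FALSE)
  out
}

#' Human-readable rule table of a fitted subgroup tree
#'
#' One row per discovered subgroup: group id (1 = lowest benefit), the
#' conjunction of split conditions along its root-to-leaf path, size, and
#' mean predicted effect.
#'
#' @param tree A `subgroup_tree`.
#' @return data.frame with columns `group`, `rule`, `n`, `mean_tau`.
#' @export
rules_text <- function(tree) {
  assert_that(inherits(tree, "subgroup_tree"), "tree must be a subgroup_tree")
  data.frame(
    group = vapply(tree$leaves, `[[`, 0, "group"),
    rule = vapply(tree$leaves, function(l) paste(l$conditions, collapse = " AND "), ""),
    n = vapply(tree$leaves, `[[`, 0, "n"),
    mean_tau = vapply(tree$leaves, `[[`, 0, "mean_tau"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.subgroup_tree <- function(x, ...) {
  cat(sprintf("<subgroup_tree> %d subgroups (max_depth %d, min_leaf %d)\n",
              length(x$leaves), x$max_depth, x$min_leaf))
  rt <- rules_text(x)
  for (i in seq_len(nrow(rt))) {
    cat(sprintf("  group %d (n=%d, mean tau %+.4f): %s\n",
                rt$group[i], rt$n[i], rt$mean_tau[i], rt$rule[i]))
  }
  invisible(x)
}

## JSON-serializable form for the pipeline artifact.
tree_to_list <- function(tree) {
  node_list <- function(node) {
    if (node$is_leaf) {
      list(leaf = TRUE, n = node$n, mean_tau = node$mean)
    } else {
      list(leaf = FALSE,
           variable = node$rule$variable,
           kind = node$rule$kind,
           threshold = node$rule$threshold,
           left_levels = node$rule$left_levels,
           reduction = node$reduction,
           left = node_list(node$left),
           right = node_list(node$right))
    }
  }
  list(max_depth = tree$max_depth, min_leaf = tree$min_leaf,
       nodes = node_list(tree$root),
       rules = rules_text(tree))
}
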