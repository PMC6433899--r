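#' False discovery rate of a selection
#'
#' Fraction of selected variables that are not causal. An empty
#' selection makes no false discoveries and is defined to have FDR 0.
#'
#' @param selected character vector of selected variable names.
#' @param truth character vector of causal variable names.
#' @return a number in [0, 1].
#' @examples
#' fdr(c("a", "b"), "a")  # 0.5
#' @export
fdr <- function(selected, truth) {
  selected <- unique(selected)
  if (length(selected) == 0L) return(0)
  length(setdiff(selected, truth)) / length(selected)
}

#' Sensitivity of a selection
#'
#' Proportion of causal variables recovered on a single replicate.
#' Undefined (error) when the truth is empty — under a null model the
#' count of falsely selected variables is the relevant quantity instead.
#'
#' @inheritParams fdr
#' @return a number in [0, 1].
#' @export
sensitivity <- function(selected, truth) {
  truth <- unique(truth)
  if (length(truth) == 0L) {
    stop("sensitivity is undefined for an empty truth set; report the false-positive count instead",
         call. = FALSE)
  }
  length(intersect(unique(selected), truth)) / length(truth)
}

#' Per-variable empirical power
#'
#' For each causal variable, the fraction of replicates in which it was
#' selected.
#'
#' @param selections list of character vectors (one selection per
#'   replicate).
#' @param truth character vector of causal variable names.
#' @return named numeric vector over `truth`.
#' @export
empirical_power <- function(selections, truth) {
  stopifnot(length(selections) >= 1L)
  truth <- unique(truth)
  counts <- vapply(truth, function(v) {
    sum(vapply(selections, function(s) v %in% s, logical(1L)))
  }, numeric(1L))
  counts / length(selections)
}

#' Jaccard index between two selections
#'
#' Standard form: intersection over union. Modified form: intersection
#' over the size of the smaller set — useful when the two selections
#' differ systematically in size. Two empty sets are identical and score
#' 1.
#'
#' @param a,b character vectors of variable names.
#' @param modified use the minimum-size denominator.
#' @return a number in [0, 1].
#' @export
jaccard_index <- function(a, b, modified = FALSE) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  if (length(a) == 0L || length(b) == 0L) return(0)
  inter <- length(intersect(a, b))
  if (modified) inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

#' Mean pairwise selection stability
#'
#' Averages the (standard or modified) Jaccard index over all unordered
#' pairs of selections.
#'
#' @param selections list of >= 2 character vectors.
#' @param modified use the minimum-size denominator.
#' @return a number in [0, 1].
#' @export
jaccard_stability <- function(selections, modified = FALSE) {
  m <- length(selections)
  if (m < 2L) stop("stability needs at least 2 selections", call. = FALSE)
  pairs <- utils::combn(m, 2L)
  mean(apply(pairs, 2L, function(ij) {
    jaccard_index(selections[[ij[1L]]], selections[[ij[2L]]],
                  modified = modified)
  }))
}

#' Downstream prediction error of a selection
#'
#' Trains a forest on the training replicate restricted to the selected
#' variables and evaluates it on an independent test replicate: RMSE for
#' regression, misclassification rate for classification. An empty
#' selection falls back to the outcome-mean / majority-class predictor
#' (flagged via attribute `baseline`).
#'
#' @param train,test [rfvs_dataset()]s with identical variable names and
#'   task.
#' @param selected character vector of selected variable names.
#' @param rf an [rf_params()] object.
#' @param seed integer seed for the evaluation forest.
#' @return the error (>= 0).
#' @export
downstream_error <- function(train, test, selected, rf = rf_params(),
                             seed = rf$seed) {
  stopifnot(inherits(train, "rfvs_dataset"), inherits(test, "rfvs_dataset"))
  if (!identical(train$var_names, test$var_names)) {
    stop("train and test replicates have different variable names",
         call. = FALSE)
  }
  if (train$task != test$task) stop("train/test task mismatch", call. = FALSE)
  if (length(selected) == 0L) {
    err <- if (train$task == "classification") {
      majority <- names(which.max(table(train$y)))
      mean(test$y != majority)
    } else {
      sqrt(mean((test$y - mean(train$y))^2))
    }
    attr(err, "baseline") <- TRUE
    return(err)
  }
  tr <- subset_variables(train, selected)
  te <- subset_variables(test, selected)
  params <- resolve_params(rf, n_individuals(tr), n_variables(tr))
  params$seed <- seed
  fit <- fit_forest(tr, params, compute_importance = FALSE)
  pred <- stats::predict(fit$fit, data = te$X, num.threads = 1L)$predictions
  if (train$task == "classification") {
    mean(pred != te$y)
  } else {
    sqrt(mean((pred - te$y)^2))
  }
}

# canonical ordering used for per-(replicate, method) seed derivation
.rfvs_methods <- c("boruta", "vita", "r2vim", "perm", "altmann", "rfe")

#' Benchmark variable-selection methods over simulated replicates
#'
#' Runs each requested selector on every replicate, computes FDR,
#' sensitivity (false-positive counts under a null model), selection
#' stability, per-variable empirical power and downstream prediction
#' error, and aggregates medians and interquartile ranges per method.
#'
#' @param replicates an `rfvs_replicates` object used for selection (and
#'   training the downstream forest).
#' @param methods character vector from `"boruta"`, `"vita"`, `"r2vim"`,
#'   `"perm"`, `"altmann"`, `"rfe"`.
#' @param rf shared forest parameters (Boruta keeps its conventional
#'   mtry/nodesize defaults but inherits the tree count).
#' @param cfgs named list of per-method config lists, e.g.
#'   `list(perm = list(no_perm = 50))`.
#' @param test_replicates for independent designs, an `rfvs_replicates`
#'   whose i-th replicate is the test set for training replicate i;
#'   `NULL` skips the error evaluation.
#' @param pairing `"independent"` (each replicate scored against the
#'   matching test replicate) or `"paired"` (replicates come in pairs
#'   sharing a causal truth; each member is evaluated on the other).
#'   Defaults to `"paired"` when `replicates$pairing` is set.
#' @param seed top-level seed; per-(replicate, method) seeds are derived
#'   from it so that results do not depend on the order of `methods`.
#' @return An object of class `rfvs_eval_report`: list with `records`
#'   (one row per method x replicate), `stability`, `power`, `summary`
#'   and `selections` (the selected sets, for reuse).
#' @details When both `"perm"` and `"altmann"` are requested, the
#'   outcome-permutation forests are computed once per replicate and
#'   shared between the two selectors. A selector failure on a replicate
#'   is recorded as missing and the benchmark continues.
#' @export
run_benchmark <- function(replicates, methods, rf = rf_params(),
                          cfgs = list(), test_replicates = NULL,
                          pairing = NULL, seed = 1L) {
  stopifnot(inherits(replicates, "rfvs_replicates"))
  methods <- vapply(methods, function(m) match.arg(m, .rfvs_methods),
                    character(1L))
  if (is.null(pairing)) {
    pairing <- if (!is.null(replicates$pairing)) "paired" else "independent"
  }
  pairing <- match.arg(pairing, c("independent", "paired"))
  reps <- replicates$replicates
  n_rep <- length(reps)
  if (pairing == "paired") {
    if (n_rep %% 2L != 0L || is.null(replicates$pairing)) {
      stop("paired mode needs an even number of replicates with a pairing index",
           call. = FALSE)
    }
  }
  if (!is.null(test_replicates)) {
    stopifnot(inherits(test_replicates, "rfvs_replicates"))
    if (length(test_replicates$replicates) < n_rep) {
      stop("need one test replicate per training replicate", call. = FALSE)
    }
  }
  # seed grid: one row per replicate; columns = shared-null seed + one
  # seed per canonical method slot
  seed_grid <- matrix(derive_seeds(seed, n_rep * (1L + length(.rfvs_methods))),
                      nrow = n_rep)
  share_null <- all(c("perm", "altmann") %in% methods)
  get_cfg <- function(m) if (!is.null(cfgs[[m]])) cfgs[[m]] else list()

  records <- list()
  selections <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) selections[[m]] <- vector("list", n_rep)

  for (r in seq_len(n_rep)) {
    data_r <- reps[[r]]
    truth_r <- truth_variables(replicates,
                               pair = if (pairing == "paired")
                                 replicates$pairing[r] else NULL)
    shared <- NULL
    if (share_null) {
      np_perm <- if (!is.null(get_cfg("perm")$no_perm))
        get_cfg("perm")$no_perm else 500L
      np_alt <- if (!is.null(get_cfg("altmann")$no_perm))
        get_cfg("altmann")$no_perm else 50L
      shared <- perm_null_importance(data_r, rf,
                                     no_perm = max(np_perm, np_alt),
                                     seed = seed_grid[r, 1L])
    }
    for (m in methods) {
      m_seed <- seed_grid[r, 1L + match(m, .rfvs_methods)]
      cfg <- get_cfg(m)
      if (m %in% c("perm", "altmann") && !is.null(shared)) {
        cfg$null <- shared
        m_seed <- shared$seed
      }
      t0 <- proc.time()[3L]
      result <- tryCatch(
        select_variables(data_r, m, rf = rf, config = cfg, seed = m_seed),
        error = function(e) {
          warning(sprintf("%s failed on replicate %d: %s", m, r,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      elapsed <- proc.time()[3L] - t0
      selections[[m]][[r]] <- if (is.null(result)) character(0)
                              else selected_variables(result)
      sel_vars <- selections[[m]][[r]]
      err <- NA_real_
      if (!is.null(result)) {
        if (pairing == "paired") {
          other <- which(replicates$pairing == replicates$pairing[r])
          other <- setdiff(other, r)
          err <- downstream_error(data_r, reps[[other]], sel_vars, rf,
                                  seed = m_seed)
        } else if (!is.null(test_replicates)) {
          err <- downstream_error(data_r, test_replicates$replicates[[r]],
                                  sel_vars, rf, seed = m_seed)
        }
      }
      records[[length(records) + 1L]] <- data.frame(
        method = m, replicate = r,
        pair = if (pairing == "paired") replicates$pairing[r] else NA_integer_,
        n_selected = if (is.null(result)) NA_integer_
                     else length(sel_vars),
        fdr = if (is.null(result) || length(truth_r) == 0L) NA_real_
              else fdr(sel_vars, truth_r),
        n_false = if (is.null(result)) NA_integer_
                  else length(setdiff(sel_vars, truth_r)),
        sensitivity = if (is.null(result) || length(truth_r) == 0L) NA_real_
                      else sensitivity(sel_vars, truth_r),
        error = as.numeric(err),
        n_forests = if (is.null(result)) NA_integer_
                    else result$n_forests_trained,
        elapsed = unname(elapsed),
        failed = is.null(result),
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, records)

  stability <- do.call(rbind, lapply(methods, function(m) {
    sels <- selections[[m]]
    if (pairing == "paired") {
      pairs <- unique(replicates$pairing)
      js <- vapply(pairs, function(pr) {
        idx <- which(replicates$pairing == pr)
        jaccard_index(sels[[idx[1L]]], sels[[idx[2L]]])
      }, numeric(1L))
      jm <- vapply(pairs, function(pr) {
        idx <- which(replicates$pairing == pr)
        jaccard_index(sels[[idx[1L]]], sels[[idx[2L]]], modified = TRUE)
      }, numeric(1L))
      data.frame(method = m, jaccard = mean(js), jaccard_modified = mean(jm),
                 n_pairs = length(pairs), stringsAsFactors = FALSE)
    } else if (n_rep < 2L) {
      data.frame(method = m, jaccard = NA_real_, jaccard_modified = NA_real_,
                 n_pairs = 0L, stringsAsFactors = FALSE)
    } else {
      data.frame(method = m,
                 jaccard = jaccard_stability(sels),
                 jaccard_modified = jaccard_stability(sels, modified = TRUE),
                 n_pairs = choose(n_rep, 2L), stringsAsFactors = FALSE)
    }
  }))

  power <- benchmark_power(replicates, selections, methods, pairing)

  summary <- do.call(rbind, lapply(methods, function(m) {
    rm_ <- records[records$method == m & !records$failed, ]
    qs <- function(x) {
      if (all(is.na(x))) c(NA_real_, NA_real_, NA_real_)
      else stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    }
    data.frame(
      method = m,
      median_sensitivity = qs(rm_$sensitivity)[2L],
      iqr_sensitivity = qs(rm_$sensitivity)[3L] - qs(rm_$sensitivity)[1L],
      median_fdr = qs(rm_$fdr)[2L],
      median_n_false = qs(rm_$n_false)[2L],
      median_error = qs(rm_$error)[2L],
      median_n_selected = qs(rm_$n_selected)[2L],
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(records = records, stability = stability, power = power,
         summary = summary, selections = selections,
         design = replicates$design, pairing = pairing, seed = seed),
    class = "rfvs_eval_report"
  )
}

# Empirical power table. Global-truth designs: per causal variable.
# Paired designs with per-pair truth and effect sizes: per |effect size|.
benchmark_power <- function(replicates, selections, methods, pairing) {
  tr <- replicates$truth
  if (nrow(tr) == 0L) return(NULL)
  if (is.null(tr$pair)) {
    do.call(rbind, lapply(methods, function(m) {
      pw <- empirical_power(selections[[m]], unique(tr$variable))
      data.frame(method = m, variable = names(pw), power = unname(pw),
                 stringsAsFactors = FALSE)
    }))
  } else {
    do.call(rbind, lapply(methods, function(m) {
      hits <- lapply(seq_along(selections[[m]]), function(r) {
        pr <- replicates$pairing[r]
        tp <- tr[tr$pair == pr, ]
        data.frame(abs_effect = abs(tp$effect_size),
                   hit = tp$variable %in% selections[[m]][[r]])
      })
      hits <- do.call(rbind, hits)
      agg <- stats::aggregate(hit ~ abs_effect, data = hits, FUN = mean)
      data.frame(method = m, abs_effect = agg$abs_effect, power = agg$hit,
                 stringsAsFactors = FALSE)
    }))
  }
}

#' @export
print.rfvs_eval_report <- function(x, ...) {
  cat(sprintf("<rfvs_eval_report> %s design, %d method(s) x %d replicate(s)\n",
              x$design, length(unique(x$records$method)),
              length(unique(x$records$replicate))))
  print(x$summary, row.names = FALSE, digits = 3)
  cat("stability (mean pairwise Jaccard):\n")
  print(x$stability, row.names = FALSE, digits = 3)
  invisible(x)
}
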