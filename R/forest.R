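#' Train a random forest
#'
#' Fits a forest with the package's standard parameterization via
#' \pkg{ranger}: bootstrap samples of size n drawn with replacement, Gini
#' splitting for classification and variance reduction for regression,
#' and unscaled (raw mean-decrease) permutation importance computed on
#' each tree's out-of-bag observations.
#'
#' @param data an [rfvs_dataset()].
#' @param params an [rf_params()] object; fractional `mtry`/`nodesize`
#'   are resolved against the dataset dimensions.
#' @param compute_importance if `FALSE`, skip the permutation-importance
#'   pass (slightly faster when only the OOB error is needed).
#'
#' @return An object of class `rfvs_forest` with elements `fit` (the
#'   ranger object), `params` (resolved), `task`, `var_names`, `inbag`
#'   (list of per-tree bootstrap count vectors) and `oob_error`
#'   (misclassification rate or mean squared error).
#'
#' @details Importance is the raw difference of per-tree OOB prediction
#'   performance before and after permuting a variable, averaged over
#'   trees (accuracy for classification, MSE for regression, signed so
#'   relevant variables score positive). It is deliberately not divided
#'   by its standard error: the scaled Z-score is known not to be
#'   normally distributed, which would invalidate the parametric
#'   (Altmann) selector built on top.
#' @examples
#' d <- rfvs_dataset(matrix(runif(200), 20, 10), rnorm(20), "regression")
#' f <- fit_forest(d, rf_params(num_trees = 50, seed = 1))
#' f$oob_error
#' @export
fit_forest <- function(data, params = rf_params(), compute_importance = TRUE) {
  stopifnot(inherits(data, "rfvs_dataset"))
  params <- resolve_params(params, n_individuals(data), n_variables(data))
  fit <- fit_ranger(data$X, data$y, data$task, params, seed = params$seed,
                    importance = compute_importance, keep_inbag = TRUE)
  structure(
    list(fit = fit, params = params, task = data$task,
         var_names = data$var_names,
         inbag = fit$inbag.counts, oob_error = fit$prediction.error),
    class = "rfvs_forest"
  )
}

#' @export
print.rfvs_forest <- function(x, ...) {
  cat(sprintf("<rfvs_forest> %d trees, mtry=%d, nodesize=%d, oob_error=%.4g (%s)\n",
              x$params$num_trees, x$params$mtry, x$params$nodesize,
              x$oob_error,
              if (x$task == "classification") "misclassification" else "MSE"))
  invisible(x)
}

# Single chokepoint for ranger calls: one thread for bit-reproducibility,
# raw permutation importance, no scaling.
fit_ranger <- function(X, y, task, params, seed, importance = TRUE,
                       keep_inbag = FALSE, case_weights = NULL,
                       holdout = FALSE) {
  if (task == "regression" && stats::var(y) == 0) {
    stop("regression outcome is constant: forest would be degenerate",
         call. = FALSE)
  }
  if (task == "classification" && nlevels(factor(y)) < 2L) {
    stop("classification outcome has a single class", call. = FALSE)
  }
  args <- list(
    x = X, y = y,
    num.trees = params$num_trees,
    mtry = params$mtry,
    min.node.size = params$nodesize,
    importance = if (importance) "permutation" else "none",
    scale.permutation.importance = FALSE,
    num.threads = 1L,
    seed = seed,
    keep.inbag = keep_inbag,
    verbose = FALSE
  )
  if (!is.null(case_weights)) {
    args$case.weights <- case_weights
    args$holdout <- holdout
  }
  do.call(ranger::ranger, args)
}

new_importance <- function(values, var_names, kind, seed) {
  stopifnot(length(values) == length(var_names), all(is.finite(values)))
  names(values) <- var_names
  structure(list(values = values, kind = kind, run_seed = as.integer(seed)),
            class = "rfvs_importance")
}

#' @export
print.rfvs_importance <- function(x, ...) {
  cat(sprintf("<rfvs_importance> %d variables, kind=%s, seed=%d\n",
              length(x$values), x$kind, x$run_seed))
  top <- sort(x$values, decreasing = TRUE)
  print(utils::head(top, 5L))
  invisible(x)
}

#' Out-of-bag permutation importance
#'
#' Extracts the per-variable OOB permutation importance from a fitted
#' forest: for each tree, the drop in prediction performance on that
#' tree's out-of-bag rows after permuting the variable's OOB values,
#' averaged over trees. A variable never used in any tree scores exactly
#' zero; trees without OOB rows contribute nothing.
#'
#' @param fit an [fit_forest()] result trained with
#'   `compute_importance = TRUE`.
#' @return An `rfvs_importance` object (`kind = "oob"`).
#' @export
oob_importance <- function(fit) {
  stopifnot(inherits(fit, "rfvs_forest"))
  if (is.null(fit$fit$variable.importance)) {
    stop("forest was fitted without importance; refit with compute_importance = TRUE",
         call. = FALSE)
  }
  new_importance(unname(fit$fit$variable.importance), fit$var_names,
                 kind = "oob", seed = fit$params$seed)
}

#' Hold-out (Vita) permutation importance
#'
#' Splits the data into two equally sized halves (stratified by class for
#' classification), trains one forest per half, and computes each
#' forest's permutation importance on the *other*, independent half. The
#' returned score per variable is the mean of the two estimates. Unlike
#' OOB importance, whose null distribution is positively skewed, the
#' hold-out null distribution is symmetric around zero — the property the
#' Vita selector relies on.
#'
#' @param data an [rfvs_dataset()] with at least 4 individuals.
#' @param params an [rf_params()] object.
#' @param seed integer; drives the half-split and both forest seeds.
#' @return An `rfvs_importance` object (`kind = "holdout"`) with
#'   attribute `n_forests = 2`.
#' @export
holdout_importance <- function(data, params = rf_params(), seed = params$seed) {
  stopifnot(inherits(data, "rfvs_dataset"))
  n <- n_individuals(data)
  if (n < 4L) stop("hold-out importance needs at least 4 individuals",
                   call. = FALSE)
  seeds <- derive_seeds(seed, 3L)
  half1 <- with_seed(seeds[1L], holdout_split(data$y, data$task))
  in1 <- as.numeric(seq_len(n) %in% half1)
  params <- resolve_params(params, n_individuals = length(half1),
                           n_variables = n_variables(data))
  f1 <- fit_ranger(data$X, data$y, data$task, params, seed = seeds[2L],
                   case_weights = in1, holdout = TRUE)
  f2 <- fit_ranger(data$X, data$y, data$task, params, seed = seeds[3L],
                   case_weights = 1 - in1, holdout = TRUE)
  vals <- (unname(f1$variable.importance) +
             unname(f2$variable.importance)) / 2
  imp <- new_importance(vals, data$var_names, kind = "holdout", seed = seed)
  attr(imp, "n_forests") <- 2L
  imp
}

# Indices of the first half of a stratified (classification) or simple
# (regression) random half-split.
holdout_split <- function(y, task) {
  n <- length(y)
  if (task == "classification") {
    idx <- unlist(lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      if (length(rows) < 2L) {
        stop(sprintf("class '%s' has fewer than 2 individuals: cannot stratify the half-split",
                     lv), call. = FALSE)
      }
      sample(rows, floor(length(rows) / 2))
    }))
    sort(idx)
  } else {
    sort(sample.int(n, floor(n / 2)))
  }
}
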