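#' r2VIM: recurrent relative variable importance
#'
#' Trains `no_runs` forests on the same data that differ only in their
#' random seed. In each run the importance scores are divided by the
#' absolute value of the most negative importance observed in that run —
#' the magnitude that pure-noise variables attain — giving relative
#' importances. If a run observed no negative importance (in practice a
#' minimum of exactly zero from unused variables), the minimal importance
#' over all runs is used as denominator instead. A variable is selected
#' when its *minimum* relative importance over the runs is at least
#' `factor`.
#'
#' @param data an [rfvs_dataset()].
#' @param rf an [rf_params()] object.
#' @param no_runs number of forests (>= 2).
#' @param factor minimal relative importance for selection.
#' @param seed integer seed; per-run forest seeds are derived from it.
#' @return An `rfvs_selection`; `diagnostics$relative_importance` holds
#'   the min-over-runs relative score and `n_forests_trained = no_runs`.
#' @export
select_r2vim <- function(data, rf = rf_params(), no_runs = 20, factor = 3,
                         seed = rf$seed) {
  stopifnot(inherits(data, "rfvs_dataset"))
  no_runs <- check_count(no_runs, "no_runs", lower = 2L)
  check_scalar_number(factor, "factor", lower = 0, strict_lower = TRUE)
  seeds <- derive_seeds(seed, no_runs)
  params <- resolve_params(rf, n_individuals(data), n_variables(data))
  imp <- vapply(seeds, function(s) {
    fit <- fit_ranger(data$X, data$y, data$task, params, seed = s)
    unname(fit$variable.importance)
  }, numeric(n_variables(data)))
  rel <- r2vim_relative(imp)
  score <- apply(rel, 1L, min)
  mean_imp <- rowMeans(imp)
  names(score) <- names(mean_imp) <- data$var_names
  sel <- score >= factor
  diagnostics <- data.frame(
    variable = data$var_names,
    importance = unname(mean_imp),
    relative_importance = unname(score),
    selected = unname(sel),
    stringsAsFactors = FALSE
  )
  selected <- data$var_names[sel][order(-score[sel])]
  new_selection_result(
    method = "r2vim", selected = selected, diagnostics = diagnostics,
    config = list(no_runs = no_runs, factor = factor,
                  num_trees = rf$num_trees),
    n_forests_trained = no_runs, seed = seed
  )
}

# Relative importance matrix: each column (run) divided by |min| of that
# run; runs without a negative minimum fall back to the global minimum.
r2vim_relative <- function(imp) {
  if (!is.matrix(imp)) imp <- matrix(imp, ncol = 1L)
  run_min <- apply(imp, 2L, min)
  global_min <- min(run_min)
  denom <- ifelse(run_min < 0, abs(run_min),
                  ifelse(global_min < 0, abs(global_min), global_min))
  if (any(denom <= 0)) {
    stop(paste("degenerate null: the minimal importance is zero in every run,",
               "relative importances cannot be computed"), call. = FALSE)
  }
  sweep(imp, 2L, denom, "/")
}
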