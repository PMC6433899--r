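#' Recursive feature elimination (minimal-set selection)
#'
#' Starts from a forest on all variables and recursively removes the
#' least important fraction, recomputing the importance ranking at every
#' step (more effective than a single initial ranking when predictors
#' are correlated), until a single variable is left. Each step records
#' the OOB prediction error of its forest. Let e* be the smallest error
#' over all steps; the *smallest* variable set whose error is within
#' `tol_pct` percent of e* (error <= e* * (1 + tol_pct/100)) is selected,
#' matching the method's goal of a minimal predictive set.
#'
#' @param data an [rfvs_dataset()].
#' @param rf an [rf_params()] object (mtry/nodesize fractions are
#'   re-resolved against the shrinking variable set at each step).
#' @param prop_rm proportion of current variables removed per step, in
#'   (0, 1); at least one variable is removed each step.
#' @param tol_pct acceptable error increase over the minimum, in percent.
#' @param seed integer seed; per-step forest seeds are derived from it.
#' @return An `rfvs_selection`; `diagnostics$step_dropped` gives the step
#'   at which each variable was eliminated (NA for variables in the final
#'   candidate set that were never dropped), and attribute `history` a
#'   data frame of step, number of variables and OOB error.
#' @details Ties in the importance ranking (e.g. several variables with
#'   exactly zero importance) are broken by original column order, so the
#'   elimination path is deterministic given the seed.
#' @export
select_rfe <- function(data, rf = rf_params(), prop_rm = 0.1, tol_pct = 10,
                       seed = rf$seed) {
  stopifnot(inherits(data, "rfvs_dataset"))
  check_scalar_number(prop_rm, "prop_rm", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (prop_rm >= 1) stop("`prop_rm` must be < 1", call. = FALSE)
  check_scalar_number(tol_pct, "tol_pct", lower = 0)

  # number of steps until one variable remains
  n_steps <- 0L
  k <- n_variables(data)
  while (k > 1L) {
    k <- k - max(1L, floor(prop_rm * k))
    n_steps <- n_steps + 1L
  }
  n_steps <- n_steps + 1L  # final single-variable forest
  seeds <- derive_seeds(seed, n_steps)

  current <- data$var_names
  step_dropped <- stats::setNames(rep(NA_integer_, n_variables(data)),
                                  data$var_names)
  imp_last <- stats::setNames(rep(NA_real_, n_variables(data)),
                              data$var_names)  # importance in last forest containing the variable
  history <- vector("list", n_steps)
  sets <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    sub <- subset_variables(data, current)
    params <- resolve_params(rf, n_individuals(sub), n_variables(sub))
    params$seed <- seeds[step]
    fit <- fit_forest(sub, params)
    imp <- oob_importance(fit)$values
    imp_last[current] <- imp[current]
    history[[step]] <- data.frame(step = step, n_vars = length(current),
                                  oob_error = fit$oob_error)
    sets[[step]] <- current
    if (length(current) == 1L) break
    n_drop <- max(1L, floor(prop_rm * length(current)))
    drop_idx <- order(imp)[seq_len(n_drop)]  # stable: ties by column order
    step_dropped[current[drop_idx]] <- step
    current <- current[-drop_idx]
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1L))])
  e_star <- min(history$oob_error)
  ok <- history$oob_error <= e_star * (1 + tol_pct / 100)
  best_step <- max(history$step[ok])  # sets shrink, so max step = smallest set
  selected_set <- order_by_importance(sets[[best_step]], imp_last)

  diagnostics <- data.frame(
    variable = data$var_names,
    importance = unname(imp_last[data$var_names]),
    step_dropped = unname(step_dropped[data$var_names]),
    selected = data$var_names %in% selected_set,
    stringsAsFactors = FALSE
  )
  res <- new_selection_result(
    method = "rfe", selected = selected_set, diagnostics = diagnostics,
    config = list(prop_rm = prop_rm, tol_pct = tol_pct,
                  num_trees = rf$num_trees),
    n_forests_trained = nrow(history), seed = seed
  )
  attr(res, "history") <- history
  res
}
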