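#' Outcome-permutation null importances
#'
#' Machinery shared by the Perm and Altmann selectors: the OOB permutation
#' importance of the original data, plus one importance vector per
#' outcome permutation, each computed from a freshly trained forest.
#' Permuting the outcome destroys every variable--outcome association
#' while leaving the correlation structure between predictors untouched,
#' so the permuted importances sample the complete null.
#'
#' @param data an [rfvs_dataset()].
#' @param rf an [rf_params()] object.
#' @param no_perm number of outcome permutations.
#' @param seed integer seed; the original-forest seed, per-permutation
#'   shuffles and per-forest seeds are all derived from it.
#' @return An object of class `rfvs_perm_null`: list with `original`
#'   (an `rfvs_importance`), `null` (matrix, variables x permutations),
#'   `no_perm`, `seed`, `n_forests`.
#' @export
perm_null_importance <- function(data, rf = rf_params(), no_perm = 500,
                                 seed = rf$seed) {
  stopifnot(inherits(data, "rfvs_dataset"))
  no_perm <- check_count(no_perm, "no_perm")
  seeds <- derive_seeds(seed, 1L + 2L * no_perm)
  params <- resolve_params(rf, n_individuals(data), n_variables(data))
  orig_fit <- fit_ranger(data$X, data$y, data$task, params, seed = seeds[1L])
  original <- new_importance(unname(orig_fit$variable.importance),
                             data$var_names, kind = "oob", seed = seed)
  null <- vapply(seq_len(no_perm), function(k) {
    y_perm <- with_seed(seeds[2L * k], sample(data$y))
    fit <- fit_ranger(data$X, y_perm, data$task, params,
                      seed = seeds[2L * k + 1L])
    unname(fit$variable.importance)
  }, numeric(n_variables(data)))
  rownames(null) <- data$var_names
  structure(
    list(original = original, null = null, no_perm = no_perm,
         seed = as.integer(seed), n_forests = no_perm + 1L),
    class = "rfvs_perm_null"
  )
}

#' @export
print.rfvs_perm_null <- function(x, ...) {
  cat(sprintf("<rfvs_perm_null> %d variables x %d permutations (+1 original forest)\n",
              nrow(x$null), x$no_perm))
  invisible(x)
}

#' Perm: nonparametric outcome-permutation selection
#'
#' Selects variables whose original importance exceeds their importance
#' in (essentially) all outcome-permutation runs. The per-variable
#' empirical p-value is the fraction of permutation importances greater
#' than or equal to the original importance (r/N, so p = 0 is attainable
#' and is required by the default threshold `p_t = 0`).
#'
#' @inheritParams perm_null_importance
#' @param p_t p-value threshold for selection.
#' @param null optionally, a precomputed [perm_null_importance()] object
#'   (with at least `no_perm` permutations); forests are then reused and
#'   `n_forests_trained` is reported as 0 for this call.
#' @return An `rfvs_selection`; without a precomputed `null`,
#'   `n_forests_trained = no_perm + 1`.
#' @export
select_perm <- function(data, rf = rf_params(), no_perm = 500, p_t = 0,
                        seed = rf$seed, null = NULL) {
  stopifnot(inherits(data, "rfvs_dataset"))
  no_perm <- check_count(no_perm, "no_perm")
  check_scalar_number(p_t, "p_t", lower = 0, upper = 1)
  trained <- 0L
  if (is.null(null)) {
    null <- perm_null_importance(data, rf, no_perm = no_perm, seed = seed)
    trained <- null$n_forests
  }
  null_check(null, data, no_perm)
  orig <- null$original$values
  p <- perm_pvalues(orig, null$null[, seq_len(no_perm), drop = FALSE])
  diagnostics <- data.frame(
    variable = data$var_names,
    importance = unname(orig),
    p_value = unname(p),
    selected = unname(p <= p_t),
    stringsAsFactors = FALSE
  )
  selected <- order_by_importance(data$var_names[p <= p_t], orig)
  new_selection_result(
    method = "perm", selected = selected, diagnostics = diagnostics,
    config = list(no_perm = no_perm, p_t = p_t, num_trees = rf$num_trees),
    n_forests_trained = trained, seed = seed
  )
}

perm_pvalues <- function(orig, null) {
  rowMeans(null >= orig)
}

null_check <- function(null, data, no_perm) {
  if (!inherits(null, "rfvs_perm_null")) {
    stop("`null` must be a perm_null_importance() result", call. = FALSE)
  }
  if (!identical(rownames(null$null), data$var_names)) {
    stop("`null` was computed on different variables", call. = FALSE)
  }
  if (ncol(null$null) < no_perm) {
    stop(sprintf("`null` has %d permutations but no_perm = %d requested",
                 ncol(null$null), no_perm), call. = FALSE)
  }
  invisible(null)
}
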