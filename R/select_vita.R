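#' Vita: selection by the mirrored hold-out null distribution
#'
#' Computes hold-out permutation importance once (two forests, see
#' [holdout_importance()]) and builds an empirical null distribution from
#' the observed non-positive scores: the negative scores, the zero
#' scores, and the negatives mirrored around zero. Because the hold-out
#' null is symmetric, this mirrored sample estimates the full null
#' distribution without any outcome permutation. The empirical p-value of
#' a variable is the fraction of the null sample greater than or equal to
#' its importance; at the default threshold `p_t = 0` a variable is
#' selected only if its importance strictly exceeds every null-sample
#' value.
#'
#' @param data an [rfvs_dataset()].
#' @param rf an [rf_params()] object.
#' @param p_t p-value threshold for selection.
#' @param seed integer seed (drives the half-split and both forests).
#' @return An `rfvs_selection` with per-variable importance and p-value;
#'   `n_forests_trained` is always 2.
#' @details The method requires some non-positive importance scores and
#'   therefore only applies in high-dimensional settings where many
#'   variables are uninformative; an error is raised otherwise.
#' @export
select_vita <- function(data, rf = rf_params(), p_t = 0, seed = rf$seed) {
  stopifnot(inherits(data, "rfvs_dataset"))
  check_scalar_number(p_t, "p_t", lower = 0, upper = 1)
  imp <- holdout_importance(data, rf, seed = seed)
  pv <- vita_pvalues(imp$values)
  diagnostics <- data.frame(
    variable = data$var_names,
    importance = unname(imp$values),
    p_value = unname(pv$p),
    selected = unname(pv$p <= p_t),
    stringsAsFactors = FALSE
  )
  selected <- order_by_importance(data$var_names[pv$p <= p_t], imp$values)
  new_selection_result(
    method = "vita", selected = selected, diagnostics = diagnostics,
    config = list(p_t = p_t, num_trees = rf$num_trees),
    n_forests_trained = 2L, seed = seed
  )
}

# Empirical p-values from the mirrored non-positive null sample.
vita_pvalues <- function(values) {
  neg <- values[values < 0]
  zero <- values[values == 0]
  if (length(neg) + length(zero) == 0L) {
    stop(paste("no non-positive hold-out importance scores: the Vita method",
               "is only applicable in the setting of high-dimensional data",
               "sets with many uninformative variables"), call. = FALSE)
  }
  null_sample <- c(neg, zero, -neg)
  p <- vapply(values, function(v) mean(null_sample >= v), numeric(1L))
  list(null_sample = unname(null_sample), p = p)
}
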