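#' Altmann: parametric outcome-permutation selection
#'
#' Reduces the number of permutations needed by the Perm approach:
#' a normal distribution is fitted by maximum likelihood (mean = sample
#' mean, sd with N denominator) to each variable's null importances from
#' `no_perm` outcome permutations, and the p-value is the upper-tail
#' probability of the original importance under that fit. With the
#' default threshold `p_t = 0`, a variable is selected when its p-value
#' underflows to zero in double precision (z above roughly 39), which
#' strong predictors reach in practice.
#'
#' @inheritParams select_perm
#' @param no_perm number of outcome permutations (>= 2 for the MLE).
#' @return An `rfvs_selection`.
#' @details The normal fit is applied to the *raw* permutation
#'   importance; the scaled Z-score variant is avoided because it is not
#'   normally distributed. If a variable's null importances have zero
#'   variance, its p-value is defined as 0 when the original importance
#'   exceeds the null mean and 1 otherwise.
#' @export
select_altmann <- function(data, rf = rf_params(), no_perm = 50, p_t = 0,
                           seed = rf$seed, null = NULL) {
  stopifnot(inherits(data, "rfvs_dataset"))
  no_perm <- check_count(no_perm, "no_perm", lower = 2L)
  check_scalar_number(p_t, "p_t", lower = 0, upper = 1)
  trained <- 0L
  if (is.null(null)) {
    null <- perm_null_importance(data, rf, no_perm = no_perm, seed = seed)
    trained <- null$n_forests
  }
  null_check(null, data, no_perm)
  orig <- null$original$values
  p <- altmann_pvalues(orig, null$null[, seq_len(no_perm), drop = FALSE])
  diagnostics <- data.frame(
    variable = data$var_names,
    importance = unname(orig),
    p_value = unname(p),
    selected = unname(p <= p_t),
    stringsAsFactors = FALSE
  )
  selected <- order_by_importance(data$var_names[p <= p_t], orig)
  new_selection_result(
    method = "altmann", selected = selected, diagnostics = diagnostics,
    config = list(no_perm = no_perm, p_t = p_t, num_trees = rf$num_trees),
    n_forests_trained = trained, seed = seed
  )
}

# Upper-tail normal p-values under the per-variable maximum-likelihood
# fit; degenerate (zero-variance) nulls give p = 0 / 1 by threshold rule.
altmann_pvalues <- function(orig, null) {
  m <- rowMeans(null)
  s <- sqrt(rowMeans((null - m)^2))
  p <- ifelse(s > 0,
              stats::pnorm(orig, mean = m, sd = s, lower.tail = FALSE),
              ifelse(orig > m, 0, 1))
  unname(p)
}
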