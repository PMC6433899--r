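#' Boruta: all-relevant selection against shadow variables
#'
#' Iteratively compares each real variable's importance with the maximum
#' importance attained by "shadow" variables — permuted copies of the
#' undecided real variables whose association with the outcome has been
#' destroyed. In each run the shadows are re-permuted, a forest is
#' trained on real + shadow variables, and a variable scores a *hit* if
#' its importance exceeds the maximum shadow importance. After every run
#' a two-sided binomial test (hits vs Binomial(runs, 0.5), Bonferroni
#' corrected across the undecided variables) confirms variables hitting
#' significantly more than half of the runs and rejects those hitting
#' significantly fewer. Rejected variables and all shadows are removed
#' and the procedure repeats until every variable is classified or
#' `max_runs` is reached; variables still undecided then are reported as
#' `"tentative"` (and not counted as selected).
#'
#' @param data an [rfvs_dataset()].
#' @param rf forest parameters; `NULL` (default) uses the Boruta
#'   convention: mtry = sqrt(number of variables in the extended set),
#'   nodesize 1 for classification / 5 for regression, `num_trees` trees.
#' @param p_value confidence level for the binomial decisions.
#' @param max_runs maximum number of forest runs.
#' @param seed integer seed.
#' @param num_trees trees per forest, used when `rf` is `NULL`.
#' @return An `rfvs_selection`; `diagnostics$status` is one of
#'   `"confirmed"`, `"rejected"`, `"tentative"`.
#' @examples
#' \donttest{
#' sim <- simulate_sim1(sim1_config(group_size = 2, n_total_vars = 30,
#'                                  n_individuals = 60, seed = 1))
#' select_boruta(sim$replicates[[1]], num_trees = 200, seed = 1)
#' }
#' @export
select_boruta <- function(data, rf = NULL, p_value = 0.01, max_runs = 100,
                          seed = 1L, num_trees = 10000) {
  stopifnot(inherits(data, "rfvs_dataset"))
  check_scalar_number(p_value, "p_value", lower = 0, upper = 1,
                      strict_lower = TRUE)
  max_runs <- check_count(max_runs, "max_runs")
  if (n_variables(data) < 1L) stop("no variables to select from", call. = FALSE)
  if (is.null(rf)) {
    rf <- boruta_default_params(data$task, num_trees = num_trees, seed = seed)
  }
  vars <- data$var_names
  p <- length(vars)
  status <- stats::setNames(rep("undecided", p), vars)
  hits <- stats::setNames(integer(p), vars)
  imp_sum <- stats::setNames(numeric(p), vars)
  imp_n <- stats::setNames(integer(p), vars)
  final_p <- stats::setNames(rep(NA_real_, p), vars)
  seeds <- matrix(derive_seeds(seed, 2L * max_runs), ncol = 2L)
  runs <- 0L

  while (any(status == "undecided") && runs < max_runs) {
    runs <- runs + 1L
    undecided <- names(status)[status == "undecided"]
    kept <- names(status)[status != "rejected"]
    shadow <- with_seed(seeds[runs, 1L], {
      apply(data$X[, undecided, drop = FALSE], 2L, sample)
    })
    if (!is.matrix(shadow)) shadow <- matrix(shadow, nrow = n_individuals(data))
    colnames(shadow) <- paste0(".shadow.", undecided)
    X_ext <- cbind(data$X[, kept, drop = FALSE], shadow)
    params <- resolve_params(rf, nrow(X_ext), ncol(X_ext))
    fit <- fit_ranger(X_ext, data$y, data$task, params,
                      seed = seeds[runs, 2L])
    imp <- fit$variable.importance
    shadow_max <- max(imp[colnames(shadow)])
    imp_real <- imp[kept]
    imp_sum[kept] <- imp_sum[kept] + imp_real
    imp_n[kept] <- imp_n[kept] + 1L
    hits[undecided] <- hits[undecided] + (imp[undecided] > shadow_max)

    dec <- boruta_decide(hits[undecided], runs, p_value)
    final_p[undecided] <- attr(dec, "p_value")
    status[undecided] <- ifelse(dec == "undecided", "undecided", dec)
  }

  tentative <- status == "undecided"
  if (any(tentative)) {
    status[tentative] <- "tentative"
    warning(sprintf("Boruta reached max_runs = %d with %d tentative variable(s)",
                    max_runs, sum(tentative)), call. = FALSE)
  }
  importance <- ifelse(imp_n > 0L, imp_sum / pmax(imp_n, 1L), 0)
  diagnostics <- data.frame(
    variable = vars,
    importance = unname(importance),
    hits = unname(hits),
    p_value = unname(final_p),
    status = unname(status),
    selected = unname(status == "confirmed"),
    stringsAsFactors = FALSE
  )
  selected <- order_by_importance(vars[status == "confirmed"], importance)
  new_selection_result(
    method = "boruta", selected = selected, diagnostics = diagnostics,
    config = list(p_value = p_value, max_runs = max_runs,
                  num_trees = rf$num_trees, mtry_mode = rf$mtry_mode,
                  nodesize = rf$nodesize),
    n_forests_trained = runs, seed = seed
  )
}

# Binomial decisions on cumulative hit counts. Two-sided exact test of
# hits ~ Binomial(runs, 1/2), Bonferroni-corrected across the variables
# still undecided in this round. Returns the per-variable status with the
# unadjusted two-sided p-values as attribute.
boruta_decide <- function(hits, runs, p_value) {
  lower <- stats::pbinom(hits, runs, 0.5)
  upper <- stats::pbinom(hits - 1L, runs, 0.5, lower.tail = FALSE)
  p_two <- pmin(1, 2 * pmin(lower, upper))
  p_adj <- pmin(1, p_two * length(hits))
  out <- rep("undecided", length(hits))
  out[p_adj <= p_value & hits > runs / 2] <- "confirmed"
  out[p_adj <= p_value & hits < runs / 2] <- "rejected"
  names(out) <- names(hits)
  attr(out, "p_value") <- p_two
  out
}
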