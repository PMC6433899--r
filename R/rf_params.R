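#' Random-forest hyperparameters
#'
#' The defaults reproduce the benchmark parameterization used throughout
#' the package: 10 000 trees, mtry = 33% of the number of variables and a
#' minimal terminal-node size of 10% of the sample size. The Boruta
#' selector overrides these with the conventional defaults of its
#' reference implementation (mtry = sqrt(p), nodesize 1 for
#' classification / 5 for regression).
#'
#' @param num_trees number of trees per forest.
#' @param mtry_mode `"fraction"` (mtry = `mtry_fraction` * p) or
#'   `"sqrt"` (mtry = floor(sqrt(p))).
#' @param mtry_fraction fraction of variables tried at each split, in
#'   (0, 1]; used when `mtry_mode = "fraction"`.
#' @param nodesize_fraction fraction of the sample size used as minimal
#'   terminal-node size, in (0, 1]; ignored when `nodesize` is given.
#' @param nodesize absolute minimal terminal-node size (overrides
#'   `nodesize_fraction`).
#' @param seed integer seed from which all per-forest and per-permutation
#'   random streams are derived.
#'
#' @return An object of class `rfvs_params`. Call [resolve_params()] to
#'   turn fractions into integer `mtry` / `nodesize` for a concrete
#'   dataset size.
#' @examples
#' resolve_params(rf_params(), n_individuals = 100, n_variables = 5000)
#' @export
rf_params <- function(num_trees = 10000, mtry_mode = c("fraction", "sqrt"),
                      mtry_fraction = 0.33, nodesize_fraction = 0.10,
                      nodesize = NULL, seed = 1L) {
  mtry_mode <- match.arg(mtry_mode)
  num_trees <- check_count(num_trees, "num_trees")
  if (mtry_mode == "fraction") {
    check_scalar_number(mtry_fraction, "mtry_fraction", lower = 0,
                        upper = 1, strict_lower = TRUE)
  }
  if (is.null(nodesize)) {
    check_scalar_number(nodesize_fraction, "nodesize_fraction", lower = 0,
                        upper = 1, strict_lower = TRUE)
  } else {
    nodesize <- check_count(nodesize, "nodesize")
  }
  seed <- check_count(seed, "seed", lower = 0L)
  structure(
    list(num_trees = num_trees, mtry_mode = mtry_mode,
         mtry_fraction = mtry_fraction, nodesize_fraction = nodesize_fraction,
         mtry = NULL, nodesize = nodesize, seed = seed),
    class = "rfvs_params"
  )
}

#' Resolve fractional parameters to integers
#'
#' @param params an [rf_params()] object.
#' @param n_individuals,n_variables dimensions of the dataset the forest
#'   will be trained on.
#' @return `params` with integer `mtry` and `nodesize` filled in:
#'   `mtry = max(1, round(mtry_fraction * n_variables))` in fraction mode,
#'   `max(1, floor(sqrt(n_variables)))` in sqrt mode;
#'   `nodesize = max(1, round(nodesize_fraction * n_individuals))` unless
#'   an absolute nodesize was given.
#' @export
resolve_params <- function(params, n_individuals, n_variables) {
  stopifnot(inherits(params, "rfvs_params"))
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_variables <- check_count(n_variables, "n_variables")
  params$mtry <- if (params$mtry_mode == "fraction") {
    max(1L, as.integer(round(params$mtry_fraction * n_variables)))
  } else {
    max(1L, as.integer(floor(sqrt(n_variables))))
  }
  params$mtry <- min(params$mtry, n_variables)
  if (is.null(params$nodesize)) {
    params$nodesize <- max(1L, as.integer(round(params$nodesize_fraction *
                                                  n_individuals)))
  }
  params
}

#' @export
print.rfvs_params <- function(x, ...) {
  cat(sprintf("<rfvs_params> num_trees=%d, mtry=%s, nodesize=%s, seed=%d\n",
              x$num_trees,
              if (is.null(x$mtry)) {
                if (x$mtry_mode == "fraction") {
                  sprintf("%.0f%% of p", 100 * x$mtry_fraction)
                } else "sqrt(p)"
              } else as.character(x$mtry),
              if (is.null(x$nodesize)) {
                sprintf("%.0f%% of n", 100 * x$nodesize_fraction)
              } else as.character(x$nodesize),
              x$seed))
  invisible(x)
}

# Boruta's conventional forest defaults: mtry = sqrt(p), nodesize 1/5.
boruta_default_params <- function(task, num_trees = 10000, seed = 1L) {
  rf_params(num_trees = num_trees, mtry_mode = "sqrt",
            nodesize = if (task == "classification") 1L else 5L,
            seed = seed)
}
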