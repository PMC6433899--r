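# SelectionResult container shared by all six selectors.

new_selection_result <- function(method, selected, diagnostics, config,
                                 n_forests_trained, seed) {
  stopifnot(is.character(selected),
            is.data.frame(diagnostics),
            all(selected %in% diagnostics$variable))
  if (!is.null(diagnostics$p_value)) {
    pv <- diagnostics$p_value
    stopifnot(all(is.na(pv) | (pv >= 0 & pv <= 1)))
  }
  structure(
    list(method = method, selected = selected, diagnostics = diagnostics,
         config = config, n_forests_trained = as.integer(n_forests_trained),
         seed = as.integer(seed)),
    class = "rfvs_selection"
  )
}

#' @export
print.rfvs_selection <- function(x, ...) {
  cat(sprintf("<rfvs_selection> method=%s: %d of %d variables selected (%d forests trained)\n",
              x$method, length(x$selected), nrow(x$diagnostics),
              x$n_forests_trained))
  if (length(x$selected) > 0L) {
    cat("  selected:", paste(utils::head(x$selected, 10L), collapse = ", "),
        if (length(x$selected) > 10L) "..." else "", "\n")
  }
  if (!is.null(x$diagnostics$status)) {
    cat("  status:", paste(sprintf("%s=%d", names(table(x$diagnostics$status)),
                                   table(x$diagnostics$status)),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Names of the selected variables
#' @param result an `rfvs_selection` object.
#' @return character vector, ordered by decreasing importance.
#' @export
selected_variables <- function(result) {
  stopifnot(inherits(result, "rfvs_selection"))
  result$selected
}

# order a selected set by decreasing importance for reporting
order_by_importance <- function(selected, importance) {
  selected[order(-importance[selected])]
}

#' Run a selector by name
#'
#' Thin dispatcher used by the benchmark harness and the command-line
#' interface.
#'
#' @param data an [rfvs_dataset()].
#' @param method one of `"boruta"`, `"vita"`, `"r2vim"`, `"perm"`,
#'   `"altmann"`, `"rfe"`.
#' @param rf an [rf_params()] object (Boruta substitutes its own forest
#'   defaults unless `rf` is explicitly tagged, see [select_boruta()]).
#' @param config named list of method-specific arguments (e.g.
#'   `list(no_perm = 50)`).
#' @param seed integer seed for this selection run.
#' @return An `rfvs_selection` object.
#' @export
select_variables <- function(data, method, rf = rf_params(),
                             config = list(), seed = rf$seed) {
  method <- match.arg(method, c("boruta", "vita", "r2vim", "perm",
                                "altmann", "rfe"))
  fun <- switch(method,
    boruta = select_boruta, vita = select_vita, r2vim = select_r2vim,
    perm = select_perm, altmann = select_altmann, rfe = select_rfe)
  if (method == "boruta" && !("rf" %in% names(config))) {
    # Boruta keeps its conventional forest defaults; only the tree count
    # and seed are taken from the shared parameterization.
    args <- c(list(data = data, seed = seed, num_trees = rf$num_trees), config)
  } else {
    args <- c(list(data = data, rf = rf, seed = seed), config)
  }
  do.call(fun, args)
}
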