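#' Construct a validated dataset
#'
#' Bundles a numeric feature matrix with an outcome and a task flag. All
#' selectors, simulators and evaluation helpers operate on this container.
#'
#' @param X numeric matrix, individuals in rows, variables in columns.
#'   Column names are used as variable names; unnamed columns are named
#'   `V1..Vp`.
#' @param y outcome: numeric for `task = "regression"`, a factor or vector
#'   with exactly two distinct values for `task = "classification"`.
#' @param task `"classification"` or `"regression"`.
#'
#' @return An object of class `rfvs_dataset`: a list with elements `X`
#'   (matrix), `y` (numeric or two-level factor), `var_names`, `task`.
#'
#' @details Missing values are rejected; variable names must be unique;
#'   at least two individuals are required. For classification the outcome
#'   is coerced to a factor and must have exactly two levels.
#'
#' @examples
#' d <- rfvs_dataset(matrix(rnorm(40), 10, 4), rnorm(10), task = "regression")
#' d
#' @export
rfvs_dataset <- function(X, y, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be a numeric matrix", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("at least 2 individuals are required", call. = FALSE)
  if (p < 1L) stop("at least 1 variable is required", call. = FALSE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in X at row %d, column %d", idx[1L], idx[2L]),
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (anyDuplicated(colnames(X))) {
    stop("variable names must be unique", call. = FALSE)
  }
  if (length(y) != n) {
    stop(sprintf("length of y (%d) does not match rows of X (%d)",
                 length(y), n), call. = FALSE)
  }
  if (anyNA(y)) stop("missing values in y", call. = FALSE)
  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) != 2L) {
      stop(sprintf("classification outcome must have exactly 2 levels, got %d",
                   nlevels(y)), call. = FALSE)
    }
  } else {
    y <- as.numeric(y)
    if (stats::var(y) == 0) {
      stop("regression outcome is constant", call. = FALSE)
    }
  }
  structure(
    list(X = X, y = y, var_names = colnames(X), task = task),
    class = "rfvs_dataset"
  )
}

#' @export
print.rfvs_dataset <- function(x, ...) {
  cat(sprintf("<rfvs_dataset> %d individuals x %d variables, task: %s\n",
              nrow(x$X), ncol(x$X), x$task))
  if (x$task == "classification") {
    tab <- table(x$y)
    cat(sprintf("  classes: %s\n",
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Number of individuals / variables in a dataset
#' @param data an `rfvs_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(data) nrow(data$X)

#' @rdname n_individuals
#' @export
n_variables <- function(data) ncol(data$X)

#' Restrict a dataset to a subset of variables
#' @param data an `rfvs_dataset`.
#' @param vars character vector of variable names to keep.
#' @return an `rfvs_dataset` with the chosen columns, in `vars` order.
#' @export
subset_variables <- function(data, vars) {
  missing <- setdiff(vars, data$var_names)
  if (length(missing) > 0L) {
    stop(sprintf("unknown variables: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  rfvs_dataset(data$X[, vars, drop = FALSE], data$y, task = data$task)
}
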