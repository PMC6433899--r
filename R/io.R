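# Tabular readers/writers: datasets, importances, selections, reports.

#' Read a dataset from delimited text
#'
#' @param path_x path to the feature table: header row of variable
#'   names, one row per individual, numeric cells.
#' @param path_y path to a single-column outcome file (with header);
#'   alternatively set `outcome` to the name of a column of `path_x`.
#' @param task `"classification"` or `"regression"`.
#' @param outcome name of the outcome column inside `path_x` (used when
#'   `path_y` is `NULL`).
#' @param sep field separator (default tab).
#' @return an [rfvs_dataset()].
#' @export
read_dataset <- function(path_x, path_y = NULL,
                         task = c("classification", "regression"),
                         outcome = NULL, sep = "\t") {
  task <- match.arg(task)
  tab <- utils::read.table(path_x, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(path_y)) {
    if (is.null(outcome) || !(outcome %in% names(tab))) {
      stop("`outcome` must name a column of the feature table when `path_y` is not given",
           call. = FALSE)
    }
    y <- tab[[outcome]]
    tab <- tab[setdiff(names(tab), outcome)]
  } else {
    ytab <- utils::read.table(path_y, header = TRUE, sep = sep,
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(ytab) != 1L) {
      stop("outcome file must have exactly one column", call. = FALSE)
    }
    y <- ytab[[1L]]
  }
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1L]
      stop(sprintf("non-numeric cell in column '%s', row %s",
                   names(tab)[j], ifelse(is.na(bad), "?", bad)),
           call. = FALSE)
    }
    if (anyNA(tab[[j]])) {
      stop(sprintf("missing value in column '%s', row %d", names(tab)[j],
                   which(is.na(tab[[j]]))[1L]), call. = FALSE)
    }
  }
  if (length(y) != nrow(tab)) {
    stop(sprintf("outcome length (%d) does not match number of rows (%d)",
                 length(y), nrow(tab)), call. = FALSE)
  }
  rfvs_dataset(as.matrix(tab), y, task = task)
}

#' Write a dataset to delimited text
#'
#' @param data an [rfvs_dataset()].
#' @param path_x,path_y output paths for the feature table and the
#'   single-column outcome file.
#' @param sep field separator.
#' @return invisibly, `data`.
#' @export
write_dataset <- function(data, path_x, path_y, sep = "\t") {
  stopifnot(inherits(data, "rfvs_dataset"))
  utils::write.table(as.data.frame(data$X), path_x, sep = sep,
                     row.names = FALSE, quote = FALSE)
  ytab <- data.frame(y = if (data$task == "classification")
    as.character(data$y) else data$y)
  utils::write.table(ytab, path_y, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(data)
}

#' Export an importance vector as TSV
#'
#' Columns: variable, importance, kind, seed.
#' @param importance an `rfvs_importance`.
#' @param path output path.
#' @export
write_importance <- function(importance, path) {
  stopifnot(inherits(importance, "rfvs_importance"))
  utils::write.table(
    data.frame(variable = names(importance$values),
               importance = unname(importance$values),
               kind = importance$kind, seed = importance$run_seed),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(importance)
}

#' Export a selection result
#'
#' Writes `<prefix>.tsv` with per-variable diagnostics (selected coded
#' 0/1) and `<prefix>.json` with method, configuration, seed and the
#' number of forests trained.
#'
#' @param result an `rfvs_selection`.
#' @param prefix output path prefix.
#' @export
write_selection <- function(result, prefix) {
  stopifnot(inherits(result, "rfvs_selection"))
  diag <- result$diagnostics
  diag$selected <- as.integer(diag$selected)
  utils::write.table(diag, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(method = result$method, config = result$config,
         seed = result$seed, n_forests_trained = result$n_forests_trained,
         selected = result$selected),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Export a benchmark report
#'
#' Writes tidy TSVs (`records.tsv`, `stability.tsv`, `power.tsv`) and a
#' JSON summary (`summary.json`) into a directory.
#'
#' @param report an `rfvs_eval_report`.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rfvs_eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$records, file.path(dir, "records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$stability, file.path(dir, "stability.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$power)) {
    utils::write.table(report$power, file.path(dir, "power.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(design = report$design, pairing = report$pairing,
         seed = report$seed, summary = report$summary,
         stability = report$stability),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  invisible(report)
}

#' Read / write a covariance matrix as dense TSV
#'
#' @param path file path; the TSV has a header of variable names.
#' @return `read_covariance`: a named square matrix.
#' @export
read_covariance <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab)
  rownames(m) <- colnames(m)
  m
}

#' @rdname read_covariance
#' @param covariance square matrix with column names.
#' @export
write_covariance <- function(covariance, path) {
  utils::write.table(as.data.frame(covariance), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(covariance)
}
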