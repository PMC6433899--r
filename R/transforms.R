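# Generic preprocessing transforms for experimental omics matrices.

#' Quartile binning into four ordinal groups
#'
#' Divides a vector of values (e.g. methylation beta values of one CpG
#' position) into four ordinal groups at the three quartile cut points,
#' lower-closed: values at or below a cut point fall into the lower bin.
#' The mapping is monotone.
#'
#' @param values numeric vector.
#' @return integer vector of bins in 1..4.
#' @details Quartiles use the standard linear-interpolation definition
#'   (`stats::quantile`, type 7). A constant vector maps entirely to bin
#'   1, with a warning.
#' @examples
#' quartile_bin(c(1, 2, 3, 4))
#' @export
quartile_bin <- function(values) {
  stopifnot(is.numeric(values))
  if (anyNA(values)) stop("missing values in input", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  if (q[1L] == q[3L] && all(values == values[1L])) {
    warning("constant vector: all values assigned to bin 1", call. = FALSE)
    return(rep(1L, length(values)))
  }
  1L + (values > q[1L]) + (values > q[2L]) + (values > q[3L])
}

#' Standardize to mean 0, standard deviation 1
#'
#' Uses the population (N-denominator) standard deviation, consistent
#' with the maximum-likelihood normal fit of the Altmann selector.
#'
#' @param values numeric vector (non-constant).
#' @return numeric vector with mean 0 and population sd 1.
#' @examples
#' standardize(c(1, 3))  # -1, 1
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values))
  if (anyNA(values)) stop("missing values in input", call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("cannot standardize a constant vector", call. = FALSE)
  (values - m) / s
}

#' log2(x + 1) transform for read counts
#'
#' @param values non-negative numeric vector.
#' @return `log2(values + 1)`.
#' @examples
#' log2p1(c(0, 1, 3))
#' @export
log2p1 <- function(values) {
  stopifnot(is.numeric(values))
  if (anyNA(values)) stop("missing values in input", call. = FALSE)
  if (any(values < 0)) {
    stop(sprintf("negative count at position %d", which(values < 0)[1L]),
         call. = FALSE)
  }
  log2(values + 1)
}
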