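# Small in-code fixtures shared across test files.

# Regression data with one strong linear predictor among uniform noise.
make_signal_data <- function(n = 80, p = 10, seed = 1, task = "regression") {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  if (task == "regression") {
    y <- 3 * X[, 1] + rnorm(n, sd = 0.2)
    rfvs_dataset(X, y, task = "regression")
  } else {
    y <- factor(ifelse(X[, 1] + rnorm(n, sd = 0.2) > 0.5, "a", "b"))
    rfvs_dataset(X, y, task = "classification")
  }
}

# Pure-noise classification data with balanced classes.
make_null_data <- function(n = 80, p = 10, seed = 1,
                           task = "classification") {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  y <- if (task == "classification") {
    factor(rep(c("a", "b"), length.out = n))
  } else rnorm(n)
  rfvs_dataset(X, y, task = task)
}

# Classification data where one column equals the outcome coding.
make_perfect_predictor_data <- function(n = 100, p_noise = 10, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(matrix(runif(n * p_noise), n, p_noise),
             as.numeric(y))
  colnames(X) <- c(paste0("noise", seq_len(p_noise)), "dup_y")
  rfvs_dataset(X, y, task = "classification")
}

fast_rf <- function(num_trees = 200, seed = 1) {
  rf_params(num_trees = num_trees, seed = seed)
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
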