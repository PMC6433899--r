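#' Configuration for the nonlinear-regression simulation design
#'
#' The design generates a quantitative outcome that depends nonlinearly
#' on three hidden base variables, plus six groups of predictors
#' correlated with the base variables and a large pool of independent
#' uniform noise variables. Groups 1-3 derive from the outcome-relevant
#' base variables (and are the causal truth); groups 4-6 derive from
#' irrelevant base variables.
#'
#' @param group_size number of correlated variables per group (n >= 2;
#'   the benchmark scenarios use 10 and 50).
#' @param n_individuals individuals per replicate (default 100).
#' @param n_total_vars total predictors per replicate (default 5000;
#'   must be at least 6 * group_size).
#' @param noise_sd_outcome sd of the additive outcome noise (default 0.2).
#' @param noise_sd_group sd of the group-noise draws (default 0.3).
#' @param null_model if `TRUE`, the outcome is generated independently of
#'   every predictor (sum of three N(0, noise_sd_outcome) draws) and the
#'   causal truth is empty.
#' @param seed integer seed.
#' @return An object of class `sim1_config`.
#' @details The j-th variable of group i is
#'   `v_ij = x_i + c_j * N(0, noise_sd_group)` with noise multiplier
#'   `c_j = 0.01 + 0.5 (j-1)/(n-1)`, so the correlation with the base
#'   variable (and hence with the outcome for groups 1-3) decreases with
#'   j. The base variables themselves are not included as predictors.
#' @export
sim1_config <- function(group_size = 10, n_individuals = 100,
                        n_total_vars = 5000, noise_sd_outcome = 0.2,
                        noise_sd_group = 0.3, null_model = FALSE,
                        seed = 1L) {
  group_size <- check_count(group_size, "group_size", lower = 2L)
  n_individuals <- check_count(n_individuals, "n_individuals", lower = 2L)
  n_total_vars <- check_count(n_total_vars, "n_total_vars")
  if (6L * group_size > n_total_vars) {
    stop("n_total_vars must be at least 6 * group_size", call. = FALSE)
  }
  check_scalar_number(noise_sd_outcome, "noise_sd_outcome", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(noise_sd_group, "noise_sd_group", lower = 0,
                      strict_lower = TRUE)
  structure(
    list(group_size = group_size, n_individuals = n_individuals,
         n_total_vars = n_total_vars, noise_sd_outcome = noise_sd_outcome,
         noise_sd_group = noise_sd_group, null_model = isTRUE(null_model),
         seed = check_count(seed, "seed", lower = 0L)),
    class = "sim1_config"
  )
}

# The nonlinear outcome surface (without noise).
sim1_outcome <- function(x1, x2, x3) {
  0.25 * exp(4 * x1) + 4 / (1 + exp(-20 * (x2 - 0.5))) + 3 * x3
}

#' Simulate replicates of the nonlinear-regression design
#'
#' @param cfg a [sim1_config()].
#' @param n_replicates number of independent replicates to generate.
#' @return An `rfvs_replicates` object: list with `replicates` (list of
#'   [rfvs_dataset()]s sharing variable names), `truth` (data frame of
#'   causal variables with group index and noise multiplier; empty for
#'   the null model), `pairing = NULL`, `task = "regression"`.
#' @examples
#' rs <- simulate_sim1(sim1_config(group_size = 2, n_total_vars = 20,
#'                                 n_individuals = 30), n_replicates = 2)
#' rs
#' @export
simulate_sim1 <- function(cfg, n_replicates = 1L) {
  stopifnot(inherits(cfg, "sim1_config"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  gs <- cfg$group_size
  n <- cfg$n_individuals
  p <- cfg$n_total_vars
  c_j <- 0.01 + 0.5 * (seq_len(gs) - 1) / (gs - 1)
  group_names <- unlist(lapply(1:6, function(i) {
    sprintf("g%d_v%d", i, seq_len(gs))
  }))
  n_noise <- p - 6L * gs
  var_names <- c(group_names,
                 if (n_noise > 0L) sprintf("noise_%d", seq_len(n_noise)))
  seeds <- derive_seeds(cfg$seed, n_replicates)

  replicates <- lapply(seeds, function(s) {
    with_seed(s, {
      x_base <- matrix(stats::runif(n * 6L), n, 6L)
      groups <- lapply(1:6, function(i) {
        noise <- matrix(stats::rnorm(n * gs, sd = cfg$noise_sd_group), n, gs)
        x_base[, i] + sweep(noise, 2L, c_j, "*")
      })
      X <- do.call(cbind, groups)
      if (n_noise > 0L) {
        X <- cbind(X, matrix(stats::runif(n * n_noise), n, n_noise))
      }
      colnames(X) <- var_names
      y <- if (cfg$null_model) {
        stats::rnorm(n, sd = cfg$noise_sd_outcome) +
          stats::rnorm(n, sd = cfg$noise_sd_outcome) +
          stats::rnorm(n, sd = cfg$noise_sd_outcome)
      } else {
        sim1_outcome(x_base[, 1L], x_base[, 2L], x_base[, 3L]) +
          stats::rnorm(n, sd = cfg$noise_sd_outcome)
      }
      rfvs_dataset(X, y, task = "regression")
    })
  })
  truth <- if (cfg$null_model) {
    data.frame(variable = character(0), group = integer(0),
               noise_multiplier = numeric(0), stringsAsFactors = FALSE)
  } else {
    data.frame(variable = sprintf("g%d_v%d", rep(1:3, each = gs),
                                  rep(seq_len(gs), 3L)),
               group = rep(1:3, each = gs),
               noise_multiplier = rep(c_j, 3L),
               stringsAsFactors = FALSE)
  }
  new_replicates(replicates, truth, pairing = NULL, task = "regression",
                 design = "sim1", config = cfg)
}

#' Configuration for the multivariate-normal classification design
#'
#' Emulates gene-expression-like data: individuals are drawn from a
#' zero-mean multivariate normal with a supplied covariance matrix (a
#' covariance estimated from real expression data, or a block-structured
#' stand-in from [standin_covariance()]). Causal variables are chosen at
#' random — `n_causal_per_effect` per effect size — and the class-1
#' individuals' means are shifted by the effect size on those columns;
#' the binary outcome is the class label. Replicates come in pairs that
#' share identical causal variables and effect sizes, supporting
#' cross-evaluation within pairs.
#'
#' @param covariance p x p symmetric positive semi-definite matrix with
#'   column names (used as variable names); unnamed columns are named.
#' @param n_individuals individuals per replicate, split into two equal
#'   classes (default 200, i.e. 100 per class).
#' @param effect_sizes vector of mean shifts.
#' @param n_causal_per_effect causal variables per effect size.
#' @param n_pairs number of replicate pairs.
#' @param seed integer seed.
#' @return An object of class `sim2_config`.
#' @export
sim2_config <- function(covariance, n_individuals = 200,
                        effect_sizes = c(-3, -2, -1, -0.5, 0.5, 1, 2, 3),
                        n_causal_per_effect = 25, n_pairs = 50, seed = 1L) {
  if (!is.matrix(covariance) || nrow(covariance) != ncol(covariance)) {
    stop("`covariance` must be a square matrix", call. = FALSE)
  }
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8))) {
    stop("`covariance` must be symmetric", call. = FALSE)
  }
  p <- ncol(covariance)
  if (is.null(colnames(covariance))) {
    colnames(covariance) <- rownames(covariance) <- paste0("V", seq_len(p))
  }
  n_individuals <- check_count(n_individuals, "n_individuals", lower = 2L)
  if (n_individuals %% 2L != 0L) {
    stop("`n_individuals` must be even (two equal classes)", call. = FALSE)
  }
  n_causal_per_effect <- check_count(n_causal_per_effect,
                                     "n_causal_per_effect")
  if (length(effect_sizes) * n_causal_per_effect > p) {
    stop(sprintf("need %d causal variables but covariance has only %d",
                 length(effect_sizes) * n_causal_per_effect, p),
         call. = FALSE)
  }
  chol_factor <- tryCatch(chol(covariance), error = function(e) {
    stop(paste("`covariance` is not positive definite; consider projecting",
               "it to the nearest positive semi-definite matrix (e.g. by",
               "truncating negative eigenvalues) before use"), call. = FALSE)
  })
  structure(
    list(covariance = covariance, chol = chol_factor,
         n_individuals = n_individuals, effect_sizes = effect_sizes,
         n_causal_per_effect = n_causal_per_effect,
         n_pairs = check_count(n_pairs, "n_pairs"),
         seed = check_count(seed, "seed", lower = 0L)),
    class = "sim2_config"
  )
}

#' Simulate paired replicates of the multivariate-normal design
#'
#' @param cfg a [sim2_config()].
#' @param n_pairs number of pairs to generate (default `cfg$n_pairs`).
#' @return An `rfvs_replicates` object with `2 * n_pairs` classification
#'   replicates, `pairing` giving the pair index of each replicate and
#'   `truth` a data frame (`pair`, `variable`, `effect_size`).
#' @export
simulate_sim2 <- function(cfg, n_pairs = cfg$n_pairs) {
  stopifnot(inherits(cfg, "sim2_config"))
  n_pairs <- check_count(n_pairs, "n_pairs")
  p <- ncol(cfg$covariance)
  n <- cfg$n_individuals
  var_names <- colnames(cfg$covariance)
  n_causal <- length(cfg$effect_sizes) * cfg$n_causal_per_effect
  seeds <- matrix(derive_seeds(cfg$seed, 3L * n_pairs), ncol = 3L)

  replicates <- vector("list", 2L * n_pairs)
  truth_list <- vector("list", n_pairs)
  for (pr in seq_len(n_pairs)) {
    causal <- with_seed(seeds[pr, 1L], {
      idx <- sample.int(p, n_causal)
      data.frame(pair = pr, variable = var_names[idx],
                 effect_size = rep(cfg$effect_sizes,
                                   each = cfg$n_causal_per_effect),
                 stringsAsFactors = FALSE)
    })
    truth_list[[pr]] <- causal
    for (half in 1:2) {
      replicates[[2L * (pr - 1L) + half]] <-
        with_seed(seeds[pr, 1L + half], {
          X <- matrix(stats::rnorm(n * p), n, p) %*% cfg$chol
          colnames(X) <- var_names
          # class labels: half class 1 after a seeded shuffle of row order
          cls <- sample(rep(1:0, each = n %/% 2L))
          idx <- match(causal$variable, var_names)
          X[cls == 1L, idx] <- sweep(X[cls == 1L, idx, drop = FALSE], 2L,
                                     causal$effect_size, "+")
          rfvs_dataset(X, factor(cls, levels = 0:1,
                                 labels = c("class0", "class1")),
                       task = "classification")
        })
    }
  }
  new_replicates(replicates, do.call(rbind, truth_list),
                 pairing = rep(seq_len(n_pairs), each = 2L),
                 task = "classification", design = "sim2", config = cfg)
}

#' Block-exchangeable stand-in covariance matrix
#'
#' A deterministic substitute for a covariance matrix estimated from
#' experimental expression data: block-diagonal with unit variances and
#' constant within-block correlation, positive semi-definite by
#' construction. It reproduces the qualitative feature that every
#' variable is correlated with at least one other variable, without
#' requiring external data.
#'
#' @param p total number of variables.
#' @param block_sizes integer vector summing to `p`.
#' @param within_block_corr correlation inside each block, in [0, 1).
#' @return A `p` x `p` covariance (here: correlation) matrix with
#'   variable names `V1..Vp`.
#' @examples
#' standin_covariance(4, c(2, 2), 0.9)
#' @export
standin_covariance <- function(p, block_sizes = p, within_block_corr = 0) {
  p <- check_count(p, "p")
  check_scalar_number(within_block_corr, "within_block_corr", lower = 0)
  if (within_block_corr >= 1) {
    stop("`within_block_corr` must be < 1", call. = FALSE)
  }
  block_sizes <- vapply(block_sizes, check_count, integer(1L),
                        name = "block_sizes")
  if (sum(block_sizes) != p) {
    stop(sprintf("block sizes sum to %d, not p = %d", sum(block_sizes), p),
         call. = FALSE)
  }
  blocks <- lapply(block_sizes, function(b) {
    m <- matrix(within_block_corr, b, b)
    diag(m) <- 1
    m
  })
  out <- matrix(0, p, p)
  at <- 0L
  for (blk in blocks) {
    idx <- at + seq_len(nrow(blk))
    out[idx, idx] <- blk
    at <- at + nrow(blk)
  }
  colnames(out) <- rownames(out) <- paste0("V", seq_len(p))
  out
}

new_replicates <- function(replicates, truth, pairing, task, design,
                           config) {
  vn <- replicates[[1L]]$var_names
  stopifnot(all(vapply(replicates, function(r) identical(r$var_names, vn),
                       logical(1L))),
            all(truth$variable %in% vn))
  structure(
    list(replicates = replicates, truth = truth, pairing = pairing,
         task = task, design = design, config = config),
    class = "rfvs_replicates"
  )
}

#' @export
print.rfvs_replicates <- function(x, ...) {
  cat(sprintf("<rfvs_replicates> %s: %d replicate(s), %d variables, %d causal%s\n",
              x$design, length(x$replicates),
              n_variables(x$replicates[[1L]]),
              length(unique(x$truth$variable)),
              if (!is.null(x$pairing)) sprintf(", %d pair(s)",
                                               max(x$pairing)) else ""))
  invisible(x)
}

#' Causal variable names of a replicate set
#'
#' @param replicates an `rfvs_replicates` object.
#' @param pair for paired designs, the pair whose truth to return;
#'   ignored otherwise.
#' @return character vector of causal variable names (empty under a null
#'   model).
#' @export
truth_variables <- function(replicates, pair = NULL) {
  stopifnot(inherits(replicates, "rfvs_replicates"))
  tr <- replicates$truth
  if (!is.null(pair) && !is.null(tr$pair)) tr <- tr[tr$pair == pair, ]
  unique(tr$variable)
}
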