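# --- Vita ------------------------------------------------------------------

test_that("Vita mirrors the non-positive scores into a symmetric null", {
  pv <- rfvarsel:::vita_pvalues(c(-0.2, 0, 0.3, 0.5))
  expect_setequal(pv$null_sample, c(-0.2, 0, 0.2))
  expect_identical(pv$p[3], 0)   # 0.3 exceeds every null value
  expect_identical(pv$p[4], 0)   # so does 0.5
  expect_identical(pv$p[1], 1)   # the negative score is below all of them

  # nothing can reach p = 0 when every importance is non-positive
  for (s in 1:20) {
    set.seed(s)
    vals <- -abs(rnorm(30))
    expect_false(any(rfvarsel:::vita_pvalues(vals)$p == 0))
  }

  expect_error(rfvarsel:::vita_pvalues(c(0.1, 0.5)), "high-dimensional")
})

test_that("Vita selects the signal on simulated data and trains 2 forests", {
  sim <- simulate_sim1(sim1_config(group_size = 5, n_total_vars = 100,
                                   n_individuals = 100, seed = 11))
  res <- select_vita(sim$replicates[[1]], fast_rf(num_trees = 300), seed = 3)
  expect_identical(res$n_forests_trained, 2L)
  expect_true(all(c("variable", "importance", "p_value", "selected") %in%
                    names(res$diagnostics)))
  expect_gt(length(selected_variables(res)), 0)
  expect_true(all(res$diagnostics$p_value >= 0 &
                    res$diagnostics$p_value <= 1))
  # top of group 1 (strongest, least noisy) is found
  expect_true("g1_v1" %in% selected_variables(res))
})

# --- r2VIM -----------------------------------------------------------------

test_that("relative importance divides by the run's |min|, with global fallback", {
  rel <- rfvarsel:::r2vim_relative(matrix(c(6, -2, 1), ncol = 1))
  expect_equal(rel[, 1], c(3, -1, 0.5))

  # run 1 has no negative minimum: the most negative value over all runs
  # is used as its denominator
  imp <- cbind(c(6, 2, 0), c(6, -2, 1))
  rel <- rfvarsel:::r2vim_relative(imp)
  expect_equal(rel[, 1], c(3, 1, 0))
  expect_equal(rel[, 2], c(3, -1, 0.5))

  expect_error(rfvarsel:::r2vim_relative(cbind(c(1, 0), c(2, 0))),
               "degenerate")
})

test_that("r2VIM selects on min relative importance >= factor", {
  d <- make_signal_data(n = 80, p = 12, seed = 4)
  res <- select_r2vim(d, fast_rf(num_trees = 200), no_runs = 5, factor = 3,
                      seed = 6)
  expect_identical(res$n_forests_trained, 5L)
  expect_true("v1" %in% selected_variables(res))
  expect_true(all(res$diagnostics$relative_importance[
    res$diagnostics$selected] >= 3))
  expect_error(select_r2vim(d, fast_rf(50), no_runs = 1), "no_runs")
})

# --- Perm ------------------------------------------------------------------

test_that("Perm p-values follow the r/N definition", {
  orig <- c(a = 0.5, b = 0.05, c = 0)
  null <- rbind(a = c(0.1, 0.2, 0.3, 0.4),
                b = c(0.1, 0.2, 0.0, 0.1),
                c = c(0, 0, 0, 0))
  p <- rfvarsel:::perm_pvalues(orig, null)
  expect_equal(unname(p), c(0, 3 / 4, 1))
  # original above all permutations -> selected at p_t = 0;
  # original below its own permutation median -> p >= 0.5, not selected
  expect_gte(p[["b"]], 0.5)
})

test_that("Perm finds a duplicated outcome among noise", {
  hit <- logical(10)
  for (s in 1:10) {
    d <- make_perfect_predictor_data(n = 60, p_noise = 30, seed = 300 + s)
    res <- select_perm(d, fast_rf(num_trees = 100, seed = s), no_perm = 20,
                       seed = s)
    hit[s] <- "dup_y" %in% selected_variables(res)
    if (s == 1) expect_identical(res$n_forests_trained, 21L)
  }
  expect_gte(mean(hit), 0.95)
})

# --- Altmann ---------------------------------------------------------------

test_that("Altmann p-values match the closed-form normal tail", {
  null <- matrix(c(0.1, -0.1, 0.0, 0.2, -0.2), nrow = 1)
  p <- rfvarsel:::altmann_pvalues(0.5, null)
  s <- sqrt(mean(null^2))
  expect_equal(s, sqrt(0.02))
  # numerical oracle: integrate the fitted normal density above 0.5
  oracle <- stats::integrate(function(x) dnorm(x, 0, s), 0.5, 40 * s,
                             rel.tol = 1e-13)$value
  expect_lt(abs(p - oracle), 1e-10)
  expect_equal(p, 2.03476e-4, tolerance = 1e-5)

  # original at the null mean: p = 1/2 by symmetry
  expect_equal(rfvarsel:::altmann_pvalues(0.0, null), 0.5)

  # z far above the null underflows to exactly 0 in double precision
  expect_identical(rfvarsel:::altmann_pvalues(45 * s, null), 0)

  # degenerate zero-variance null
  zn <- matrix(0, nrow = 1, ncol = 4)
  expect_identical(rfvarsel:::altmann_pvalues(0.3, zn), 0)
  expect_identical(rfvarsel:::altmann_pvalues(-0.3, zn), 1)
  expect_identical(rfvarsel:::altmann_pvalues(0, zn), 1)
})

test_that("Perm and Altmann share permutation forests when a null is supplied", {
  d <- make_signal_data(n = 60, p = 10, seed = 8)
  pn <- perm_null_importance(d, fast_rf(num_trees = 100), no_perm = 10,
                             seed = 13)
  expect_identical(pn$n_forests, 11L)
  res_p <- select_perm(d, fast_rf(100), no_perm = 10, seed = 13, null = pn)
  res_a <- select_altmann(d, fast_rf(100), no_perm = 10, seed = 13, null = pn)
  expect_identical(res_p$n_forests_trained, 0L)
  expect_identical(res_a$n_forests_trained, 0L)
  expect_identical(res_p$diagnostics$importance, res_a$diagnostics$importance)
  expect_error(select_perm(d, fast_rf(100), no_perm = 50, seed = 1,
                           null = pn), "50")
})

# --- Boruta ----------------------------------------------------------------

test_that("Boruta binomial decisions match a brute-force recount", {
  for (runs in c(1L, 5L, 13L, 30L)) {
    hits <- 0:runs
    names(hits) <- paste0("v", hits)
    dec <- rfvarsel:::boruta_decide(hits, runs, p_value = 0.01)
    # oracle: stats::binom.test per variable, Bonferroni across variables
    oracle <- vapply(hits, function(h) {
      p_adj <- min(1, binom.test(h, runs, 0.5)$p.value * length(hits))
      if (p_adj <= 0.01 && h > runs / 2) "confirmed"
      else if (p_adj <= 0.01 && h < runs / 2) "rejected"
      else "undecided"
    }, character(1))
    expect_identical(as.character(dec), unname(oracle))
  }
})

test_that("one Boruta run cannot classify anything", {
  d <- make_signal_data(n = 50, p = 5, seed = 2)
  expect_warning(
    res <- select_boruta(d, num_trees = 100, max_runs = 1, seed = 1),
    "tentative")
  expect_true(all(res$diagnostics$status == "tentative"))
  expect_length(selected_variables(res), 0)
  expect_identical(res$n_forests_trained, 1L)
})

test_that("Boruta confirms a duplicated outcome among noise", {
  hit <- logical(10)
  for (s in 1:10) {
    d <- make_perfect_predictor_data(n = 100, p_noise = 50, seed = 400 + s)
    res <- suppressWarnings(
      select_boruta(d, num_trees = 300, max_runs = 30, seed = s))
    hit[s] <- "dup_y" %in% selected_variables(res)
  }
  expect_gte(mean(hit), 0.95)
})

test_that("Boruta confirms nothing under a pure null model", {
  clean <- logical(12)
  for (s in 1:12) {
    d <- make_null_data(n = 100, p = 500, seed = 500 + s)
    res <- suppressWarnings(
      select_boruta(d, num_trees = 150, max_runs = 30, seed = s))
    clean[s] <- length(selected_variables(res)) == 0
  }
  expect_gte(mean(clean), 0.9)
})

# --- RFE -------------------------------------------------------------------

test_that("RFE keeps a perfect predictor in a small final set", {
  hit <- logical(20)
  sizes <- integer(20)
  for (s in 1:20) {
    d <- make_perfect_predictor_data(n = 60, p_noise = 9, seed = 600 + s)
    res <- select_rfe(d, fast_rf(num_trees = 150), seed = s)
    hit[s] <- "dup_y" %in% selected_variables(res)
    sizes[s] <- length(selected_variables(res))
  }
  expect_gte(mean(hit), 0.95)
  expect_lte(median(sizes), 5)
})

test_that("RFE removes floor(prop_rm * p) variables per step, at least one", {
  d <- make_signal_data(n = 50, p = 50, seed = 3)
  res <- select_rfe(d, fast_rf(num_trees = 50), prop_rm = 0.1, seed = 1)
  h <- attr(res, "history")
  expect_identical(h$n_vars[1:3], c(50L, 45L, 41L))  # 50-5, 45-4(floor 4.5)
  expect_identical(tail(h$n_vars, 1), 1L)
  # tail of the path removes exactly one variable per step
  expect_identical(diff(tail(h$n_vars, 3)), c(-1L, -1L))
  expect_identical(res$n_forests_trained, nrow(h))
})

test_that("zero tolerance returns exactly the error-minimizing set", {
  d <- make_signal_data(n = 50, p = 20, seed = 5)
  res <- select_rfe(d, fast_rf(num_trees = 100), tol_pct = 0, seed = 2)
  h <- attr(res, "history")
  best <- max(h$step[h$oob_error == min(h$oob_error)])
  expect_identical(length(selected_variables(res)), h$n_vars[best])
})

# --- Cross-method properties -----------------------------------------------

test_that("all-relevant selectors never pick an appended constant column", {
  d <- make_signal_data(n = 70, p = 10, seed = 6)
  X <- cbind(d$X, const = 2.5)
  d2 <- rfvs_dataset(X, d$y, task = "regression")
  rf <- fast_rf(num_trees = 150, seed = 3)
  pn <- perm_null_importance(d2, rf, no_perm = 10, seed = 3)
  picks <- list(
    vita = select_vita(d2, rf, seed = 3),
    r2vim = select_r2vim(d2, rf, no_runs = 3, seed = 3),
    perm = select_perm(d2, rf, no_perm = 10, seed = 3, null = pn),
    altmann = select_altmann(d2, rf, no_perm = 10, seed = 3, null = pn),
    boruta = suppressWarnings(select_boruta(d2, num_trees = 150,
                                            max_runs = 25, seed = 3))
  )
  for (res in picks) {
    expect_false("const" %in% selected_variables(res), label = res$method)
  }
})

test_that("weakening the evidence threshold never shrinks the selection", {
  d <- make_signal_data(n = 60, p = 10, seed = 7)
  rf <- fast_rf(num_trees = 100, seed = 4)
  pn <- perm_null_importance(d, rf, no_perm = 10, seed = 4)
  for (p_lo in c(0, 0.1)) {
    s1 <- selected_variables(select_perm(d, rf, 10, p_t = p_lo, null = pn))
    s2 <- selected_variables(select_perm(d, rf, 10, p_t = p_lo + 0.3,
                                         null = pn))
    expect_true(all(s1 %in% s2))
    a1 <- selected_variables(select_altmann(d, rf, 10, p_t = p_lo, null = pn))
    a2 <- selected_variables(select_altmann(d, rf, 10, p_t = p_lo + 0.3,
                                            null = pn))
    expect_true(all(a1 %in% a2))
  }
  hi <- selected_variables(select_r2vim(d, rf, no_runs = 3, factor = 3,
                                        seed = 4))
  lo <- selected_variables(select_r2vim(d, rf, no_runs = 3, factor = 1,
                                        seed = 4))
  expect_true(all(hi %in% lo))

  v0 <- selected_variables(select_vita(d, rf, p_t = 0, seed = 4))
  v1 <- selected_variables(select_vita(d, rf, p_t = 0.2, seed = 4))
  expect_true(all(v0 %in% v1))
})

test_that("the dispatcher routes methods and Boruta keeps its forest defaults", {
  d <- make_signal_data(n = 50, p = 8, seed = 9)
  res <- select_variables(d, "vita", rf = fast_rf(100, seed = 2), seed = 2)
  expect_identical(res$method, "vita")
  resb <- suppressWarnings(
    select_variables(d, "boruta", rf = fast_rf(100, seed = 2),
                     config = list(max_runs = 5), seed = 2))
  expect_identical(resb$config$mtry_mode, "sqrt")
  expect_identical(resb$config$nodesize, 5L)  # regression task
  expect_identical(resb$config$num_trees, 100L)
})
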