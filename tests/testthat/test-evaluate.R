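test_that("FDR and sensitivity follow their set-arithmetic definitions", {
  expect_identical(fdr(c("a", "b"), "a"), 0.5)
  expect_identical(fdr(character(0), c("a", "b")), 0)
  expect_identical(fdr(c("a", "b"), c("a", "b")), 0)
  expect_identical(sensitivity(c("a", "b", "x"), c("a", "b")), 1)
  expect_identical(sensitivity("x", c("a", "b")), 0)
  expect_equal(sensitivity(paste0("v", 1:93), paste0("v", 1:150)), 0.62)
  expect_error(sensitivity("a", character(0)), "empty truth")

  # fdr + precision = 1 on nonempty selections
  set.seed(1)
  for (i in 1:20) {
    sel <- sample(letters, sample(1:10, 1))
    tr <- sample(letters, 8)
    prec <- length(intersect(sel, tr)) / length(sel)
    expect_equal(fdr(sel, tr) + prec, 1)
  }
})

test_that("empirical power is a per-variable recount over replicates", {
  sels <- list(c("a", "b"), c("a"), c("a", "c"), c("b", "a"))
  pw <- empirical_power(sels, c("a", "b", "c"))
  expect_equal(unname(pw), c(1, 0.5, 0.25))
  # brute-force recount oracle on random selections
  set.seed(2)
  sels <- lapply(1:7, function(i) sample(letters[1:10], sample(0:6, 1)))
  truth <- letters[1:5]
  pw <- empirical_power(sels, truth)
  for (v in truth) {
    expect_equal(pw[[v]], mean(vapply(sels, function(s) v %in% s,
                                      logical(1))))
  }
})

test_that("Jaccard indices behave on the boundary and hand cases", {
  expect_identical(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_identical(jaccard_index("a", "b"), 0)
  expect_identical(jaccard_index(character(0), character(0)), 1)
  expect_identical(jaccard_index(character(0), "a"), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d"),
                             modified = TRUE), 2 / 3)

  # modified >= standard for every pair
  set.seed(3)
  for (i in 1:30) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_gte(jaccard_index(a, b, modified = TRUE), jaccard_index(a, b))
  }

  sels <- list(c("a", "b"), c("b", "c"), c("a", "b"))
  expect_equal(jaccard_stability(sels),
               mean(c(1 / 3, 1, 1 / 3)))
  expect_error(jaccard_stability(list("a")), "at least 2")
})

test_that("downstream error is near zero for a kept perfect predictor and 1/2 for none", {
  d <- make_perfect_predictor_data(n = 60, p_noise = 5, seed = 1)
  err <- downstream_error(d, d, "dup_y", fast_rf(num_trees = 100), seed = 1)
  expect_lt(err, 0.05)
  base <- downstream_error(d, d, character(0), fast_rf(100))
  expect_equal(as.numeric(base), 0.5)
  expect_true(isTRUE(attr(base, "baseline")))

  d2 <- make_signal_data(n = 50, p = 5, seed = 2)
  expect_error(downstream_error(d, d2, "v1"), "task mismatch|variable names")
})

test_that("the benchmark bookkeeping covers methods x replicates", {
  rs <- simulate_sim1(sim1_config(group_size = 3, n_total_vars = 60,
                                  n_individuals = 60, seed = 21),
                      n_replicates = 2)
  test_rs <- simulate_sim1(sim1_config(group_size = 3, n_total_vars = 60,
                                       n_individuals = 60, seed = 22),
                           n_replicates = 2)
  rep_ <- run_benchmark(rs, c("vita", "rfe"), rf = fast_rf(num_trees = 100),
                        test_replicates = test_rs, seed = 5)
  expect_identical(nrow(rep_$records), 4L)
  expect_setequal(rep_$records$method, c("vita", "rfe"))
  expect_true(all(rep_$records$error >= 0))
  expect_true(all(rep_$records$fdr >= 0 & rep_$records$fdr <= 1))
  expect_identical(nrow(rep_$stability), 2L)
  expect_true(all(c("jaccard", "jaccard_modified") %in%
                    names(rep_$stability)))
  # power rows: one per method x causal variable
  expect_identical(nrow(rep_$power), 2L * 9L)

  # aggregates do not depend on replicate order (same seeds per replicate
  # index, metrics recomputed from scratch)
  expect_identical(sort(rep_$records$sensitivity),
                   sort(run_benchmark(rs, c("vita", "rfe"),
                                      rf = fast_rf(100),
                                      test_replicates = test_rs,
                                      seed = 5)$records$sensitivity))
})

test_that("paired mode cross-evaluates within pairs and rejects odd sets", {
  cov <- standin_covariance(40, rep(10, 4), 0.3)
  cfg <- sim2_config(cov, n_individuals = 40, effect_sizes = c(-3, 3),
                     n_causal_per_effect = 3, n_pairs = 2, seed = 9)
  rs <- simulate_sim2(cfg)
  rep_ <- run_benchmark(rs, "vita", rf = fast_rf(num_trees = 150), seed = 4)
  expect_identical(rep_$pairing, "paired")
  expect_identical(nrow(rep_$records), 4L)
  expect_identical(rep_$records$pair, rep(1:2, each = 2L))
  # paired power table is per absolute effect size
  expect_setequal(rep_$power$abs_effect, 3)

  rs_odd <- rs
  rs_odd$replicates <- rs_odd$replicates[1:3]
  rs_odd$pairing <- rs_odd$pairing[1:3]
  expect_error(run_benchmark(rs_odd, "vita", pairing = "paired"),
               "even")
})

test_that("a failing selector is recorded as missing, not fatal", {
  rs <- simulate_sim1(sim1_config(group_size = 3, n_total_vars = 20,
                                  n_individuals = 30, seed = 31),
                      n_replicates = 2)
  # r2VIM with an impossible config errors inside the loop
  suppressWarnings(expect_warning(
    rep_ <- run_benchmark(rs, c("vita", "r2vim"), rf = fast_rf(100),
                          cfgs = list(r2vim = list(no_runs = 1)), seed = 2),
    "failed"))
  expect_true(all(rep_$records$failed[rep_$records$method == "r2vim"]))
  expect_false(any(rep_$records$failed[rep_$records$method == "vita"]))
})
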