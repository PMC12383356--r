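test_that("z-standardization uses the run's own mean and population sd", {
  z <- zscore_trace(c(1, 2, 3))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(101)
  for (rep in 1:10) {
    f <- stats::rnorm(sample(5:50, 1), mean = 100, sd = 7)
    z <- zscore_trace(f)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
    # location/scale invariance
    expect_equal(zscore_trace(3.5 * f + 42), z)
  }
  expect_error(zscore_trace(rep(7, 10)), "sd = 0")
  expect_error(zscore_trace(5), "at least 2")
})

test_that("mean z-curve averages per-run standardized curves", {
  f <- c(1, 3, 2, 5, 4)
  mk <- function(fit) {
    bfoalign:::new_run_trace(
      data.frame(iteration = seq_along(fit), best_fitness = fit,
                 best_blosum = fit, best_interaction = 0,
                 nfe = seq_along(fit), elapsed_s = 0),
      NULL, "x", NULL)
  }
  rs <- run_set(list(mk(f), mk(f), mk(f)), "same")
  expect_equal(mean_zcurve(rs), zscore_trace(f))
  # antisymmetric pair cancels
  rs2 <- run_set(list(mk(f), mk(-f)), "anti")
  expect_lt(max(abs(mean_zcurve(rs2))), 1e-12)
  # 30 synthetic runs equal the brute-force average
  set.seed(103)
  runs <- lapply(1:30, function(k) mk(stats::rnorm(5)))
  rs3 <- run_set(runs, "rand")
  brute <- Reduce(`+`, lapply(runs, zscore_trace)) / 30
  expect_equal(mean_zcurve(rs3), brute)
  # constant runs are reported with their index
  expect_error(mean_zcurve(run_set(list(mk(f), mk(rep(1, 5))), "bad")),
               "run 2")
})

test_that("convergence iteration finds the first threshold crossing", {
  expect_equal(convergence_iteration(c(0, 50, 95, 100), 0.95), 3L)
  expect_equal(convergence_iteration(c(10, 50, 95, 100), 1), 4L)
  expect_equal(convergence_iteration(c(10, 100, 50, 60), 0.95), 2L)
  # linear-scan oracle over random traces (positive fitness)
  set.seed(107)
  for (rep in 1:50) {
    f <- stats::runif(sample(5:40, 1), min = 1, max = 100)
    frac <- stats::runif(1, 0.5, 1)
    got <- convergence_iteration(f, frac)
    rm_ <- cummax(f)
    oracle <- NA_integer_
    for (t in seq_along(f)) {
      if (rm_[t] >= frac * max(f)) { oracle <- t; break }
    }
    expect_equal(got, oracle)
  }
  expect_error(convergence_iteration(c(1, 2), 0), "frac")
})

test_that("threshold NFE discards exactly the runs below the pooled median", {
  mk <- function(fit, nfe_step = 8) {
    bfoalign:::new_run_trace(
      data.frame(iteration = seq_along(fit), best_fitness = fit,
                 best_blosum = fit, best_interaction = 0,
                 nfe = nfe_step * seq_along(fit), elapsed_s = 0),
      NULL, "x", NULL)
  }
  # single run per set with bests 10 and 20: tHi = 15, first run discarded
  res <- threshold_nfe(run_set(list(mk(c(5, 10))), "a"),
                       run_set(list(mk(c(15, 20))), "b"))
  expect_equal(res$thi, 15)
  expect_equal(res$discarded_a, 1L)
  expect_length(res$nfe_a, 0)
  expect_equal(res$nfe_b, 8)   # crosses 15 at iteration 1

  # identical sets: same tHi, identical NFE distributions, nothing dropped
  sa <- run_set(lapply(1:5, function(k) mk(c(1, 2, 3 + k))), "a")
  sb <- run_set(lapply(1:5, function(k) mk(c(1, 2, 3 + k))), "b")
  res <- threshold_nfe(sa, sb)
  expect_equal(res$nfe_a, res$nfe_b)
  expect_equal(res$thi, stats::median(3 + 1:5))

  # constructed asymmetry: every best of set A exceeds every best of set B,
  # so all B runs at or below the pooled median are discarded
  sa <- run_set(lapply(1:4, function(k) mk(c(50, 100 + k))), "a")
  sb <- run_set(lapply(1:4, function(k) mk(c(1, 2 + k))), "b")
  res <- threshold_nfe(sa, sb)
  expect_length(res$discarded_b, 4)
  expect_length(res$discarded_a, 0)
  # discarded + reported == total, and discards are exactly best < tHi
  bests_b <- vapply(sb$traces, function(tr) max(tr$iterations$best_fitness),
                    numeric(1))
  expect_equal(sort(res$discarded_b), which(bests_b < res$thi))
  expect_equal(length(res$nfe_b) + length(res$discarded_b), 4)
})

test_that("compare_runs gates on normality and reports Cohen's d", {
  # identical samples: d = 0, non-significant
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.8)
  rep0 <- compare_runs(x, x)
  expect_equal(rep0$cohens_d, 0)
  expect_gt(rep0$p_value, 0.05)

  # two normal samples one sd apart: Welch route, d ~ 1
  set.seed(109)
  a <- stats::rnorm(30)
  b <- stats::rnorm(30, mean = 1)
  rep1 <- compare_runs(a, b)
  expect_equal(rep1$test, "welch_t")
  expect_lt(abs(rep1$cohens_d - 1), 0.5)   # sampling error at n = 30
  expect_lt(rep1$p_value, 0.05)

  # heavy outliers route to Mann-Whitney
  a2 <- c(stats::rnorm(20), 50, 80, 120)
  b2 <- stats::rnorm(23, mean = 0.5)
  rep2 <- compare_runs(a2, b2)
  expect_equal(rep2$test, "mann_whitney_u")

  expect_error(compare_runs(1:2, 1:5), ">= 3")
  expect_error(compare_runs(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("comparison reports serialize to JSON", {
  set.seed(113)
  rep1 <- compare_runs(stats::rnorm(10), stats::rnorm(10, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison_json(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$cohens_d, rep1$cohens_d)
  expect_equal(back$test, rep1$test)
})
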