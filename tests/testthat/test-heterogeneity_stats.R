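test_that("tabulation reproduces simulator truth counts", {
  truth <- mini_truth()
  bins <- truth$layout$bins
  bins$cpg_positions <- truth$cpg_positions_per_bin
  tab <- tabulate_events(truth$events, bins)
  expect_equal(tab$all_abs, truth$bin_counts)
  expect_equal(sum(tab$cpg_abs), sum(truth$events$is_cpg))
  empty <- tabulate_events(truth$events[0, ], bins)
  expect_true(all(empty$all_abs == 0))
})

test_that("overlapping strata each count their events fully", {
  truth <- mini_truth()
  bins <- truth$layout$bins
  big <- rep(TRUE, nrow(truth$events))
  nested <- truth$events$bin <= 2
  tab <- tabulate_events(truth$events, bins,
                         strata = list(cf = big, r1 = nested))
  expect_equal(sum(tab$cf_abs), nrow(truth$events))
  expect_equal(sum(tab$r1_abs), sum(nested))
})

test_that("density is events per 100 kb with guarded denominator", {
  expect_equal(mutation_density(178, 91454), 194.6, tolerance = 1e-3)
  expect_equal(mutation_density(0, 1000), 0)
  expect_equal(mutation_density(396, 16094), 2460.5, tolerance = 1e-4)
  expect_error(mutation_density(1, 0), "positive")
})

test_that("proportionality chi-square matches the textbook formula and its invariances", {
  set.seed(12)
  for (rep in 1:10) {
    k <- 6
    w <- sample(50:500, k)
    o <- sapply(w * 2, function(m) rpois(1, m))
    got <- chi2_proportionality(o, w, exclude_bins = integer(0))
    e <- sum(o) * w / sum(w)
    expect_equal(got$chi2, sum((o - e)^2 / e))
    expect_equal(got$df, k - 1L)
    expect_equal(got$p, pchisq(got$chi2, k - 1, lower.tail = FALSE))
    expect_equal(sum(got$contributions), got$chi2)
    rescaled <- chi2_proportionality(o, w * 7.3, exclude_bins = integer(0))
    expect_equal(rescaled$chi2, got$chi2)
  }
  prop <- chi2_proportionality(c(10, 20, 30), c(1, 2, 3),
                               exclude_bins = integer(0))
  expect_equal(prop$chi2, 0)
})

test_that("weighted mean of per-bin densities equals the pooled density", {
  tab <- msy_event_table()
  d <- mutation_density(tab$all_abs, tab$effective_bases)
  pooled <- mutation_density(sum(tab$all_abs), sum(tab$effective_bases))
  expect_equal(sum(d * tab$effective_bases) / sum(tab$effective_bases), pooled)
})

test_that("ratio statistics reproduce the published fold and Ts/Tv factors", {
  tab <- msy_event_table()
  bt <- msy_bin_table()
  tab$cpg_positions <- bt$cpg_positions
  rs <- ratio_stats(tab)
  expect_equal(rs$tstv_cpg, 367 / 29)
  expect_equal(round(rs$tstv_cpg, 1), 12.7)
  expect_equal(round(rs$tstv_noncpg, 1), 1.5)
  expect_equal(round(rs$cpg_fold, 1), 12.2)
  expect_equal(round(rs$cpg_density, 1), 2460.5)
  # non-CpG transversions vary more across bins than transitions
  expect_gt(rs$cv_noncpg_tv, rs$cv_noncpg_tr)
  flat <- tab
  flat$noncpg_tr <- 50L; flat$noncpg_tv <- 50L
  flat$effective_bases <- 80000L
  rs2 <- ratio_stats(flat)
  expect_equal(rs2$cv_noncpg_tr, 0)
})

test_that("correlation handles exact fits and rejects degenerate input", {
  x <- 1:10
  expect_equal(correlate_bins(x, 2 * x + 1, exclude_bins = integer(0))$r, 1)
  expect_equal(correlate_bins(x, -x, exclude_bins = integer(0))$r, -1)
  expect_error(correlate_bins(rep(1, 5), 1:5, exclude_bins = integer(0)),
               "variance")
  expect_error(correlate_bins(1:2, 2:1, exclude_bins = integer(0)), "3 paired")
})

test_that("stepwise regression keeps a perfect predictor and controls false selection", {
  set.seed(33)
  y <- rnorm(18, 100, 10)
  X <- data.frame(good = y, junk = rnorm(18))
  fit <- regress_density(y, X, mode = "stepwise", exclude_bins = integer(0))
  expect_equal(fit$selected, "good")
  expect_equal(fit$multiple_R, 1)

  # pure-noise predictors: per-predictor false-selection rate near the
  # entry threshold
  reps <- 200
  hits <- 0; tot <- 0
  for (r in seq_len(reps)) {
    y <- rnorm(18)
    X <- data.frame(a = rnorm(18), b = rnorm(18), c = rnorm(18))
    sel <- regress_density(y, X, mode = "stepwise",
                           exclude_bins = integer(0))$selected
    hits <- hits + length(sel); tot <- tot + 3
  }
  rate <- hits / tot
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("stepwise recovers true generating predictors at strong effect sizes", {
  set.seed(44)
  ok <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    X <- data.frame(matrix(rnorm(18 * 7), 18, 7))
    y <- 3 * X[[2]] - 3 * X[[5]] + rnorm(18, sd = 0.5)
    sel <- regress_density(y, X, mode = "stepwise",
                           exclude_bins = integer(0))$selected
    if (all(c("X2", "X5") %in% sel)) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("full regression reports multiple R and drops collinear predictors", {
  set.seed(55)
  X <- data.frame(a = rnorm(18), b = rnorm(18))
  y <- X$a + rnorm(18)
  fit <- regress_density(y, X, mode = "full", exclude_bins = integer(0))
  expect_true(fit$multiple_R >= 0 && fit$multiple_R <= 1)
  expect_length(fit$fitted, 18)
  X$c <- X$a * 2
  expect_warning(regress_density(y, X, mode = "full",
                                 exclude_bins = integer(0)), "collinear")
})
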