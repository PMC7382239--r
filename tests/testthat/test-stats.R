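test_that("KS and Kuiper statistics match the ECDF-scan oracles", {
  set.seed(5)
  for (i in 1:100) {
    a <- round(rnorm(sample(3:20, 1)), 2)   # rounding forces ties sometimes
    b <- round(rnorm(sample(3:20, 1), 0.5), 2)
    st <- cpp_ks_kuiper_stat(a, b)
    expect_identical(unname(st[["D"]] == ks_oracle(a, b)), TRUE)
    expect_equal(st[["V"]], kuiper_oracle(a, b), tolerance = 1e-14)
    expect_gte(st[["V"]], st[["D"]])   # V = D+ + D- >= max(D+, D-)
  }
})

test_that("degenerate and disjoint samples give the boundary statistics", {
  x <- c(0.1, 0.5, 0.9, 0.3)
  r <- ks_two_sample(x, x, p_mode = "asymptotic")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  k <- kuiper_two_sample(x, x, p_mode = "asymptotic")
  expect_equal(k$statistic, 0)
  expect_equal(k$p_value, 1)
  a <- runif(10); b <- runif(10) + 2
  expect_equal(ks_two_sample(a, b, p_mode = "asymptotic")$statistic, 1)
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

test_that("asymptotic KS p agrees with stats::ks.test at moderate n", {
  set.seed(11)
  a <- rnorm(60); b <- rnorm(55, 0.4)
  ours <- ks_two_sample(a, b, p_mode = "asymptotic")
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  # exact mode matches R's exact two-sample distribution
  exact <- ks_two_sample(a, b, p_mode = "exact")
  ref_e <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
  expect_equal(exact$p_value, ref_e$p.value, tolerance = 1e-9)
})

test_that("Kuiper V is invariant under common circular rotation", {
  set.seed(21)
  a <- runif(25, -90, 90)
  b <- runif(30, -90, 90)
  v0 <- kuiper_two_sample(a, b, circular = TRUE, p_mode = "asymptotic")$statistic
  for (shift in c(37, -58, 90, 144)) {
    vs <- kuiper_two_sample(wrap_shift(a, shift), wrap_shift(b, shift),
                            circular = TRUE, p_mode = "asymptotic")$statistic
    expect_equal(vs, v0, tolerance = 1e-12)
  }
  # the plain KS statistic is NOT rotation invariant in general (sanity)
  d0 <- ks_two_sample(angles_to_unit(a), angles_to_unit(b),
                      p_mode = "asymptotic")$statistic
  d1 <- ks_two_sample(angles_to_unit(wrap_shift(a, 37)),
                      angles_to_unit(wrap_shift(b, 37)),
                      p_mode = "asymptotic")$statistic
  expect_false(isTRUE(all.equal(d0, d1, tolerance = 1e-12)))
})

test_that("permutation p-values are valid and detect concentration", {
  # null: permutation p approximately uniform (sub-uniform), n = 15
  set.seed(31)
  ps <- vapply(1:300, function(i) {
    a <- rnorm(15); b <- rnorm(15)
    ks_two_sample(a, b, p_mode = "permutation", n_perm = 199,
                  seed = i)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    rate <- mean(ps <= alpha)
    expect_lt(rate, alpha + 3.5 * sqrt(alpha * (1 - alpha) / 300))
  }
  # power: quarter-turn concentrated angles vs uniform
  set.seed(32)
  conc <- runif(30, -20, 25)
  unif <- runif(30, -90, 90)
  r <- kuiper_two_sample(conc, unif, circular = TRUE,
                         p_mode = "permutation", n_perm = 999, seed = 1)
  expect_lt(r$p_value, 0.01)
})

test_that("the permuted statistic matches the direct statistic computation", {
  set.seed(41)
  a <- rnorm(12); b <- rnorm(14)
  perm <- cpp_perm_stats(a, b, 50, "ks", 7)
  # permutations of the pooled sample must yield achievable KS values
  expect_true(all(perm >= 0 & perm <= 1))
  # identical seed reproduces the permutation stream
  expect_identical(perm, cpp_perm_stats(a, b, 50, "ks", 7))
})

test_that("uniformity test calibrates on uniform angles and rejects spikes", {
  set.seed(51)
  ok <- vapply(1:10, function(i) {
    ang <- runif(40, -90, 90)
    uniformity_test(ang, n_rep = 21, seed = i)$p_median
  }, numeric(1))
  expect_gte(mean(ok > 0.05), 0.9)
  spike <- rnorm(40, 0, 5)
  r <- uniformity_test(spike, n_rep = 21, seed = 1)
  expect_lt(r$p_median, 0.01)
  expect_true(r$significant)
  # single-draw variant is the n_rep = 1 configuration
  r1 <- uniformity_test(spike, n_rep = 1, seed = 1)
  expect_equal(length(r1$p_values), 1L)
})

test_that("bootstrap CI behaves on constants and covers the mean", {
  const <- rep(3.3, 20)
  b <- bootstrap_effect(const, mean, n_boot = 300, seed = 1)
  expect_equal(unname(diff(b$ci)), 0)
  expect_equal(b$statistic, 3.3)
  # subsample curve at full n equals the plain statistic
  set.seed(61)
  x <- rnorm(50)
  bs <- bootstrap_effect(x, mean, n_boot = 300,
                         subsample_sizes = c(10, 25, 50), seed = 2)
  expect_equal(bs$subsample_curve$statistic[3], mean(x), tolerance = 1e-12)
  # modest coverage check (the full-scale one runs in acceptance)
  cover <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    x <- rnorm(60)
    ci <- bootstrap_effect(x, mean, n_boot = 400, seed = i)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.85)
})

test_that("circular mean axis averages nematic angles correctly", {
  expect_equal(circular_mean_axis(c(10, 20)), 15, tolerance = 1e-9)
  expect_equal(circular_mean_axis(c(85, -85)), 90, tolerance = 1e-9)  # wraps
  expect_equal(circular_mean_axis(c(0, 90, 0)), 0, tolerance = 1e-9)
})

test_that("one-sided permutation mean test orders samples correctly", {
  set.seed(71)
  a <- rnorm(20, 1); b <- rnorm(20, 0)
  r <- perm_test_mean_greater(a, b, n_perm = 999, seed = 1)
  expect_lt(r$p_value, 0.05)
  r2 <- perm_test_mean_greater(b, a, n_perm = 999, seed = 1)
  expect_gt(r2$p_value, 0.5)
})
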