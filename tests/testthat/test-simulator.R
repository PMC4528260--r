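test_that("cumulative coalescent rates have the right closed forms and inverses", {
  expect_equal(cumulative_rate(demography("constant", N = 1e3), 0.7), 0.7)
  dexp1 <- demography("exponential", N = 1e3, beta = 1)
  expect_equal(cumulative_rate(dexp1, log(2)), 1)
  dpw <- demography("piecewise", N = 1e3, x = 1e3, a = 0.25)  # x_N = 1
  expect_equal(cumulative_rate(dpw, 2), 1 + 1 / 0.25)
  expect_equal(cumulative_rate(dpw, 0.5), 0.5)
  # inverse round-trips
  for (dem in list(demography("constant", N = 10),
                   dexp1, dpw,
                   demography("exponential", N = 10, beta = 2.5))) {
    tt <- c(0.01, 0.3, 1.2, 4)
    expect_equal(skywis:::inverse_cumulative_rate(dem, cumulative_rate(dem, tt)), tt)
  }
  expect_error(cumulative_rate(dexp1, -1), "non-negative")
})

test_that("constant-size coalescence times are exponential at each level", {
  set.seed(41)
  dem <- demography("constant", N = 100)
  draws <- t(replicate(3000, sample_coalescence_times(4, dem)$times))
  for (k in 4:2) {
    p <- stats::ks.test(draws[, paste0("T", k)], "pexp", k * (k - 1) / 2)$p.value
    expect_gt(p, 0.005)
  }
  # accumulated-time moment identity: E[T_{n -> l}] = 2c / (n (n - c))
  set.seed(42)
  acc <- replicate(4000, sum(sample_coalescence_times(10, dem)$times[1:4]))
  z <- (mean(acc) - 2 * 4 / (10 * 6)) / (sd(acc) / sqrt(4000))
  expect_lt(abs(z), 4)
})

test_that("a piecewise demography with ratio 1 is the constant coalescent", {
  set.seed(7)
  a <- sample_coalescence_times(6, demography("piecewise", N = 50, x = 25, a = 1))
  set.seed(7)
  b <- sample_coalescence_times(6, demography("constant", N = 50))
  expect_identical(a$times, b$times)
})

test_that("strong exponential growth shortens the TMRCA stochastically", {
  set.seed(8)
  t_const <- replicate(400, sample_coalescence_times(8, demography("constant", N = 1))$tmrca)
  t_exp <- replicate(400, sample_coalescence_times(8, demography("exponential", N = 1, beta = 8))$tmrca)
  expect_lt(stats::wilcox.test(t_exp, t_const, alternative = "less")$p.value, 1e-6)
})

test_that("simulated datasets are reproducible and respect the mutation model", {
  dem <- demography("constant", N = 500)
  d1 <- simulate_dataset(n = 6, L = 40, dem = dem, theta = 2, seed = 33)
  d2 <- simulate_dataset(n = 6, L = 40, dem = dem, theta = 2, seed = 33)
  expect_identical(d1$alignment, d2$alignment)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_equal(length(d1$alignment), 6L)
  expect_true(all(nchar(d1$alignment) == 40L))
  expect_equal(ape::Ntip(d1$tree), 6L)
  # mu = 0: everything is the MRCA sequence
  d0 <- simulate_dataset(n = 5, L = 30, dem = dem, mu = 0, seed = 9)
  expect_equal(length(unique(d0$alignment)), 1L)
  # theta derived from mu: theta = 2 N mu L
  dmu <- simulate_dataset(n = 3, L = 100, dem = dem, mu = 1e-5, seed = 1)
  expect_equal(dmu$theta, 2 * 500 * 1e-5 * 100)
})

test_that("pairwise diversity matches the coalescent expectation", {
  set.seed(55)
  dem <- demography("constant", N = 100)
  th <- 1.5
  diffs <- replicate(1500, {
    d <- simulate_dataset(n = 2, L = 200, dem = dem, theta = th)
    a <- strsplit(d$alignment[[1]], "")[[1]]
    b <- strsplit(d$alignment[[2]], "")[[1]]
    sum(a != b)
  })
  # E[diffs] = theta for small theta/L (homoplasy negligible at theta/L << 1)
  z <- (mean(diffs) - th) / (sd(diffs) / sqrt(length(diffs)))
  expect_lt(abs(z), 4)
})

test_that("serial designs place tips at their sampling times", {
  dem <- demography("exponential", N = 1000, beta = 1)
  d <- simulate_dataset(L = 50, dem = dem, theta = 1,
                        sample_times = c(0, 0.5, 1),
                        sample_counts = c(4, 3, 2), seed = 12)
  expect_equal(length(d$alignment), 9L)
  expect_equal(sort(unique(d$tip_times)), c(0, 0.5, 1))
  expect_equal(as.vector(table(d$tip_times)), c(4L, 3L, 2L))
  expect_gt(d$tmrca, 1)
})
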