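test_that("epoch cutting points follow the logarithmic rule and end at the TMRCA", {
  expect_equal(round(durbin_li_cutpoints(1, 5), 4),
               c(0.0615, 0.1609, 0.3215, 0.5809, 1))
  expect_equal(round(durbin_li_cutpoints(0.5, 4), 4),
               c(0.0565, 0.1449, 0.2834, 0.5))
  expect_identical(durbin_li_cutpoints(0.7312, 1), 0.7312)
  for (tm in c(0.2, 1, 13.7))
    expect_identical(durbin_li_cutpoints(tm, 8)[8], tm)
  expect_error(durbin_li_cutpoints(0, 5), "positive")
})

test_that("epoch statistics conserve durations and coalescences", {
  h <- fake_history(
    n0 = 5,
    kinds = c("COALESCENCE", "MUTATION", "COALESCENCE", "COALESCENCE", "COALESCENCE"),
    waits = c(0.05, 0.05, 0.1, 0.3, 0.5),
    lineages_after = c(4L, 4L, 3L, 2L, 1L))
  cuts <- durbin_li_cutpoints(h$tmrca, 3)
  st <- epoch_statistics(h, cuts)
  expect_equal(sum(st$delta_t), h$tmrca)
  expect_equal(sum(st$c), 4L)
  expect_equal(st$d[1], 5L)
  expect_equal(st$d[-1], (st$d - st$c)[-nrow(st)])
  # n = 2, one epoch
  h2 <- fake_history(2, "COALESCENCE", 0.4, 1L)
  st2 <- epoch_statistics(h2, durbin_li_cutpoints(0.4, 1))
  expect_equal(st2$delta_t, 0.4)
  expect_equal(st2$d, 2L)
  expect_equal(st2$c, 1L)
})

test_that("a coalescence exactly on a boundary belongs to the more recent epoch", {
  h <- fake_history(3, c("COALESCENCE", "COALESCENCE"), c(0.25, 0.75),
                    lineages_after = c(2L, 1L))
  st <- epoch_statistics(h, c(0.25, 1))  # boundary exactly at the first event
  expect_equal(st$c, c(1L, 1L))
  expect_equal(st$d, c(3L, 2L))
})

test_that("the moment estimator evaluates Eq-of-moments arithmetic and guards c = 0", {
  expect_equal(epoch_ne(0.37, 2, 1), 0.37)      # consistent with T2 * choose(2,2)
  expect_equal(epoch_ne(0.1, 10, 9), 1 / 18)
  expect_equal(epoch_ne(c(0.1, 0.2), c(10, 4), c(9, 2)), c(1 / 18, 0.4))
  expect_error(epoch_ne(0.1, 5, 0), "merged")
  expect_error(epoch_ne(0.1, 5, 5), "merged")
})

test_that("empty epochs merge into their older neighbour preserving totals", {
  st <- data.frame(epoch = 1:4,
                   t_start = c(0, 0.1, 0.3, 0.6),
                   t_end = c(0.1, 0.3, 0.6, 1.0),
                   delta_t = c(0.1, 0.2, 0.3, 0.4),
                   d = c(5L, 3L, 3L, 2L),
                   c = c(2L, 0L, 1L, 1L))
  mg <- skywis:::merge_empty_epochs(st)
  expect_equal(nrow(mg), 3L)
  expect_equal(sum(mg$delta_t), 1.0)
  expect_equal(sum(mg$c), 4L)
  # the pooled epoch spans the emptied window and keeps its recent-edge count
  expect_equal(mg$t_start[2], 0.1)
  expect_equal(mg$t_end[2], 0.6)
  expect_equal(mg$d[2], 3L)
})

test_that("classical per-interval estimates are the T_k * choose(k,2) plug-in", {
  h <- fake_history(
    n0 = 4, kinds = rep("COALESCENCE", 3),
    waits = c(2 / (4 * 3), 2 / (3 * 2), 1),
    lineages_after = c(3L, 2L, 1L))
  ne <- classical_estimates(h)
  expect_equal(unname(ne["T4"]), 1)
  expect_equal(unname(ne["T3"]), 1)
  expect_equal(unname(ne["T2"]), 1)
})

test_that("pointwise combination reproduces the two-genealogy worked scheme", {
  # two step functions with three epochs each and known weights; the combined
  # curve must switch epoch indices at each genealogy's own cutting points and
  # renormalize once the shorter genealogy's TMRCA is passed
  s1 <- list(breaks = c(0, 0.2, 0.6, 1.2), values = c(10, 20, 30), tmrca = 1.2)
  s2 <- list(breaks = c(0, 0.1, 0.4, 0.8), values = c(1, 2, 3), tmrca = 0.8)
  w <- c(0.6, 0.4)
  expect_equal(pointwise_estimate(0.05, list(s1, s2), w), 0.6 * 10 + 0.4 * 1)
  expect_equal(pointwise_estimate(0.15, list(s1, s2), w), 0.6 * 10 + 0.4 * 2)
  expect_equal(pointwise_estimate(0.3, list(s1, s2), w), 0.6 * 20 + 0.4 * 2)
  expect_equal(pointwise_estimate(0.5, list(s1, s2), w), 0.6 * 20 + 0.4 * 3)
  expect_equal(pointwise_estimate(0.7, list(s1, s2), w), 0.6 * 30 + 0.4 * 3)
  # beyond TMRCA of genealogy 2 only genealogy 1 contributes
  expect_equal(pointwise_estimate(1.0, list(s1, s2), w), 30)
  expect_true(is.na(pointwise_estimate(1.3, list(s1, s2), w)))
  # a single genealogy yields its own step function
  expect_equal(pointwise_estimate(c(0.05, 0.3, 1.0), list(s1), 1), c(10, 20, 30))
})

test_that("uniform weights give the plain average of per-genealogy step functions", {
  m <- mutation_model(theta = 0, L = 1)
  cfg <- sample_config(rep("A", 6))
  ens <- sample_ensemble(cfg, m, J = 30, seed = 8)
  expect_equal(ens$normalized_weights, rep(1 / 30, 30))
  steps <- lapply(ens$histories, skywis:::history_step_function, n_cum = 3)
  tmin <- min(vapply(steps, function(s) s$tmrca, 0))
  tt <- seq(1e-4, tmin, length.out = 7)
  manual <- rowMeans(vapply(steps, function(s)
    s$values[findInterval(tt, s$breaks, left.open = TRUE, all.inside = TRUE)],
    numeric(7)))
  expect_equal(pointwise_estimate(tt, steps, ens$normalized_weights), manual)
})

test_that("the end-to-end curve behaves on a small dataset", {
  m <- mutation_model(theta = 0.5, L = 4)
  cfg <- sample_config(c(rep("ACGT", 4), "ACGA", "TCGT"))
  cv <- skywis_curve(cfg, m, J = 40, n_cum = 5, seed = 21, mu = 1e-6)
  expect_s3_class(cv, "skywis_curve")
  expect_true(all(cv$ne > 0))
  expect_true(all(diff(cv$time_start) > 0))
  expect_equal(cv$time_end[-nrow(cv)], cv$time_start[-1])
  N <- 0.5 / (2 * 1e-6 * 4)
  expect_equal(cv$ne_gen, cv$ne * N)
  expect_equal(attr(cv, "N_scale"), N)
  # time averaging over the full support is a duration-weighted mean
  expect_equal(time_averaged_ne(cv),
               sum(cv$ne * (cv$time_end - cv$time_start)) /
                 sum(cv$time_end - cv$time_start))
  # J = 1: the curve is that genealogy's own (merged-epoch) step function
  cv1 <- skywis_curve(cfg, m, J = 1, n_cum = 4, seed = 3, truncate = NULL)
  ens1 <- sample_ensemble(cfg, m, J = 1, seed = 3)
  step1 <- skywis:::history_step_function(ens1$histories[[1]], n_cum = 4)
  got <- pointwise_estimate((cv1$time_start + cv1$time_end) / 2, list(step1), 1)
  expect_equal(cv1$ne, got)
})
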