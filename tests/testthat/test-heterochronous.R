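test_that("sampling schedules validate their structure", {
  expect_error(sampling_schedule(c(0.5, 1), list("A", "C")), "must be 0")
  expect_error(sampling_schedule(c(0, 0), list("A", "C")), "increasing")
  expect_error(sampling_schedule(c(0, 1), list("AC", "A")), "length")
  sch <- sampling_schedule(c(0, 0.5, 1), list(c("AC", "AC"), "GT", "AC"))
  expect_equal(sch$counts, c(2L, 1L, 1L))
})

test_that("occupancy probability is the exponential survival of the event clock", {
  expect_equal(occupancy_probability(2, 0, 0), 1)
  expect_equal(occupancy_probability(2, 0, log(2)), 0.5)
  expect_equal(occupancy_probability(3, 2, 0.4), exp(-total_event_rate(3, 2) * 0.4))
  d <- seq(0, 3, by = 0.5)
  expect_true(all(diff(occupancy_probability(4, 1, d)) < 0))
  expect_true(all(occupancy_probability(5, 1, 1) < occupancy_probability(4, 1, 1)))
  expect_error(occupancy_probability(2, 1, -0.1), "non-negative")
  # additions in the forward chain contribute the same survival factor
  m <- mutation_model(theta = 2, L = 1)
  cfg <- sample_config(c("A", "A", "C"))
  expect_equal(
    forward_transition_prob(cfg, list(kind = "SAMPLE_ADDITION"), m, gap = 0.3),
    occupancy_probability(3, 2, 0.3))
  expect_equal(
    forward_transition_prob(cfg, list(kind = "SAMPLE_ADDITION"), m, gap = 0), 1)
})

test_that("a single sampling time reproduces the homochronous sampler exactly", {
  m <- mutation_model(theta = 1.2, L = 2)
  seqs <- c("AC", "AC", "GT")
  sch <- sampling_schedule(0, list(seqs))
  set.seed(31)
  h_het <- sample_genealogy_hetero(sch, m)
  set.seed(31)
  h_hom <- sample_genealogy(sample_config(seqs), m)
  expect_identical(h_het$events, h_hom$events)
  expect_identical(h_het$log_forward, h_hom$log_forward)
  expect_identical(h_het$log_proposal, h_hom$log_proposal)
})

test_that("lineages jump by the scheduled counts exactly at the sampling times", {
  m <- mutation_model(theta = 0.8, L = 2)
  sch <- sampling_schedule(c(0, 0.5, 1),
                           list(rep("AC", 5), rep("AC", 3), rep("GT", 2)))
  set.seed(13)
  for (i in 1:10) {
    h <- sample_genealogy_hetero(sch, m)
    ev <- h$events
    adds <- ev[ev$kind == "SAMPLE_ADDITION", ]
    expect_equal(adds$abs_time, c(0.5, 1))
    before <- c(h$n0, head(ev$lineages_after, -1L))[ev$kind == "SAMPLE_ADDITION"]
    expect_equal(adds$lineages_after - before, c(3L, 2L))
    expect_equal(sum(ev$kind == "COALESCENCE"), 10 - 1L)
    expect_equal(ev$lineages_after[nrow(ev)], 1L)
    expect_gt(h$tmrca, 1)
    expect_true(is.finite(raw_weight(h)))
  }
})

test_that("a lone lineage with theta = 0 waits deterministically for the next sample", {
  m <- mutation_model(theta = 0, L = 1)
  sch <- sampling_schedule(c(0, 2), list(c("A", "A"), c("A", "A")))
  set.seed(2)
  h <- sample_genealogy_hetero(sch, m)
  ev <- h$events
  add <- which(ev$kind == "SAMPLE_ADDITION")
  # if the first pair coalesced before t = 2, the survivor waits at zero rate
  if (add > 1L) expect_equal(ev$abs_time[add], 2)
  expect_equal(sum(ev$kind == "COALESCENCE"), 3L)
})

test_that("per-interval cutting points land exactly on the sampling times", {
  expect_equal(hetero_cutpoints(numeric(0), 1, 5), durbin_li_cutpoints(1, 5))
  ts <- c(0.5, 1)
  cuts <- hetero_cutpoints(ts, 2.5, 3)
  expect_true(all(diff(cuts) > 0))
  expect_true(all(vapply(ts, function(x) any(abs(cuts - x) < 1e-12), TRUE)))
  expect_identical(cuts[length(cuts)], 2.5)
  # the uncorrected published rule overshoots interior intervals
  cuts_printed <- hetero_cutpoints(ts, 2.5, 3, printed_form = TRUE)
  # last cutting point of interval 2 under the printed rule: t1 + t2 = 1.5
  expect_equal(cuts_printed[6], 0.5 + 1)
  expect_error(hetero_cutpoints(c(0.5, 1), 0.9, 3), "older")
})

test_that("smoothing replaces only the first epoch older than each sampling time", {
  cv <- data.frame(time_start = c(0, 0.3, 0.5, 0.9),
                   time_end = c(0.3, 0.5, 0.9, 1.4),
                   ne = c(2, 2, 7, 3))
  out <- smooth_at_sampling_times(cv, 0.5)
  expect_equal(out$ne, c(2, 2, 2, 3))
  # a constant curve is unchanged, and no sampling times is the identity
  flat <- data.frame(time_start = c(0, 1), time_end = c(1, 2), ne = c(5, 5))
  expect_equal(smooth_at_sampling_times(flat, 1)$ne, c(5, 5))
  expect_equal(smooth_at_sampling_times(cv, numeric(0)), cv)
})

test_that("serial additions merge into existing types correctly", {
  m <- mutation_model(theta = 0, L = 1)
  sch <- sampling_schedule(c(0, 0.4), list(c("A", "A", "A"), c("A", "A")))
  set.seed(17)
  h <- sample_genealogy_hetero(sch, m)
  expect_equal(sum(h$events$kind == "COALESCENCE"), 4L)
  expect_equal(h$n_total, 5L)
  # with one type and theta = 0 every weight factor is forced
  expect_equal(raw_weight(h), 0)
})
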