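test_that("forward transition probabilities match the embedded chain of the coalescent", {
  m <- mutation_model(theta = 1, L = 1)
  h2 <- sample_config(c("A", "A"))
  expect_equal(
    forward_transition_prob(h2, list(kind = "COALESCENCE", subject = "A", result = "A"), m),
    0.5)
  # with theta = 0 no mutation move has positive probability
  m0 <- mutation_model(theta = 0, L = 1)
  expect_equal(
    forward_transition_prob(h2, list(kind = "MUTATION", subject = "A", result = "C"), m0),
    0)
  # from a single-type configuration the chain's moves are exhaustive
  p_coal <- forward_transition_prob(h2, list(kind = "COALESCENCE", subject = "A", result = "A"), m)
  p_mut <- sum(vapply(one_step_neighbors(m, "A"), function(b)
    forward_transition_prob(h2, list(kind = "MUTATION", subject = "A", result = b), m), 0))
  expect_equal(p_coal + p_mut, 1)
})

test_that("raw weight is zero for the forced pure-coalescence history", {
  m <- mutation_model(theta = 0, L = 1)
  h <- sample_genealogy(sample_config(c("A", "A")), m)
  expect_equal(raw_weight(h), 0)
})

test_that("weight normalization is a shift-invariant softmax", {
  expect_equal(normalize_weights(log(c(1, 1, 1, 1))), rep(0.25, 4))
  expect_equal(normalize_weights(log(c(1, 3))), c(0.25, 0.75))
  lw <- c(-3.2, -1.1, -7.9)
  expect_equal(normalize_weights(lw), normalize_weights(lw + 123.4))
  expect_equal(sum(normalize_weights(rnorm(50))), 1, tolerance = 1e-12)
  expect_error(normalize_weights(c(-Inf, -Inf)), "-Inf")
})

test_that("effective sample size ranges between 1 and J", {
  expect_equal(effective_sample_size(rep(1 / 8, 8)), 8)
  expect_equal(effective_sample_size(c(1, 0, 0)), 1)
  set.seed(2)
  for (i in 1:5) {
    w <- normalize_weights(rnorm(20))
    ess <- effective_sample_size(w)
    expect_gte(ess, 1)
    expect_lte(ess, 20)
  }
})

test_that("recursion oracle reproduces closed-form pair probabilities", {
  # independent closed form: Exp(1) coalescence + geometric number of JC69
  # events, via the eigenvalues of the event matrix (helper-fixtures.R)
  for (th in c(0.3, 0.7, 1, 2)) {
    m <- mutation_model(theta = th, L = 1)
    expect_equal(gt_recursion_oracle(sample_config(c("A", "A")), m),
                 pair_prob_L1(th, identical = TRUE), tolerance = 1e-12)
    expect_equal(gt_recursion_oracle(sample_config(c("A", "C")), m),
                 pair_prob_L1(th, identical = FALSE), tolerance = 1e-12)
  }
  m0 <- mutation_model(theta = 0, L = 1)
  expect_equal(gt_recursion_oracle(sample_config("G"), m0), 1 / 4)
  expect_equal(gt_recursion_oracle(sample_config(c("A", "A")), m0), 1 / 4)
  expect_equal(gt_recursion_oracle(sample_config(c("A", "C")), m0), 0)
})

test_that("likelihood estimate and ensemble bookkeeping are consistent", {
  m <- mutation_model(theta = 0.5, L = 1)
  cfg <- sample_config(c("A", "A", "C"))
  ens <- sample_ensemble(cfg, m, J = 200, seed = 99)
  expect_length(ens$histories, 200)
  expect_equal(sum(ens$normalized_weights), 1, tolerance = 1e-12)
  expect_true(all(ens$normalized_weights >= 0))
  # J = 1: the estimate is the single raw weight
  e1 <- sample_ensemble(cfg, m, J = 1, seed = 5)
  expect_equal(likelihood_estimate(e1), exp(e1$log_raw_weights))
  expect_equal(likelihood_estimate(e1, absolute = TRUE, model = m),
               exp(e1$log_raw_weights) / 4)
  # ensembles are reproducible from the seed
  ens2 <- sample_ensemble(cfg, m, J = 200, seed = 99)
  expect_identical(ens$log_raw_weights, ens2$log_raw_weights)
})

test_that("identical sequences with theta = 0 give exactly uniform weights", {
  m <- mutation_model(theta = 0, L = 2)
  ens <- sample_ensemble(sample_config(rep("AG", 5)), m, J = 50, seed = 1)
  expect_true(all(ens$log_raw_weights == ens$log_raw_weights[1]))
  expect_equal(ens$normalized_weights, rep(1 / 50, 50))
})
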