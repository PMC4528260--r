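# Shared helpers for the test suite. All fixtures are built in code.

# Closed-form ordered stationary sampling probability for a PAIR of single-site
# JC69 sequences: the pair coalesces after Exp(1); the number of mutation
# events separating them is Geometric(1/(1+theta)); eigen-decomposition of the
# JC69 event matrix gives (P^m)_aa = 1/4 + (3/4)(-1/3)^m. Independent of the
# package's recursion oracle.
pair_prob_L1 <- function(theta, identical) {
  g <- 1 / (1 + 4 * theta / 3)
  if (identical) (1 / 4) * (1 / 4 + (3 / 4) * g)
  else (1 / 4) * (1 / 4 - (1 / 4) * g)
}

# Build a genealogy_history object by hand from a compact event description
# (used to test bookkeeping independently of the sampler).
fake_history <- function(n0, kinds, waits, lineages_after,
                         subjects = rep("A", length(kinds)),
                         results = subjects) {
  structure(
    list(events = data.frame(kind = kinds, subject = subjects, result = results,
                             waiting_time = waits, abs_time = cumsum(waits),
                             lineages_after = lineages_after,
                             stringsAsFactors = FALSE),
         log_forward = 0, log_proposal = 0,
         tmrca = sum(waits), n0 = n0, n_total = n0,
         initial_config = NULL, schedule_times = 0),
    class = "genealogy_history")
}
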