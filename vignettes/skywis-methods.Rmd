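---
title: "Estimating effective population size through time by importance sampling over genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effective population size through time by importance sampling over genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(skywis)
```

## The problem

The genealogy of a sample of homologous DNA sequences carries the signature of
the population's demographic history: in an expanding population, lineages
coalesce faster as we move into the past (where the population was small), so
coalescent intervals shorten. Skyline-type methods invert this logic and read
a piecewise-constant effective population size $N_e(t)$ off the coalescence
times. Classical skyline plots do this from a *single* estimated genealogy,
inheriting both its phylogenetic error and its coalescent noise.

This package instead samples a large number $J$ of genealogical
reconstructions directly from the sequence data, weights each one by how well
it explains the data, and estimates $N_e(t)$ as the weighted average of the
per-genealogy skyline estimates. The three ingredients are:

1. a backward-in-time **proposal distribution** over genealogies
   (the Stephens–Donnelly conditional-sampling construction),
2. **importance weights** correcting the proposal to the constant-size
   coalescent likelihood,
3. a **per-epoch method-of-moments estimator** of $N_e$ combined across
   genealogies on common time intervals.

Time is measured in units of $N$ generations throughout (the coalescent
scale on which a pair of lineages coalesces at rate 1), with $\theta = 2N\mu$
the scaled mutation rate per sequence. Conversions to generations use
$N = \theta / (2 \mu L)$ when a per-site per-generation rate $\mu$ is
supplied.

## Proposing genealogies backward from the data

A state is a *sample configuration*: the multiset of distinct sequence types
with multiplicities. With $k$ lineages present, the time to the next event
(coalescence or mutation) is exponential with rate $k(k-1+\theta)/2$. The
embedded chain proposes each event in two stages: a lineage of type $\alpha$
is chosen uniformly; then with
$x_1 = \theta \sum_\beta \hat\pi(\beta \mid H - \alpha) P_{\beta\alpha}$
(the sum running over the $3L$ one-step mutational neighbours of $\alpha$) and
$x_2 = n(\alpha) - 1$, a mutation is proposed with probability
$x_1/(x_1+x_2)$ — the target $\beta$ drawn proportional to
$\hat\pi(\beta \mid H-\alpha) P_{\beta\alpha}$ — and a coalescence of two
$\alpha$ lineages otherwise. The chain stops at the most recent common
ancestor.

Here $\hat\pi(\beta \mid H)$ is the Stephens–Donnelly approximate conditional
sampling probability: the chance that one more sequence drawn from the
population is of type $\beta$, approximated by picking a random member of $H$
and mutating it a geometric number of times. Two evaluation modes are
provided:

* an **exact** dense evaluation of the geometric series over the full $4^L$
  type space, feasible for $L \le 5$ and used by the tests and oracles;
* a **per-site factorized** evaluation for real alignments, applying the
  geometric chain independently at each site with rate $\theta_s = \theta/L$:
  $\hat\pi(\beta\mid H) = \sum_\alpha \frac{n(\alpha)}{n} \prod_s
  M[\alpha_s, \beta_s]$, with
  $M = \frac{n}{n+\theta_s}\bigl(I - \tfrac{\theta_s}{n+\theta_s}P\bigr)^{-1}$.

The factorization is exact at $L = 1$ (asserted by the tests) and elsewhere
it is an approximation *inside the proposal only*: importance sampling
remains unbiased for any strictly positive proposal, because the weights use
the proposal probabilities actually realized, not the intended ideal. All
weight arithmetic is in log space; a reconstruction of a 50-sequence
alignment involves hundreds of events whose probability products underflow
double precision otherwise.

Design choices worth stating explicitly:

* **Mutation events always change the site** (JC69 event matrix with zero
  diagonal, off-diagonal $1/3$). Silent events would only rescale $\theta$.
* The two-stage draw is *not* the same as normalizing the ideal backward
  kernel jointly over $(\alpha, \text{event})$ — the normalizer depends on
  $\alpha$. We keep the two-stage scheme and compute the proposal probability
  of the path as sampled, which keeps the weights valid regardless.
* **Waiting times cancel** between target and proposal (both exponential at
  the same total rate) and are excluded from the weights; they do enter the
  epoch estimates.
* Each genealogy runs on its own RNG substream derived once from the master
  seed, so ensembles are reproducible and order-independent.

## Importance weights

The weight of genealogy $G^{(j)}$ is $W^{(j)} = P(G^{(j)}\mid\theta) /
Q(G^{(j)})$, with both terms products of embedded-chain move probabilities.
The forward (target) factors are those of the constant-size coalescent with
mutation: for a move acting on a configuration with $n$ sequences,

$$
p(\text{coalescence of } \alpha) = \frac{n(\alpha)\,(n(\alpha)-1)}{n\,(n-1+\theta)},
\qquad
p(\text{mutation } \beta\to\alpha) = \frac{n(\alpha)}{n}\,
  \frac{\theta}{n-1+\theta}\,P_{\beta\alpha}.
$$

The coalescence numerator $n(\alpha)(n(\alpha)-1)$ — rather than
$n(\alpha)(n-1)$ — matters: with these factors, the sum over all histories of
the forward products, multiplied by the uniform stationary probability
$4^{-L}$ of the MRCA type, equals the *ordered* stationary sampling
probability of the data exactly. We verified this identity by solving the
history-sum linear system and an independently derived configuration
recursion to ten digits for all single-site configurations up to $n = 5$
(the recursion is exposed as `gt_recursion_oracle()` and doubles as the
correctness oracle for the sampler: the mean raw weight times $4^{-L}$ must
match it). A pleasant by-product of the construction: at $L = 1$ the
factorized $\hat\pi$ is exact, the proposal becomes essentially optimal, and
the raw weights are constant across histories — the estimator is then exact
up to floating-point noise.

Normalized weights $w^{(j)} = W^{(j)}/\sum_k W^{(k)}$ are computed by
max-shifted exponentiation, and the effective sample size
$\mathrm{ESS} = 1/\sum_j (w^{(j)})^2$ is reported with every run.

## Epochs and the weighted curve

Coalescences crowd near the present, so per-interval estimates there are
noisy. Each genealogy's time axis $(0, \mathrm{TMRCA}]$ is cut into
$n_{cum}$ logarithmically growing epochs,

$$
t_{cut,b} = 0.1\exp\Bigl\{\frac{b}{n_{cum}}\log(1 + 10\,\mathrm{TMRCA})\Bigr\} - 0.1 ,
$$

with the last cutting point exactly at the TMRCA. Within an epoch of length
$\Delta t_b$, with $d_b$ lineages at its recent edge and $c_b$ coalescences
inside, the moment estimate is
$\hat N_{e,b} = \Delta t_b\, d_b (d_b - c_b) / (2 c_b)$. Epochs are
half-open $(t_{b-1}, t_b]$, so boundary coalescences resolve
deterministically. Epochs with $c_b = 0$ are merged into their older
neighbour (the pooled epoch keeps the largest lineage count among the pooled
windows — the recent edge's count for homochronous data), which preserves
$\sum_b \Delta t_b = \mathrm{TMRCA}$ and $\sum_b c_b = n - 1$.

The combined curve evaluates, at every time $t$, the weighted average of the
per-genealogy step functions over the genealogies whose TMRCA is older than
$t$, renormalizing the weights among the survivors. Evaluation is on the
union of all cutting points (exact) or on a uniform grid of 512 points when
the union exceeds $10^5$ breakpoints. By default the curve is truncated at
the weighted 95th-percentile TMRCA so a single long genealogy does not
stretch the axis; `truncate = NULL` disables this.

### A caveat the tests quantify: small-count ratio bias

$\hat N_{e,b}$ has the random count $c_b$ in its denominator, and the epoch
windows are fixed by the cutting-point rule rather than by the coalescences
themselves. On pure constant-size coalescent trees (no mutation, times fed
directly to the epoch machinery) the per-epoch mean of $\hat N_{e,b}$ is
**not** 1: across 5000 trees we measure upward bias from roughly $+15\%$ in
epochs with $E[c_b] \approx 7$ to $+50$–$70\%$ where $E[c_b] \approx 1$–$2$
— the familiar $E[1/c] > 1/E[c]$ effect, vanishing only as $c_b$ grows or
when a single epoch spans the whole tree (where the estimator is exactly
unbiased, as the tests assert). Consequences for whole-curve summaries are
visible in the constant-size validation scenario: time-averaged estimates
tend to sit above the true size, increasingly so toward the TMRCA where
epochs hold few coalescences. We implement the estimator as defined and
report this property rather than patching it (e.g. by conditional debiasing),
since the package's purpose is the method as stated; the acceptance tests
record the measured behaviour.

A second, separate effect pushes the same way on diverse data: with many
distinct types the proposal must undo every mutation before lineages can
merge, raw weights become extremely variable (ESS near 1), and the curve is
effectively that of the best-weighted genealogy, whose deep coalescence
times still overshoot. This is intrinsic to plain importance sampling with
this proposal at large $\theta$; the weights *do* prefer shorter, more
plausible genealogies (the correlation between log-weight and TMRCA is
negative), which tempers but does not remove the overshoot.

## Serially sampled sequences

For heterochronous data the sampler adds the scheduled sequence sets when the
backward simulation reaches their sampling times: a proposed event that would
cross $t_s$ is discarded and time is truncated to $t_s$ (exact, by
memorylessness of the exponential clock), the no-event survival factor
$\exp(-\lambda\Delta)$ over the closing gap entering both the target and the
proposal accumulators with $\lambda$ computed from the lineage count actually
alive during the gap — the factors cancel in the weight, as they must, since
the truncation construction is shared. A lone surviving lineage can mutate
(rate $\theta/2$) while waiting for the next sample; its conditional type
distribution falls back to the uniform stationary law.

Epoch cutting points are laid out per sampling interval, with the rule's span
taken as $t_s - t_{s-1}$ so that each interval's last cutting point lands
exactly on $t_s$. The published form of this rule uses $t_s$ for the span
and therefore overshoots any interior interval (its final cutting point lands
at $t_{s-1} + t_s$, and the sequence is not even monotone across intervals);
we treat that as a typographical defect, and keep the uncorrected variant
available behind `printed_form = TRUE` for comparison only. The oldest
interval's epoch count is the base count scaled by its relative span
(minimum 2). Because adding sequences at $t_s$ creates an artificial
discontinuity, the value on the first epoch older than $t_s$ is replaced by
the value just more recent than $t_s$ (`smooth_at_sampling_times()`).

## The simulator

`simulate_dataset()` provides the validation fixtures: coalescence times are
drawn by closed-form inversion of the cumulative rate
$\Lambda(t) = \int_0^t du/\nu(u)$ for constant, piecewise-constant and
exponential $N_e(t)$ (solving $\Lambda(v + T_k) = \Lambda(v) + 2E/(k(k-1))$,
$E \sim \mathrm{Exp}(1)$), topologies by uniform pair merges, and sequences
by dropping $\mathrm{Poisson}(\tfrac{\theta}{2}\times\text{branch length})$
JC69 events per branch from a uniform MRCA sequence. Serial designs insert
tips at their sampling times. The tests verify the time-change against
closed-form survival functions (Kolmogorov–Smirnov), the accumulated-time
moment identity $E[T_{n\to\ell}] = 2c/(n(n-c))$, the equivalence of a
ratio-1 piecewise model with the constant coalescent, and the pairwise
diversity $E[\text{differences}] \approx \theta$ for $\theta/L \ll 1$.

What the simulator does *not* emulate about real data: recombination, rate
heterogeneity across sites or lineages, selection, population structure,
indels, and sequencing error. Passing validation on these fixtures therefore
demonstrates internal consistency of the machinery under the model's own
assumptions, not robustness to their violation.

## Validation scenarios and problem sizes

The package's validation suite exercises four demographic scenarios chosen to
mirror the standard test cases for skyline methods, at problem sizes chosen
to keep the full suite to a few minutes of CPU:

* **constant size**: 50 sequences, $N = 2000$, $\theta = 8$ held fixed with
  the alignment length reduced to $L = 500$ (per-site rate rescaled
  accordingly), $J = 1000$, $n_{cum} = 49$;
* **piecewise constant**: 25 sequences, $N = 10^4$ dropping to $aN = 2500$
  beyond $x = 5000$ generations ($a = 0.25$), $\theta = 10$ (the published
  description of this scenario gives a rate whose unit is ambiguous; we read
  it per sequence, which gives a diversity in the plausible range),
  $n_{cum} = 4$ — the reconstruction should jump near $x$;
* **exponential growth** $N_e(t) = N e^{-\beta t}$, $\beta = 1$ per $N$
  generations, $\theta = 1$, $L = 1000$ — the curve should decrease from
  present to past;
* the same exponential scenario with **serial sampling** (25 sequences at
  $t=0$, 15 at $t=0.5$, 10 at $t=1$ in $N$-generation units) — the decrease
  should persist also in the oldest epochs, where the added sequences supply
  coalescent information the homochronous design lacks.

Qualitative claims (a jump near the change point, monotone decrease) are
asserted as sign tests over ten replicate simulations rather than by
comparing to digitized figures.

## Numerical conventions

* $\hat\pi$ is clamped below at $10^{-300}$ before logs in the exported
  evaluator; the sampler itself works on max-shifted log scales and never
  forms the raw products.
* The branch probability $x_1/(x_1+x_2)$ is computed from $\log x_1$ with
  `log1p` guards, so astronomically small $x_1$ (long sequences) degrades
  gracefully to a forced coalescence instead of NaN.
* Ties of a proposed event time with a sampling time break toward truncation.
* The per-site matrix $M$ is memoized per lineage count within a model
  object.
* `sample.int(..., prob =)` handles unnormalized scores; all categorical
  draws use it directly.

## Known limitations

* No confidence or credible bands — the method provides point curves.
* No recombination, no substitution models beyond JC69 (the per-site event
  matrix is pluggable in the data structures, but only JC69 ships), no rate
  heterogeneity, single locus.
* The ESS of the weighted ensemble collapses for large $\theta$ and long
  alignments; the reported ESS should always be inspected before trusting
  fine structure in the curve.
* The per-epoch moment estimator carries the small-count upward bias
  quantified above.

## A worked miniature

```{r example}
dem <- demography("exponential", N = 1e4, beta = 1)
d <- simulate_dataset(n = 12, L = 200, dem = dem, theta = 1, seed = 42)
cfg <- sample_config(unname(d$alignment))
cfg
model <- mutation_model(theta = 1, L = 200)
curve <- skywis_curve(cfg, model, J = 100, n_cum = 6, mu = d$mu, seed = 7)
curve
head(as.data.frame(curve))
```

The `ne` column is in units of the present size $N$; `ne_gen` is in
individuals via $N = \theta/(2\mu L)$. For an expanding population the values
should drift downward with `time_start`.
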