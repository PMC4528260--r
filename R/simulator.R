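# Coalescent simulator under time-varying Ne(t): genealogy times by inversion
# of the cumulative coalescent rate, random topology, JC69 sequences dropped
# along branches. Provides the validation fixtures for the estimator.

#' Specify a demographic history Ne(t)
#'
#' Supported forms, with time \eqn{t} measured from the present to the past:
#' \itemize{
#'   \item \code{constant}: \eqn{N_e(t) = N};
#'   \item \code{piecewise}: \eqn{N_e(t) = N} for \eqn{t < x} and \eqn{a N}
#'     for \eqn{t \ge x}, with the change time \code{x} given in generations;
#'   \item \code{exponential}: \eqn{N_e(t) = N \exp(-\beta t)} with the decay
#'     rate \eqn{\beta} per \eqn{N} generations (expansion toward the present).
#' }
#' Internally all times are in units of \eqn{N} generations
#' (\eqn{\tilde t = t/N}) and \eqn{\nu(t) = N_e(t)/N}.
#'
#' @param form \code{"constant"}, \code{"piecewise"} or \code{"exponential"}.
#' @param N Present-day effective size \eqn{N = N_e(0)} (haploid), in
#'   individuals; sets the generations scale.
#' @param x Change time in generations (piecewise only).
#' @param a Ancestral/current size ratio (piecewise only), \eqn{a > 0}.
#' @param beta Exponential decay rate per N generations.
#' @return Object of class \code{demography}.
#' @export
#' @examples
#' demography("piecewise", N = 1e4, x = 5000, a = 0.25)
demography <- function(form = c("constant", "piecewise", "exponential"),
                       N, x = NULL, a = NULL, beta = NULL) {
  form <- match.arg(form)
  stopifnot(is.numeric(N), N > 0)
  if (form == "piecewise") {
    if (is.null(x) || is.null(a) || x <= 0 || a <= 0)
      stop("piecewise demography needs change time x > 0 (generations) and ratio a > 0")
  }
  if (form == "exponential") {
    if (is.null(beta)) stop("exponential demography needs a rate beta")
  }
  structure(list(form = form, N = N, x = x, a = a, beta = beta,
                 x_N = if (!is.null(x)) x / N else NULL),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  msg <- switch(x$form,
    constant = sprintf("constant Ne = %g", x$N),
    piecewise = sprintf("piecewise Ne: %g for t < %g generations, then %g",
                        x$N, x$x, x$a * x$N),
    exponential = sprintf("exponential Ne(t) = %g * exp(-%g t) (t in N generations)",
                          x$N, x$beta))
  cat("Demography:", msg, "\n")
  invisible(x)
}

#' Cumulative coalescent rate
#'
#' \eqn{\Lambda(t) = \int_0^t 1/\nu(u)\, du} with \eqn{\nu(t) = N_e(t)/N},
#' in N-generation units. Closed forms: constant \eqn{t}; exponential
#' \eqn{(e^{\beta t} - 1)/\beta}; piecewise \eqn{t} below the change point
#' \eqn{\tilde x} and \eqn{\tilde x + (t - \tilde x)/a} above.
#'
#' @param dem A [demography()].
#' @param t Time(s) from the present, in N-generation units, \eqn{t \ge 0}.
#' @return \eqn{\Lambda(t)}.
#' @export
cumulative_rate <- function(dem, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  switch(dem$form,
    constant = t,
    exponential = if (dem$beta == 0) t else (exp(dem$beta * t) - 1) / dem$beta,
    piecewise = ifelse(t < dem$x_N, t, dem$x_N + (t - dem$x_N) / dem$a))
}

# Closed-form inverse of the cumulative rate.
inverse_cumulative_rate <- function(dem, u) {
  switch(dem$form,
    constant = u,
    exponential = if (dem$beta == 0) u else log1p(dem$beta * u) / dem$beta,
    piecewise = ifelse(u < dem$x_N, u, dem$x_N + (u - dem$x_N) * dem$a))
}

#' Simulate coalescence times under a variable population size
#'
#' Inverse-transform sampling of the level-by-level coalescence times: with
#' \eqn{k} lineages and accumulated time \eqn{v}, draw \eqn{E \sim Exp(1)} and
#' solve \eqn{\Lambda(v + T_k) = \Lambda(v) + 2E/(k(k-1))} in closed form.
#' Under a constant demography this reduces to independent
#' \eqn{T_k \sim Exp(k(k-1)/2)}.
#'
#' @param n Sample size, \eqn{n \ge 2}.
#' @param dem A [demography()].
#' @return List with \code{times} (named \eqn{T_n, \dots, T_2}, N-generation
#'   units), \code{v} (accumulated event times) and \code{tmrca}.
#' @export
sample_coalescence_times <- function(n, dem) {
  stopifnot(n >= 2)
  v <- 0
  tk <- numeric(n - 1L)
  vk <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    k <- n - i + 1L
    e <- stats::rexp(1)
    u <- cumulative_rate(dem, v) + 2 * e / (k * (k - 1))
    v_new <- inverse_cumulative_rate(dem, u)
    tk[i] <- v_new - v
    vk[i] <- v_new
    v <- v_new
  }
  list(times = stats::setNames(tk, paste0("T", n:2)), v = vk, tmrca = v)
}

# Simulate a genealogy (topology + times) under `dem`, possibly with tips
# added at later sampling times. `tip_times`/`tip_counts` describe the serial
# design (first time must be 0). Returns an ape "phylo" with branch lengths
# in N-generation units, plus node depths.
simulate_genealogy_tree <- function(tip_counts, tip_times, dem) {
  n_total <- sum(tip_counts)
  # node bookkeeping: tips 1..n_total (in sampling-time order), internals after
  tip_time_per_tip <- rep(tip_times, tip_counts)
  node_time <- c(tip_time_per_tip, rep(NA_real_, n_total - 1L))
  next_internal <- n_total + 1L
  edge <- matrix(0L, 2L * (n_total - 1L), 2L)
  edge_len <- numeric(2L * (n_total - 1L))
  n_edge <- 0L
  active <- which(tip_time_per_tip == 0)
  pending <- which(tip_time_per_tip > 0)
  t <- 0
  repeat {
    k <- length(active)
    if (k <= 1L && length(pending) == 0L) break
    t_next_sample <- if (length(pending)) min(tip_time_per_tip[pending]) else Inf
    t_cand <- if (k >= 2L) {
      e <- stats::rexp(1)
      inverse_cumulative_rate(dem, cumulative_rate(dem, t) + 2 * e / (k * (k - 1)))
    } else Inf
    if (t_cand >= t_next_sample) {
      newly <- pending[abs(tip_time_per_tip[pending] - t_next_sample) < 1e-12]
      active <- c(active, newly)
      pending <- setdiff(pending, newly)
      t <- t_next_sample
    } else {
      pair <- sample(active, 2L)
      parent <- next_internal
      next_internal <- next_internal + 1L
      node_time[parent] <- t_cand
      for (ch in pair) {
        n_edge <- n_edge + 1L
        edge[n_edge, ] <- c(parent, ch)
        edge_len[n_edge] <- t_cand - node_time[ch]
      }
      active <- c(setdiff(active, pair), parent)
      t <- t_cand
    }
  }
  # internals were numbered in coalescence order (root created last); remap to
  # the ape convention root = n_total + 1 (old id j -> 3*n_total - j)
  remap <- function(v) ifelse(v > n_total, 3L * n_total - v, v)
  edge <- matrix(remap(edge), ncol = 2L)
  nt <- node_time
  nt[remap((n_total + 1L):(2L * n_total - 1L))] <-
    node_time[(n_total + 1L):(2L * n_total - 1L)]
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = paste0("s", seq_len(n_total)),
                         Nnode = n_total - 1L),
                    class = "phylo")
  list(tree = tree, node_time = nt, tmrca = t,
       tip_times = tip_time_per_tip)
}

# Drop JC69 mutations along the branches of a simulated genealogy:
# Poisson(theta/2 * branch length) events per lineage, uniform site, 1/3 base
# change; the MRCA sequence is uniform. Returns the tip sequences.
simulate_sequences_on_tree <- function(sim_tree, theta, L,
                                       site_matrix = jc69_site_matrix()) {
  tree <- sim_tree$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  # edges were recorded parent-first in order of coalescence (increasing
  # height), so traversing them in reverse visits every parent after it got
  # its sequence
  for (i in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[i, 1L]
    child <- tree$edge[i, 2L]
    s <- seqs[[parent]]
    m <- stats::rpois(1L, theta / 2 * tree$edge.length[i])
    if (m > 0) for (j in seq_len(m)) {
      site <- sample.int(L, 1L)
      s[site] <- sample.int(4L, 1L, prob = site_matrix[s[site], ])
    }
    seqs[[child]] <- s
  }
  vapply(seq_len(n_tip), function(i) decode_sequence(seqs[[i]]), "")
}

#' Simulate an alignment under a demographic scenario
#'
#' Simulates a coalescent genealogy under the demography (by closed-form
#' inversion of the cumulative rate), then drops JC69 mutations along its
#' branches (rate \eqn{\theta/2} per lineage per unit of N generations,
#' uniform site, equal base changes) from a uniform MRCA sequence.
#'
#' Supply either the per-site per-generation mutation rate \code{mu} (then
#' \eqn{\theta = 2 N \mu L}) or \code{theta} directly.
#'
#' @param n Number of sequences sampled at present (homochronous), or NULL
#'   when \code{sample_times}/\code{sample_counts} describe a serial design.
#' @param L Sequence length (sites).
#' @param dem A [demography()].
#' @param mu Per-site per-generation mutation rate (optional if \code{theta}
#'   given).
#' @param theta Scaled mutation rate per sequence (optional if \code{mu} given).
#' @param sample_times,sample_counts Serial design: strictly increasing times
#'   (N-generation units, starting at 0) and sequence counts per time.
#' @param seed Optional integer seed.
#' @return Object of class \code{simulated_dataset}: list with
#'   \code{alignment} (named character vector), \code{tree} (ape \code{phylo},
#'   branch lengths in N-generation units), \code{tip_times}, \code{theta},
#'   \code{mu}, \code{L}, \code{demography}.
#' @export
#' @examples
#' dem <- demography("constant", N = 2000)
#' d <- simulate_dataset(n = 5, L = 100, dem = dem, theta = 8, seed = 1)
#' d
simulate_dataset <- function(n = NULL, L, dem, mu = NULL, theta = NULL,
                             sample_times = 0, sample_counts = n,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) {
    if (is.null(mu)) stop("supply 'mu' or 'theta'")
    theta <- 2 * dem$N * mu * L
  } else if (is.null(mu)) {
    mu <- theta / (2 * dem$N * L)
  }
  if (is.null(sample_counts)) stop("supply 'n' or 'sample_counts'")
  if (sample_times[1L] != 0) stop("the first sampling time must be 0")
  st <- simulate_genealogy_tree(as.integer(sample_counts), sample_times, dem)
  aln <- simulate_sequences_on_tree(st, theta, L)
  names(aln) <- st$tree$tip.label
  structure(list(alignment = aln, tree = st$tree,
                 tip_times = st$tip_times, tmrca = st$tmrca,
                 theta = theta, mu = mu, L = as.integer(L), demography = dem),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d sequences of %d sites (theta = %g), TMRCA = %.4g N generations\n",
    length(x$alignment), x$L, x$theta, x$tmrca))
  print(x$demography)
  invisible(x)
}
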