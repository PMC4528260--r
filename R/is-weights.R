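# Importance weights: forward chain probabilities, raw and normalized weights,
# the likelihood estimate, and an exact recursion oracle for tiny samples.

#' Forward transition probability of one embedded-chain move
#'
#' Probability, under the constant-size coalescent with mutation, of the
#' embedded-chain move realized by \code{event} from the configuration
#' \code{config} (the configuration the move acts on, with \eqn{n} sequences):
#' \deqn{MUTATION \alpha\to\beta: \frac{n(\alpha)}{n}\,\frac{\theta}{n-1+\theta}\,P_{\alpha\beta},
#' \qquad COALESCENCE of \alpha: \frac{n(\alpha)}{n}\,\frac{n(\alpha)-1}{n-1+\theta}.}
#' Summed over all possible moves from \code{config} these probabilities need
#' not total 1 move-by-move for each branch, but the products over a complete
#' history, multiplied by the uniform stationary probability \eqn{4^{-L}} of
#' the MRCA type, sum to the stationary sampling probability of the data
#' (see [gt_recursion_oracle()]).
#'
#' For a \code{SAMPLE_ADDITION} event (serial sampling) the contribution is the
#' no-event survival factor \eqn{\exp(-\lambda\Delta)} over the closing gap;
#' supply the gap length via \code{gap} and the lineage count alive during the
#' gap via \code{config}.
#'
#' @param config A [sample_config()] (the configuration with \eqn{n} sequences
#'   that the move acts on).
#' @param event List with \code{kind} (\code{"MUTATION"}, \code{"COALESCENCE"}
#'   or \code{"SAMPLE_ADDITION"}), \code{subject} and \code{result} sequence
#'   strings (ignored for additions).
#' @param model A [mutation_model()].
#' @param gap Gap length before a \code{SAMPLE_ADDITION} (ignored otherwise).
#' @return A probability.
#' @export
#' @examples
#' m <- mutation_model(theta = 1, L = 1)
#' h <- sample_config(c("A", "A"))
#' forward_transition_prob(h, list(kind = "COALESCENCE", subject = "A", result = "A"), m)
forward_transition_prob <- function(config, event, model, gap = NULL) {
  theta <- model$theta
  n <- n_sequences(config)
  if (event$kind == "SAMPLE_ADDITION") {
    if (is.null(gap) || gap < 0) stop("addition events need a non-negative 'gap'")
    return(occupancy_probability(n, theta, gap))
  }
  i <- match(toupper(event$subject), config$types)
  if (is.na(i)) stop("event subject type not present in configuration")
  na <- config$count[i]
  if (event$kind == "COALESCENCE") {
    if (na < 2L) stop("coalescence needs at least two copies of the subject type")
    return((na / n) * ((na - 1) / (n - 1 + theta)))
  }
  if (event$kind != "MUTATION") stop("unknown event kind: ", event$kind)
  p <- sequence_transition_prob(model, event$subject, event$result)
  (na / n) * (theta / (n - 1 + theta)) * p
}

#' Log raw importance weight of a history
#'
#' \eqn{\log W = \log P(G|\theta) - \log Q(G)}, the accumulated forward-chain
#' log-probability minus the accumulated proposal log-probability. The data
#' likelihood given the reconstruction is 1 (the chain terminates at the data
#' by construction) and the uniform stationary probability of the MRCA type
#' (\eqn{4^{-L}} under JC69) is a constant across histories, omitted here and
#' reinstated only when an absolute likelihood is requested
#' ([likelihood_estimate()]). Waiting-time densities cancel exactly between
#' target and proposal (both exponential with the same rate) and are excluded
#' from both accumulators' event terms.
#'
#' @param history A [sample_genealogy()] result.
#' @return Log raw weight (finite).
#' @export
raw_weight <- function(history) {
  lw <- history$log_forward - history$log_proposal
  if (!is.finite(lw)) stop("non-finite importance weight accumulators")
  lw
}

#' Normalize log importance weights
#'
#' Max-shifted exponentiation (log-sum-exp): invariant under addition of a
#' constant to all log weights; the result sums to 1.
#'
#' @param log_raw Numeric vector of log raw weights.
#' @return Normalized weights \eqn{w^{(j)}}.
#' @export
#' @examples
#' normalize_weights(log(c(1, 3)))  # 0.25 0.75
normalize_weights <- function(log_raw) {
  if (length(log_raw) < 1L) stop("need at least one weight")
  m <- max(log_raw)
  if (!is.finite(m)) stop("all log weights are -Inf")
  w <- exp(log_raw - m)
  w / sum(w)
}

#' Effective sample size of an importance-sampling ensemble
#'
#' \eqn{1/\sum_j w_j^2}: the equivalent number of equally weighted draws;
#' between 1 (one dominant genealogy) and \eqn{J} (uniform weights).
#'
#' @param w Normalized weights (or a \code{weighted_ensemble}).
#' @return Effective sample size.
#' @export
effective_sample_size <- function(w) {
  if (inherits(w, "weighted_ensemble")) w <- w$normalized_weights
  1 / sum(w^2)
}

#' Sample an ensemble of weighted genealogies
#'
#' Draws \eqn{J} independent histories with [sample_genealogy()] and computes
#' raw and normalized importance weights. Each genealogy uses its own RNG
#' substream (a per-genealogy seed derived once from \code{seed}), so the
#' ensemble is reproducible and does not depend on evaluation order.
#'
#' @inheritParams sample_genealogy
#' @param J Number of genealogies.
#' @param seed Optional integer seed.
#' @return An object of class \code{weighted_ensemble}: list with
#'   \code{histories}, \code{log_raw_weights}, \code{normalized_weights}.
#' @export
sample_ensemble <- function(config, model, J = 1000, schedule = NULL,
                            seed = NULL, max_events = 1e6) {
  stopifnot(J >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, J)
  histories <- vector("list", J)
  for (j in seq_len(J)) {
    set.seed(seeds[j])
    histories[[j]] <- sample_genealogy(config, model, schedule = schedule,
                                       max_events = max_events)
  }
  lw <- vapply(histories, raw_weight, 0)
  structure(
    list(histories = histories, log_raw_weights = lw,
         normalized_weights = normalize_weights(lw)),
    class = "weighted_ensemble"
  )
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  J <- length(x$histories)
  cat(sprintf("Weighted genealogy ensemble: J = %d, ESS = %.1f\n",
              J, effective_sample_size(x$normalized_weights)))
  tm <- vapply(x$histories, function(h) h$tmrca, 0)
  cat(sprintf("  TMRCA range [%.3g, %.3g], weighted mean %.3g N generations\n",
              min(tm), max(tm), sum(x$normalized_weights * tm)))
  invisible(x)
}

#' Importance-sampling likelihood estimate
#'
#' \eqn{\hat L = J^{-1} \sum_j W^{(j)}}, computed stably from log raw weights.
#' With \code{absolute = TRUE} the omitted uniform MRCA stationary factor
#' \eqn{4^{-L}} is reinstated, giving an estimate of the stationary sampling
#' probability of the (ordered) sample.
#'
#' @param ensemble A [sample_ensemble()] result (or a numeric vector of log
#'   raw weights).
#' @param absolute Multiply by \eqn{4^{-L}}? Requires \code{model}.
#' @param model A [mutation_model()] (only for \code{absolute = TRUE}).
#' @return The likelihood estimate.
#' @export
likelihood_estimate <- function(ensemble, absolute = FALSE, model = NULL) {
  lw <- if (inherits(ensemble, "weighted_ensemble")) ensemble$log_raw_weights
        else as.numeric(ensemble)
  m <- max(lw)
  est <- exp(m) * mean(exp(lw - m))
  if (absolute) {
    if (is.null(model)) stop("'model' required for an absolute likelihood")
    est <- est * 4^(-model$L)
  }
  est
}

# ---- exact recursion oracle ------------------------------------------------

# Enumerate all configurations of total size m over S types (compositions).
.compositions <- function(m, S) {
  if (S == 1L) return(matrix(m, 1L, 1L))
  out <- vector("list", m + 1L)
  for (k in 0:m) {
    sub <- .compositions(m - k, S - 1L)
    out[[k + 1L]] <- cbind(rep.int(k, nrow(sub)), sub)
  }
  unname(do.call(rbind, out))
}

#' Exact stationary sampling probability by recursion (test oracle)
#'
#' Solves the configuration recursion of the constant-size coalescent with
#' finite-sites mutation exactly, level by level in the sample size:
#' \deqn{n(n-1+\theta)\,q(c) = \sum_\alpha c_\alpha(c_\alpha-1)\,q(c - e_\alpha)
#'  + \theta \sum_\alpha c_\alpha \sum_\beta P_{\beta\alpha}\, q(c - e_\alpha + e_\beta),}
#' with \eqn{q(\{\alpha\}) = 4^{-L}}. The value returned is the ordered
#' sampling probability \eqn{q(D)}: the probability that \eqn{n} sequentially
#' labelled genes drawn from the stationary population have the observed types
#' in a fixed order. The mean raw importance weight times \eqn{4^{-L}}
#' estimates exactly this quantity.
#'
#' @param config A [sample_config()] (small: the full type space \eqn{4^L}
#'   must be enumerable and the per-level configuration count below
#'   \code{max_states}).
#' @param model A [mutation_model()].
#' @param max_states Cap on configurations per level (default 3000).
#' @return The exact ordered sampling probability.
#' @export
#' @examples
#' m <- mutation_model(theta = 0, L = 1)
#' gt_recursion_oracle(sample_config(c("A", "A")), m)  # 1/4
gt_recursion_oracle <- function(config, model, max_states = 3000) {
  L <- model$L
  if (L > 2) stop("oracle limited to L <= 2")
  theta <- model$theta
  S <- 4L^L
  types <- type_space(L)
  P <- seq_event_matrix(model)
  n <- n_sequences(config)
  target <- integer(S)
  idx <- apply(config$seq, 1L, type_index)
  target[idx] <- target[idx] + config$count
  if (n == 1L) return(1 / S)
  key <- function(v) paste(v, collapse = ",")
  q <- new.env(parent = emptyenv())
  for (a in seq_len(S)) {
    v <- integer(S); v[a] <- 1L
    assign(key(v), 1 / S, envir = q)
  }
  # precompute positive mutation transitions per type
  nbrs <- lapply(seq_len(S), function(a) which(P[, a] > 0))
  for (m in 2:n) {
    cfg <- .compositions(m, S)
    nc <- nrow(cfg)
    if (nc > max_states)
      stop("configuration space exceeds 'max_states' (", nc, " > ", max_states, ")")
    keys <- apply(cfg, 1L, key)
    pos <- new.env(parent = emptyenv())
    for (i in seq_len(nc)) assign(keys[i], i, envir = pos)
    A <- diag(nc)
    rhs <- numeric(nc)
    denom <- m * (m - 1 + theta)
    for (i in seq_len(nc)) {
      c0 <- cfg[i, ]
      occ <- which(c0 > 0L)
      for (a in occ) {
        if (c0[a] >= 2L) {
          cm <- c0; cm[a] <- cm[a] - 1L
          rhs[i] <- rhs[i] + c0[a] * (c0[a] - 1) * get(key(cm), envir = q) / denom
        }
        if (theta > 0) for (b in nbrs[[a]]) {
          cn <- c0; cn[a] <- cn[a] - 1L; cn[b] <- cn[b] + 1L
          j <- get(key(cn), envir = pos)
          A[i, j] <- A[i, j] - theta * c0[a] * P[b, a] / denom
        }
      }
    }
    x <- solve(A, rhs)
    for (i in seq_len(nc)) assign(keys[i], x[i], envir = q)
  }
  get(key(target), envir = q)
}
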