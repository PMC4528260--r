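# Backward-in-time genealogy sampler under the Stephens-Donnelly proposal.
# Times are in units of N generations throughout (pair-coalescence rate 1,
# so E[T_2] = 1 for a constant-size population).

#' Total event rate with k lineages
#'
#' Rate of the next event (coalescence or mutation) backward in time when
#' \eqn{k} lineages are present: \eqn{k(k-1+\theta)/2} per unit of \eqn{N}
#' generations. With \eqn{k = 1} this reduces to the mutation rate
#' \eqn{\theta/2}, used only before the MRCA in serially-sampled gaps.
#'
#' @param k Lineage count, \eqn{k \ge 1}.
#' @param theta Scaled mutation rate per sequence.
#' @return Event rate (per N generations).
#' @export
#' @examples
#' total_event_rate(2, 0)   # 1
#' total_event_rate(50, 8)  # 1425
total_event_rate <- function(k, theta) {
  if (any(k < 1)) stop("lineage count must be >= 1")
  k * (k - 1 + theta) / 2
}

# Proposal scores for a mutation move of a sequence of type `alpha` given the
# remaining configuration (seqm, counts) = H - alpha with n = sum(counts)
# lineages. Returns, on a max-shifted scale:
#   S[y, s]  proportional to pi_hat(beta_{s,y} | H - alpha) for the neighbour
#            beta obtained by setting site s of alpha to base y (0 at y = alpha_s)
#   log_x1   log of x1 = theta * sum_beta pi_hat(beta | H - alpha) * P_{beta,alpha}
# All pi-hat evaluations use the per-site factorized mode; computed in log
# space so that long sequences cannot underflow.
sd_mutation_scores <- function(model, seqm, counts, alpha) {
  L <- model$L
  theta <- model$theta
  n <- sum(counts)
  if (n == 0L) {
    # empty conditioning set: pi-hat falls back to the uniform stationary law
    S <- matrix(1, 4L, L)
    S[cbind(alpha, seq_len(L))] <- 0
    return(list(S = S, sumS = 3 * L, log_x1 = log(theta) - L * log(4)))
  }
  M <- site_chain_matrix(model, n)
  K <- nrow(seqm)
  den <- matrix(M[cbind(as.vector(seqm), rep(alpha, each = K))], K, L)
  logp <- rowSums(log(den))
  mx <- max(logp)
  W <- counts * exp(logp - mx)
  S <- matrix(0, 4L, L)
  for (y in 1:4) {
    ratio <- matrix(M[as.vector(seqm) + (y - 1L) * 4L], K, L) / den
    S[y, ] <- colSums(W * ratio)
  }
  S[cbind(alpha, seq_len(L))] <- 0
  sumS <- sum(S)
  # pi_hat(beta_{s,y}) = S[y,s] * exp(mx) / n;  P_{beta,alpha} = site_P/L,
  # uniform 1/(3L) per neighbour under JC69
  log_x1 <- log(theta) - log(3 * L) + log(sumS) + mx - log(n)
  list(S = S, sumS = sumS, log_x1 = log_x1)
}

# log(x1/(x1+x2)) and log(x2/(x1+x2)) computed stably from log(x1) and x2.
branch_logprobs <- function(log_x1, x2) {
  if (x2 == 0L) return(c(mut = 0, coal = -Inf))
  if (!is.finite(log_x1)) return(c(mut = -Inf, coal = 0))  # x1 = 0
  d <- log_x1 - log(x2)
  if (d > 37) c(mut = -exp(-d), coal = -d - log1p(exp(-d)))
  else if (d < -37) c(mut = d - log1p(exp(d)), coal = -exp(d))
  else c(mut = d - log1p(exp(d)), coal = -log1p(exp(d)))
}

#' Propose a single backward event from a configuration
#'
#' One draw of the Stephens-Donnelly two-stage proposal: (1) choose a lineage
#' uniformly (type \eqn{\alpha} with probability \eqn{n(\alpha)/n}); (2) with
#' \eqn{x_1 = \theta \sum_\beta \hat\pi(\beta | H - \alpha) P_{\beta\alpha}}
#' (sum over one-step neighbours) and \eqn{x_2 = n(\alpha) - 1}, choose a
#' mutation with probability \eqn{x_1/(x_1+x_2)} (the target \eqn{\beta} drawn
#' proportional to \eqn{\hat\pi(\beta|H-\alpha) P_{\beta\alpha}}) or a
#' coalescence with probability \eqn{x_2/(x_1+x_2)}.
#'
#' @param config A [sample_config()] with at least 2 lineages.
#' @param model A [mutation_model()].
#' @return A list with \code{kind} (\code{"MUTATION"} or \code{"COALESCENCE"}),
#'   \code{subject} and \code{result} sequence strings, and \code{log_prob},
#'   the log of the exact probability of the realized choices.
#' @export
propose_event <- function(config, model) {
  if (n_sequences(config) < 2L) stop("need at least 2 lineages to propose an event")
  st <- list(seqm = config$seq, counts = config$count, types = config$types)
  ev <- .propose_from_state(st, model)
  list(kind = ev$kind, subject = ev$subject, result = ev$result,
       log_prob = ev$log_prob, prob = exp(ev$log_prob))
}

# Internal single-event proposal on a raw state list(seqm, counts, types).
.propose_from_state <- function(st, model) {
  counts <- st$counts
  n <- sum(counts)
  theta <- model$theta
  a <- if (length(counts) == 1L) 1L else sample.int(length(counts), 1L, prob = counts)
  x2 <- counts[a] - 1L
  if (theta == 0 && x2 == 0L)
    stop("singleton type with theta = 0: data unreachable under the model ",
         "(distinct sequences cannot coalesce without mutation)")
  log_pick <- log(counts[a] / n)
  if (theta == 0) {
    return(list(kind = "COALESCENCE", type_idx = a,
                subject = st$types[a], result = st$types[a],
                log_prob = log_pick,
                log_fwd = log(counts[a] / n) + log((counts[a] - 1) / (n - 1 + theta))))
  }
  # configuration minus the chosen lineage
  if (counts[a] > 1L) {
    seqm_m <- st$seqm
    cnt_m <- counts
    cnt_m[a] <- cnt_m[a] - 1L
  } else {
    seqm_m <- st$seqm[-a, , drop = FALSE]
    cnt_m <- counts[-a]
  }
  sc <- sd_mutation_scores(model, seqm_m, cnt_m, st$seqm[a, ])
  bp <- branch_logprobs(sc$log_x1, x2)
  is_mut <- log(stats::runif(1)) < bp[["mut"]]
  if (is_mut) {
    cell <- sample.int(length(sc$S), 1L, prob = as.vector(sc$S))
    y <- (cell - 1L) %% 4L + 1L
    s <- (cell - 1L) %/% 4L + 1L
    bvec <- st$seqm[a, ]
    bvec[s] <- y
    # forward factor: the realized backward move a -> b undoes a forward
    # mutation b -> a; subject-type count taken in the acting configuration
    lf <- log(counts[a] / n) + log(theta / (n - 1 + theta)) +
      log(model$site_matrix[y, st$seqm[a, s]] / model$L)
    list(kind = "MUTATION", type_idx = a, site = s, base = y,
         subject = st$types[a], result = decode_sequence(bvec), result_vec = bvec,
         log_prob = log_pick + bp[["mut"]] + log(sc$S[cell] / sc$sumS),
         log_fwd = lf)
  } else {
    list(kind = "COALESCENCE", type_idx = a,
         subject = st$types[a], result = st$types[a],
         log_prob = log_pick + bp[["coal"]],
         log_fwd = log(counts[a] / n) + log((counts[a] - 1) / (n - 1 + theta)))
  }
}

# Apply a proposed event to a raw state, returning the new state.
.apply_event <- function(st, ev) {
  if (ev$kind == "COALESCENCE") {
    st$counts[ev$type_idx] <- st$counts[ev$type_idx] - 1L  # count >= 2 guaranteed
  } else {
    a <- ev$type_idx
    j <- match(ev$result, st$types)
    if (!is.na(j)) {
      st$counts[j] <- st$counts[j] + 1L
    } else {
      st$seqm <- rbind(st$seqm, ev$result_vec)
      st$types <- c(st$types, ev$result)
      st$counts <- c(st$counts, 1L)
    }
    if (st$counts[a] > 1L) {
      st$counts[a] <- st$counts[a] - 1L
    } else {
      st$seqm <- st$seqm[-a, , drop = FALSE]
      st$types <- st$types[-a]
      st$counts <- st$counts[-a]
    }
  }
  st
}

# Merge an added sample set (sample_config) into a raw state.
.add_sequences <- function(st, add) {
  for (i in seq_along(add$types)) {
    j <- match(add$types[i], st$types)
    if (!is.na(j)) {
      st$counts[j] <- st$counts[j] + add$count[i]
    } else {
      st$seqm <- rbind(st$seqm, add$seq[i, ])
      st$types <- c(st$types, add$types[i])
      st$counts <- c(st$counts, add$count[i])
    }
  }
  st
}

#' Sample one genealogical history backward from the data
#'
#' Simulates a genealogical reconstruction of the sample under the
#' Stephens-Donnelly proposal: waiting times are exponential with rate
#' [total_event_rate()], events are drawn by [propose_event()], and the exact
#' log-probability of every realized choice is accumulated (\code{log_proposal})
#' together with the forward chain log-probability of the same moves
#' (\code{log_forward}). The history ends when a single lineage remains (after
#' all scheduled additions, if a sampling schedule is supplied).
#'
#' For serially sampled data, whenever a proposed event time would cross the
#' next sampling time \eqn{t_s} the event is discarded, time is truncated to
#' \eqn{t_s} and the scheduled sequences are added (exact by memorylessness of
#' the exponential); the no-event survival factor \eqn{\exp(-\lambda \Delta)}
#' over the closing gap is accumulated into both \code{log_forward} and
#' \code{log_proposal}, with \eqn{\lambda} computed from the lineage count
#' actually alive during the gap.
#'
#' @param config A [sample_config()]: the sequences observed at time 0.
#' @param model A [mutation_model()].
#' @param schedule Optional [sampling_schedule()]; its time-0 set must equal
#'   \code{config}. Additions at later times are taken from the schedule.
#' @param max_events Guard against non-convergence (default \code{1e6}).
#' @return An object of class \code{genealogy_history}: a list with
#'   \code{events} (data frame: kind, subject, result, waiting_time, abs_time,
#'   lineages_after), \code{log_forward}, \code{log_proposal}, \code{tmrca},
#'   \code{n0}, \code{n_total} and \code{initial_config}.
#' @export
#' @examples
#' m <- mutation_model(theta = 0, L = 1)
#' h <- sample_genealogy(sample_config(c("A", "A")), m)
#' h$events
sample_genealogy <- function(config, model, schedule = NULL, max_events = 1e6) {
  if (config$L != model$L) stop("configuration length does not match model L")
  add_times <- numeric(0)
  add_sets <- list()
  if (!is.null(schedule) && length(schedule$times) > 1L) {
    add_times <- schedule$times[-1L]
    add_sets <- schedule$sets[-1L]
  }
  st <- list(seqm = config$seq, counts = config$count, types = config$types)
  theta <- model$theta
  n <- sum(st$counts)
  n0 <- n
  t <- 0
  log_fwd <- 0
  log_prop <- 0
  s_ptr <- 1L
  n_add <- length(add_times)
  ev_kind <- character(0); ev_sub <- character(0); ev_res <- character(0)
  ev_wait <- numeric(0); ev_abs <- numeric(0); ev_lin <- integer(0)
  i <- 0L
  repeat {
    if (n == 1L && s_ptr > n_add) break
    i <- i + 1L
    if (i > max_events)
      stop("event cap exceeded (", max_events, "); reconstruction did not converge")
    rate <- total_event_rate(n, theta)
    w <- if (rate > 0) stats::rexp(1) / rate else Inf
    if (s_ptr <= n_add && t + w >= add_times[s_ptr]) {
      # truncate at the sampling time; ties break toward truncation
      delta <- add_times[s_ptr] - t
      log_fwd <- log_fwd - rate * delta
      log_prop <- log_prop - rate * delta
      st <- .add_sequences(st, add_sets[[s_ptr]])
      n_new <- sum(st$counts)
      ev_kind[i] <- "SAMPLE_ADDITION"
      ev_sub[i] <- ""; ev_res[i] <- ""
      ev_wait[i] <- delta; ev_abs[i] <- add_times[s_ptr]; ev_lin[i] <- n_new
      t <- add_times[s_ptr]
      n <- n_new
      s_ptr <- s_ptr + 1L
      next
    }
    t <- t + w
    ev <- .propose_from_state(st, model)
    st <- .apply_event(st, ev)
    if (ev$kind == "COALESCENCE") n <- n - 1L
    log_prop <- log_prop + ev$log_prob
    log_fwd <- log_fwd + ev$log_fwd
    ev_kind[i] <- ev$kind
    ev_sub[i] <- ev$subject; ev_res[i] <- ev$result
    ev_wait[i] <- w; ev_abs[i] <- t; ev_lin[i] <- n
  }
  structure(
    list(
      events = data.frame(kind = ev_kind, subject = ev_sub, result = ev_res,
                          waiting_time = ev_wait, abs_time = ev_abs,
                          lineages_after = ev_lin, stringsAsFactors = FALSE),
      log_forward = log_fwd, log_proposal = log_prop,
      tmrca = t, n0 = n0,
      n_total = n0 + if (n_add) sum(vapply(add_sets, function(s) sum(s$count), 0L)) else 0L,
      initial_config = config,
      schedule_times = if (n_add) c(0, add_times) else 0
    ),
    class = "genealogy_history"
  )
}

#' @export
print.genealogy_history <- function(x, ...) {
  cat(sprintf(
    "Genealogical history: %d sequences, %d events (%d coalescences, %d mutations), TMRCA = %.4g N generations\n",
    x$n_total, nrow(x$events), sum(x$events$kind == "COALESCENCE"),
    sum(x$events$kind == "MUTATION"), x$tmrca))
  cat(sprintf("  log forward = %.4f, log proposal = %.4f, log weight = %.4f\n",
              x$log_forward, x$log_proposal, x$log_forward - x$log_proposal))
  invisible(x)
}

#' Coalescence times of a sampled history
#'
#' Total time during which exactly \eqn{k} lineages were present, for
#' \eqn{k = 2, \dots, n}. For a homochronous history this is the classical
#' \eqn{T_k} (waiting times of all events since the previous coalescence are
#' accumulated into the epoch of the following one), and the times sum to the
#' TMRCA. For serially sampled histories lineage counts are not monotone and
#' the value for each \eqn{k} pools all stretches spent at \eqn{k} lineages.
#'
#' @param history A [sample_genealogy()] result.
#' @return Named numeric vector \code{T2 ... Tn}.
#' @export
coalescence_times <- function(history) {
  ev <- history$events
  if (nrow(ev) == 0L || ev$kind[nrow(ev)] != "COALESCENCE")
    stop("incomplete history")
  before <- c(history$n0, utils::head(ev$lineages_after, -1L))
  kmax <- max(before)
  tk <- vapply(2:kmax, function(k) sum(ev$waiting_time[before == k]), 0)
  stats::setNames(tk, paste0("T", 2:kmax))
}
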