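# Epoch construction (Durbin-Li time discretization), per-epoch moment
# estimates of Ne, and the weighted multi-genealogy skywis curve.

#' Durbin-Li epoch cutting points
#'
#' Logarithmically growing epoch boundaries on \eqn{(0, TMRCA]}:
#' \deqn{t_{cut,b} = 0.1\,\exp\{(b/n_{cum})\log(1 + 10\,TMRCA)\} - 0.1,
#'   \quad b = 1, \dots, n_{cum},}
#' so epochs are short near the present (where coalescences crowd) and long in
#' the deep past. The final cutting point equals the TMRCA exactly.
#'
#' @param tmrca Time to the most recent common ancestor (N-generation units).
#' @param n_cum Number of epochs.
#' @return Increasing numeric vector of \code{n_cum} cutting points, the last
#'   equal to \code{tmrca}.
#' @export
#' @examples
#' round(durbin_li_cutpoints(1, 5), 4)  # 0.0615 0.1609 0.3215 0.5811 1.0000
durbin_li_cutpoints <- function(tmrca, n_cum) {
  if (tmrca <= 0) stop("'tmrca' must be positive")
  if (n_cum < 1) stop("'n_cum' must be >= 1")
  b <- seq_len(n_cum)
  cuts <- 0.1 * exp((b / n_cum) * log(1 + 10 * tmrca)) - 0.1
  cuts[n_cum] <- tmrca
  cuts
}

#' Per-epoch coalescent statistics of a history
#'
#' For each epoch \eqn{(t_{cut,b-1}, t_{cut,b}]} (half-open; \eqn{t_{cut,0}=0};
#' a coalescence exactly on a boundary belongs to the more recent epoch's older
#' edge): the duration \eqn{\Delta t_b}, the number of lineages \eqn{d_b} at
#' the epoch's recent edge (just after \eqn{t_{cut,b-1}}, so additions at a
#' sampling time count toward the epoch that starts there), and the number of
#' coalescences \eqn{c_b} inside the epoch. Conservation:
#' \eqn{\sum_b \Delta t_b = TMRCA} and \eqn{\sum_b c_b = n_{total} - 1}.
#'
#' @param history A [sample_genealogy()] result.
#' @param cutpoints Epoch boundaries from [durbin_li_cutpoints()] or
#'   [hetero_cutpoints()] built from this history's TMRCA.
#' @return Data frame with columns \code{epoch}, \code{t_start}, \code{t_end},
#'   \code{delta_t}, \code{d}, \code{c}.
#' @export
epoch_statistics <- function(history, cutpoints) {
  B <- length(cutpoints)
  if (abs(cutpoints[B] - history$tmrca) > 1e-9 * max(1, history$tmrca))
    stop("last cutting point must equal the history's TMRCA")
  starts <- c(0, cutpoints[-B])
  ev <- history$events
  coal_t <- ev$abs_time[ev$kind == "COALESCENCE"]
  add_t <- ev$abs_time[ev$kind == "SAMPLE_ADDITION"]
  add_n <- if (length(add_t)) diff(c(history$n0,
      ev$lineages_after[ev$kind == "SAMPLE_ADDITION"])) else integer(0)
  # additions jump the count; recompute added counts robustly from the events
  if (length(add_t)) {
    idx <- which(ev$kind == "SAMPLE_ADDITION")
    before <- c(history$n0, utils::head(ev$lineages_after, -1L))[idx]
    add_n <- ev$lineages_after[idx] - before
  }
  # lineages alive just after time t: n0 + additions(<= t) - coalescences(<= t)
  d <- vapply(starts, function(t0) {
    history$n0 + sum(add_n[add_t <= t0 + 1e-12]) - sum(coal_t <= t0 + 1e-12)
  }, 0)
  cc <- vapply(seq_len(B), function(b) {
    sum(coal_t > starts[b] + 1e-12 & coal_t <= cutpoints[b] + 1e-12)
  }, 0)
  # the MRCA coalescence sits exactly on the last boundary
  data.frame(epoch = seq_len(B), t_start = starts, t_end = cutpoints,
             delta_t = cutpoints - starts, d = as.integer(d), c = as.integer(cc))
}

#' Method-of-moments epoch estimate of the effective population size
#'
#' \deqn{\hat N_{e,b} = \Delta t_b\, d_b (d_b - c_b) / (2 c_b)}
#' in units of \eqn{N} generations: the observed epoch duration is equated to
#' the coalescent expectation of the time to take \eqn{d} lineages down by
#' \eqn{c} coalescences. Vectorized.
#'
#' @param delta_t Epoch duration (N-generation units).
#' @param d Lineages at the epoch's recent edge (\eqn{d \ge 2}).
#' @param c Coalescences within the epoch (\eqn{1 \le c \le d - 1}).
#' @return Estimated relative effective size (units of N).
#' @export
#' @examples
#' epoch_ne(0.1, 10, 9)  # 1/18
epoch_ne <- function(delta_t, d, c) {
  if (any(c < 1) || any(d - c < 1))
    stop("epochs with c = 0 or d = c must be merged before estimation")
  delta_t * d * (d - c) / (2 * c)
}

#' Classical skyline estimates from a single history
#'
#' Per-coalescent-interval moment estimates \eqn{\hat N_{e,k} = T_k\,k(k-1)/2}
#' (units of N generations), the single-genealogy skyline this method averages
#' over. Diagnostic output.
#'
#' @param history A homochronous [sample_genealogy()] result.
#' @return Named numeric vector over \eqn{k = 2, \dots, n}.
#' @export
classical_estimates <- function(history) {
  tk <- coalescence_times(history)
  k <- as.integer(sub("^T", "", names(tk)))
  stats::setNames(tk * k * (k - 1) / 2, names(tk))
}

# Merge epochs with no coalescence into their older neighbour: the pooled
# epoch keeps the recent edge of the emptied epoch, the coalescence count of
# the receiver, and the largest lineage count among the pooled windows (for
# homochronous data that is the recent edge's count, since counts only
# decrease; for serial data a sampling addition inside the pool raises it,
# and the maximum is the count that actually participated in the pooled
# coalescences). Preserves sum(delta_t) and sum(c); since only the receiver
# contributes coalescences, d - c >= 1 always holds for the pooled epoch.
# The last epoch always contains the MRCA coalescence.
merge_empty_epochs <- function(stats) {
  keep <- list()
  pend_start <- NULL
  pend_d <- NULL
  for (b in seq_len(nrow(stats))) {
    row <- stats[b, ]
    if (!is.null(pend_start)) {
      row$t_start <- pend_start
      row$delta_t <- row$t_end - pend_start
      row$d <- max(pend_d, row$d)
      pend_start <- NULL
    }
    if (row$c == 0L) {
      pend_start <- row$t_start
      pend_d <- row$d
    } else {
      keep[[length(keep) + 1L]] <- row
    }
  }
  if (!is.null(pend_start))
    stop("trailing epoch without a coalescence; malformed history")
  out <- do.call(rbind, keep)
  out$epoch <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Per-history piecewise-constant Ne step function (after merging empty
# epochs): list(breaks, values, tmrca) with values[i] on (breaks[i], breaks[i+1]].
history_step_function <- function(history, n_cum, schedule_times = NULL,
                                  printed_form = FALSE) {
  tm <- history$tmrca
  if (is.null(schedule_times) || length(schedule_times) <= 1L) {
    cuts <- durbin_li_cutpoints(tm, n_cum)
  } else {
    cuts <- hetero_cutpoints(schedule_times[-1L], tm, n_cum,
                             printed_form = printed_form)
  }
  st <- merge_empty_epochs(epoch_statistics(history, cuts))
  list(breaks = c(0, st$t_end),
       values = epoch_ne(st$delta_t, st$d, st$c),
       tmrca = tm)
}

#' Pointwise weighted skywis estimate
#'
#' Evaluates the weighted average of per-genealogy step functions at times
#' \code{t}:
#' \deqn{\hat N_e(t) = \frac{\sum_j w^{(j)} \hat N_{e,b_j(t)}^{(j)}
#'  \,[t \le TMRCA^{(j)}]}{\sum_j w^{(j)} [t \le TMRCA^{(j)}]},}
#' where \eqn{b_j(t)} is the epoch of genealogy \eqn{j} containing \eqn{t};
#' genealogies whose TMRCA is older than \eqn{t} stop contributing and the
#' remaining weights are renormalized. \code{NA} beyond every TMRCA.
#'
#' @param t Numeric vector of evaluation times (N-generation units).
#' @param steps List of per-genealogy step functions
#'   (\code{list(breaks, values, tmrca)}), as built inside [skywis_curve()].
#' @param weights Normalized importance weights, parallel to \code{steps}.
#' @return Numeric vector of estimates at \code{t}.
#' @export
pointwise_estimate <- function(t, steps, weights) {
  num <- numeric(length(t))
  den <- numeric(length(t))
  for (j in seq_along(steps)) {
    sj <- steps[[j]]
    alive <- t <= sj$tmrca + 1e-12
    if (!any(alive)) next
    b <- findInterval(t[alive], sj$breaks, left.open = TRUE, all.inside = TRUE)
    num[alive] <- num[alive] + weights[j] * sj$values[b]
    den[alive] <- den[alive] + weights[j]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Weighted quantile of TMRCAs (type-1 step quantile).
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1L]]
}

#' Estimate the effective-population-size curve (skywis plot)
#'
#' End-to-end estimator: samples \eqn{J} genealogies from the data under the
#' Stephens-Donnelly proposal, computes importance weights, builds per-genealogy
#' epoch estimates on Durbin-Li cutting points (\code{n_cum} epochs; for serial
#' sampling, per-interval cutting points), and combines them with
#' [pointwise_estimate()] on the union of all cutting points (or a uniform grid
#' when the union exceeds \code{grid_cap} breakpoints). The curve is truncated
#' at the weighted \code{truncate}-quantile TMRCA (default 95\%) so that a
#' single long genealogy does not dominate the old tail; set
#' \code{truncate = NULL} to keep the full support.
#'
#' @param config A [sample_config()] (sequences observed at time 0).
#' @param model A [mutation_model()].
#' @param J Number of genealogies (default 1000).
#' @param n_cum Number of epochs per genealogy; defaults to \eqn{n - 1}. For
#'   serial sampling this is the per-interval epoch count (the final,
#'   oldest interval is scaled by its relative span).
#' @param schedule Optional [sampling_schedule()].
#' @param mu Optional per-site per-generation mutation rate; when given, the
#'   curve also carries a generations axis via \eqn{N = \theta/(2 \mu L)}.
#' @param seed Optional integer seed.
#' @param truncate Weighted TMRCA quantile at which to cut the curve
#'   (default 0.95), or \code{NULL}.
#' @param grid_cap,grid_size Breakpoint-union cap and uniform-grid fallback size.
#' @param smooth For serial sampling, apply [smooth_at_sampling_times()]
#'   (default TRUE).
#' @param ensemble Optionally, a precomputed [sample_ensemble()] to reuse
#'   (then \code{J} and \code{seed} are ignored).
#' @return Object of class \code{skywis_curve}: a data frame with columns
#'   \code{time_start}, \code{time_end}, \code{ne} (units of N) and, when
#'   \code{mu} is given, \code{time_start_gen}, \code{time_end_gen},
#'   \code{ne_gen} (generations). Attributes record \eqn{\theta}, J,
#'   \code{n_cum}, the ESS and the scale \eqn{N}.
#' @export
skywis_curve <- function(config, model, J = 1000, n_cum = NULL, schedule = NULL,
                         mu = NULL, seed = NULL, truncate = 0.95,
                         grid_cap = 1e5, grid_size = 512, smooth = TRUE,
                         ensemble = NULL) {
  if (is.null(ensemble))
    ensemble <- sample_ensemble(config, model, J = J, schedule = schedule,
                                seed = seed)
  J <- length(ensemble$histories)
  n_total <- ensemble$histories[[1L]]$n_total
  if (is.null(n_cum)) {
    S <- if (is.null(schedule)) 1L else length(schedule$times)
    n_cum <- max(2L, as.integer(round((n_total - 1) / S)))
  }
  sched_times <- if (is.null(schedule)) NULL else schedule$times
  steps <- lapply(ensemble$histories, history_step_function, n_cum = n_cum,
                  schedule_times = sched_times)
  w <- ensemble$normalized_weights
  tmr <- vapply(steps, function(s) s$tmrca, 0)
  t_end <- if (is.null(truncate)) max(tmr) else weighted_quantile(tmr, w, truncate)
  breaks <- sort(unique(c(0, unlist(lapply(steps, function(s) s$breaks)),
                          sched_times, t_end)))
  breaks <- breaks[breaks <= t_end + 1e-12]
  if (length(breaks) > grid_cap)
    breaks <- seq(0, t_end, length.out = grid_size + 1L)
  mid <- (utils::head(breaks, -1L) + utils::tail(breaks, -1L)) / 2
  ne <- pointwise_estimate(mid, steps, w)
  out <- data.frame(time_start = utils::head(breaks, -1L),
                    time_end = utils::tail(breaks, -1L), ne = ne)
  out <- out[!is.na(out$ne), ]
  rownames(out) <- NULL
  if (smooth && !is.null(sched_times) && length(sched_times) > 1L)
    out <- smooth_at_sampling_times(out, sched_times[-1L])
  N_scale <- if (!is.null(mu)) model$theta / (2 * mu * model$L) else NA_real_
  if (!is.null(mu)) {
    out$time_start_gen <- out$time_start * N_scale
    out$time_end_gen <- out$time_end * N_scale
    out$ne_gen <- out$ne * N_scale
  }
  structure(out,
            class = c("skywis_curve", "data.frame"),
            theta = model$theta, L = model$L, J = J, n_cum = n_cum,
            ess = effective_sample_size(ensemble$normalized_weights),
            N_scale = N_scale, mu = mu,
            schedule_times = sched_times)
}

#' @export
print.skywis_curve <- function(x, ...) {
  cat(sprintf(
    "skywis curve: %d intervals on [0, %.4g] N generations (J = %d, n_cum = %d, ESS = %.1f)\n",
    nrow(x), max(x$time_end), attr(x, "J"), attr(x, "n_cum"), attr(x, "ess")))
  if (!is.na(attr(x, "N_scale")))
    cat(sprintf("  scale N = %.6g (generations axis available)\n", attr(x, "N_scale")))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more intervals\n", nrow(x) - 6L))
  invisible(x)
}

#' Plot a skywis curve
#'
#' Step plot of the estimated effective population size through time (present
#' at the left). Uses the generations axis when available.
#'
#' @param x A [skywis_curve()].
#' @param log Plot the size axis on a log scale? Default TRUE.
#' @param ... Passed to [plot()].
#' @export
plot.skywis_curve <- function(x, log = TRUE, ...) {
  gen <- !is.na(attr(x, "N_scale"))
  t0 <- if (gen) x$time_start_gen else x$time_start
  t1 <- if (gen) x$time_end_gen else x$time_end
  v <- if (gen) x$ne_gen else x$ne
  xlab <- if (gen) "time before present (generations)" else "time before present (N generations)"
  ylab <- if (gen) "effective population size" else "Ne(t) / N"
  plot(NA, xlim = range(c(t0, t1)), ylim = range(v),
       log = if (log) "y" else "", xlab = xlab, ylab = ylab, ...)
  graphics::segments(t0, v, t1, v, lwd = 2)
  invisible(x)
}

#' Time-averaged value of a skywis curve
#'
#' Duration-weighted mean of the step function over \code{[from, to]}
#' (defaults to the full support), on the N-generation axis or, with
#' \code{units = "generations"}, on the generations axis.
#'
#' @param curve A [skywis_curve()].
#' @param from,to Averaging window (in the chosen units).
#' @param units \code{"N"} or \code{"generations"}.
#' @return The time-averaged estimate.
#' @export
time_averaged_ne <- function(curve, from = NULL, to = NULL,
                             units = c("N", "generations")) {
  units <- match.arg(units)
  gen <- units == "generations"
  if (gen && is.na(attr(curve, "N_scale")))
    stop("curve has no generations axis (no 'mu' supplied)")
  t0 <- if (gen) curve$time_start_gen else curve$time_start
  t1 <- if (gen) curve$time_end_gen else curve$time_end
  v <- if (gen) curve$ne_gen else curve$ne
  if (is.null(from)) from <- min(t0)
  if (is.null(to)) to <- max(t1)
  lo <- pmax(t0, from)
  hi <- pmin(t1, to)
  dur <- pmax(hi - lo, 0)
  if (sum(dur) == 0) stop("averaging window does not intersect the curve")
  sum(v * dur) / sum(dur)
}
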