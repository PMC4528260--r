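# Serially sampled (heterochronous) sequences: sampling schedules, the
# occupancy/survival factors, per-interval epochs, and boundary smoothing.

#' Construct a sampling schedule for serially sampled sequences
#'
#' Times are measured from the present to the past in units of \eqn{N}
#' generations, with \eqn{t_0 = 0} the most recent sample. Each sampling time
#' carries the set of sequences collected then.
#'
#' @param times Strictly increasing numeric vector starting at 0.
#' @param sequences List of character vectors, parallel to \code{times}: the
#'   sequences added at each time (equal lengths across all sets).
#' @return Object of class \code{sampling_schedule}: list with \code{times},
#'   \code{counts} and \code{sets} (a [sample_config()] per time).
#' @export
#' @examples
#' sch <- sampling_schedule(c(0, 0.5), list(c("AC", "AC", "GT"), c("AC")))
#' sch
sampling_schedule <- function(times, sequences) {
  if (length(times) != length(sequences))
    stop("'times' and 'sequences' must be parallel")
  if (times[1L] != 0) stop("the first sampling time must be 0 (the present)")
  if (is.unsorted(times, strictly = TRUE)) stop("sampling times must be strictly increasing")
  sets <- lapply(sequences, sample_config)
  L <- vapply(sets, function(s) s$L, 0L)
  if (length(unique(L)) != 1L) stop("all sequence sets must share one length L")
  structure(list(times = as.numeric(times),
                 counts = vapply(sets, function(s) sum(s$count), 0L),
                 sets = sets),
            class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("Sampling schedule: %d sampling times, %d sequences total\n",
              length(x$times), sum(x$counts)))
  for (s in seq_along(x$times))
    cat(sprintf("  t = %g N generations: %d sequences\n", x$times[s], x$counts[s]))
  invisible(x)
}

#' No-event occupancy probability over a gap
#'
#' Survival probability that no coalescence or mutation occurs among \eqn{k}
#' lineages over a gap of length \eqn{\Delta} (N-generation units):
#' \eqn{\exp(-\lambda\Delta)} with \eqn{\lambda = k(k-1+\theta)/2}. Its
#' complement is the "some event occurs" factor of the serial-sampling
#' embedded chain.
#'
#' @param k Lineages alive during the gap.
#' @param theta Scaled mutation rate per sequence.
#' @param delta Gap length, \eqn{\Delta \ge 0}.
#' @return A probability.
#' @export
#' @examples
#' occupancy_probability(2, 0, log(2))  # 1/2
occupancy_probability <- function(k, theta, delta) {
  if (any(delta < 0)) stop("gap length must be non-negative")
  exp(-total_event_rate(k, theta) * delta)
}

#' Sample a genealogy for serially sampled sequences
#'
#' Convenience wrapper around [sample_genealogy()]: the time-0 set of the
#' schedule is the initial configuration and later sets are added when the
#' backward simulation reaches their sampling times (proposed events that
#' would cross a sampling time are discarded and time is truncated there,
#' which is exact by memorylessness). With a single sampling time this is
#' identical to the homochronous sampler.
#'
#' @param schedule A [sampling_schedule()].
#' @param model A [mutation_model()].
#' @param max_events Guard against non-convergence.
#' @return A \code{genealogy_history}, as for [sample_genealogy()].
#' @export
sample_genealogy_hetero <- function(schedule, model, max_events = 1e6) {
  sample_genealogy(schedule$sets[[1L]], model, schedule = schedule,
                   max_events = max_events)
}

#' Epoch cutting points for serially sampled data
#'
#' Durbin-Li cutting points applied per sampling interval: within
#' \eqn{(t_{s-1}, t_s]} the boundaries are
#' \deqn{t_{s-1} + 0.1\,\exp\{(b/n_{cum}^{(s)})\log(1 + 10\,(t_s - t_{s-1}))\} - 0.1,}
#' so the last cutting point of each interval lands exactly on \eqn{t_s}; the
#' final (oldest) interval runs to the TMRCA. The per-interval span
#' \eqn{t_s - t_{s-1}} inside the logarithm is a correction of the published
#' form of the rule, which uses \eqn{t_s} and therefore overshoots the
#' interval whenever \eqn{t_{s-1} > 0}; the uncorrected variant is available
#' via \code{printed_form = TRUE}.
#'
#' The oldest interval's epoch count defaults to \code{n_cum} scaled by its
#' span relative to the mean span of the sampling intervals, with a minimum
#' of 2.
#'
#' @param sampling_times Strictly increasing sampling times \eqn{t_1 < \dots <
#'   t_{S-1}} (excluding the present, \eqn{t_0 = 0}).
#' @param tmrca TMRCA of the history (must exceed the last sampling time).
#' @param n_cum Epochs per sampling interval (scalar, or vector of length
#'   \eqn{S} giving each interval's count explicitly).
#' @param printed_form Use the uncorrected overshooting rule? Default FALSE.
#' @return Increasing vector of cutting points, the last equal to
#'   \code{tmrca}, passing exactly through every sampling time.
#' @export
hetero_cutpoints <- function(sampling_times, tmrca, n_cum, printed_form = FALSE) {
  if (length(sampling_times) == 0L) return(durbin_li_cutpoints(tmrca, n_cum))
  if (is.unsorted(sampling_times, strictly = TRUE) || any(sampling_times <= 0))
    stop("sampling times must be positive and strictly increasing")
  if (tmrca <= sampling_times[length(sampling_times)])
    stop("TMRCA must be older than the last sampling time")
  edges <- c(0, sampling_times, tmrca)
  S <- length(edges) - 1L
  spans <- diff(edges)
  if (length(n_cum) == 1L) {
    ncum_s <- rep(as.integer(n_cum), S)
    ncum_s[S] <- max(2L, as.integer(round(n_cum * spans[S] / mean(spans[-S]))))
  } else {
    if (length(n_cum) != S) stop("'n_cum' must be scalar or one count per interval")
    ncum_s <- as.integer(n_cum)
  }
  if (any(ncum_s < 1L)) stop("epoch counts must be >= 1")
  out <- numeric(0)
  for (s in seq_len(S)) {
    span <- if (printed_form) edges[s + 1L] else spans[s]
    b <- seq_len(ncum_s[s])
    cuts <- edges[s] + 0.1 * exp((b / ncum_s[s]) * log(1 + 10 * span)) - 0.1
    if (!printed_form) cuts[ncum_s[s]] <- edges[s + 1L]
    out <- c(out, cuts)
  }
  # the uncorrected published rule can overshoot an interval's end and
  # produce a non-monotone sequence; only the corrected rule is validated
  if (!printed_form && is.unsorted(out, strictly = TRUE))
    stop("cutting points are not strictly increasing; check the schedule")
  out
}

#' Smooth a skywis curve at the sampling times
#'
#' The addition of new sequences at a sampling time \eqn{t_s} creates an
#' artificial discontinuity; the value on the first epoch older than
#' \eqn{t_s} is replaced by the value of the epoch immediately more recent
#' than \eqn{t_s}. All other values are unchanged; with no sampling times
#' inside the curve's support this is the identity.
#'
#' @param curve A \code{skywis_curve} (or plain data frame with columns
#'   \code{time_start}, \code{time_end}, \code{ne}).
#' @param sampling_times Sampling times \eqn{t_1, \dots} (excluding 0).
#' @return The smoothed curve (same shape).
#' @export
smooth_at_sampling_times <- function(curve, sampling_times) {
  eps <- 1e-9
  for (ts in sampling_times) {
    older <- which(curve$time_start >= ts - eps)
    recent <- which(curve$time_end <= ts + eps)
    if (length(older) == 0L || length(recent) == 0L) next
    i_after <- older[1L]
    i_before <- recent[length(recent)]
    curve$ne[i_after] <- curve$ne[i_before]
    if ("ne_gen" %in% names(curve))
      curve$ne_gen[i_after] <- curve$ne_gen[i_before]
  }
  curve
}
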