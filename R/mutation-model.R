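# Finite-sites mutation structure: sequence types over {A,C,G,T}, the single-event
# transition probabilities P_ab, and the Stephens-Donnelly approximate conditional
# sampling probability pi-hat.

.BASES <- c("A", "C", "G", "T")

#' Jukes-Cantor per-site mutation event matrix
#'
#' Returns the 4x4 row-stochastic matrix of base changes for a single mutation
#' event under the JC69 convention used throughout this package: a mutation
#' event always changes the site, to each of the three other bases with equal
#' probability (off-diagonal 1/3, diagonal 0). Silent events would merely
#' rescale the mutation rate \eqn{\theta}.
#'
#' @return A 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
#' @examples
#' jc69_site_matrix()
jc69_site_matrix <- function() {
  m <- matrix(1 / 3, 4L, 4L, dimnames = list(.BASES, .BASES))
  diag(m) <- 0
  m
}

#' Construct a finite-sites mutation model
#'
#' Bundles the scaled mutation rate \eqn{\theta = 2N\mu} (per sequence,
#' dimensionless), the number of sites \eqn{L}, and the per-site mutation event
#' matrix. A whole-sequence mutation event picks one of the \eqn{L} sites
#' uniformly and changes its base according to \code{site_matrix}, so the
#' sequence-level transition probability between types at Hamming distance one
#' is \code{site_matrix[x, y] / L} and zero otherwise.
#'
#' @param theta Scaled mutation rate per sequence, \eqn{\theta \ge 0}.
#' @param L Number of sites (alignment length).
#' @param site_matrix 4x4 row-stochastic per-mutation-event base change matrix;
#'   defaults to [jc69_site_matrix()]. Only JC69 is shipped, but any
#'   row-stochastic matrix with zero diagonal is accepted.
#' @return An object of class \code{mutation_model}.
#' @export
#' @examples
#' m <- mutation_model(theta = 8, L = 100)
#' m
mutation_model <- function(theta, L, site_matrix = jc69_site_matrix()) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta), theta >= 0,
            is.numeric(L), length(L) == 1L, L >= 1)
  site_matrix <- as.matrix(site_matrix)
  if (!identical(dim(site_matrix), c(4L, 4L)))
    stop("'site_matrix' must be a 4x4 matrix")
  if (max(abs(rowSums(site_matrix) - 1)) > 1e-12)
    stop("'site_matrix' rows must sum to 1")
  if (any(site_matrix < 0))
    stop("'site_matrix' entries must be non-negative")
  dimnames(site_matrix) <- list(.BASES, .BASES)
  structure(
    list(theta = theta, L = as.integer(L), site_matrix = site_matrix,
         cache = new.env(parent = emptyenv())),
    class = "mutation_model"
  )
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("Finite-sites mutation model: theta = %g (per sequence), L = %d sites\n",
              x$theta, x$L))
  invisible(x)
}

# Encode a character vector of equal-length ACGT sequences as an integer matrix
# (rows = sequences, A=1 C=2 G=3 T=4). Errors on any other character.
encode_sequences <- function(x) {
  x <- toupper(x)
  L <- nchar(x[1L])
  if (any(nchar(x) != L)) stop("sequences must all have the same length")
  chars <- strsplit(x, "", fixed = TRUE)
  m <- matrix(0L, length(x), L)
  for (i in seq_along(chars)) {
    idx <- match(chars[[i]], .BASES)
    if (anyNA(idx))
      stop("sequence contains characters outside {A,C,G,T}: ",
           paste(unique(chars[[i]][is.na(idx)]), collapse = ", "))
    m[i, ] <- idx
  }
  m
}

decode_sequence <- function(v) paste(.BASES[v], collapse = "")

#' Single-event transition probability between two sequence types
#'
#' Probability that one whole-sequence mutation event turns type \code{a} into
#' type \code{b}: \code{site_matrix[x, y] / L} when the two types differ at
#' exactly one site (with bases x -> y there), and 0 otherwise (a single event
#' changes exactly one site, chosen uniformly; there are no silent events).
#'
#' @param model A [mutation_model()].
#' @param a,b Sequence strings of length \code{model$L}.
#' @return A probability.
#' @export
#' @examples
#' m <- mutation_model(theta = 1, L = 4)
#' sequence_transition_prob(m, "ACGT", "ACGA")  # 1/12
sequence_transition_prob <- function(model, a, b) {
  va <- encode_sequences(a)[1L, ]
  vb <- encode_sequences(b)[1L, ]
  if (length(va) != model$L || length(vb) != model$L)
    stop("sequence length does not match model L")
  d <- which(va != vb)
  if (length(d) != 1L) return(0)
  model$site_matrix[va[d], vb[d]] / model$L
}

#' One-mutation-step neighbours of a sequence type
#'
#' Enumerates all types reachable from \code{a} by a single mutation event,
#' i.e. all types at Hamming distance one with a positive site-matrix entry
#' (all 3L of them under JC69).
#'
#' @inheritParams sequence_transition_prob
#' @return Character vector of neighbouring sequence types.
#' @export
one_step_neighbors <- function(model, a) {
  v <- encode_sequences(a)[1L, ]
  if (length(v) != model$L) stop("sequence length does not match model L")
  out <- character(0)
  for (s in seq_len(model$L)) {
    for (y in which(model$site_matrix[v[s], ] > 0)) {
      w <- v
      w[s] <- y
      out <- c(out, decode_sequence(w))
    }
  }
  out
}

# Per-site geometric-chain matrix used by the factorized pi-hat:
#   M = (n / (n + theta_s)) * (I - (theta_s / (n + theta_s)) P)^(-1),
# theta_s = theta / L. Row-stochastic; memoized per lineage count n in the
# model's cache (theta is fixed within a model).
site_chain_matrix <- function(model, n) {
  key <- as.character(n)
  cached <- model$cache[[key]]
  if (!is.null(cached)) return(cached)
  ts <- model$theta / model$L
  if (ts == 0) {
    M <- diag(4)
  } else {
    g <- ts / (n + ts)
    M <- (n / (n + ts)) * solve(diag(4) - g * model$site_matrix)
    if (any(M < 0)) stop("singular or invalid per-site system")  # cannot occur for theta >= 0
  }
  dimnames(M) <- list(.BASES, .BASES)
  model$cache[[key]] <- M
  M
}

# Full type space and sequence-level single-event matrix for small L (exact
# mode and oracles). Type index: site 1 most significant, base order A,C,G,T.
type_space <- function(L) {
  if (L > 5) stop("type space enumeration limited to L <= 5")
  # expand.grid varies the first column fastest; we want site L least
  # significant, so generate columns in order (site L, ..., site 1) and flip.
  m <- as.matrix(expand.grid(rep(list(1:4), L)))[, L:1, drop = FALSE]
  dimnames(m) <- NULL
  m
}

type_index <- function(v) {
  L <- length(v)
  1L + sum((v - 1L) * 4L^(L - seq_len(L)))
}

seq_event_matrix <- function(model) {
  L <- model$L
  if (L > 5) stop("exact mode limited to L <= 5")
  key <- "seq_event_matrix"
  cached <- model$cache[[key]]
  if (!is.null(cached)) return(cached)
  S <- 4L^L
  P <- matrix(0, S, S)
  for (s in seq_len(L)) {
    mats <- rep(list(diag(4)), L)
    mats[[s]] <- model$site_matrix
    P <- P + Reduce(kronecker, mats) / L
  }
  model$cache[[key]] <- P
  P
}

#' Approximate conditional sampling probability (pi-hat)
#'
#' The Stephens-Donnelly approximation to the probability that an additional
#' sequence sampled from the population is of type \code{target}, given the
#' currently observed configuration \code{config}: a random existing sequence
#' is chosen and mutated a geometric number of times (success probability
#' \eqn{n/(n+\theta)}).
#'
#' Two evaluation modes are provided. \code{"factorized"} (the default, used
#' for real sequence data) applies the geometric chain independently per site
#' with per-site rate \eqn{\theta_s = \theta/L}; this keeps the evaluation
#' linear in \eqn{L} and is a valid proposal ingredient for importance
#' sampling, which is unbiased for any strictly positive proposal.
#' \code{"exact"} resolves the full \eqn{4^L}-type geometric series by a dense
#' linear solve and is retained for small \eqn{L} (tests and oracles); the two
#' modes coincide at \eqn{L = 1}.
#'
#' @param model A [mutation_model()].
#' @param target Sequence string of length \code{model$L}.
#' @param config A [sample_config()] (non-empty).
#' @param method \code{"factorized"} or \code{"exact"}.
#' @return A probability, clamped below at \code{1e-300}.
#' @export
#' @examples
#' m <- mutation_model(theta = 1, L = 1)
#' h <- sample_config("A")
#' pi_hat(m, "A", h, method = "exact")  # 4/7
pi_hat <- function(model, target, config, method = c("factorized", "exact")) {
  method <- match.arg(method)
  if (sum(config$count) == 0L) stop("empty sample configuration")
  if (config$L != model$L) stop("configuration length does not match model L")
  tv <- encode_sequences(target)[1L, ]
  if (length(tv) != model$L) stop("target length does not match model L")
  n <- sum(config$count)
  if (method == "factorized") {
    M <- site_chain_matrix(model, n)
    K <- nrow(config$seq)
    pr <- numeric(K)
    for (i in seq_len(K))
      pr[i] <- prod(M[cbind(config$seq[i, ], tv)])
    val <- sum(config$count * pr) / n
  } else {
    theta <- model$theta
    if (theta == 0) {
      types <- apply(config$seq, 1L, decode_sequence)
      i <- match(decode_sequence(tv), types)
      val <- if (is.na(i)) 0 else config$count[i] / n
    } else {
      P <- seq_event_matrix(model)
      S <- nrow(P)
      g <- theta / (n + theta)
      e <- numeric(S)
      e[type_index(tv)] <- 1
      col <- solve(diag(S) - g * P, e)  # symmetric under JC69, column = row
      idx <- apply(config$seq, 1L, type_index)
      val <- (n / (n + theta)) * sum(config$count * col[idx]) / n
    }
  }
  max(val, 1e-300)
}

#' Truncated brute-force evaluation of pi-hat (test oracle)
#'
#' Partial sum of the geometric mutation series defining pi-hat, truncated at
#' \code{m_max} mutation events. Monotone non-decreasing in \code{m_max} and
#' converging to the exact-mode [pi_hat()] with geometric error bound
#' \eqn{(\theta/(n+\theta))^{m_{max}+1}}.
#'
#' @inheritParams pi_hat
#' @param m_max Number of mutation events to include.
#' @param max_types Guard on the enumerable type space (default 1024).
#' @return A probability (partial sum).
#' @export
pi_hat_truncated <- function(model, target, config, m_max, max_types = 1024) {
  if (sum(config$count) == 0L) stop("empty sample configuration")
  if (4^model$L > max_types)
    stop("type space exceeds enumeration cap; increase 'max_types' or reduce L")
  n <- sum(config$count)
  theta <- model$theta
  tv <- encode_sequences(target)[1L, ]
  ti <- type_index(tv)
  P <- seq_event_matrix(model)
  S <- nrow(P)
  u <- numeric(S)
  idx <- apply(config$seq, 1L, type_index)
  u[idx] <- u[idx] + config$count / n
  succ <- n / (n + theta)
  fail <- theta / (n + theta)
  total <- 0
  wt <- succ
  for (m in 0:m_max) {
    total <- total + wt * u[ti]
    if (m < m_max) {
      u <- as.vector(u %*% P)
      wt <- wt * fail
    }
  }
  total
}
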