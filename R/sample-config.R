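# Sample configurations: multisets of distinct sequence types with multiplicities.

#' Construct a sample configuration
#'
#' A sample configuration is the multiset of distinct sequence types observed
#' in an alignment, with their multiplicities. Identical sequences are
#' collapsed; types are stored in lexicographic order so that a configuration
#' has a canonical representation.
#'
#' @param sequences Character vector of equal-length ACGT sequences (repeats
#'   allowed), or the distinct types when \code{counts} is given.
#' @param counts Optional positive integer multiplicities, parallel to
#'   \code{sequences}.
#' @return An object of class \code{sample_config} with fields \code{types}
#'   (character), \code{seq} (integer matrix, one row per type), \code{count}
#'   (integer) and \code{L}.
#' @export
#' @examples
#' h <- sample_config(c("ACG", "ACG", "ACT"))
#' h
sample_config <- function(sequences, counts = NULL) {
  if (length(sequences) == 0L) stop("empty sample configuration")
  sequences <- toupper(sequences)
  if (is.null(counts)) {
    tab <- table(sequences)
    types <- names(tab)
    counts <- as.integer(tab)
  } else {
    if (length(counts) != length(sequences))
      stop("'counts' must be parallel to 'sequences'")
    counts <- as.integer(counts)
    if (any(counts < 1L)) stop("multiplicities must be >= 1")
    agg <- tapply(counts, sequences, sum)
    types <- names(agg)
    counts <- as.integer(agg)
  }
  o <- order(types)
  types <- types[o]
  counts <- counts[o]
  structure(
    list(types = types, seq = encode_sequences(types), count = counts,
         L = nchar(types[1L])),
    class = "sample_config"
  )
}

#' @export
print.sample_config <- function(x, ...) {
  cat(sprintf("Sample configuration: %d sequences, %d distinct types, L = %d\n",
              sum(x$count), length(x$count), x$L))
  show <- utils::head(seq_along(x$types), 8L)
  for (i in show) {
    s <- x$types[i]
    if (nchar(s) > 40) s <- paste0(substr(s, 1, 40), "...")
    cat(sprintf("  %s  x%d\n", s, x$count[i]))
  }
  if (length(x$types) > 8L) cat(sprintf("  ... and %d more types\n",
                                        length(x$types) - 8L))
  invisible(x)
}

#' Total number of sequences in a configuration
#' @param config A [sample_config()].
#' @return Integer sample size.
#' @export
n_sequences <- function(config) sum(config$count)

# Rebuild a sample_config from internal pieces (used by the sampler).
config_from_internal <- function(seqm, counts) {
  types <- apply(seqm, 1L, decode_sequence)
  sample_config(types, counts)
}
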