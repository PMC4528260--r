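# FASTA / schedule input, TSV output and end-to-end orchestration.

#' Read an alignment into a sample configuration
#'
#' Reads a FASTA file of equal-length, ungapped ACGT sequences (mixed case is
#' uppercased), collapses identical sequences into a configuration of types
#' with multiplicities, and retains the label-to-type map.
#'
#' @param path FASTA file path.
#' @return List with \code{config} (a [sample_config()]), \code{labels}
#'   (record names in file order) and \code{sequences} (named character
#'   vector of the uppercased sequences).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  chars <- as.character(dna)
  seqs <- vapply(chars, function(x) toupper(paste(x, collapse = "")), "")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences have unequal lengths: ", paste(L, collapse = ", "))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGT]", "", seqs[bad]), "")))
    stop("alignment contains characters outside {A,C,G,T} (e.g. ",
         paste(utils::head(ch, 5L), collapse = ", "),
         "); gaps and ambiguity codes are not supported")
  }
  list(config = sample_config(unname(seqs)), labels = names(seqs),
       sequences = seqs)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of ACGT sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("s", seq_along(sequences))
  dna <- ape::as.DNAbin(strsplit(tolower(sequences), ""))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a serial-sampling schedule
#'
#' The schedule is a TSV with columns \code{label} and \code{time}
#' (N-generation units, 0 = present); sequences come from a single FASTA
#' containing every label.
#'
#' @param schedule_path TSV path (header \code{label", "time}).
#' @param fasta_path FASTA with one record per label.
#' @return A [sampling_schedule()].
#' @export
read_schedule <- function(schedule_path, fasta_path) {
  tab <- utils::read.delim(schedule_path, stringsAsFactors = FALSE)
  if (!all(c("label", "time") %in% names(tab)))
    stop("schedule file needs columns 'label' and 'time'")
  aln <- read_alignment(fasta_path)
  miss <- setdiff(tab$label, names(aln$sequences))
  if (length(miss))
    stop("schedule labels missing from FASTA: ", paste(utils::head(miss, 5L), collapse = ", "))
  times <- sort(unique(tab$time))
  if (times[1L] != 0) stop("the schedule must include time 0 (the present)")
  sets <- lapply(times, function(ts) unname(aln$sequences[tab$label[tab$time == ts]]))
  sampling_schedule(times, sets)
}

#' Run the full skywis estimation and write its outputs
#'
#' End-to-end orchestration: samples genealogies, computes weights, builds the
#' weighted curve and writes (1) the curve TSV (\code{time_start},
#' \code{time_end}, \code{ne}, plus generations columns when \code{mu} is
#' given), (2) a per-genealogy diagnostics TSV (index, TMRCA, log weight),
#' (3) a JSON-like run metadata file recording \eqn{\theta}, J,
#' \code{n_cum}, seed, ESS and unit conventions. Outputs are reproducible
#' from (inputs, seed).
#'
#' @param config A [sample_config()], or a FASTA path.
#' @param theta Scaled mutation rate per sequence.
#' @param out_dir Output directory (created if needed).
#' @param J,n_cum,mu,seed,schedule,truncate See [skywis_curve()].
#' @return The [skywis_curve()], invisibly; files under \code{out_dir}.
#' @export
run_skywis <- function(config, theta, out_dir, J = 1000, n_cum = NULL,
                       mu = NULL, seed = NULL, schedule = NULL,
                       truncate = 0.95) {
  if (is.character(config)) config <- read_alignment(config)$config
  if (missing(theta) || is.null(theta)) stop("'theta' is required")
  model <- mutation_model(theta = theta, L = config$L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ens <- sample_ensemble(config, model, J = J, schedule = schedule, seed = seed)
  curve <- skywis_curve(config, model, n_cum = n_cum, schedule = schedule,
                        mu = mu, truncate = truncate, ensemble = ens)
  utils::write.table(as.data.frame(curve),
                     file.path(out_dir, "skywis_curve.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  diag <- data.frame(
    genealogy = seq_along(ens$histories),
    tmrca = vapply(ens$histories, function(h) h$tmrca, 0),
    log_weight = ens$log_raw_weights,
    weight = ens$normalized_weights)
  utils::write.table(diag, file.path(out_dir, "genealogy_diagnostics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(
    sprintf('{'),
    sprintf('  "n_sequences": %d,', n_sequences(config)),
    sprintf('  "n_types": %d,', length(config$count)),
    sprintf('  "L": %d,', config$L),
    sprintf('  "theta_per_sequence": %g,', theta),
    if (!is.null(mu)) sprintf('  "mu_per_site_per_generation": %g,', mu),
    if (!is.null(mu)) sprintf('  "N_scale": %g,', theta / (2 * mu * config$L)),
    sprintf('  "J": %d,', length(ens$histories)),
    sprintf('  "n_cum": %d,', attr(curve, "n_cum")),
    if (!is.null(seed)) sprintf('  "seed": %d,', as.integer(seed)),
    sprintf('  "ess": %g,', effective_sample_size(ens$normalized_weights)),
    sprintf('  "time_units": "N generations (pair-coalescence rate 1)"'),
    sprintf('}'))
  writeLines(meta, file.path(out_dir, "run_metadata.json"))
  message(sprintf(
    "skywis: n = %d (%d types), theta = %g, J = %d, n_cum = %d, ESS = %.1f",
    n_sequences(config), length(config$count), theta, length(ens$histories),
    attr(curve, "n_cum"), effective_sample_size(ens$normalized_weights)))
  invisible(curve)
}

#' Write a simulated dataset to disk
#'
#' FASTA alignment, Newick tree (branch lengths in N-generation units) and a
#' JSON sidecar recording the true demography and parameters.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory.
#' @param prefix File name prefix (default \code{"sim"}).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$alignment, file.path(dir, paste0(prefix, ".fasta")))
  ape::write.tree(dataset$tree, file.path(dir, paste0(prefix, ".nwk")))
  dem <- dataset$demography
  side <- c(
    '{',
    sprintf('  "form": "%s",', dem$form),
    sprintf('  "N": %g,', dem$N),
    if (!is.null(dem$x)) sprintf('  "change_time_generations": %g,', dem$x),
    if (!is.null(dem$a)) sprintf('  "ratio_a": %g,', dem$a),
    if (!is.null(dem$beta)) sprintf('  "beta_per_N_generations": %g,', dem$beta),
    sprintf('  "theta_per_sequence": %g,', dataset$theta),
    sprintf('  "mu_per_site_per_generation": %g,', dataset$mu),
    sprintf('  "L": %d,', dataset$L),
    sprintf('  "time_units": "N generations"'),
    '}')
  writeLines(side, file.path(dir, paste0(prefix, "_truth.json")))
  invisible(dir)
}
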