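#' Sample one motif instance from the generative model
#'
#' Draws a spacer configuration from the (renormalized) configuration
#' prior, then anchor residues from `phi` and spacer residues from
#' `spacer`. Uses the current R random number stream; call `set.seed()`
#' for reproducible draws.
#'
#' @param model A `nologo_model`.
#' @return A list with `sequence` (a string of `config length` residues)
#'   and `config` (the drawn configuration, 1-row matrix).
#' @export
sample_nes <- function(model) {
  stopifnot(inherits(model, "nologo_model"))
  pr <- config_prior(model)
  k <- sample.int(length(pr), 1L, prob = pr)
  cfg <- model$configs[k, , drop = FALSE]
  len <- config_length(cfg)
  res <- character(len)
  hy <- hydrophobic_offsets(cfg) + 1L
  sp <- spacer_offsets(cfg) + 1L
  res[hy] <- sample(model$alphabet, 4L, replace = TRUE, prob = model$phi)
  res[sp] <- sample(model$alphabet, length(sp), replace = TRUE,
                    prob = model$spacer)
  list(sequence = paste(res, collapse = ""), config = cfg)
}

#' Sample a training window containing one motif
#'
#' Plants a sampled motif at a random start within the first
#' `max_start_positions` positions of a background window, the window
#' format consumed by [em_fit()] and (with its annotation) by
#' [estimate_from_alignment()].
#'
#' @param model A `nologo_model`.
#' @param window_len Window length in residues (default 25).
#' @param max_start_positions Largest allowed motif start (default 12).
#' @return A list with `window`, `nes_start` (1-based) and `config`.
#' @export
sample_window <- function(model, window_len = 25L, max_start_positions = 12L) {
  drawn <- sample_nes(model)
  len <- config_length(drawn$config)
  smax <- min(max_start_positions, window_len - model$total_length + 1L)
  s <- sample.int(smax, 1L)
  bg <- sample(model$alphabet, window_len, replace = TRUE,
               prob = model$background)
  bg[s + 0:(len - 1L)] <- strsplit(drawn$sequence, "")[[1L]]
  list(window = paste(bg, collapse = ""), nes_start = s, config = drawn$config)
}

#' Specification of a synthetic planted-motif proteome
#'
#' @param model Generating `nologo_model`.
#' @param n_proteins Number of proteins to simulate.
#' @param length_mean,length_sd Protein lengths are drawn from a normal
#'   distribution with these moments (defaults 495 and 150 residues,
#'   matching the average yeast protein length used in the proteome-rate
#'   arithmetic), clipped below at `length_min`.
#' @param length_min Minimum protein length (default 60).
#' @param nes_per_protein Number of motifs planted per protein (default 1).
#' @param min_separation Minimum distance in residues between planted motif
#'   starts (default 25, so a 25-residue window never spans two motifs).
#' @param seed Seed recorded with, and used for, the simulation.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(model, n_proteins = 30L, length_mean = 495,
                            length_sd = 150, length_min = 60L,
                            nes_per_protein = 1L, min_separation = 25L,
                            seed = 1L) {
  stopifnot(inherits(model, "nologo_model"), n_proteins >= 1,
            length_mean > 0, length_sd >= 0, nes_per_protein >= 0)
  structure(list(model = model, n_proteins = as.integer(n_proteins),
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = as.integer(length_min),
                 nes_per_protein = as.integer(nes_per_protein),
                 min_separation = as.integer(min_separation),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic proteome with planted motifs
#'
#' Background residues are drawn from the model's background distribution;
#' motifs sampled from the model are planted at recorded, non-overlapping
#' coordinates at least `min_separation` residues apart. Fully reproducible
#' from the recorded seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `sequences` (named character vector), `truth`
#'   (data.frame `protein_id`, `start`, `end`, `config`), `annotations`
#'   (window-format training records for the planted motifs) and `seed`.
#'   When a protein is too short to host the requested motifs, fewer are
#'   planted and a warning is raised.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  model <- spec$model
  set.seed(spec$seed)
  lens <- pmax(spec$length_min,
               as.integer(round(stats::rnorm(spec$n_proteins,
                                             spec$length_mean, spec$length_sd))))
  ids <- sprintf("synthetic_protein_%03d", seq_len(spec$n_proteins))
  seqs <- character(spec$n_proteins)
  truth <- list(); ann <- list()
  shortfall <- 0L
  for (p in seq_len(spec$n_proteins)) {
    res <- sample(model$alphabet, lens[p], replace = TRUE,
                  prob = model$background)
    starts <- integer(0)
    for (j in seq_len(spec$nes_per_protein)) {
      drawn <- sample_nes(model)
      mlen <- config_length(drawn$config)
      cand <- seq_len(max(lens[p] - mlen + 1L, 0L))
      if (length(starts))
        cand <- cand[vapply(cand, function(s)
          all(abs(s - starts) >= spec$min_separation), logical(1))]
      if (!length(cand)) { shortfall <- shortfall + 1L; next }
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      res[s + 0:(mlen - 1L)] <- strsplit(drawn$sequence, "")[[1L]]
      starts <- c(starts, s)
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = ids[p], start = s, end = s + mlen - 1L,
        config = config_label(drawn$config), stringsAsFactors = FALSE)
    }
    seqs[p] <- paste(res, collapse = "")
  }
  # annotation windows (up to 25 residues of context) cut from the final
  # sequences, after all motifs are in place
  for (t in seq_along(truth)) {
    tr <- truth[[t]]
    lenp <- nchar(seqs[[match(tr$protein_id, ids)]])
    ws <- max(1L, min(tr$start, lenp - 25L + 1L))
    cfg <- parse_config_labels(tr$config)
    ann[[t]] <- data.frame(
      id = sprintf("%s:%d", tr$protein_id, tr$start),
      window = substr(seqs[[match(tr$protein_id, ids)]], ws,
                      min(lenp, ws + 24L)),
      nes_start = tr$start - ws + 1L,
      c1 = cfg[1L, 1L], c2 = cfg[1L, 2L], c3 = cfg[1L, 3L],
      stringsAsFactors = FALSE)
  }
  if (shortfall > 0L)
    warning(shortfall, " motif(s) could not be planted (proteins too short or crowded)")
  empty_truth <- data.frame(protein_id = character(0), start = integer(0),
                            end = integer(0), config = character(0))
  list(sequences = stats::setNames(seqs, ids),
       truth = if (length(truth)) do.call(rbind, truth) else empty_truth,
       annotations = if (length(ann)) do.call(rbind, ann) else NULL,
       seed = spec$seed)
}

#' Write a truth table to TSV
#'
#' @param truth Data.frame with at least `protein_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))   # first token of the header
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
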