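#' The canonical amino-acid alphabet
#'
#' Ordered one-letter codes of the 20 canonical amino acids. Every residue
#' distribution in the package is a probability vector named by, and ordered
#' as, this alphabet, and the order is serialized with every model so that
#' scans are reproducible across platforms.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Hydrophobic residue class used for initialization and diagnostics
#'
#' The residue class conventionally accepted at NES hydrophobic anchor
#' positions (Leu, Ile, Val, Met, Phe, Ala, Trp, Tyr). Used to break the
#' hydrophobic/spacer symmetry when initializing expectation-maximization
#' and to orient fitted models canonically.
#'
#' @format Character vector of length 8.
#' @export
HYDROPHOBIC_AA <- c("L", "I", "V", "M", "F", "A", "W", "Y")

#' Encode an amino-acid sequence as alphabet indices
#'
#' Non-canonical letters (X, B, Z, U, *, ...) map to `NA`; downstream
#' likelihood code assigns them an identical flat factor under the motif and
#' background components, so they contribute exactly zero to every
#' log-likelihood ratio.
#'
#' @param x A single character string (one protein or peptide sequence).
#' @param warn Warn when non-canonical residues are present.
#' @return Integer vector of indices into [AA_ALPHABET] (`NA` for
#'   non-canonical residues).
#' @export
encode_sequence <- function(x, warn = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_ALPHABET)
  if (warn && anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    warning(sprintf("sequence contains %d non-canonical residue(s) (%s); they contribute 0 to llr",
                    sum(is.na(idx)), paste(bad, collapse = ",")))
  }
  idx
}

#' Validate and normalize a 20-entry residue probability vector
#'
#' @param p Numeric vector of length 20 (optionally named by [AA_ALPHABET];
#'   names are reordered to the alphabet when present).
#' @param what Label used in error messages.
#' @param positive Require strictly positive entries (background models).
#' @return Named numeric vector over [AA_ALPHABET] summing to 1.
#' @export
residue_model <- function(p, what = "residue model", positive = FALSE) {
  if (!is.numeric(p) || length(p) != 20L)
    stop(what, " must be a numeric vector of length 20")
  if (!is.null(names(p))) {
    if (!setequal(names(p), AA_ALPHABET))
      stop(what, " names must be the 20 canonical amino acids")
    p <- p[AA_ALPHABET]
  } else {
    names(p) <- AA_ALPHABET
  }
  if (any(p < 0)) stop(what, " has negative entries")
  if (positive && any(p <= 0)) stop(what, " must have strictly positive entries")
  if (abs(sum(p) - 1) > 1e-9)
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  p
}

#' Estimate background residue frequencies from sequences
#'
#' Counts canonical residues over a set of protein sequences (e.g. a whole
#' proteome FASTA) and returns relative frequencies, the background model
#' used by both the NES mixture model and the PSSM baseline.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param pseudocount Count added per amino acid before normalizing
#'   (guarantees strictly positive frequencies; default 1).
#' @return Named probability vector over [AA_ALPHABET].
#' @export
background_from_sequences <- function(sequences, pseudocount = 1) {
  stopifnot(is.character(sequences), length(sequences) > 0)
  idx <- unlist(lapply(sequences, encode_sequence, warn = FALSE))
  counts <- tabulate(idx[!is.na(idx)], nbins = 20L) + pseudocount
  residue_model(counts / sum(counts), "background", positive = TRUE)
}

#' Read background residue frequencies from a two-column TSV
#'
#' The file must have columns `residue` and `frequency` (a header is
#' expected), one row per canonical amino acid. Frequencies are renormalized
#' to sum exactly to 1.
#'
#' @param path Path to the TSV file.
#' @return Named probability vector over [AA_ALPHABET].
#' @export
read_background_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "frequency") %in% names(tab)))
    stop("background TSV needs columns 'residue' and 'frequency'")
  p <- stats::setNames(tab$frequency, toupper(tab$residue))
  if (!setequal(names(p), AA_ALPHABET))
    stop("background TSV must cover exactly the 20 canonical amino acids")
  p <- p[AA_ALPHABET]
  residue_model(p / sum(p), "background", positive = TRUE)
}

#' Write background residue frequencies to a two-column TSV
#'
#' @param background Named probability vector over [AA_ALPHABET].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background_tsv <- function(background, path) {
  background <- residue_model(background, "background", positive = TRUE)
  utils::write.table(
    data.frame(residue = names(background), frequency = unname(background)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
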