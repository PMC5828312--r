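#' Construct a fixed-length PSSM model
#'
#' The position-specific scoring matrix baseline: an independent residue
#' distribution per motif column, scored against a background model with
#' the standard log-likelihood ratio. A length-L PSSM has `19 L` free
#' parameters (190 for L = 10), versus 44 for the variable-spacer mixture.
#'
#' @param columns 20 x L numeric matrix of per-column residue
#'   probabilities (rows ordered as [AA_ALPHABET]), or a list of L
#'   20-entry probability vectors.
#' @param background Background residue distribution (strictly positive).
#' @return An object of class `pssm_model`.
#' @export
pssm_model <- function(columns, background) {
  if (is.list(columns)) columns <- do.call(cbind, columns)
  if (!is.matrix(columns) || nrow(columns) != 20L || ncol(columns) < 1L)
    stop("columns must be a 20 x L matrix (L >= 1)")
  columns <- apply(columns, 2L, residue_model, what = "PSSM column")
  rownames(columns) <- AA_ALPHABET
  colnames(columns) <- paste0("pos", seq_len(ncol(columns)))
  structure(list(columns = columns,
                 background = residue_model(background, "background",
                                            positive = TRUE),
                 length = ncol(columns)),
            class = "pssm_model")
}

#' @export
print.pssm_model <- function(x, ...) {
  cat(sprintf("PSSM model, %d columns, %d free parameters\n",
              x$length, n_free_parameters(x)))
  cons <- rownames(x$columns)[apply(x$columns, 2L, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' @export
n_free_parameters.pssm_model <- function(model) {
  model$length * (nrow(model$columns) - 1L)
}

#' Estimate a PSSM from equal-length aligned windows
#'
#' Per-column residue counts with pseudocount smoothing (denominator
#' `N + 20 * pseudocount`).
#'
#' @param aligned_windows Character vector of equal-length amino-acid
#'   windows (the conventional NES alignment uses 12 columns).
#' @param pseudocount Smoothing count per amino acid per column (default 1).
#' @param background Background residue distribution.
#' @return A `pssm_model`.
#' @export
estimate_pssm <- function(aligned_windows, pseudocount = 1, background = NULL) {
  stopifnot(is.character(aligned_windows), length(aligned_windows) > 0)
  lens <- nchar(aligned_windows)
  if (length(unique(lens)) != 1L)
    stop("aligned windows must all have the same length (got lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  L <- lens[1L]
  if (is.null(background)) background <- background_from_sequences(aligned_windows)
  enc <- vapply(aligned_windows, encode_sequence, integer(L), warn = FALSE)
  cols <- matrix(0, 20L, L)
  for (j in seq_len(L)) {
    xj <- enc[j, ]
    counts <- tabulate(xj[!is.na(xj)], nbins = 20L)
    cols[, j] <- (counts + pseudocount) / (sum(counts) + 20 * pseudocount)
  }
  pssm_model(cols, background)
}

#' PSSM log-likelihood ratio of a window
#'
#' Sum over columns of `log(column probability / background probability)`
#' (natural log). Non-canonical residues contribute 0.
#'
#' @param window Amino-acid string exactly as long as the PSSM.
#' @param pssm A `pssm_model`.
#' @return The log-likelihood ratio in nats.
#' @export
pssm_llr <- function(window, pssm) {
  stopifnot(inherits(pssm, "pssm_model"))
  xidx <- encode_sequence(window)
  if (length(xidx) != pssm$length)
    stop("window length ", length(xidx), " does not match PSSM length ",
         pssm$length)
  pssm_llr_encoded(xidx, pssm)
}

pssm_llr_encoded <- function(xidx, pssm) {
  lr <- log(pssm$columns) - log(pssm$background)   # 20 x L score matrix
  v <- lr[cbind(xidx, seq_len(pssm$length))]
  sum(v[!is.na(xidx)])
}

#' Score every start position of a protein with a PSSM
#'
#' @param sequence Amino-acid string.
#' @param pssm A `pssm_model`.
#' @param protein_id Identifier attached to the returned track.
#' @return A data.frame (`protein_id`, `start`, `llr`, `length`), one row
#'   per position `1 .. len - L + 1`; empty with a warning when the
#'   sequence is shorter than the PSSM.
#' @export
scan_protein_pssm <- function(sequence, pssm, protein_id = "protein") {
  stopifnot(inherits(pssm, "pssm_model"))
  xidx <- encode_sequence(sequence)
  L <- pssm$length
  if (length(xidx) < L) {
    warning("sequence '", protein_id, "' shorter than the PSSM; no positions scored")
    return(data.frame(protein_id = character(0), start = integer(0),
                      llr = numeric(0), length = integer(0)))
  }
  lr <- log(pssm$columns) - log(pssm$background)
  lr <- rbind(lr, 0)                     # sentinel row: NA residues score 0
  xi <- xidx; xi[is.na(xi)] <- 21L
  n <- length(xi) - L + 1L
  idx <- outer(seq_len(n), 0:(L - 1L), "+")
  V <- matrix(lr[cbind(as.vector(xi[idx]), rep(seq_len(L), each = n))], n, L)
  data.frame(protein_id = protein_id, start = seq_len(n),
             llr = rowSums(V), length = L, stringsAsFactors = FALSE)
}

#' Serialize a PSSM to JSON
#'
#' @param pssm A `pssm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_model <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm_model"))
  jsonlite::write_json(list(alphabet = AA_ALPHABET,
                            columns = unname(pssm$columns),
                            background = unname(pssm$background)),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a PSSM from its JSON serialization
#'
#' @param path Path to a file written by [write_pssm_model()].
#' @return A `pssm_model`.
#' @export
read_pssm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$alphabet), AA_ALPHABET))
    stop("PSSM file uses an unexpected alphabet order")
  pssm_model(obj$columns, obj$background)
}
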