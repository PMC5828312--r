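#' Scan settings
#'
#' @param window_len Length in residues of the peptide windows used for
#'   posterior decoding (default 25, the conventional NES context window).
#' @param max_start_positions Number of candidate motif start positions
#'   considered within a window (default 12, so a 13-residue padded motif
#'   always fits a 25-residue window). For shorter windows the value is
#'   clamped, with a warning, to `window length - padded length + 1`.
#' @param llr_threshold Score above which a window is reported as a
#'   candidate (default 0: more likely motif than background).
#' @return A list of class `scan_settings`.
#' @export
scan_settings <- function(window_len = 25L, max_start_positions = 12L,
                          llr_threshold = 0) {
  stopifnot(window_len >= 1, max_start_positions >= 1)
  structure(list(window_len = as.integer(window_len),
                 max_start_positions = as.integer(max_start_positions),
                 llr_threshold = llr_threshold),
            class = "scan_settings")
}

# Candidate starts 1..W for a window, clamping W to what the length allows.
clamp_starts <- function(window_nchar, model, settings, warn = TRUE) {
  wmax <- window_nchar - model$total_length + 1L
  if (wmax < 1L) stop("window shorter than the padded motif length (",
                      model$total_length, ")")
  W <- settings$max_start_positions
  if (wmax < W) {
    if (warn) warning("window of ", window_nchar,
                      " residues supports only ", wmax, " start positions")
    W <- wmax
  }
  W
}

# llr and per-config log-likelihoods at every start of an encoded sequence.
# Returns list(llr = numeric track, loglik = n x K matrix, lprior).
scan_core <- function(xidx, model) {
  w <- model$total_length
  n <- length(xidx) - w + 1L
  if (n < 1L) return(list(llr = numeric(0), loglik = NULL))
  lay <- config_layout(model$configs, w)
  vphi <- clamp_neginf(.lookup(log(model$phi), xidx))
  vspa <- clamp_neginf(.lookup(log(model$spacer), xidx))
  vbg  <- .lookup(log(model$background), xidx)
  idx <- outer(seq_len(n), 0:(w - 1L), "+")
  Vphi <- matrix(vphi[idx], n, w)
  Vspa <- matrix(vspa[idx], n, w)
  Vbg  <- matrix(vbg[idx], n, w)
  LL <- restore_neginf(Vphi %*% t(lay$H) + Vspa %*% t(lay$S) + Vbg %*% t(lay$P))
  lprior <- log(config_prior(model))
  Jm <- sweep(LL, 2L, lprior, "+")
  m <- apply(Jm, 1L, max)
  num <- ifelse(is.finite(m), m + log(rowSums(exp(Jm - m))), m)
  den <- rowSums(Vbg)
  list(llr = num - den, loglik = LL, lprior = lprior)
}

#' Score every start position of a protein with the motif llr
#'
#' Computes the log-likelihood ratio of the `model$total_length`-residue
#' stretch beginning at every position `1 .. len - total_length + 1`.
#' Positions too close to the C-terminus to host the padded motif are not
#' scored.
#'
#' @param sequence Amino-acid string.
#' @param model A `nologo_model`.
#' @param protein_id Identifier attached to the returned track.
#' @return A data.frame (`start`, `llr`, `best_config`, `length`) with one
#'   row per scored position; `best_config` is the maximum-posterior
#'   configuration at that start and `length` its motif length. Returns an
#'   empty track with a warning when the sequence is too short.
#' @export
scan_protein <- function(sequence, model, protein_id = "protein") {
  stopifnot(inherits(model, "nologo_model"))
  xidx <- encode_sequence(sequence)
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      llr = numeric(0), best_config = character(0),
                      length = integer(0))
  if (length(xidx) < model$total_length) {
    warning("sequence '", protein_id, "' shorter than the padded motif length; no positions scored")
    return(empty)
  }
  sc <- scan_core(xidx, model)
  J <- sweep(sc$loglik, 2L, sc$lprior, "+")
  best <- max.col(J, ties.method = "first")
  data.frame(protein_id = protein_id,
             start = seq_along(sc$llr),
             llr = sc$llr,
             best_config = rownames(model$configs)[best],
             length = config_length(model$configs)[best],
             stringsAsFactors = FALSE)
}

#' Scan a set of proteins
#'
#' @param sequences Named character vector of protein sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams scan_protein
#' @return Row-bound tracks of [scan_protein()] for every protein.
#' @export
scan_proteins <- function(sequences, model) {
  stopifnot(is.character(sequences))
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("protein", seq_along(sequences))
  do.call(rbind, lapply(seq_along(sequences), function(i)
    scan_protein(sequences[[i]], model, protein_id = ids[[i]])))
}

#' Most probable motif start within a window
#'
#' The start among `1..W` maximizing the llr; ties break toward the
#' smallest index.
#'
#' @param window Amino-acid string of at least `model$total_length`
#'   residues.
#' @param model A `nologo_model`.
#' @param settings A [scan_settings()] object.
#' @return 1-based start position.
#' @export
best_start <- function(window, model, settings = scan_settings()) {
  xidx <- encode_sequence(window)
  W <- clamp_starts(length(xidx), model, settings)
  track <- scan_core(xidx, model)$llr[seq_len(W)]
  which.max(track)   # which.max takes the first maximum: smallest index
}

#' Posterior over spacer configurations at a fixed start
#'
#' Bayes' rule over the allowed configurations for the padded motif
#' beginning at `start`: configuration-conditional likelihood times prior,
#' normalized by the mixture likelihood.
#'
#' @param window Amino-acid string.
#' @param model A `nologo_model`.
#' @param start 1-based start of the candidate motif within `window`.
#' @return Named probability vector over the allowed configurations
#'   (sums to 1).
#' @export
posterior_configurations <- function(window, model, start = 1L) {
  stopifnot(inherits(model, "nologo_model"))
  xidx <- encode_sequence(window)
  if (start < 1L || start + model$total_length - 1L > length(xidx))
    stop("window cannot accommodate ", model$total_length,
         " residues at start ", start)
  lj <- config_loglik(xidx[start + 0:(model$total_length - 1L)], model) +
    log(config_prior(model))
  tot <- logsumexp(lj)
  if (!is.finite(tot))
    stop("window has zero likelihood under the model at this start")
  exp(lj - tot)
}

#' Posterior over motif start positions within a window
#'
#' Normalizes the marginal likelihood of the padded motif across candidate
#' starts `1..W` (uniform prior over starts).
#'
#' @inheritParams best_start
#' @return Probability vector over starts `1..W` (sums to 1).
#' @export
posterior_start <- function(window, model, settings = scan_settings()) {
  xidx <- encode_sequence(window)
  W <- clamp_starts(length(xidx), model, settings)
  lls <- vapply(seq_len(W), function(s)
    logsumexp(config_loglik(xidx[s + 0:(model$total_length - 1L)], model) +
                log(config_prior(model))),
    numeric(1))
  tot <- logsumexp(lls)
  if (!is.finite(tot)) stop("window has zero likelihood at every start")
  exp(lls - tot)
}

#' Per-residue posterior probability of being a hydrophobic anchor
#'
#' For each residue `k` of the window, sums over candidate starts `i` and
#' configurations `C` the product of the start posterior, the
#' configuration posterior given that start, and the indicator that
#' configuration `C` places a hydrophobic anchor at offset `k - i`.
#' Because every configuration has exactly four anchors, the vector always
#' sums to 4.
#'
#' @inheritParams best_start
#' @param marginalize_start If `TRUE` (default) starts are marginalized
#'   with their posterior weights; if `FALSE` all weight is placed on the
#'   llr-best start (the "best start" view of the same decomposition).
#' @return Numeric vector, one entry per window residue, each in `[0, 1]`.
#' @export
posterior_hydrophobic <- function(window, model, settings = scan_settings(),
                                  marginalize_start = TRUE) {
  xidx <- encode_sequence(window)
  W <- clamp_starts(length(xidx), model, settings)
  if (marginalize_start) {
    ps <- posterior_start(window, model, settings)
  } else {
    ps <- numeric(W)
    ps[best_start(window, model, settings)] <- 1
  }
  lay <- config_layout(model$configs, model$total_length)
  out <- numeric(length(xidx))
  for (i in seq_len(W)) {
    if (ps[i] == 0) next
    pc <- posterior_configurations(window, model, start = i)
    anchor <- drop(pc %*% lay$H)            # P(offset is anchor | start = i)
    span <- i + 0:(model$total_length - 1L)
    out[span] <- out[span] + ps[i] * anchor
  }
  out
}

#' Full posterior decoding of one window
#'
#' @inheritParams posterior_hydrophobic
#' @return A list of class `nologo_posterior` with elements `best_start`,
#'   `config_posterior` (at the best start), `start_posterior` and
#'   `hydrophobic_posterior`, plus the window itself.
#' @export
posterior_profile <- function(window, model, settings = scan_settings(),
                              marginalize_start = TRUE) {
  bs <- best_start(window, model, settings)
  structure(list(
    window = window,
    best_start = bs,
    config_posterior = posterior_configurations(window, model, start = bs),
    start_posterior = posterior_start(window, model, settings),
    hydrophobic_posterior = posterior_hydrophobic(window, model, settings,
                                                  marginalize_start)
  ), class = "nologo_posterior")
}

#' @export
print.nologo_posterior <- function(x, ...) {
  cat("Posterior decoding of", nchar(x$window), "residue window\n")
  cat("  best start:", x$best_start, "\n")
  top <- sort(x$config_posterior, decreasing = TRUE)[1:3]
  cat("  top configurations:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Align hydrophobic-posterior profiles on their best-scoring start
#'
#' Shifts each profile so its llr-best start falls in the `anchor` column
#' (column 6 by convention), for heat-map display of many windows. Residues
#' shifted outside the matrix are dropped; vacated cells are `NA`. Profiles
#' from windows shorter than the matrix width are placed by the same rule
#' but clamped so they remain within the matrix (edge-anchored).
#'
#' @param profiles List of `nologo_posterior` objects (or a list of lists
#'   with elements `hydrophobic_posterior` and `best_start`).
#' @param anchor Column at which each profile's best start is placed
#'   (default 6).
#' @param width Number of columns of the output matrix (default: longest
#'   profile).
#' @return Numeric matrix, one row per profile, `NA` for unoccupied cells.
#' @export
align_profiles_for_heatmap <- function(profiles, anchor = 6L, width = NULL) {
  hp <- lapply(profiles, `[[`, "hydrophobic_posterior")
  bs <- vapply(profiles, `[[`, numeric(1), "best_start")
  if (is.null(width)) width <- max(lengths(hp))
  out <- matrix(NA_real_, length(hp), width)
  for (r in seq_along(hp)) {
    len <- length(hp[[r]])
    shift <- anchor - bs[r]
    if (len < width)   # short window: keep it whole (edge-anchor)
      shift <- min(max(shift, 0L), width - len)
    pos <- seq_len(len) + shift
    keep <- pos >= 1L & pos <= width
    out[r, pos[keep]] <- hp[[r]][keep]
  }
  rownames(out) <- names(profiles)
  out
}
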