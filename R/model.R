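#' Construct a variable-spacer NES mixture model
#'
#' The model treats an NES as four hydrophobic anchor residues drawn from a
#' shared distribution `phi`, separated by three spacers whose residues are
#' drawn from a shared distribution `spacer` and whose lengths follow
#' `spacer_lengths`. Marginalizing over the allowed spacer configurations
#' gives a mixture (27 components for the full 1..3 spacer range) in which
#' all components share the same 44 free parameters: 2 x 19 residue
#' parameters plus 3 x 2 spacer-length parameters.
#'
#' Because components have different motif lengths, every component's
#' probability is padded with background-generated residues up to the
#' longest allowed configuration (13 residues for the full set), so that
#' all mixture components are probabilities over the same number of
#' residues and their posteriors are comparable.
#'
#' @param phi Hydrophobic-position residue distribution (20 probabilities
#'   over [AA_ALPHABET]).
#' @param spacer Spacer-position residue distribution (20 probabilities).
#' @param spacer_lengths 3x3 matrix; row `a`, column `b` is the probability
#'   that spacer `a` has length `b` residues. Rows must each sum to 1.
#' @param background Background residue distribution (strictly positive).
#' @param configs Allowed spacer configurations (matrix as returned by
#'   [enumerate_configurations()], or character labels like `"3-2-1"`).
#'   Defaults to the full 27-configuration set.
#' @param pseudocount Pseudocount recorded with the model (provenance only).
#' @return An object of class `nologo_model`.
#' @examples
#' m <- nologo_model(
#'   phi = rep(1/20, 20), spacer = rep(1/20, 20),
#'   spacer_lengths = matrix(1/3, 3, 3), background = rep(1/20, 20))
#' m$total_length   # 13
#' @export
nologo_model <- function(phi, spacer, spacer_lengths, background,
                         configs = enumerate_configurations(),
                         pseudocount = NA_real_) {
  if (is.character(configs)) configs <- parse_config_labels(configs)
  configs <- as_config_matrix(configs)
  if (nrow(configs) < 1L) stop("need at least one allowed configuration")
  if (!is.matrix(spacer_lengths) || !all(dim(spacer_lengths) == c(3L, 3L)))
    stop("spacer_lengths must be a 3x3 matrix")
  if (any(spacer_lengths < 0)) stop("spacer_lengths has negative entries")
  if (any(abs(rowSums(spacer_lengths) - 1) > 1e-9))
    stop("each spacer_lengths row must sum to 1")
  if (max(configs) > ncol(spacer_lengths))
    stop("a configuration uses a spacer length outside the spacer_lengths support")
  dimnames(spacer_lengths) <- list(paste0("spacer", 1:3),
                                   paste0("len", seq_len(ncol(spacer_lengths))))
  model <- structure(list(
    alphabet = AA_ALPHABET,
    phi = residue_model(phi, "phi"),
    spacer = residue_model(spacer, "spacer"),
    spacer_lengths = spacer_lengths,
    background = residue_model(background, "background", positive = TRUE),
    configs = configs,
    total_length = max(config_length(configs)),
    pseudocount = pseudocount
  ), class = "nologo_model")
  model
}

#' @export
print.nologo_model <- function(x, ...) {
  cat("Variable-spacer NES mixture model\n")
  cat(sprintf("  %d allowed configurations, motif lengths %d-%d (padded to %d)\n",
              nrow(x$configs), min(config_length(x$configs)),
              max(config_length(x$configs)), x$total_length))
  cat(sprintf("  %d free parameters\n", n_free_parameters(x)))
  top <- function(p) paste(sprintf("%s=%.2f", names(sort(p, decreasing = TRUE))[1:3],
                                   sort(p, decreasing = TRUE)[1:3]), collapse = " ")
  cat("  phi   :", top(x$phi), "\n")
  cat("  spacer:", top(x$spacer), "\n")
  pr <- sort(config_prior(x), decreasing = TRUE)
  cat(sprintf("  most probable configuration: %s (prior %.3f)\n",
              names(pr)[1L], pr[1L]))
  invisible(x)
}

#' Number of free parameters of a motif model
#'
#' For the variable-spacer mixture: 19 free parameters for each of the two
#' shared residue distributions plus 2 for each of the three spacer-length
#' rows, i.e. 44. For a PSSM of length L: 19 L (190 for L = 10).
#'
#' @param model A `nologo_model` or `pssm_model`.
#' @return Integer count of free parameters.
#' @export
n_free_parameters <- function(model) UseMethod("n_free_parameters")

#' @export
n_free_parameters.nologo_model <- function(model) {
  2L * (length(model$alphabet) - 1L) + 3L * (ncol(model$spacer_lengths) - 1L)
}

#' Prior probability of each allowed spacer configuration
#'
#' The product of the three spacer-length probabilities, renormalized over
#' the model's allowed configuration set (for the full 27-configuration set
#' the product form already sums to 1).
#'
#' @param model A `nologo_model`.
#' @param config Optionally, a single configuration whose prior to return;
#'   must be in the allowed set.
#' @return Named probability vector over the allowed configurations (or a
#'   single probability when `config` is given).
#' @export
config_prior <- function(model, config = NULL) {
  stopifnot(inherits(model, "nologo_model"))
  cm <- model$configs
  raw <- model$spacer_lengths[cbind(1L, cm[, 1L])] *
         model$spacer_lengths[cbind(2L, cm[, 2L])] *
         model$spacer_lengths[cbind(3L, cm[, 3L])]
  pr <- stats::setNames(raw / sum(raw), rownames(cm))
  if (is.null(config)) return(pr)
  lab <- config_label(as_config_matrix(config))
  if (!lab %in% names(pr)) stop("configuration ", lab, " is not in the allowed set")
  pr[[lab]]
}

# Log-probability lookups for an encoded window; NA (non-canonical) residues
# get log-probability 0 under every component so they cancel in the llr.
.lookup <- function(logp, idx) {
  v <- logp[idx]
  v[is.na(idx)] <- 0
  v
}

# The 0/1 layout masks enter matrix products, where 0 * -Inf would give NaN;
# zero-probability factors are clamped to a sentinel far below any legitimate
# 13-residue log-likelihood and restored to -Inf afterwards.
.NEGINF_SENTINEL <- -1e9

clamp_neginf <- function(x) {
  x[x == -Inf] <- .NEGINF_SENTINEL
  x
}

restore_neginf <- function(x) {
  x[x < .NEGINF_SENTINEL / 100] <- -Inf
  x
}

# Per-configuration log-likelihoods of the first `total_length` residues of
# an encoded window: anchors under phi, spacers under `spacer`, positions
# beyond the configuration's own length under the background (padding).
# Returns a named vector over the allowed configurations.
config_loglik <- function(xidx, model) {
  w <- model$total_length
  if (length(xidx) < w) stop("window shorter than the model's total length (", w, ")")
  xidx <- xidx[seq_len(w)]
  lay <- config_layout(model$configs, w)
  vphi <- clamp_neginf(.lookup(log(model$phi), xidx))
  vspa <- clamp_neginf(.lookup(log(model$spacer), xidx))
  vbg  <- .lookup(log(model$background), xidx)
  restore_neginf(drop(lay$H %*% vphi + lay$S %*% vspa + lay$P %*% vbg))
}

#' Likelihood of a window under one spacer configuration
#'
#' The probability of the first `model$total_length` residues of `window`:
#' hydrophobic anchors under `phi`, spacer positions under `spacer`, and
#' residues beyond the configuration's own length under the background
#' model (so that all configurations describe the same number of residues).
#'
#' @param window Amino-acid string, at least `model$total_length` residues.
#' @param config A single allowed configuration.
#' @param model A `nologo_model`.
#' @param log Return the log-likelihood instead of the probability.
#' @return A probability (or log-probability).
#' @export
likelihood_given_config <- function(window, config, model, log = FALSE) {
  stopifnot(inherits(model, "nologo_model"))
  lab <- config_label(as_config_matrix(config))
  if (!lab %in% rownames(model$configs))
    stop("configuration ", lab, " is not in the allowed set")
  ll <- config_loglik(encode_sequence(window), model)[[lab]]
  if (log) ll else exp(ll)
}

#' Marginal likelihood of a window under the mixture model
#'
#' Sums the configuration-conditional likelihoods weighted by the
#' (renormalized) configuration prior. Computed in log space with
#' log-sum-exp.
#'
#' @inheritParams likelihood_given_config
#' @return A probability (or log-probability).
#' @export
likelihood <- function(window, model, log = FALSE) {
  stopifnot(inherits(model, "nologo_model"))
  ll <- logsumexp(config_loglik(encode_sequence(window), model) +
                    log(config_prior(model)))
  if (log) ll else exp(ll)
}

#' Log-likelihood ratio of a window: motif mixture vs background
#'
#' The natural-log ratio of the mixture likelihood of the first
#' `model$total_length` residues to their probability under the background
#' model. The background mixture over configurations with uniform weights
#' collapses to the plain background product because the weights sum to 1.
#' Windows scoring above 0 are candidate motif instances.
#'
#' @inheritParams likelihood_given_config
#' @param base Logarithm base for the returned score: `"nat"` (default,
#'   natural log) or `"log2"` for bits.
#' @return The log-likelihood ratio (a float; 0 means indistinguishable
#'   from background).
#' @export
llr <- function(window, model, base = c("nat", "log2")) {
  base <- match.arg(base)
  stopifnot(inherits(model, "nologo_model"))
  xidx <- encode_sequence(window)
  score <- llr_encoded(xidx, model)
  if (base == "log2") score / log(2) else score
}

# llr on an already encoded window (internal fast path).
llr_encoded <- function(xidx, model) {
  num <- logsumexp(config_loglik(xidx, model) + log(config_prior(model)))
  den <- sum(.lookup(log(model$background), xidx[seq_len(model$total_length)]))
  num - den
}

# Numerically stable log(sum(exp(x))); -Inf inputs are handled exactly.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Serialize a model to JSON
#'
#' Writes the alphabet order, the four distributions, the allowed
#' configuration list and the recorded pseudocount, so a scan can be
#' reproduced bit-for-bit from the file.
#'
#' @param model A `nologo_model`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_nologo_model <- function(model, path) {
  stopifnot(inherits(model, "nologo_model"))
  obj <- list(
    alphabet = model$alphabet,
    phi = unname(model$phi),
    spacer = unname(model$spacer),
    spacer_lengths = unname(model$spacer_lengths),
    background = unname(model$background),
    allowed_configs = unname(model$configs),
    pseudocount_used = model$pseudocount
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a model from its JSON serialization
#'
#' @param path Path to a file written by [write_nologo_model()].
#' @return A `nologo_model`.
#' @export
read_nologo_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$alphabet), AA_ALPHABET))
    stop("model file uses an unexpected alphabet order")
  ps <- obj$pseudocount_used
  nologo_model(phi = obj$phi, spacer = obj$spacer,
               spacer_lengths = obj$spacer_lengths,
               background = obj$background,
               configs = obj$allowed_configs,
               pseudocount = if (is.null(ps)) NA_real_ else ps)
}
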