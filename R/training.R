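#' Read motif training annotations from TSV
#'
#' The annotation format is the machine-readable equivalent of a hand
#' alignment: columns `id`, `window` (amino-acid sequence), `nes_start`
#' (1-based position of the first hydrophobic anchor within the window) and
#' `c1`, `c2`, `c3` (the spacer configuration).
#'
#' @param path Path to the annotation TSV (header required).
#' @return A data.frame with the columns above.
#' @export
read_nes_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "window", "nes_start", "c1", "c2", "c3")
  if (!all(need %in% names(tab)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  validate_annotations(tab)
  tab
}

validate_annotations <- function(annotations) {
  if (nrow(annotations) == 0L) stop("no annotations supplied")
  lens <- config_length(annotations[, c("c1", "c2", "c3")])
  over <- annotations$nes_start + lens - 1L > nchar(annotations$window)
  if (any(annotations$nes_start < 1L))
    stop("annotation(s) with nes_start < 1: ",
         paste(annotations$id[annotations$nes_start < 1L], collapse = ", "))
  if (any(over))
    stop("annotated motif overruns its window for record(s): ",
         paste(annotations$id[over], collapse = ", "))
  invisible(annotations)
}

#' Estimate model parameters from an annotated alignment
#'
#' Supervised estimation by counting, with pseudocount smoothing. The
#' hydrophobic distribution pools the residues at all four anchor positions
#' of every motif (denominator `4N + 20 * pseudocount`); the spacer
#' distribution pools all spacer-position residues; the spacer-length rows
#' count each spacer slot's observed sizes (denominator
#' `N + n_sizes * pseudocount`, with `n_sizes = 3`).
#'
#' @param annotations Data.frame as returned by [read_nes_annotations()],
#'   or a list of such rows.
#' @param pseudocount Smoothing count added per amino acid / spacer size
#'   (default 1).
#' @param background Background residue distribution to attach to the model.
#' @param configs Allowed configuration set of the resulting model
#'   (default: all 27).
#' @return A `nologo_model`.
#' @examples
#' ann <- data.frame(id = "ex", window = "LEEELEELELXXX",
#'                   nes_start = 1, c1 = 3, c2 = 2, c3 = 1)
#' m <- estimate_from_alignment(ann, background = rep(1/20, 20))
#' m$spacer_lengths[1, ]   # spacer 1: one observation of length 3
#' @export
estimate_from_alignment <- function(annotations, pseudocount = 1,
                                    background = NULL,
                                    configs = enumerate_configurations()) {
  annotations <- as.data.frame(annotations)
  validate_annotations(annotations)
  if (is.null(background)) background <- background_from_sequences(annotations$window)
  n_sizes <- 3L
  phi_counts <- spa_counts <- stats::setNames(numeric(20L), AA_ALPHABET)
  len_counts <- matrix(0, 3L, n_sizes)
  for (r in seq_len(nrow(annotations))) {
    cfg <- as_config_matrix(as.integer(annotations[r, c("c1", "c2", "c3")]))
    if (max(cfg) > n_sizes)
      stop("annotation ", annotations$id[r], " uses a spacer longer than ", n_sizes)
    xidx <- encode_sequence(annotations$window[r], warn = FALSE)
    s0 <- annotations$nes_start[r]           # 1-based anchor position
    hy <- s0 + hydrophobic_offsets(cfg)
    sp <- s0 + spacer_offsets(cfg)
    hi <- xidx[hy]; si <- xidx[sp]
    phi_counts <- phi_counts + tabulate(hi[!is.na(hi)], nbins = 20L)
    spa_counts <- spa_counts + tabulate(si[!is.na(si)], nbins = 20L)
    len_counts[cbind(1:3, as.integer(cfg))] <- len_counts[cbind(1:3, as.integer(cfg))] + 1
  }
  phi <- (phi_counts + pseudocount) / (sum(phi_counts) + 20 * pseudocount)
  spa <- (spa_counts + pseudocount) / (sum(spa_counts) + 20 * pseudocount)
  sl <- (len_counts + pseudocount) / (rowSums(len_counts) + n_sizes * pseudocount)
  nologo_model(phi = phi, spacer = spa, spacer_lengths = sl,
               background = background, configs = configs,
               pseudocount = pseudocount)
}

#' Expectation-maximization settings
#'
#' @param max_iter Maximum number of E-M iterations (default 500).
#' @param tol Relative total log-likelihood change below which iteration
#'   stops (default 1e-6).
#' @param seed Seed for the random-perturbation initialization mode.
#' @param pseudocount Smoothing applied inside every M-step (default 1),
#'   the same rule as supervised estimation; prevents zero-collapse.
#' @param init_mode `"hydrophobic"` (default): initialize the anchor
#'   distribution by up-weighting the hydrophobic residue class
#'   ([HYDROPHOBIC_AA]) threefold over background, breaking the
#'   anchor/spacer symmetry; `"random"`: seeded multiplicative perturbation
#'   of the background for both residue distributions.
#' @param max_start_positions Largest number of latent start positions per
#'   window (default 12; clamped per window to what its length allows).
#' @return A list of class `em_settings`.
#' @export
em_settings <- function(max_iter = 500L, tol = 1e-6, seed = 1L,
                        pseudocount = 1, init_mode = c("hydrophobic", "random"),
                        max_start_positions = 12L) {
  stopifnot(max_iter >= 1, tol > 0, pseudocount >= 0, max_start_positions >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), pseudocount = pseudocount,
                 init_mode = match.arg(init_mode),
                 max_start_positions = as.integer(max_start_positions)),
            class = "em_settings")
}

#' Fit the mixture model to unaligned windows by expectation-maximization
#'
#' Treats both the motif start position (within the first
#' `max_start_positions` residues of each window, uniformly a priori) and
#' the spacer configuration as latent variables. The E-step computes each
#' window's joint posterior over (start, configuration) under the current
#' parameters; the M-step re-estimates the anchor and spacer residue
#' distributions and the spacer-length rows from posterior-weighted counts
#' with pseudocount smoothing. The spacer-length prior starts uniform so the
#' fit is unbiased with respect to expectations about motif architecture.
#'
#' After convergence a label-switching guard enforces the canonical
#' orientation: if the spacer distribution carries more mass on
#' [HYDROPHOBIC_AA] than the anchor distribution, the two are swapped and
#' the spacer-length rows reversed.
#'
#' @param windows Character vector of unaligned amino-acid windows, each at
#'   least as long as the model's padded motif length (13 for the default
#'   configuration set).
#' @param background Background residue distribution (held fixed).
#' @param settings An [em_settings()] object.
#' @param configs Allowed configuration set (default: all 27).
#' @return A list with elements `model` (the fitted `nologo_model`),
#'   `loglik` (per-iteration total data log-likelihood trace, non-decreasing)
#'   and `iterations`.
#' @export
em_fit <- function(windows, background, settings = em_settings(),
                   configs = enumerate_configurations()) {
  stopifnot(is.character(windows), length(windows) > 0,
            inherits(settings, "em_settings"))
  configs <- as_config_matrix(configs)
  width <- max(config_length(configs))
  short <- nchar(windows) < width
  if (any(short))
    stop(sum(short), " window(s) shorter than the padded motif length (", width, ")")
  background <- residue_model(background, "background", positive = TRUE)
  n_sizes <- 3L
  pc <- settings$pseudocount

  # Enumerate every (window, start) candidate placement once; X holds the
  # residue indices of each placement's `width`-residue stretch.
  enc <- lapply(windows, encode_sequence, warn = FALSE)
  nstarts <- pmin(nchar(windows) - width + 1L, settings$max_start_positions)
  rows <- do.call(rbind, unlist(lapply(seq_along(enc), function(w) {
    lapply(seq_len(nstarts[w]), function(s) c(w, s))
  }), recursive = FALSE))
  X <- t(vapply(seq_len(nrow(rows)),
                function(r) enc[[rows[r, 1L]]][rows[r, 2L] + 0:(width - 1L)],
                integer(width)))
  group <- rows[, 1L]
  lay <- config_layout(configs, width)
  lbg_row <- rowSums(matrix(.lookup(log(background), X), nrow(X), width))

  lookup_mat <- function(logp) matrix(.lookup(logp, X), nrow(X), width)
  init <- em_init(background, settings)
  phi <- init$phi; spa <- init$spacer
  sl <- matrix(1 / n_sizes, 3L, n_sizes)
  trace <- numeric(0)
  ll_prev <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: joint log posterior over (start, configuration) per window
    prior <- config_prior_raw(sl, configs)
    LL <- restore_neginf(
      lookup_mat(clamp_neginf(log(phi))) %*% t(lay$H) +
      lookup_mat(clamp_neginf(log(spa))) %*% t(lay$S) +
      lookup_mat(log(background)) %*% t(lay$P))
    J <- sweep(LL, 2L, log(prior), "+") - log(nstarts[group])
    wmax <- vapply(split(seq_len(nrow(J)), group),
                   function(ix) max(J[ix, ]), numeric(1))
    ll_w <- wmax + log(vapply(split(seq_len(nrow(J)), group),
                              function(ix) sum(exp(J[ix, ] - max(J[ix, ]))),
                              numeric(1)))
    post <- exp(J - ll_w[group])
    ll <- sum(ll_w)
    trace <- c(trace, ll)
    # M-step: posterior-weighted counts with pseudocount smoothing
    phi_w <- post %*% lay$H
    spa_w <- post %*% lay$S
    phi_counts <- weight_by_residue(X, phi_w)
    spa_counts <- weight_by_residue(X, spa_w)
    phi <- (phi_counts + pc) / (sum(phi_counts) + 20 * pc)
    spa <- (spa_counts + pc) / (sum(spa_counts) + 20 * pc)
    cs <- colSums(post)
    len_counts <- matrix(0, 3L, n_sizes)
    for (a in 1:3) for (b in seq_len(n_sizes))
      len_counts[a, b] <- sum(cs[configs[, a] == b])
    sl <- (len_counts + pc) / (rowSums(len_counts) + n_sizes * pc)
    done <- iter >= settings$max_iter ||
      (is.finite(ll_prev) && abs(ll - ll_prev) <= settings$tol * abs(ll_prev))
    ll_prev <- ll
    if (done) break
  }

  # Canonical orientation: anchors must be the more hydrophobic role
  hmass <- function(p) sum(p[HYDROPHOBIC_AA])
  if (hmass(spa) > hmass(phi)) {
    tmp <- phi; phi <- spa; spa <- tmp
    sl <- sl[3:1, , drop = FALSE]
  }
  model <- nologo_model(phi = phi, spacer = spa, spacer_lengths = sl,
                        background = background, configs = configs,
                        pseudocount = pc)
  list(model = model, loglik = trace, iterations = iter)
}

# Unnormalized-prior helper shared with config_prior (sl rows already sum to 1,
# but restriction to a subset of configurations requires renormalization).
config_prior_raw <- function(sl, configs) {
  raw <- sl[cbind(1L, configs[, 1L])] * sl[cbind(2L, configs[, 2L])] *
         sl[cbind(3L, configs[, 3L])]
  raw / sum(raw)
}

# Accumulate cell weights W (same shape as X) into 20 residue bins.
weight_by_residue <- function(X, W) {
  ok <- !is.na(X)
  counts <- numeric(20L)
  agg <- tapply(W[ok], X[ok], sum)
  counts[as.integer(names(agg))] <- agg
  stats::setNames(counts, AA_ALPHABET)
}

em_init <- function(background, settings) {
  if (settings$init_mode == "hydrophobic") {
    phi <- background
    phi[HYDROPHOBIC_AA] <- 3 * phi[HYDROPHOBIC_AA]
    phi <- phi / sum(phi)
    spa <- background
  } else {
    rng <- local({ set.seed(settings$seed); list(
      a = stats::runif(20L, 0.5, 1.5), b = stats::runif(20L, 0.5, 1.5)) })
    phi <- background * rng$a; phi <- phi / sum(phi)
    spa <- background * rng$b; spa <- spa / sum(spa)
  }
  list(phi = stats::setNames(phi, AA_ALPHABET),
       spacer = stats::setNames(spa, AA_ALPHABET))
}
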