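# Independent brute-force reference implementations, deliberately written in
# plain probability space with explicit loops (no sharing with the package's
# log-space/matrix code paths), plus random fixture builders.

aa_index <- function(ch) match(ch, nologo::AA_ALPHABET)

# Explicit mixture likelihood: sum over every allowed configuration of the
# product of per-position probabilities, padded with background terms.
bf_mixture_likelihood <- function(window, model) {
  x <- strsplit(window, "", fixed = TRUE)[[1L]]
  w <- model$total_length
  pr <- config_prior(model)
  total <- 0
  for (k in seq_len(nrow(model$configs))) {
    cfg <- model$configs[k, , drop = FALSE]
    p <- 1
    for (o in hydrophobic_offsets(cfg)) p <- p * model$phi[[aa_index(x[o + 1L])]]
    for (o in spacer_offsets(cfg)) p <- p * model$spacer[[aa_index(x[o + 1L])]]
    len <- config_length(cfg)
    if (len < w)
      for (o in seq.int(len, w - 1L)) p <- p * model$background[[aa_index(x[o + 1L])]]
    total <- total + p * pr[[k]]
  }
  total
}

bf_config_terms <- function(window, model) {
  pr <- config_prior(model)
  vapply(seq_len(nrow(model$configs)), function(k) {
    cfg <- model$configs[k, , drop = FALSE]
    likelihood_given_config(window, cfg, model) * pr[[k]]
  }, numeric(1))
}

bf_config_posterior <- function(window, model) {
  terms <- bf_config_terms(window, model)
  terms / sum(terms)
}

bf_start_posterior <- function(window, model, W) {
  liks <- vapply(seq_len(W), function(s) {
    sub <- substr(window, s, s + model$total_length - 1L)
    bf_mixture_likelihood(sub, model)
  }, numeric(1))
  liks / sum(liks)
}

bf_hydrophobic_posterior <- function(window, model, W) {
  ps <- bf_start_posterior(window, model, W)
  n <- nchar(window)
  out <- numeric(n)
  for (i in seq_len(W)) {
    sub <- substr(window, i, i + model$total_length - 1L)
    pc <- bf_config_posterior(sub, model)
    for (k in seq_len(nrow(model$configs))) {
      cfg <- model$configs[k, , drop = FALSE]
      for (b in hydrophobic_offsets(cfg)) {
        pos <- i + b
        out[pos] <- out[pos] + ps[i] * pc[k]
      }
    }
  }
  out
}

# Two-sided Fisher's exact p-value by exhaustive enumeration over all 2x2
# tables with the observed margins, from hypergeometric point probabilities
# computed directly with choose().
bf_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  pt <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  probs <- vapply(lo:hi, pt, numeric(1))
  p_obs <- pt(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random valid model with all 27 configurations (Dirichlet-like draws).
random_model <- function(seed, configs = enumerate_configurations()) {
  set.seed(seed)
  draw <- function(n, conc = 1) { g <- stats::rgamma(n, conc); g / sum(g) }
  sl <- rbind(draw(3), draw(3), draw(3))
  nologo_model(phi = draw(20), spacer = draw(20), spacer_lengths = sl,
               background = draw(20, conc = 5) * 0.98 + 0.001,
               configs = configs)
}

random_window <- function(n = 25L) {
  paste(sample(nologo::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Windows sampled from a model together with their true annotations.
sample_annotated <- function(model, n, window_len = 25L) {
  sims <- lapply(seq_len(n), function(i) sample_window(model, window_len))
  ann <- data.frame(
    id = paste0("w", seq_len(n)),
    window = vapply(sims, `[[`, character(1), "window"),
    nes_start = vapply(sims, `[[`, integer(1), "nes_start"),
    t(vapply(sims, function(s) as.integer(s$config), integer(3))),
    stringsAsFactors = FALSE)
  names(ann)[4:6] <- c("c1", "c2", "c3")
  ann
}

# Plant one motif drawn from `model` (re-drawn until its in-context llr
# exceeds `min_llr`) at `pos` in a background protein of length `len`.
plant_high_scoring <- function(model, len = 100L, pos = 40L, min_llr = 7) {
  prot <- sample(nologo::AA_ALPHABET, len, replace = TRUE,
                 prob = model$background)
  repeat {
    drawn <- sample_nes(model)
    cand <- prot
    cand[pos + 0:(nchar(drawn$sequence) - 1L)] <-
      strsplit(drawn$sequence, "", fixed = TRUE)[[1L]]
    sq <- paste(cand, collapse = "")
    if (llr(substr(sq, pos, pos + model$total_length - 1L), model) > min_llr)
      return(sq)
  }
}
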