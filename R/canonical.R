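#' Typical proteome background residue frequencies
#'
#' Average amino-acid frequencies of globular proteins (Robinson-Robinson
#' style), a standard stand-in background when no proteome FASTA is at
#' hand. For real scans, estimate the background from the proteome under
#' study with [background_from_sequences()].
#'
#' @return Named probability vector over [AA_ALPHABET].
#' @export
typical_background <- function() {
  bg <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
          Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
          L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
          S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)
  residue_model((bg / sum(bg))[AA_ALPHABET], "background", positive = TRUE)
}

#' A synthetic NES-like generating model
#'
#' A fixed, fully synthetic model with the qualitative features reported
#' for Crm1-dependent NESs: hydrophobic anchors dominated by leucine
#' (p(L) = 0.6, then I/V/F/M), spacers with a moderate acidic/polar
#' preference, and spacer lengths favouring the classical 3-2-1
#' configuration. It is not fitted to any curated NES collection; it
#' exists so that training, scanning and the evaluation harness can be
#' exercised end-to-end on simulated proteomes with a known ground truth.
#'
#' @param phi_L Probability of leucine at anchor positions (default 0.6;
#'   the remaining anchor mass keeps its default proportions). Lowering it
#'   weakens the separation between motif and background.
#' @param background Background distribution (default [typical_background()]).
#' @param configs Allowed configuration set (default: all 27).
#' @return A `nologo_model`.
#' @export
synthetic_nes_model <- function(phi_L = 0.6, background = typical_background(),
                                configs = enumerate_configurations()) {
  stopifnot(phi_L > 0, phi_L < 1)
  phi <- stats::setNames(rep(0.0025, 20L), AA_ALPHABET)
  phi[c("L", "I", "V", "F", "M", "A", "W", "Y")] <-
    c(0.60, 0.10, 0.08, 0.08, 0.05, 0.03, 0.015, 0.015)
  # rescale the non-L anchor mass so p(L) = phi_L and the vector sums to 1
  phi["L"] <- 0
  phi <- phi / sum(phi) * (1 - phi_L)
  phi["L"] <- phi_L
  spa <- stats::setNames(rep(0.0075, 20L), AA_ALPHABET)
  spa[c("E", "D", "S", "Q", "N", "T", "K", "G", "R", "P", "A", "H")] <-
    c(0.18, 0.14, 0.11, 0.08, 0.07, 0.07, 0.06, 0.06, 0.05, 0.05, 0.04, 0.03)
  spa <- spa / sum(spa)
  sl <- rbind(c(0.15, 0.25, 0.60),
              c(0.25, 0.55, 0.20),
              c(0.60, 0.25, 0.15))
  nologo_model(phi = phi, spacer = spa, spacer_lengths = sl,
               background = background, configs = configs)
}
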