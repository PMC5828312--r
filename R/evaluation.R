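#' Collect candidate predictions from a scored track
#'
#' Keeps every scored position with llr strictly greater than `threshold`
#' (default 0: more likely motif than background), as prediction records
#' with 1-based inclusive coordinates.
#'
#' @param track A track as returned by [scan_protein()],
#'   [scan_proteins()] or [scan_protein_pssm()].
#' @param threshold Score cut-off (strict inequality).
#' @return Data.frame with columns `protein_id`, `start`, `end`, `score`.
#' @export
collect_candidates <- function(track, threshold = 0) {
  keep <- track$llr > threshold
  data.frame(protein_id = track$protein_id[keep],
             start = track$start[keep],
             end = track$start[keep] + track$length[keep] - 1L,
             score = track$llr[keep],
             stringsAsFactors = FALSE)
}

#' Read a truth set of motif coordinates from TSV
#'
#' Columns `protein_id`, `start`, `end` (1-based inclusive).
#'
#' @param path Path to the truth TSV (header required).
#' @return Data.frame of truth records.
#' @export
read_truth_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "start", "end") %in% names(tab)))
    stop("truth TSV needs columns protein_id, start, end")
  if (any(tab$start > tab$end)) stop("truth records with start > end")
  tab
}

#' Read predictions from a generic TSV
#'
#' Accepts the track/candidate format of this package or external
#' predictor output with columns `protein_id`, `start`, `score` and either
#' `end` or `length`.
#'
#' @param path Path to the prediction TSV (header required).
#' @return Data.frame with columns `protein_id`, `start`, `end`, `score`.
#' @export
read_predictions_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(tab$score) && !is.null(tab$llr)) tab$score <- tab$llr
  if (is.null(tab$end) && !is.null(tab$length))
    tab$end <- tab$start + tab$length - 1L
  need <- c("protein_id", "start", "end", "score")
  if (!all(need %in% names(tab)))
    stop("prediction TSV needs columns protein_id, start, end|length, score|llr")
  tab[, need]
}

#' Label predictions as true and false positives against a truth set
#'
#' A prediction overlapping a truth motif by at least one residue counts
#' toward that motif; each truth motif keeps its highest-scoring
#' overlapping prediction as its single true-positive representative (one
#' prediction may represent two truth motifs it overlaps). Predictions
#' overlapping no truth motif are chained into tiles by transitive
#' one-residue overlap, and the highest-scoring member of each tile is one
#' false positive. The operation is idempotent: re-labelling its own
#' representatives changes nothing.
#'
#' @param preds Data.frame with columns `protein_id`, `start`, `end`,
#'   `score` (as from [collect_candidates()]).
#' @param truth Data.frame with columns `protein_id`, `start`, `end`.
#' @param exclusive If `TRUE`, a prediction may represent at most one truth
#'   motif (assigned greedily by score); default `FALSE`.
#' @return A list of class `labelled_predictions` with data.frames
#'   `true_positives` (one row per recovered truth motif, with
#'   `truth_start`/`truth_end`) and `false_positives` (one row per tile),
#'   plus `n_truth`.
#' @export
label_predictions <- function(preds, truth, exclusive = FALSE) {
  stopifnot(all(c("protein_id", "start", "end", "score") %in% names(preds)),
            all(c("protein_id", "start", "end") %in% names(truth)))
  unknown <- setdiff(unique(preds$protein_id), unique(truth$protein_id))
  if (length(unknown))
    stop("prediction(s) reference protein(s) absent from the truth set: ",
         paste(unknown, collapse = ", "))
  preds <- as.data.frame(preds); truth <- as.data.frame(truth)
  n_pred <- nrow(preds)
  overlaps_truth <- rep(FALSE, n_pred)
  taken <- rep(FALSE, n_pred)
  tp <- vector("list", nrow(truth))
  for (t in seq_len(nrow(truth))) {
    hit <- which(preds$protein_id == truth$protein_id[t] &
                   preds$start <= truth$end[t] &
                   preds$end >= truth$start[t] &
                   !(exclusive & taken))
    overlaps_truth[hit] <- TRUE
    if (length(hit)) {
      rep_i <- hit[which.max(preds$score[hit])]
      taken[rep_i] <- TRUE
      tp[[t]] <- cbind(preds[rep_i, , drop = FALSE],
                       truth_start = truth$start[t],
                       truth_end = truth$end[t])
    }
  }
  tp <- if (any(!vapply(tp, is.null, logical(1))))
    do.call(rbind, tp) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), score = numeric(0),
               truth_start = integer(0), truth_end = integer(0))
  rownames(tp) <- NULL

  rest <- preds[!overlaps_truth, , drop = FALSE]
  fp <- tile_representatives(rest)
  structure(list(true_positives = tp, false_positives = fp,
                 n_truth = nrow(truth)),
            class = "labelled_predictions")
}

# Chain predictions into tiles by transitive >= 1-residue overlap within
# each protein and keep the max-score member of each tile.
tile_representatives <- function(preds) {
  if (nrow(preds) == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  out <- lapply(split(preds, preds$protein_id), function(p) {
    p <- p[order(p$start, p$end), , drop = FALSE]
    tile <- integer(nrow(p))
    cur <- 1L; cur_end <- p$end[1L]; tile[1L] <- 1L
    for (i in seq_len(nrow(p))[-1L]) {
      if (p$start[i] <= cur_end) {            # >= 1 residue overlap
        cur_end <- max(cur_end, p$end[i])
      } else {
        cur <- cur + 1L; cur_end <- p$end[i]
      }
      tile[i] <- cur
    }
    do.call(rbind, lapply(split(p, tile), function(g)
      g[which.max(g$score), , drop = FALSE]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$protein_id, res$start), , drop = FALSE]
}

#' @export
print.labelled_predictions <- function(x, ...) {
  cat(sprintf("Labelled predictions: %d/%d truth motifs recovered, %d false-positive tiles\n",
              nrow(x$true_positives), x$n_truth, nrow(x$false_positives)))
  invisible(x)
}

#' ROC points from labelled predictions
#'
#' Sweeps a score threshold over the sorted distinct scores of the labelled
#' representatives. At each threshold, TPR is the fraction of truth motifs
#' whose representative scores at or above it, and FPR the number of
#' false-positive tiles at or above it divided by the number of negative
#' residues. Both axes are non-decreasing as the threshold drops; the
#' curve starts at (0, 0).
#'
#' @param labelled A `labelled_predictions` object (or a list of them, to
#'   pool representatives across several proteomes/seeds).
#' @param n_negative_residues Number of true-negative residues (total
#'   residues of the evaluated proteins minus residues inside truth
#'   motifs), the FPR denominator.
#' @param n_truth Number of truth motifs; defaults to the count recorded in
#'   `labelled`.
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labelled, n_negative_residues, n_truth = NULL) {
  if (inherits(labelled, "labelled_predictions")) labelled <- list(labelled)
  tp_scores <- unlist(lapply(labelled, function(l) l$true_positives$score))
  fp_scores <- unlist(lapply(labelled, function(l) l$false_positives$score))
  if (is.null(n_truth)) n_truth <- sum(vapply(labelled, `[[`, numeric(1), "n_truth"))
  if (n_truth <= 0) stop("need a positive number of truth motifs")
  if (n_negative_residues <= 0) stop("need a positive number of negative residues")
  thr <- sort(unique(c(tp_scores, fp_scores)), decreasing = TRUE)
  fp_at <- vapply(thr, function(t) sum(fp_scores >= t), numeric(1))
  tp_at <- vapply(thr, function(t) sum(tp_scores >= t), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp_at / n_negative_residues),
             tpr = c(0, tp_at / n_truth))
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the ROC points. With `normalize = TRUE`
#' (default) the area is divided by `max(fpr) * max(tpr)`, i.e. the AUC is
#' rescaled to the rectangle the observed curve spans, so that a random
#' scorer is near 0.5 and a perfect separator 1 even when only a small part
#' of FPR space is observed.
#'
#' @param roc Data.frame from [roc_points()].
#' @param normalize Rescale to the observed curve extent.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc, normalize = TRUE) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  a <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (normalize) {
    denom <- max(x) * max(y)
    if (denom == 0) return(NA_real_)
    a <- a / denom
  }
  a
}

#' Count of true-negative residues for ROC analysis
#'
#' Total residues of the evaluated proteins minus the residues inside the
#' truth motifs.
#'
#' @param total_residues Combined length of the evaluated proteins.
#' @param motif_residues Combined length of the truth motifs.
#' @return Integer count of negative residues.
#' @export
negative_residues <- function(total_residues, motif_residues) {
  stopifnot(total_residues > 0, motif_residues >= 0,
            motif_residues <= total_residues)
  as.integer(total_residues - motif_residues)
}

#' Proteome-wide per-residue false-positive rate
#'
#' The per-residue rate at which motif predictions would match the expected
#' prevalence of export substrates: the substrate fraction of the proteome
#' (optionally rounded) divided by the average protein length. With the
#' conventional yeast inputs (700 substrates of 5917 proteins, average
#' length 495, fraction rounded to 2 decimals) this gives 0.000242.
#'
#' @param n_substrates Number of proteins expected to carry the motif.
#' @param n_proteins Number of proteins in the proteome.
#' @param avg_protein_len Average protein length in residues.
#' @param round_digits Decimals to which the substrate fraction is rounded
#'   before dividing (default 2, matching the conventional calculation);
#'   `NULL` for no rounding.
#' @return The per-residue false-positive rate.
#' @export
proteome_fpr <- function(n_substrates, n_proteins, avg_protein_len,
                         round_digits = 2) {
  stopifnot(n_substrates > 0, n_proteins > 0, avg_protein_len > 0)
  frac <- n_substrates / n_proteins
  if (!is.null(round_digits)) frac <- round(frac, round_digits)
  frac / avg_protein_len
}

#' Compare two predictors' recall by Fisher's exact test
#'
#' Two-sided Fisher's exact test of independence on the 2x2 table of
#' true-positive and false-negative counts of two predictors at a common
#' false-positive rate.
#'
#' @param tp1,fn1 True-positive and false-negative counts of predictor 1.
#' @param tp2,fn2 Counts of predictor 2.
#' @return The two-sided p-value.
#' @export
compare_predictors <- function(tp1, fn1, tp2, fn2) {
  counts <- c(tp1, fn1, tp2, fn2)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero contingency table")
  tab <- matrix(as.integer(counts), nrow = 2L, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Cluster posterior probability vectors
#'
#' Agglomerative clustering of posterior vectors (configuration posteriors
#' or per-residue hydrophobic posteriors) with Euclidean distance and
#' average linkage, for heat-map display of motif-architecture classes.
#'
#' @param mat Numeric matrix, one posterior vector per row (at least 2
#'   rows; no `NA`s).
#' @return A list with `order` (leaf ordering, a permutation of row
#'   indices), `merge` and `height` (the agglomeration tree), and the
#'   underlying `hclust` object.
#' @export
cluster_posteriors <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster")
  if (anyNA(mat)) stop("posterior matrix contains NA rows; remove or impute them")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "average")
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}
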