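#' Spacer configurations
#'
#' A spacer configuration is the triple of gap lengths (c1, c2, c3) between
#' the four hydrophobic anchor residues of an NES. With each spacer allowed
#' 1 to 3 residues there are 27 configurations, spanning motif lengths 7
#' (1-1-1) to 13 (3-3-3). Configurations are represented as integer matrices
#' with one row per configuration and columns `c1`, `c2`, `c3`; rows carry
#' the conventional "c1-c2-c3" label.
#'
#' @param c1,c2,c3 Spacer lengths in residues (positive integers).
#' @return A 1-row configuration matrix.
#' @examples
#' spacer_config(3, 2, 1)           # the classical "3-2-1" NES architecture
#' config_length(spacer_config(3, 2, 1))  # 10 residues
#' @export
spacer_config <- function(c1, c2, c3) {
  v <- c(c1, c2, c3)
  if (any(v != round(v)) || any(v < 1)) stop("spacer lengths must be positive integers")
  m <- matrix(as.integer(v), nrow = 1L, dimnames = list(NULL, c("c1", "c2", "c3")))
  rownames(m) <- config_label(m)
  m
}

#' Enumerate all spacer configurations within length bounds
#'
#' Returns every (c1, c2, c3) triple with each component in
#' `[min_len, max_len]`, in lexicographic order with c1 varying slowest.
#' The default bounds (1, 3) give the full set of 27 configurations.
#'
#' @param min_len,max_len Bounds on each spacer length (residues).
#' @return Integer matrix with columns `c1`, `c2`, `c3`, one row per
#'   configuration, row names "c1-c2-c3".
#' @examples
#' nrow(enumerate_configurations())      # 27
#' enumerate_configurations(1, 1)        # just 1-1-1, length 7
#' @export
enumerate_configurations <- function(min_len = 1L, max_len = 3L) {
  if (length(min_len) != 1L || length(max_len) != 1L ||
      min_len != round(min_len) || max_len != round(max_len) ||
      min_len < 1 || min_len > max_len)
    stop("need integer bounds with 1 <= min_len <= max_len")
  r <- seq.int(min_len, max_len)
  g <- expand.grid(c3 = r, c2 = r, c1 = r)   # c1 outermost
  m <- as.matrix(g[, c("c1", "c2", "c3")])
  storage.mode(m) <- "integer"
  rownames(m) <- config_label(m)
  m
}

#' Total motif length of spacer configurations
#'
#' Four hydrophobic anchors plus the three spacers: `4 + c1 + c2 + c3`.
#'
#' @param configs Configuration matrix (rows are configurations).
#' @return Integer vector of motif lengths in residues.
#' @export
config_length <- function(configs) {
  configs <- as_config_matrix(configs)
  as.integer(4L + rowSums(configs))
}

#' Hydrophobic anchor offsets of a configuration
#'
#' 0-based offsets of the four hydrophobic positions from the motif start:
#' `{0, 1 + c1, 2 + c1 + c2, 3 + c1 + c2 + c3}`.
#'
#' @param config A single configuration (1-row matrix or length-3 vector).
#' @return Integer vector of four 0-based offsets.
#' @export
hydrophobic_offsets <- function(config) {
  config <- as_config_matrix(config)
  if (nrow(config) != 1L) stop("expected a single configuration")
  c1 <- config[1L, 1L]; c2 <- config[1L, 2L]; c3 <- config[1L, 3L]
  as.integer(c(0L, 1L + c1, 2L + c1 + c2, 3L + c1 + c2 + c3))
}

#' Spacer offsets of a configuration
#'
#' The complement of [hydrophobic_offsets()] within `[0, length)`.
#'
#' @inheritParams hydrophobic_offsets
#' @return Integer vector of 0-based spacer offsets.
#' @export
spacer_offsets <- function(config) {
  config <- as_config_matrix(config)
  len <- config_length(config)
  setdiff(seq.int(0L, len - 1L), hydrophobic_offsets(config))
}

#' Configuration labels of the form "c1-c2-c3"
#'
#' @param configs Configuration matrix.
#' @return Character vector of labels, e.g. `"3-2-1"`.
#' @export
config_label <- function(configs) {
  configs <- as_config_matrix(configs)
  unname(apply(configs, 1L, paste, collapse = "-"))
}

#' Parse configuration labels back into a configuration matrix
#'
#' Accepts labels like `"3-2-1"`; used to read restricted configuration
#' class lists (e.g. the canonical consensus classes) from config files.
#'
#' @param labels Character vector of "c1-c2-c3" labels.
#' @return Integer configuration matrix.
#' @export
parse_config_labels <- function(labels) {
  parts <- strsplit(labels, "-", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("configuration labels must look like 'c1-c2-c3'")
  m <- do.call(rbind, lapply(parts, as.integer))
  if (anyNA(m) || any(m < 1)) stop("configuration labels must contain positive integers")
  colnames(m) <- c("c1", "c2", "c3")
  storage.mode(m) <- "integer"
  rownames(m) <- config_label(m)
  m
}

# Coerce vectors / data.frames / matrices to the canonical K x 3 integer form.
as_config_matrix <- function(configs) {
  if (is.matrix(configs) || is.data.frame(configs)) {
    m <- as.matrix(configs)
  } else if (is.numeric(configs) && length(configs) == 3L) {
    m <- matrix(configs, nrow = 1L)
  } else {
    stop("cannot interpret configurations")
  }
  if (ncol(m) != 3L) stop("configurations must have 3 spacer columns")
  if (any(m != round(m)) || any(m < 1)) stop("spacer lengths must be positive integers")
  storage.mode(m) <- "integer"
  colnames(m) <- c("c1", "c2", "c3")
  rownames(m) <- unname(apply(m, 1L, paste, collapse = "-"))
  m
}

#' Reverse-orientation variants of configurations
#'
#' Reverse-binding NES classes are represented by reversing the spacer
#' triple: a motif read C-terminal to N-terminal with spacers (c1, c2, c3)
#' has forward-read spacers (c3, c2, c1). This keeps scoring on the forward
#' sequence.
#'
#' @param configs Configuration matrix.
#' @return Configuration matrix with each row's spacers reversed.
#' @export
reverse_configs <- function(configs) {
  configs <- as_config_matrix(configs)
  as_config_matrix(configs[, 3:1, drop = FALSE])
}

# 0/1 layout masks for a configuration set padded to `width` residues:
# H[k, o] = 1 if offset o (1-based col = offset 0..width-1) is hydrophobic
# under configuration k; S likewise for spacers; P for background padding
# beyond the configuration's length. Rows partition [0, width) for each k.
config_layout <- function(configs, width) {
  configs <- as_config_matrix(configs)
  K <- nrow(configs)
  H <- S <- P <- matrix(0, K, width, dimnames = list(rownames(configs), NULL))
  lens <- config_length(configs)
  if (width < max(lens)) stop("layout width shorter than longest configuration")
  for (k in seq_len(K)) {
    hy <- hydrophobic_offsets(configs[k, , drop = FALSE]) + 1L
    sp <- spacer_offsets(configs[k, , drop = FALSE]) + 1L
    H[k, hy] <- 1
    S[k, sp] <- 1
    if (lens[k] < width) P[k, seq.int(lens[k] + 1L, width)] <- 1
  }
  list(H = H, S = S, P = P, lengths = lens)
}
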