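# Sequence-context analysis of probe-modified residues: +/-10-residue
# windows around modified cysteines or lysines, position-specific scoring
# matrix (log2-odds against a background), and a permutation test for
# hydrophobicity enrichment around the modified site.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard residues (positive =
#'   hydrophobic).
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Modified-residue context windows
#'
#' A set of fixed-width sequence windows centered on a modified residue
#' (position 11 of 21 for the default half-width of 10), with a pad
#' character where the window runs past a sequence end.
#'
#' @param windows Character vector of equal-length windows (odd length;
#'   default width 21).
#' @param residue_type Center residue: `"K"` or `"C"`.
#' @param background Named amino-acid frequency vector summing to 1;
#'   default uniform over the 20 standard residues.
#' @param pad Pad character (default `"_"`), excluded from all statistics.
#' @return A `context_windows` list.
#' @export
context_window_set <- function(windows, residue_type = c("K", "C"),
                               background = NULL, pad = "_") {
  residue_type <- match.arg(residue_type)
  stopifnot(length(windows) >= 1L, is.character(windows))
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("all windows must have the same length",
                            call. = FALSE)
  if (w %% 2L == 0L) stop("window length must be odd", call. = FALSE)
  center <- (w + 1L) %/% 2L
  centers <- substr(windows, center, center)
  if (!all(centers == residue_type)) {
    stop("center residue must be ", sQuote(residue_type), " in every window",
         call. = FALSE)
  }
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20L), AMINO_ACIDS)
  }
  stopifnot(abs(sum(background) - 1) < 1e-6,
            all(AMINO_ACIDS %in% names(background)))
  structure(list(windows = windows, width = w, center = center,
                 residue_type = residue_type,
                 background = background[AMINO_ACIDS], pad = pad),
            class = "context_windows")
}

# windows as a character matrix (rows = windows, cols = positions)
.window_matrix <- function(w) {
  do.call(rbind, strsplit(w$windows, "", fixed = TRUE))
}

#' Position-specific scoring matrix of a window set
#'
#' Per position, the log2 ratio of observed amino-acid frequency (pad
#' positions excluded from the counts) over the background, both with a
#' pseudo-frequency added.
#'
#' @param w A [context_window_set()].
#' @param pseudo_freq Pseudo-frequency added to observed and background
#'   frequencies (default 0.01).
#' @return Numeric matrix, positions (-half..+half) x 20 residues, with an
#'   `observed_freq` attribute holding the raw frequency matrix.
#' @export
context_pssm <- function(w, pseudo_freq = 0.01) {
  stopifnot(inherits(w, "context_windows"), pseudo_freq >= 0)
  mat <- .window_matrix(w)
  half <- (w$width - 1L) %/% 2L
  pos_labels <- as.character(seq(-half, half))
  freq <- matrix(0, nrow = w$width, ncol = 20L,
                 dimnames = list(pos_labels, AMINO_ACIDS))
  for (j in seq_len(w$width)) {
    col <- mat[, j]
    col <- col[col != w$pad]
    if (length(col) > 0L) {
      tab <- table(factor(col, levels = AMINO_ACIDS))
      freq[j, ] <- as.numeric(tab) / length(col)
    }
  }
  scores <- log2(freq + pseudo_freq) -
    matrix(log2(w$background + pseudo_freq), nrow = w$width, ncol = 20L,
           byrow = TRUE)
  dimnames(scores) <- dimnames(freq)
  attr(scores, "observed_freq") <- freq
  scores
}

#' Hydrophobicity enrichment around the modified residue
#'
#' Statistic: mean hydropathy over all non-center, non-pad residues pooled
#' across windows. The one-sided permutation p-value is the fraction of
#' window sets resampled from the background whose statistic is at least the
#' observed one (with the +1 correction keeping p in (0, 1]).
#'
#' @param w A [context_window_set()].
#' @param scale Named hydropathy scale over the 20 residues; default
#'   Kyte-Doolittle.
#' @param n_perm Permutation count (default 10000).
#' @param seed Seed for the permutation draws.
#' @return Tibble with `statistic` (mean window hydropathy),
#'   `background_mean`, `p_perm`, `n_windows`, `n_residues`.
#' @export
hydrophobicity_enrichment <- function(w, scale = kyte_doolittle(),
                                      n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(w, "context_windows"),
            all(AMINO_ACIDS %in% names(scale)))
  mat <- .window_matrix(w)
  flank <- mat[, -w$center, drop = FALSE]
  res <- flank[flank != w$pad]
  if (length(res) == 0L) stop("no non-pad flanking residues", call. = FALSE)
  if (length(w$windows) == 1L) {
    warning("single window: permutation test has low power")
  }
  obs <- mean(scale[res])
  bg_mean <- sum(w$background * scale[names(w$background)])
  n <- length(res)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample(AMINO_ACIDS, n, replace = TRUE, prob = w$background)
      mean(scale[draw])
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  tibble::tibble(statistic = obs, background_mean = bg_mean, p_perm = p,
                 n_windows = length(w$windows), n_residues = n)
}
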