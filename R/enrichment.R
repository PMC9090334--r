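# Label-free pull-down enrichment: per-protein fold change between the
# (S)-probe and (R)-probe conditions, two-sample t-test on log2 intensities,
# strict-threshold hit selection and a graph-ready node table.

#' Per-protein enrichment statistics
#'
#' Fold change is the ratio of mean linear intensities (S over R); the
#' p-value comes from an unpaired two-sided t-test on log2-transformed
#' intensities, pooled-variance Student by default (Welch behind a flag).
#' Intensities that are missing or non-positive are treated as missing;
#' proteins with fewer than two finite values in either condition are
#' flagged untested (`p = NA`), not imputed.
#'
#' @param lfq Tibble or data frame with a `protein` column plus one column
#'   per sample (linear intensities).
#' @param design Tibble with columns `sample`, `condition` (values `"S"` and
#'   `"R"`), or a named character vector mapping sample to condition.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return An `enrichment_results` tibble: `protein`, `n_s`, `n_r`, `fc`,
#'   `log2fc`, `p`, `neg_log10_p`, `tested`.
#' @export
enrichment_stats <- function(lfq, design, var_equal = TRUE) {
  if (is.character(design)) {
    design <- tibble::tibble(sample = names(design), condition = unname(design))
  }
  stopifnot(all(c("sample", "condition") %in% names(design)),
            all(design$condition %in% c("S", "R")),
            all(design$sample %in% names(lfq)))
  s_cols <- design$sample[design$condition == "S"]
  r_cols <- design$sample[design$condition == "R"]
  if (length(s_cols) < 2L || length(r_cols) < 2L) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  if (anyDuplicated(lfq$protein)) stop("protein ids must be unique",
                                       call. = FALSE)

  ms <- as.matrix(lfq[, s_cols, drop = FALSE])
  mr <- as.matrix(lfq[, r_cols, drop = FALSE])
  ms[!is.finite(ms) | ms <= 0] <- NA_real_
  mr[!is.finite(mr) | mr <= 0] <- NA_real_
  ls <- log2(ms)
  lr <- log2(mr)

  n_s <- rowSums(is.finite(ls))
  n_r <- rowSums(is.finite(lr))
  mean_s <- rowMeans(ms, na.rm = TRUE)
  mean_r <- rowMeans(mr, na.rm = TRUE)
  fc <- mean_s / mean_r

  lm_s <- rowMeans(ls, na.rm = TRUE)
  lm_r <- rowMeans(lr, na.rm = TRUE)
  var_s <- rowSums((ls - lm_s)^2, na.rm = TRUE) / pmax(n_s - 1L, 1L)
  var_r <- rowSums((lr - lm_r)^2, na.rm = TRUE) / pmax(n_r - 1L, 1L)
  diff <- lm_s - lm_r

  tested <- n_s >= 2L & n_r >= 2L
  if (var_equal) {
    df <- n_s + n_r - 2L
    sp2 <- ((n_s - 1L) * var_s + (n_r - 1L) * var_r) / df
    se <- sqrt(sp2 * (1 / n_s + 1 / n_r))
  } else {
    u_s <- var_s / n_s
    u_r <- var_r / n_r
    se <- sqrt(u_s + u_r)
    df <- (u_s + u_r)^2 /
      (u_s^2 / pmax(n_s - 1L, 1L) + u_r^2 / pmax(n_r - 1L, 1L))
  }
  t_stat <- diff / se
  t_stat[diff == 0] <- 0  # identical means: p = 1 even at zero variance
  p <- 2 * pt(-abs(t_stat), df)
  p <- pmax(p, .Machine$double.xmin)
  p[!tested] <- NA_real_

  out <- tibble::tibble(
    protein = lfq$protein,
    n_s = as.integer(n_s), n_r = as.integer(n_r),
    fc = fc, log2fc = log2(fc),
    p = p, neg_log10_p = -log10(p),
    tested = tested
  )
  class(out) <- c("enrichment_results", class(out))
  out
}

#' Select enriched hits
#'
#' Strict thresholds, matching "enriched more than 2-fold" at p below 0.05:
#' a protein is selected iff `fc > fc_min` and `p < p_max` (a protein at
#' exactly the threshold is not selected). No multiple-testing correction by
#' default; Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @param results [enrichment_stats()] output.
#' @param fc_min Fold-change threshold (exclusive).
#' @param p_max P-value threshold (exclusive).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The selected subset of `results`.
#' @export
select_hits <- function(results, fc_min = 2, p_max = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p_use <- if (adjust == "BH") {
    stats::p.adjust(results$p, method = "BH")
  } else results$p
  dplyr::filter(results, .data$tested, .data$fc > fc_min, p_use < p_max)
}

#' Graph-ready node table
#'
#' Deterministic node table for a Cytoscape-style overview of enrichment:
#' box size is -log10(p) and fold change is binned for coloring.
#'
#' @param results [enrichment_stats()] output.
#' @param fc_breaks Fold-change bin edges (linear scale).
#' @return Tibble `protein`, `fc`, `fc_bin`, `size`, ordered by protein id.
#' @export
graph_table <- function(results, fc_breaks = c(0, 2, 5, 10, 60, Inf)) {
  results |>
    dplyr::filter(is.finite(.data$p)) |>
    dplyr::transmute(
      protein = .data$protein,
      fc = .data$fc,
      fc_bin = cut(.data$fc, breaks = fc_breaks, right = FALSE),
      size = -log10(.data$p)
    ) |>
    dplyr::arrange(.data$protein)
}

#' Volcano plot of enrichment results
#'
#' @param object [enrichment_stats()] output.
#' @param fc_min,p_max Thresholds drawn and used to color hits (as in
#'   [select_hits()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_results
#' @export
autoplot.enrichment_results <- function(object, fc_min = 2, p_max = 0.05,
                                        ...) {
  df <- dplyr::filter(object, .data$tested)
  df$hit <- df$fc > fc_min & df$p < p_max
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = log2(fc_min), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (S / R)", y = "-log10 p") +
    ggplot2::theme_minimal()
}
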