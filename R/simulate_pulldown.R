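# Simulator for streptavidin pull-down LFQ matrices comparing the active
# (S)-probe condition against the inactive (R)-enantiomer control, with a
# planted enriched-protein set including a few very strong (>60-fold) hits.

#' Parameters for the pull-down LFQ simulator
#'
#' Defaults emulate the study's pull-down: 42 enriched proteins of which 3
#' exceed 60-fold, three replicates per condition, log-normal replicate
#' noise.
#'
#' @param n_proteins Proteins quantified.
#' @param n_replicates Replicates per condition (>= 2).
#' @param n_enriched Planted enriched proteins.
#' @param strong_hits Of those, proteins with fold change above 60.
#' @param fc_log2_range Uniform range of planted log2 fold changes for the
#'   ordinary enriched proteins.
#' @param strong_fc_log2_range Range for the strong hits (above log2 60).
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param missingness Probability that any single intensity is missing
#'   (missing at random). Default 0: the default matrix is complete, as in a
#'   complete-case protein-group table; raise to emulate dropout.
#' @param base_log2_mean,base_log2_sd Log2 baseline-intensity distribution.
#' @param seed Integer seed.
#' @return A `pulldown_sim_params` list.
#' @export
pulldown_sim_params <- function(n_proteins = 2000L,
                                n_replicates = 3L,
                                n_enriched = 42L,
                                strong_hits = 3L,
                                fc_log2_range = c(1.5, 5.9),
                                strong_fc_log2_range = c(6.0, 7.2),
                                noise_sd = 0.4,
                                missingness = 0,
                                base_log2_mean = 23,
                                base_log2_sd = 2,
                                seed = 1L) {
  stopifnot(strong_hits <= n_enriched, n_enriched <= n_proteins,
            n_replicates >= 2L, missingness >= 0, missingness < 1)
  structure(list(n_proteins = n_proteins, n_replicates = n_replicates,
                 n_enriched = n_enriched, strong_hits = strong_hits,
                 fc_log2_range = fc_log2_range,
                 strong_fc_log2_range = strong_fc_log2_range,
                 noise_sd = noise_sd, missingness = missingness,
                 base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
                 seed = seed),
            class = "pulldown_sim_params")
}

#' Simulate a pull-down LFQ experiment
#'
#' Non-enriched proteins have expected log2 fold change 0 between the S and
#' R conditions; enriched proteins carry their planted fold change in the S
#' condition. Replicate noise is i.i.d. normal on the log2 scale; optional
#' missing values are inserted at random.
#'
#' @param p A [pulldown_sim_params()] object.
#' @return A `pulldown_sim` list: `lfq` (tibble `protein` + one column per
#'   sample, linear intensities), `design` (tibble `sample`, `condition` in
#'   S/R), `truth` (tibble `protein`, `enriched`, `strong`, `true_log2fc`),
#'   `params`.
#' @export
simulate_pulldown <- function(p) {
  stopifnot(inherits(p, "pulldown_sim_params"))
  withr::with_seed(p$seed, {
    proteins <- sprintf("PROT%04d", seq_len(p$n_proteins))
    enriched_idx <- sample.int(p$n_proteins, p$n_enriched)
    strong_idx <- enriched_idx[seq_len(p$strong_hits)]
    lfc <- numeric(p$n_proteins)
    ordinary <- setdiff(enriched_idx, strong_idx)
    lfc[ordinary] <- runif(length(ordinary), p$fc_log2_range[1],
                           p$fc_log2_range[2])
    lfc[strong_idx] <- runif(length(strong_idx), p$strong_fc_log2_range[1],
                             p$strong_fc_log2_range[2])

    base <- rnorm(p$n_proteins, p$base_log2_mean, p$base_log2_sd)
    samples <- c(paste0("S_", seq_len(p$n_replicates)),
                 paste0("R_", seq_len(p$n_replicates)))
    cond <- rep(c("S", "R"), each = p$n_replicates)
    log2m <- sapply(seq_along(samples), function(j) {
      base + (if (cond[j] == "S") lfc else 0) +
        rnorm(p$n_proteins, 0, p$noise_sd)
    })
    m <- 2^log2m
    if (p$missingness > 0) {
      m[runif(length(m)) < p$missingness] <- NA_real_
    }
    colnames(m) <- samples
    lfq <- tibble::as_tibble(as.data.frame(m))
    lfq <- dplyr::bind_cols(tibble::tibble(protein = proteins), lfq)
    structure(list(
      lfq = lfq,
      design = tibble::tibble(sample = samples, condition = cond),
      truth = tibble::tibble(
        protein = proteins,
        enriched = seq_len(p$n_proteins) %in% enriched_idx,
        strong = seq_len(p$n_proteins) %in% strong_idx,
        true_log2fc = lfc
      ),
      params = p
    ), class = "pulldown_sim")
  })
}

#' Write a pull-down simulation to files
#'
#' @param sim A `pulldown_sim`.
#' @param dir Output directory.
#' @return Invisibly, the written paths (LFQ CSV, design CSV, truth JSON).
#' @export
write_pulldown_files <- function(sim, dir) {
  stopifnot(inherits(sim, "pulldown_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lfq_path <- file.path(dir, "lfq.csv")
  design_path <- file.path(dir, "design.csv")
  truth_path <- file.path(dir, "truth.json")
  write.csv(sim$lfq, lfq_path, row.names = FALSE)
  write.csv(sim$design, design_path, row.names = FALSE)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(lfq_path, design_path, truth_path))
}
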