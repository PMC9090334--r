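# Simulator for an EMS forward-genetics resistance screen in a pseudo-haploid
# cell line: per-clone annotated coding variants (transition-dominated SNVs,
# ~Poisson passenger genes per clone), one planted causal gene that is mutated
# in most clones and expression-silenced in the rest, and an RNA-seq count
# matrix carrying the silencing signal.

#' Gene universe for screen simulations
#'
#' Deterministic table of gene ids with coding lengths and baseline
#' expression, used as the mutational target space and the transcriptome.
#'
#' @param n_genes Number of genes (default 20000, a human-transcriptome-scale
#'   universe).
#' @param seed Integer seed.
#' @return Tibble with `gene`, `chrom`, `start`, `length_bp`, `base_mean`
#'   (expected parental counts before library-size scaling).
#' @export
gene_universe <- function(n_genes = 20000L, seed = 1L) {
  withr::with_seed(seed, {
    tibble::tibble(
      gene = sprintf("GENE%05d", seq_len(n_genes)),
      chrom = paste0("chr", 1L + (seq_len(n_genes) - 1L) %% 22L),
      start = 100000L + 5000L * seq_len(n_genes),
      length_bp = pmax(300L, as.integer(round(rlnorm(n_genes, log(1500), 0.6)))),
      base_mean = rlnorm(n_genes, meanlog = log(30), sdlog = 1.3)
    )
  })
}

#' Parameters for the resistance-screen simulator
#'
#' Defaults emulate the study conditions of a DAC-resistance screen: four
#' clones, around nine coding-mutated genes per clone, a transition-dominated
#' EMS spectrum, one clone silenced ~200-fold at the causal gene instead of
#' mutated.
#'
#' @param n_clones Number of resistant clones.
#' @param genes Gene universe tibble (see [gene_universe()]); generated from
#'   `seed` when `NULL`.
#' @param passenger_mean Expected qualifying coding-mutated passenger genes
#'   per clone (Poisson mean).
#' @param transition_fraction Fraction of SNVs that are transitions.
#' @param causal_gene Gene id of the planted causal gene; sampled from the
#'   universe when `NULL`.
#' @param silenced_clone_count Clones silenced (not mutated) at the causal
#'   gene.
#' @param unexplained_clone_count Clones with neither causal mutation nor
#'   silencing (used by the second-round-screen preset where one clone is
#'   unexplained).
#' @param silencing_fold Expression fold-reduction applied to the causal gene
#'   in silenced clones.
#' @param depth_mean,depth_size Negative-binomial read-depth model for DP.
#' @param af_shape1,af_shape2 Beta model for passenger allele fractions
#'   (mode near 1; occasional lower values exercise the AF filter).
#' @param causal_af_shape1 First Beta shape for causal-variant AF; larger
#'   than the passenger shape because selection fixes the causal mutation in
#'   every cell of a resistant clone.
#' @param consequence_probs Named sampling probabilities over qualifying
#'   consequence classes; frameshifts default to 0 (EMS induces point
#'   mutations, not indels).
#' @param chaff_mean Expected non-qualifying variants per clone (synonymous
#'   or low-AF records that the filters must remove).
#' @param n_shared_background Germline-like variants present in the parental
#'   line and every clone (removed by parental subtraction).
#' @param causal_cpm Parental expression level planted for the causal gene
#'   (CPM); the screen is RNA-seq-based so the causal gene must be expressed.
#' @param dispersion Negative-binomial count dispersion (size = 1/dispersion).
#' @param seed Integer seed; same seed, byte-identical outputs.
#' @return A `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_clones = 4L,
                              genes = NULL,
                              passenger_mean = 9,
                              transition_fraction = 0.85,
                              causal_gene = NULL,
                              silenced_clone_count = 1L,
                              unexplained_clone_count = 0L,
                              silencing_fold = 200,
                              depth_mean = 60,
                              depth_size = 10,
                              af_shape1 = 50,
                              af_shape2 = 1.5,
                              causal_af_shape1 = 200,
                              consequence_probs = c(missense_variant = 0.75,
                                                    stop_gained = 0.25,
                                                    frameshift_variant = 0),
                              chaff_mean = 5,
                              n_shared_background = 50L,
                              causal_cpm = 400,
                              dispersion = 0.1,
                              seed = 1L) {
  stopifnot(
    silenced_clone_count + unexplained_clone_count < n_clones,
    transition_fraction >= 0, transition_fraction <= 1,
    passenger_mean > 0, silencing_fold >= 1
  )
  if (is.null(genes)) genes <- gene_universe(seed = seed)
  if (is.null(causal_gene)) {
    causal_gene <- withr::with_seed(seed + 101L, sample(genes$gene, 1L))
  }
  if (!causal_gene %in% genes$gene) {
    stop("causal_gene ", sQuote(causal_gene), " is not in the gene universe",
         call. = FALSE)
  }
  structure(list(n_clones = n_clones, genes = genes,
                 passenger_mean = passenger_mean,
                 transition_fraction = transition_fraction,
                 causal_gene = causal_gene,
                 silenced_clone_count = silenced_clone_count,
                 unexplained_clone_count = unexplained_clone_count,
                 silencing_fold = silencing_fold,
                 depth_mean = depth_mean, depth_size = depth_size,
                 af_shape1 = af_shape1, af_shape2 = af_shape2,
                 causal_af_shape1 = causal_af_shape1,
                 consequence_probs = consequence_probs,
                 chaff_mean = chaff_mean,
                 n_shared_background = n_shared_background,
                 causal_cpm = causal_cpm, dispersion = dispersion,
                 seed = seed),
            class = "screen_sim_params")
}

# one SNV per row for the given genes; EMS-style transition-dominated spectrum
.sim_snvs <- function(genes_tbl, clone_id, consequence, af, p) {
  n <- nrow(genes_tbl)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is_ts <- runif(n) < p$transition_fraction
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  alt <- character(n)
  alt[is_ts] <- transition[ref[is_ts]]
  for (i in which(!is_ts)) {
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"),
                             c(ref[i], transition[[ref[i]]])), 1L)
  }
  tibble::tibble(
    clone_id = clone_id,
    chrom = genes_tbl$chrom,
    pos = genes_tbl$start +
      as.integer(floor(runif(n) * genes_tbl$length_bp)),
    ref = ref,
    alt = unname(alt),
    gene = genes_tbl$gene,
    consequence = consequence,
    af = af,
    dp = rnbinom(n, size = p$depth_size, mu = p$depth_mean)
  )
}

.sample_consequence <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate an EMS resistance screen
#'
#' Generates per-clone annotated variant tables (plus a parental table), an
#' RNA-seq count matrix, and a ground-truth record. Non-silenced,
#' non-unexplained clones carry one qualifying causal-gene variant with
#' allele fraction near 1; silenced clones instead have the causal gene's
#' counts reduced `silencing_fold`-fold. Passenger genes are Poisson per
#' clone, sampled with probability proportional to coding length.
#'
#' @param p A [screen_sim_params()] object.
#' @return A `screen_sim` list: `variants` (tibble incl. `clone_id =
#'   "parental"` rows), `counts` (gene x sample integer matrix; first column
#'   `parental`), `truth` (list with causal gene, per-clone status and
#'   planted variants), `params`.
#' @export
simulate_resistance_screen <- function(p) {
  stopifnot(inherits(p, "screen_sim_params"))
  withr::with_seed(p$seed, {
    clones <- sprintf("C%02d", seq_len(p$n_clones))
    status <- rep("mutated", p$n_clones)
    special <- sample(seq_len(p$n_clones),
                      p$silenced_clone_count + p$unexplained_clone_count)
    status[special[seq_len(p$silenced_clone_count)]] <- "silenced"
    if (p$unexplained_clone_count > 0L) {
      status[special[p$silenced_clone_count + seq_len(p$unexplained_clone_count)]] <-
        "unexplained"
    }

    genes <- p$genes
    causal_row <- genes[genes$gene == p$causal_gene, ]
    w <- genes$length_bp * (genes$gene != p$causal_gene)

    # germline-like background shared by parental and every clone
    shared_idx <- sample.int(nrow(genes), p$n_shared_background, prob = w)
    shared <- .sim_snvs(genes[shared_idx, ], "parental",
                        .sample_consequence(p$n_shared_background,
                                            p$consequence_probs),
                        rbeta(p$n_shared_background, p$af_shape1, p$af_shape2),
                        p)

    n_passenger <- integer(p$n_clones)
    clone_tbls <- purrr::map2(seq_len(p$n_clones), status, function(k, st) {
      cl <- clones[k]
      n_pass <- rpois(1L, p$passenger_mean)
      pass_idx <- sample.int(nrow(genes), n_pass, prob = w)
      n_passenger[k] <<- length(unique(genes$gene[pass_idx]))
      pass <- .sim_snvs(genes[pass_idx, ], cl,
                        .sample_consequence(n_pass, p$consequence_probs),
                        rbeta(n_pass, p$af_shape1, p$af_shape2), p)
      n_chaff <- rpois(1L, p$chaff_mean)
      chaff_idx <- sample.int(nrow(genes), n_chaff, prob = w)
      chaff_syn <- runif(n_chaff) < 0.6
      chaff_csq <- rep("missense_variant", n_chaff)
      chaff_csq[chaff_syn] <- "synonymous_variant"
      chaff_af <- rbeta(n_chaff, 5, 5)
      chaff_af[chaff_syn] <- rbeta(sum(chaff_syn), p$af_shape1, p$af_shape2)
      chaff <- .sim_snvs(genes[chaff_idx, ], cl, chaff_csq, chaff_af, p)
      causal <- if (st == "mutated") {
        .sim_snvs(causal_row, cl,
                  .sample_consequence(1L, p$consequence_probs),
                  rbeta(1L, p$causal_af_shape1, p$af_shape2), p)
      } else NULL
      shared_cl <- shared
      shared_cl$clone_id <- cl
      dplyr::bind_rows(causal, pass, chaff, shared_cl)
    })

    variants <- dplyr::bind_rows(c(list(shared), clone_tbls)) |>
      dplyr::arrange(.data$clone_id, .data$chrom, .data$pos)

    # RNA-seq counts: parental + one sample per clone
    base <- genes$base_mean
    names(base) <- genes$gene
    base[p$causal_gene] <- p$causal_cpm * 1e-6 * sum(base)
    sf <- rlnorm(p$n_clones + 1L, 0, 0.2)
    mu <- outer(base, sf)
    colnames(mu) <- c("parental", clones)
    for (i in which(status == "silenced")) {
      mu[p$causal_gene, clones[i]] <- mu[p$causal_gene, clones[i]] / p$silencing_fold
    }
    counts <- matrix(
      as.integer(rnbinom(length(mu), size = 1 / p$dispersion, mu = mu)),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )

    truth <- list(
      causal_gene = p$causal_gene,
      silencing_fold = p$silencing_fold,
      clones = tibble::tibble(
        clone_id = clones,
        status = status,
        n_passenger_genes = n_passenger
      ),
      causal_variants = dplyr::filter(variants, .data$gene == p$causal_gene,
                                      .data$clone_id != "parental")
    )
    structure(list(variants = variants, counts = counts, truth = truth,
                   params = p),
              class = "screen_sim")
  })
}

# ---- file emission ---------------------------------------------------------

.vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##source=sdrscreen-simulator",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele|Annotation|Impact|Gene_Name|Gene_ID'\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

.write_clone_vcf <- function(tbl, path) {
  tbl <- dplyr::arrange(
    tbl,
    as.integer(sub("chr", "", .data$chrom)), .data$pos
  )
  info <- sprintf(
    "DP=%d;AF=%.4f;ANN=%s|%s|MODERATE|%s|%s",
    tbl$dp, tbl$af, tbl$alt, tbl$consequence, tbl$gene, tbl$gene
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  tbl$chrom, tbl$pos, tbl$ref, tbl$alt, info)
  writeLines(c(.vcf_header(), body), path)
  invisible(path)
}

#' Write resistance-screen simulation to files
#'
#' Emits one VCF 4.2 per clone, a parental VCF, the count matrix as TSV and
#' the ground truth as JSON. Output is byte-identical for identical
#' simulations.
#'
#' @param sim A `screen_sim` from [simulate_resistance_screen()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_screen_files <- function(sim, dir) {
  stopifnot(inherits(sim, "screen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cl in unique(sim$variants$clone_id)) {
    path <- file.path(dir, paste0(cl, ".vcf"))
    .write_clone_vcf(dplyr::filter(sim$variants, .data$clone_id == cl), path)
    paths <- c(paths, path)
  }
  counts_path <- file.path(dir, "counts.tsv")
  counts_df <- data.frame(gene = rownames(sim$counts), sim$counts,
                          check.names = FALSE)
  write.table(counts_df, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(causal_gene = sim$truth$causal_gene,
         silencing_fold = sim$truth$silencing_fold,
         clones = sim$truth$clones,
         causal_variants = sim$truth$causal_variants),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, counts_path, truth_path))
}

#' Read a simulated count matrix TSV
#'
#' @param path TSV with a `gene` column followed by one column per sample.
#' @return Integer matrix, genes as rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
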