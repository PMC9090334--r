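# Forward-genetics inference on EMS-mutagenized resistant clones: filter
# clone-specific qualifying coding variants, rank genes by recurrence across
# independently mutagenized clones, flag expression-silenced genes, and
# nominate candidates that explain every clone either by mutation or by
# silencing.

#' Variant filter policy
#'
#' Defaults follow the screen's published filter: allele fraction at least
#' 0.9 (inclusive), depth greater than 10 reads (strict), and a consequence
#' among frameshift, missense and nonsense classes (Sequence Ontology terms
#' as emitted by SnpEff; "nonsense" covers stop_gained/stop_lost/start_lost).
#'
#' @param af_min Minimum allele fraction (inclusive).
#' @param dp_min Depth threshold (exclusive: retained variants have
#'   `dp > dp_min`).
#' @param consequence_set Qualifying consequence classes.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(af_min = 0.9, dp_min = 10,
                          consequence_set = c("missense_variant",
                                              "stop_gained", "stop_lost",
                                              "start_lost",
                                              "frameshift_variant")) {
  stopifnot(af_min >= 0, af_min <= 1, dp_min >= 0,
            length(consequence_set) >= 1L)
  structure(list(af_min = af_min, dp_min = dp_min,
                 consequence_set = consequence_set), class = "filter_policy")
}

#' Expression-silencing policy
#'
#' A gene is flagged silenced in a clone when the parental-to-clone CPM
#' ratio (with pseudocounts) reaches `min_fold` and the gene is expressed in
#' the parental line (`min_parental_cpm`). Thresholds are pipeline defaults;
#' the published screen applied this channel qualitatively to a ~200-fold
#' loss.
#'
#' @param min_fold Minimum parental/clone CPM fold (>= 1).
#' @param min_parental_cpm Expression floor for evaluating a gene.
#' @param pseudocount Added to both CPM values before the ratio.
#' @return A `silencing_policy` list.
#' @export
silencing_policy <- function(min_fold = 50, min_parental_cpm = 5,
                             pseudocount = 0.5) {
  stopifnot(min_fold > 1, pseudocount > 0)
  structure(list(min_fold = min_fold, min_parental_cpm = min_parental_cpm,
                 pseudocount = pseudocount), class = "silencing_policy")
}

#' Read SnpEff-annotated variants from a VCF
#'
#' Parses a VCF 4.2 file with `DP`/`AF` INFO keys and an optional
#' SnpEff-style `ANN` subfield into a tidy variant table. Multi-allelic
#' records are decomposed into one row per ALT allele; the first ANN entry
#' matching the allele (or the first entry overall) supplies gene and
#' consequence; records lacking ANN get consequence `"unannotated"`.
#'
#' @param path VCF file path.
#' @param clone_id Clone label for the `clone_id` column; defaults to the
#'   file name without extension.
#' @return Tibble with columns `clone_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `af`, `dp`.
#' @export
read_annotated_variants <- function(path, clone_id = NULL) {
  if (is.null(clone_id)) clone_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(tibble::tibble(clone_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          consequence = character(), af = numeric(),
                          dp = integer()))
  }
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  af_raw <- vcfR::extract.info(vcf, "AF")
  ann_raw <- vcfR::extract.info(vcf, "ANN")
  if ((!is.null(vcfR::extract.info(vcf, "DP")) && anyNA(dp))) {
    stop("non-numeric DP field in ", path, call. = FALSE)
  }

  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    afs <- suppressWarnings(as.numeric(
      strsplit(if (is.null(af_raw)) NA_character_ else af_raw[i], ",",
               fixed = TRUE)[[1]]))
    if (length(afs) == 1L) afs <- rep(afs, length(alts))
    anns <- if (is.null(ann_raw) || is.na(ann_raw[i])) character(0) else
      strsplit(ann_raw[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(seq_along(alts), function(j) {
      gene <- NA_character_
      csq <- "unannotated"
      if (length(anns) > 0L) {
        fields_list <- strsplit(anns, "|", fixed = TRUE)
        hit <- which(vapply(fields_list, function(f) f[1] == alts[j],
                            logical(1)))
        f <- fields_list[[if (length(hit) > 0L) hit[1] else 1L]]
        csq <- if (length(f) >= 2L) f[2] else "unannotated"
        gene <- if (length(f) >= 4L) f[4] else NA_character_
      }
      tibble::tibble(
        clone_id = clone_id,
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[j],
        gene = gene,
        consequence = csq,
        af = afs[j],
        dp = dp[i]
      )
    })
  })
  if (any(!is.na(rows$af) & (rows$af < 0 | rows$af > 1))) {
    stop("AF outside [0, 1] in ", path, call. = FALSE)
  }
  rows
}

#' Filter clone-specific qualifying variants
#'
#' A variant is retained iff it has no parental match on (chrom, pos, ref,
#' alt), `af >= af_min`, `dp > dp_min`, and a qualifying consequence. A
#' parental variant at any allele fraction masks the clone variant.
#'
#' @param clone Variant tibble for one clone (see
#'   [read_annotated_variants()]).
#' @param parental Variant tibble for the parental line.
#' @param policy A [filter_policy()].
#' @return The retained subset of `clone`.
#' @export
filter_clone_specific <- function(clone, parental, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  out <- clone
  if (nrow(out) > 0L && nrow(parental) > 0L) {
    out <- dplyr::anti_join(out, parental,
                            by = c("chrom", "pos", "ref", "alt"))
  }
  dplyr::filter(out,
                .data$af >= policy$af_min,
                .data$dp > policy$dp_min,
                .data$consequence %in% policy$consequence_set)
}

#' Gene recurrence across clones
#'
#' Counts, for each gene, the clones whose filtered variant set touches it,
#' and keeps genes recurring in at least `min_clones` clones. Default 3
#' ("shared by more than two clones"). Sorted by clone count descending,
#' then gene id.
#'
#' @param clone_genes Tibble with columns `clone_id` and `gene` (one row per
#'   mutated gene per clone; duplicates are collapsed), e.g. filtered
#'   variants.
#' @param min_clones Minimum recurrence (>= 1).
#' @return Tibble `gene`, `n_clones`, `clones` (comma-joined sorted ids).
#' @export
gene_recurrence <- function(clone_genes, min_clones = 3L) {
  stopifnot(min_clones >= 1L)
  clone_genes |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::distinct(.data$clone_id, .data$gene) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      clones = paste(sort(.data$clone_id), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_clones >= min_clones) |>
    dplyr::arrange(dplyr::desc(.data$n_clones), .data$gene)
}

#' Detect expression silencing per clone
#'
#' Computes, per gene and clone, the fold reduction of clone CPM relative to
#' parental CPM (pseudocounts on both sides) and flags genes meeting the
#' silencing policy. Counts are CPM-normalized per sample; replicate columns
#' within a group are averaged on the CPM scale.
#'
#' @param counts Gene x sample count matrix (rownames = genes), or a data
#'   frame with a `gene` column.
#' @param parental_samples Column names of parental samples.
#' @param clone_samples Named list mapping clone id to its column names.
#' @param policy A [silencing_policy()].
#' @param flagged_only Return only flagged rows (default `FALSE`).
#' @return Tibble `clone_id`, `gene`, `parental_cpm`, `clone_cpm`, `fold`,
#'   `silenced`.
#' @export
expression_silencing <- function(counts, parental_samples, clone_samples,
                                 policy = silencing_policy(),
                                 flagged_only = FALSE) {
  stopifnot(inherits(policy, "silencing_policy"))
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, setdiff(names(counts), "gene"), drop = FALSE])
    rownames(m) <- counts$gene
    counts <- m
  }
  all_cols <- c(parental_samples, unlist(clone_samples))
  missing_cols <- setdiff(all_cols, colnames(counts))
  if (length(missing_cols) > 0L) {
    stop("sample columns not in counts: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib[all_cols] == 0)) stop("zero library size", call. = FALSE)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  par_cpm <- rowMeans(cpm[, parental_samples, drop = FALSE])
  pc <- policy$pseudocount
  out <- purrr::imap_dfr(clone_samples, function(cols, cl) {
    cl_cpm <- rowMeans(cpm[, cols, drop = FALSE])
    fold <- (par_cpm + pc) / (cl_cpm + pc)
    flag <- fold >= policy$min_fold & par_cpm >= policy$min_parental_cpm
    keep <- if (flagged_only) which(flag) else seq_along(fold)
    tibble::tibble(
      clone_id = cl,
      gene = rownames(counts)[keep],
      parental_cpm = unname(par_cpm[keep]),
      clone_cpm = unname(cl_cpm[keep]),
      fold = unname(fold[keep]),
      silenced = unname(flag[keep])
    )
  })
  out
}

#' Assemble per-gene evidence across clones
#'
#' Merges the mutation channel (filtered clone-specific variants) with the
#' silencing channel into one row per gene, with coverage = fraction of
#' screened clones explained by either channel.
#'
#' @param mutated Tibble `clone_id`, `gene` of qualifying mutations (e.g.
#'   row-bound [filter_clone_specific()] output).
#' @param silenced Tibble `clone_id`, `gene` of silencing flags (e.g.
#'   [expression_silencing()] output restricted to `silenced`).
#' @param clones Character vector of all screened clone ids (the coverage
#'   denominator).
#' @return Tibble `gene`, `clones_mutated`, `clones_silenced` (list
#'   columns), `n_mutated`, `n_silenced`, `coverage`.
#' @export
build_gene_evidence <- function(mutated, silenced, clones) {
  stopifnot(length(clones) >= 1L)
  mut <- mutated |>
    dplyr::filter(!is.na(.data$gene), .data$clone_id %in% clones) |>
    dplyr::distinct(.data$clone_id, .data$gene)
  sil <- silenced
  if ("silenced" %in% names(sil)) sil <- dplyr::filter(sil, .data$silenced)
  sil <- sil |>
    dplyr::filter(!is.na(.data$gene), .data$clone_id %in% clones) |>
    dplyr::distinct(.data$clone_id, .data$gene)
  genes <- sort(union(mut$gene, sil$gene))
  purrr::map_dfr(genes, function(g) {
    cm <- sort(mut$clone_id[mut$gene == g])
    cs <- sort(sil$clone_id[sil$gene == g])
    tibble::tibble(
      gene = g,
      clones_mutated = list(cm),
      clones_silenced = list(cs),
      n_mutated = length(cm),
      n_silenced = length(cs),
      coverage = length(union(cm, cs)) / length(clones)
    )
  })
}

#' Nominate causal candidates
#'
#' Ranks genes by coverage (fraction of clones explained by mutation or
#' silencing) descending, then by number of mutated clones, then gene id.
#' Genes explaining every clone are labelled full-coverage candidates — the
#' inference pattern that singles out the bioactivating enzyme.
#'
#' @param evidence Tibble from [build_gene_evidence()].
#' @return `evidence` ranked, with logical `full_coverage` and integer
#'   `rank` columns.
#' @export
nominate_candidates <- function(evidence) {
  if (nrow(evidence) == 0L) {
    return(dplyr::mutate(evidence, full_coverage = logical(0),
                         rank = integer(0)))
  }
  evidence |>
    dplyr::arrange(dplyr::desc(.data$coverage), dplyr::desc(.data$n_mutated),
                   .data$gene) |>
    dplyr::mutate(full_coverage = .data$coverage >= 1,
                  rank = dplyr::row_number())
}

#' Export the bipartite gene-clone graph
#'
#' Writes the evidence as a SIF edge list (`gene <relation> clone`, one edge
#' per line, relation `mutated` or `silenced`) with deterministic ordering,
#' suitable for Cytoscape import.
#'
#' @param evidence Tibble from [build_gene_evidence()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
export_gene_clone_graph <- function(evidence, path) {
  edges <- purrr::pmap_dfr(
    list(evidence$gene, evidence$clones_mutated, evidence$clones_silenced),
    function(g, cm, cs) {
      dplyr::bind_rows(
        tibble::tibble(gene = g, relation = "mutated",
                       clone = as.character(cm)),
        tibble::tibble(gene = g, relation = "silenced",
                       clone = as.character(cs))
      )
    }
  )
  if (nrow(edges) > 0L) {
    edges <- dplyr::arrange(edges, .data$gene, .data$relation, .data$clone)
    writeLines(sprintf("%s\t%s\t%s", edges$gene, edges$relation, edges$clone),
               path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

#' Run the full resistance-screen inference
#'
#' Convenience wrapper chaining the screen stages on an in-memory variant
#' table and count matrix: per-clone parental subtraction and filtering,
#' gene recurrence, silencing detection, evidence assembly and candidate
#' nomination.
#'
#' @param variants Variant tibble including `clone_id = parental_id` rows.
#' @param counts Gene x sample count matrix with a column per clone plus the
#'   parental column.
#' @param parental_id Clone id / column name of the parental line.
#' @param policy A [filter_policy()].
#' @param sil_policy A [silencing_policy()].
#' @param min_clones Recurrence threshold (see [gene_recurrence()]).
#' @return List with `filtered`, `recurrence`, `silencing` (flagged rows),
#'   `evidence`, `candidates`.
#' @export
run_resistance_screen <- function(variants, counts, parental_id = "parental",
                                  policy = filter_policy(),
                                  sil_policy = silencing_policy(),
                                  min_clones = 3L) {
  clones <- setdiff(unique(variants$clone_id), parental_id)
  parental <- dplyr::filter(variants, .data$clone_id == parental_id)
  filtered <- purrr::map_dfr(clones, function(cl) {
    filter_clone_specific(
      dplyr::filter(variants, .data$clone_id == cl), parental, policy)
  })
  silencing <- expression_silencing(
    counts,
    parental_samples = parental_id,
    clone_samples = setNames(as.list(intersect(clones, colnames(counts))),
                             intersect(clones, colnames(counts))),
    policy = sil_policy, flagged_only = TRUE
  )
  evidence <- build_gene_evidence(filtered, silencing, clones)
  list(
    filtered = filtered,
    recurrence = gene_recurrence(filtered, min_clones = min_clones),
    silencing = silencing,
    evidence = evidence,
    candidates = nominate_candidates(evidence)
  )
}
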