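make_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"a\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, lines), path)
  path
}

test_that("VCF reading decomposes alleles and parses ANN, DP, AF", {
  path <- make_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tDP=30;AF=0.95;ANN=G|missense_variant|MODERATE|GENE1|GENE1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\tDP=40;AF=0.5,0.4;ANN=T|stop_gained|HIGH|GENE2|GENE2,G|missense_variant|MODERATE|GENE2|GENE2",
    "chr2\t300\t.\tG\tA\t.\tPASS\tDP=12;AF=0.99"
  ))
  v <- read_annotated_variants(path, clone_id = "cl")
  expect_equal(nrow(v), 4L)  # multi-allelic record decomposed
  expect_equal(v$clone_id, rep("cl", 4))
  expect_equal(v$gene[1], "GENE1")
  expect_equal(v$consequence[1], "missense_variant")
  # per-allele ANN matching on the split record
  two <- v[v$pos == 200, ]
  expect_equal(two$alt, c("T", "G"))
  expect_equal(two$consequence, c("stop_gained", "missense_variant"))
  expect_equal(two$af, c(0.5, 0.4))
  # record without ANN
  expect_equal(v$consequence[v$pos == 300], "unannotated")
  expect_equal(v$dp, c(30L, 40L, 40L, 12L))
})

test_that("clone-specific filter applies all four rules with correct strictness", {
  pol <- filter_policy()
  parental <- tibble::tibble(clone_id = "parental", chrom = "chr1",
                             pos = 5L, ref = "A", alt = "G",
                             gene = "gP", consequence = "missense_variant",
                             af = 0.3, dp = 50L)
  clone <- tibble::tibble(
    clone_id = "c",
    chrom = "chr1", pos = c(1L, 2L, 3L, 4L, 5L, 6L),
    ref = "A", alt = "G",
    gene = paste0("g", 1:6),
    consequence = c("missense_variant", "missense_variant",
                    "missense_variant", "synonymous_variant",
                    "missense_variant", "stop_gained"),
    af = c(0.95, 0.95, 0.85, 0.95, 0.95, 0.90),
    dp = c(20L, 10L, 20L, 20L, 20L, 11L)
  )
  kept <- filter_clone_specific(clone, parental, pol)
  # pos1 passes; pos2 dp=10 not >10; pos3 af<0.9; pos4 synonymous;
  # pos5 masked by parental at any parental AF; pos6 af=0.9 inclusive, dp=11
  expect_setequal(kept$pos, c(1L, 6L))
  expect_equal(nrow(filter_clone_specific(clone[0, ], parental, pol)), 0L)
})

test_that("filter matches the brute-force rule oracle on random tables", {
  set.seed(12)
  pol <- filter_policy()
  for (i in 1:60) {
    clone <- random_variant_tbl(sample(0:20, 1))
    parental <- random_variant_tbl(sample(0:10, 1), clone_id = "parental")
    got <- filter_clone_specific(clone, parental, pol)
    want <- bf_filter(clone, parental, pol$af_min, pol$dp_min,
                      pol$consequence_set)
    expect_equal(dplyr::arrange(got, chrom, pos, alt),
                 dplyr::arrange(want, chrom, pos, alt))
  }
})

test_that("tightening thresholds never grows the retained set", {
  set.seed(13)
  for (i in 1:20) {
    clone <- random_variant_tbl(25)
    parental <- random_variant_tbl(5, clone_id = "parental")
    base <- filter_clone_specific(clone, parental, filter_policy())
    tighter_af <- filter_clone_specific(clone, parental,
                                        filter_policy(af_min = 0.97))
    tighter_dp <- filter_clone_specific(clone, parental,
                                        filter_policy(dp_min = 25))
    key <- function(x) paste(x$chrom, x$pos, x$alt)
    expect_true(all(key(tighter_af) %in% key(base)))
    expect_true(all(key(tighter_dp) %in% key(base)))
  }
})

test_that("gene recurrence counts clones, breaks ties lexically, honors min_clones", {
  cg <- tibble::tibble(
    clone_id = c("A", "A", "B", "C", "C", "D"),
    gene = c("g1", "g2", "g1", "g1", "g3", "g1"))
  r <- gene_recurrence(cg, min_clones = 3)
  expect_equal(r$gene, "g1")
  expect_equal(r$n_clones, 4L)
  expect_equal(r$clones, "A,B,C,D")

  expect_equal(nrow(gene_recurrence(cg[0, ], 3)), 0L)

  tie <- tibble::tibble(clone_id = rep(c("A", "B", "C"), 2),
                        gene = rep(c("g2", "g1"), each = 3))
  rt <- gene_recurrence(tie, min_clones = 3)
  expect_equal(rt$gene, c("g1", "g2"))  # lexical within equal counts

  # lowering min_clones never shrinks the table
  r1 <- gene_recurrence(cg, min_clones = 1)
  expect_true(all(r$gene %in% r1$gene))
  expect_gte(nrow(r1), nrow(r))
})

test_that("expression silencing flags by CPM fold with floor and pseudocount", {
  # filler gene g0 fixes both library sizes at 1e6, so CPM = raw count
  par_counts <- c(200L, 800L, 2L, 2L, 4L, 2L, 100L)
  cl_counts <- c(1L, 799L, 2L, 0L, 4L, 2L, 0L)
  counts <- matrix(
    c(1e6L - sum(par_counts), par_counts, 1e6L - sum(cl_counts), cl_counts),
    ncol = 2, dimnames = list(paste0("g", 0:7), c("parental", "c1")))
  pol <- silencing_policy(min_fold = 50, min_parental_cpm = 5,
                          pseudocount = 0.5)
  res <- expression_silencing(counts, "parental", list(c1 = "c1"), pol)
  g1 <- res[res$gene == "g1", ]
  expect_true(g1$silenced)      # ~200x CPM loss, well-expressed parent
  expect_gt(g1$fold, 50)
  expect_equal(g1$fold, 200.5 / 1.5, tolerance = 1e-9)
  g4 <- res[res$gene == "g4", ] # clone count 0: pseudocount keeps fold finite
  expect_true(is.finite(g4$fold))
  expect_false(g4$silenced)     # parental CPM 2 below the expression floor
  g7 <- res[res$gene == "g7", ] # clone 0 with expressed parent: flagged
  expect_true(g7$silenced)
  expect_equal(g7$fold, 100.5 / 0.5, tolerance = 1e-9)
  expect_false(any(res$silenced[res$gene %in% c("g0", "g2", "g3", "g5", "g6")]))

  zero <- counts; zero[, 2] <- 0L
  expect_error(expression_silencing(zero, "parental", list(c1 = "c1"), pol),
               "zero library")
  expect_error(expression_silencing(counts, "parental", list(c1 = "nope"),
                                    pol), "not in counts")
})

test_that("candidate nomination ranks by coverage and labels full coverage", {
  ev <- build_gene_evidence(
    mutated = tibble::tibble(clone_id = c("1", "2", "3", "1", "2"),
                             gene = c("X", "X", "X", "Y", "Y")),
    silenced = tibble::tibble(clone_id = "4", gene = "X"),
    clones = c("1", "2", "3", "4"))
  cand <- nominate_candidates(ev)
  expect_equal(cand$gene, c("X", "Y"))
  expect_equal(cand$coverage, c(1, 0.5))
  expect_equal(cand$full_coverage, c(TRUE, FALSE))
  expect_equal(cand$rank, 1:2)

  empty <- nominate_candidates(build_gene_evidence(
    tibble::tibble(clone_id = character(), gene = character()),
    tibble::tibble(clone_id = character(), gene = character()),
    clones = "1"))
  expect_equal(nrow(empty), 0L)
})

test_that("gene-clone graph export is deterministic SIF", {
  ev <- build_gene_evidence(
    mutated = tibble::tibble(clone_id = c("c1", "c2", "c3"), gene = "X"),
    silenced = tibble::tibble(clone_id = character(), gene = character()),
    clones = c("c1", "c2", "c3"))
  p1 <- tempfile(); p2 <- tempfile()
  export_gene_clone_graph(ev, p1)
  export_gene_clone_graph(ev, p2)
  expect_equal(readLines(p1), c("X\tmutated\tc1", "X\tmutated\tc2",
                                "X\tmutated\tc3"))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  pe <- tempfile()
  export_gene_clone_graph(ev[0, ], pe)
  expect_equal(length(readLines(pe)), 0L)
})
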