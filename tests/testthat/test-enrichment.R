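lfq_from_log2 <- function(s, r) {
  tibble::tibble(protein = "p1",
                 S_1 = 2^s[1], S_2 = 2^s[2], S_3 = 2^s[3],
                 R_1 = 2^r[1], R_2 = 2^r[2], R_3 = 2^r[3])
}
design6 <- tibble::tibble(sample = c("S_1", "S_2", "S_3", "R_1", "R_2", "R_3"),
                          condition = rep(c("S", "R"), each = 3))

test_that("pooled t on log2 intensities matches the hand-computed example", {
  res <- enrichment_stats(lfq_from_log2(c(8, 9, 10), c(1, 2, 3)), design6)
  # mean diff 7, pooled var 1, se = sqrt(2/3): t = 8.573 on 4 df
  expect_equal(res$log2fc, log2(mean(2^c(8, 9, 10)) / mean(2^c(1, 2, 3))))
  expect_equal(res$p, 2 * pt(-7 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(round(7 / sqrt(2 / 3), 3), 8.573)
})

test_that("identical conditions give zero fold change and p = 1", {
  res <- enrichment_stats(lfq_from_log2(c(8, 9, 10), c(8, 9, 10)), design6)
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)
})

test_that("enrichment stats match stats::t.test on random matrices", {
  set.seed(21)
  n <- 40
  m <- matrix(2^rnorm(n * 6, 20, 2), nrow = n)
  colnames(m) <- design6$sample
  lfq <- dplyr::bind_cols(tibble::tibble(protein = paste0("p", 1:n)),
                          tibble::as_tibble(m))
  res <- enrichment_stats(lfq, design6)
  res_w <- enrichment_stats(lfq, design6, var_equal = FALSE)
  for (i in seq_len(n)) {
    ref <- stats::t.test(log2(m[i, 1:3]), log2(m[i, 4:6]), var.equal = TRUE)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
    ref_w <- stats::t.test(log2(m[i, 1:3]), log2(m[i, 4:6]))
    expect_equal(res_w$p[i], ref_w$p.value, tolerance = 1e-10)
  }
})

test_that("proteins without two finite values per condition are flagged untested", {
  lfq <- lfq_from_log2(c(8, 9, 10), c(1, 2, 3))
  lfq$S_2 <- NA_real_
  lfq$S_3 <- 0       # non-positive intensity counts as missing
  res <- enrichment_stats(lfq, design6)
  expect_false(res$tested)
  expect_true(is.na(res$p))
  expect_error(
    enrichment_stats(lfq[, c("protein", "S_1", "R_1", "R_2")],
                     design6[c(1, 4, 5), ]),
    "at least 2 samples")
})

test_that("hit selection thresholds are strict and BH option tightens them", {
  res <- tibble::tibble(
    protein = paste0("p", 1:5),
    fc = c(2.0, 3, 3, 1.9, 60),
    p = c(0.01, 0.05, 0.01, 0.001, 0.049),
    tested = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  sel <- select_hits(res)
  expect_setequal(sel$protein, c("p3", "p5"))  # fc=2 and p=0.05 excluded
  sel_bh <- select_hits(res, adjust = "BH")
  expect_true(all(sel_bh$protein %in% sel$protein))
})

test_that("graph table encodes -log10 p as size deterministically", {
  res <- tibble::tibble(protein = c("b", "a"), fc = c(3, 70),
                        p = c(0.01, 1), tested = TRUE)
  g1 <- graph_table(res)
  expect_equal(g1$protein, c("a", "b"))  # ordered by id
  expect_equal(g1$size, c(0, 2))
  expect_identical(g1, graph_table(res))
})

test_that("PSSM scores are zero on an exactly background-matched window set", {
  # 20 windows; each non-center position carries each residue exactly once
  set.seed(81)
  cols <- replicate(21, sample(aa20), simplify = FALSE)
  wins <- vapply(1:20, function(i) {
    chars <- vapply(cols, function(cl) cl[i], character(1))
    chars[11] <- "K"
    paste(chars, collapse = "")
  }, character(1))
  # center column is all K, so make position 11's score check separate
  pssm <- context_pssm(context_window_set(wins, "K"), pseudo_freq = 0.01)
  off_center <- pssm[setdiff(rownames(pssm), "0"), ]
  expect_true(max(abs(off_center)) < 1e-12)
})

test_that("single-window PSSM has the closed-form score and pads are excluded", {
  w <- context_window_set("AAAAAAAAAAKAAAAAAAAAA", "K")
  pssm <- context_pssm(w, pseudo_freq = 0.01)
  expect_equal(pssm["-1", "A"], log2(1.01) - log2(0.06), tolerance = 1e-12)
  expect_equal(pssm["0", "K"], log2(1.01) - log2(0.06), tolerance = 1e-12)

  padded <- context_window_set(paste0("_____", strrep("A", 5), "K",
                                      strrep("A", 5), "_____"), "K")
  freq <- attr(context_pssm(padded), "observed_freq")
  expect_true(all(freq["-10", ] == 0))  # all-pad position excluded from counts
  expect_equal(freq["-1", "A"], 1)
})

test_that("PSSM observed frequencies match a brute-force tally and invert from scores", {
  set.seed(22)
  wins <- vapply(1:10, function(i) random_window("K"), character(1))
  w <- context_window_set(wins, "K")
  pssm <- context_pssm(w, pseudo_freq = 0.02)
  freq <- attr(pssm, "observed_freq")
  mat <- do.call(rbind, strsplit(wins, ""))
  for (pos in c(1, 5, 14, 21)) {
    tab <- table(factor(mat[, pos], levels = aa20)) / 10
    expect_equal(unname(freq[pos, ]), as.numeric(tab))
  }
  # exponentiating recovers frequencies up to the pseudo-frequency
  recon <- 2^pssm * matrix(1 / 20 + 0.02, 21, 20) - 0.02
  expect_equal(recon, freq, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("window-set construction validates shape and center residue", {
  expect_error(context_window_set(c("AAKAA", "AAKA"), "K"), "same length")
  expect_error(context_window_set("AAAKAA", "K"), "odd")
  expect_error(context_window_set("AACAA", "K"), "center residue")
})

test_that("hydrophobicity permutation test flags an all-leucine context", {
  w <- context_window_set(rep(paste0(strrep("L", 10), "K", strrep("L", 10)), 5),
                          "K")
  h <- hydrophobicity_enrichment(w, n_perm = 2000, seed = 2)
  expect_equal(h$statistic, 3.8)
  expect_lte(h$p_perm, 1 / 2000)
  expect_equal(h$n_residues, 100)

  expect_warning(
    hydrophobicity_enrichment(
      context_window_set(paste0(strrep("L", 10), "K", strrep("L", 10)), "K"),
      n_perm = 100, seed = 1),
    "low power")
})

test_that("hydrophobicity p-values are roughly uniform under the null", {
  set.seed(23)
  ps <- vapply(1:60, function(i) {
    wins <- vapply(1:8, function(j) random_window("C"), character(1))
    hydrophobicity_enrichment(context_window_set(wins, "C"),
                              n_perm = 400, seed = i)$p_perm
  }, numeric(1))
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
  # KS-style sanity: mean near 0.5, spread across the unit interval
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.25), 0.1)
  expect_gt(mean(ps > 0.75), 0.1)
})
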