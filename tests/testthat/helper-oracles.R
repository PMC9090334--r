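# Independent brute-force oracles used across the suite.

# adduct assignment by exhaustive search over all (base, n) pairs
bf_assign <- function(base_masses, peak, shift, max_adducts, tol) {
  best <- NULL
  for (b in seq_along(base_masses)) {
    for (n in 0:max_adducts) {
      resid <- peak - (base_masses[[b]] + n * shift)
      cand <- list(base = names(base_masses)[b], n = n, resid = resid)
      if (is.null(best) ||
          abs(resid) < abs(best$resid) - 1e-12 ||
          (abs(abs(resid) - abs(best$resid)) <= 1e-12 &&
           (n < best$n || (n == best$n && b < match(best$base, names(base_masses)))))) {
        best <- cand
      }
    }
  }
  if (abs(best$resid) <= tol) best else NULL
}

# clone-specific variant filter by independent literal rule application
bf_filter <- function(clone, parental, af_min, dp_min, consequence_set) {
  keep <- logical(nrow(clone))
  for (i in seq_len(nrow(clone))) {
    v <- clone[i, ]
    in_parental <- any(parental$chrom == v$chrom & parental$pos == v$pos &
                         parental$ref == v$ref & parental$alt == v$alt)
    keep[i] <- !in_parental && v$af >= af_min && v$dp > dp_min &&
      v$consequence %in% consequence_set
  }
  clone[keep, ]
}

# random small variant table for property tests
random_variant_tbl <- function(n, clone_id = "C") {
  tibble::tibble(
    clone_id = clone_id,
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    pos = sample(1:30, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sample(paste0("g", 1:8), n, replace = TRUE),
    consequence = sample(c("missense_variant", "stop_gained",
                           "synonymous_variant", "unannotated"),
                         n, replace = TRUE),
    af = round(runif(n, 0.5, 1), 2),
    dp = sample(0:40, n, replace = TRUE)
  )
}

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_window <- function(center = "K", width = 21L) {
  half <- (width - 1L) %/% 2L
  paste0(paste(sample(aa20, half, TRUE), collapse = ""), center,
         paste(sample(aa20, half, TRUE), collapse = ""))
}
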