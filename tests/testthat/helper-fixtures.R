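# small programmatic fixtures shared across test files

# a well-formed record table; override any field via ...
toy_records <- function(n = 3, ...) {
  rec <- data.frame(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "T"), length.out = n),
    eaf = seq(0.1, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.05, n),
    pval = rep(1e-9, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

toy_sumstats <- function(n = 3, trait_id = "trait", trait_type = "quantitative",
                         ...) {
  sumstats(toy_records(n, ...), trait_id, trait_type)
}

# instrument set built directly from effect vectors (already harmonized)
toy_instruments <- function(bx, by, sx = rep(0.05, length(bx)),
                            sy = rep(0.05, length(bx))) {
  n <- length(bx)
  pairs <- data.frame(
    variant_id = sprintf("rs%d", seq_len(n)), chrom = "1", pos = seq_len(n),
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = sx, pval_exp = 1e-10, eaf_exp = 0.3,
    beta_out = by, se_out = sy, pval_out = 0.01, eaf_out = 0.3,
    action = "kept", stringsAsFactors = FALSE)
  instrument_set(pairs)
}

# independent brute-force greedy clumping oracle (straight transcription of
# the rule, no shared code with clump_variants)
clump_oracle <- function(rec, rmat, r2_max, window_kb) {
  rec <- rec[order(rec$pval, rec$variant_id), ]
  kept <- character(0)
  for (k in seq_len(nrow(rec))) {
    ok <- TRUE
    for (j in seq_along(kept)) {
      pos_j <- rec$pos[rec$variant_id == kept[j]]
      if (abs(rec$pos[k] - pos_j) <= window_kb * 1000 &&
          rmat[rec$variant_id[k], kept[j]]^2 >= r2_max) ok <- FALSE
    }
    if (ok) kept <- c(kept, rec$variant_id[k])
  }
  kept
}
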