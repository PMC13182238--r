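ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) ALLELE_COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants on id and aligns the outcome effect to the exposure's
#' effect allele. Swapped alleles flip the outcome beta sign and replace the
#' outcome frequency by its complement (`action = "sign_flipped"`); alleles on
#' the opposite strand are complemented and re-compared
#' (`action = "strand_flipped"`, with a sign flip when the complemented
#' alleles are additionally swapped). Palindromic (A/T or C/G) variants are
#' aligned by effect-allele frequency; those with frequency within
#' `palindrome_eaf_window` of 0.5 on either trait, or with missing frequency,
#' are ambiguous and dropped (`action = "dropped_palindromic"`).
#' Irreconcilable allele sets are dropped (`action = "dropped_mismatch"`).
#'
#' Harmonization is idempotent: re-harmonizing the kept pairs changes nothing.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_window half-width of the ambiguity band around
#'   eaf = 0.5 for palindromic variants (default 0.08, i.e. \[0.42, 0.58\]).
#' @return data.frame of class `harmonized_pairs` with one row per shared
#'   variant: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_exp`, `se_exp`, `pval_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `pval_out`, `eaf_out`, `action`. Kept rows are those with action in
#'   `kept`, `sign_flipped`, `strand_flipped`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (nrow(exposure) == 0L || nrow(outcome) == 0L)
    stopf("both summary-statistic sets must be non-empty")
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L) {
    warnf("no shared variants between exposure and outcome")
    return(empty_pairs())
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$variant_id), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$variant_id), ]

  out <- data.frame(
    variant_id = shared, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval, eaf_exp = ex$eaf,
    beta_out = ou$beta, se_out = ou$se, pval_out = ou$pval, eaf_out = ou$eaf,
    action = NA_character_, stringsAsFactors = FALSE)

  for (k in seq_along(shared)) {
    ea <- ex$effect_allele[k]; oa <- ex$other_allele[k]
    bea <- ou$effect_allele[k]; boa <- ou$other_allele[k]
    pal <- is_palindromic(ea, oa)
    if (pal) {
      # complement equals swap: strand orientation is unresolvable from
      # alleles alone; use allele frequency, dropping near-0.5 or missing
      if (!setequal(c(ea, oa), c(bea, boa))) {
        out$action[k] <- "dropped_mismatch"; next
      }
      ef <- ex$eaf[k]; of <- ou$eaf[k]
      if (is.na(ef) || is.na(of) ||
          abs(ef - 0.5) <= palindrome_eaf_window ||
          abs(of - 0.5) <= palindrome_eaf_window) {
        out$action[k] <- "dropped_palindromic"; next
      }
      if (bea == ea) {
        # frequencies on opposite sides of 0.5 imply opposite-strand report
        if (sign(ef - 0.5) != sign(of - 0.5)) {
          out$beta_out[k] <- -ou$beta[k]
          out$eaf_out[k] <- 1 - ou$eaf[k]
          out$action[k] <- "sign_flipped"
        } else out$action[k] <- "kept"
      } else {
        if (sign(ef - 0.5) == sign(1 - of - 0.5)) {
          out$beta_out[k] <- -ou$beta[k]
          out$eaf_out[k] <- 1 - ou$eaf[k]
          out$action[k] <- "sign_flipped"
        } else out$action[k] <- "kept"
      }
      next
    }
    if (bea == ea && boa == oa) {
      out$action[k] <- "kept"
    } else if (bea == oa && boa == ea) {
      out$beta_out[k] <- -ou$beta[k]
      out$eaf_out[k] <- 1 - ou$eaf[k]
      out$action[k] <- "sign_flipped"
    } else {
      cea <- unname(ALLELE_COMPLEMENT[bea]); coa <- unname(ALLELE_COMPLEMENT[boa])
      if (cea == ea && coa == oa) {
        out$action[k] <- "strand_flipped"
      } else if (cea == oa && coa == ea) {
        out$beta_out[k] <- -ou$beta[k]
        out$eaf_out[k] <- 1 - ou$eaf[k]
        out$action[k] <- "strand_flipped"
      } else {
        out$action[k] <- "dropped_mismatch"
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

empty_pairs <- function() {
  out <- data.frame(
    variant_id = character(0), chrom = character(0), pos = numeric(0),
    effect_allele = character(0), other_allele = character(0),
    beta_exp = numeric(0), se_exp = numeric(0), pval_exp = numeric(0),
    eaf_exp = numeric(0), beta_out = numeric(0), se_out = numeric(0),
    pval_out = numeric(0), eaf_out = numeric(0), action = character(0),
    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

kept_pairs <- function(pairs) {
  pairs[pairs$action %in% c("kept", "sign_flipped", "strand_flipped"), ,
        drop = FALSE]
}

#' Greedy LD clumping
#'
#' Prunes variants to an approximately independent set: variants are sorted by
#' ascending p-value (ties broken by lexicographic variant id) and retained iff
#' their squared correlation with every already-retained variant within
#' `window_kb` kilobases (closed interval on base-pair distance) is below
#' `r2_max`. Variant pairs absent from the LD matrix are treated as r = 0 with
#' a warning.
#'
#' @param records a [sumstats] object (or data.frame with `variant_id`, `pos`,
#'   `pval`).
#' @param ld an [ld_matrix], or `NULL` to treat all pairs as uncorrelated.
#' @param r2_max clumping threshold on r-squared, in (0, 1\] (default 0.01).
#' @param window_kb window in kilobases within which LD is considered
#'   (default 10000).
#' @return character vector of retained variant ids in selection order.
#' @export
clump_variants <- function(records, ld = NULL, r2_max = 0.01, window_kb = 10000) {
  if (!is.numeric(r2_max) || length(r2_max) != 1L || is.na(r2_max) ||
      r2_max <= 0 || r2_max > 1)
    stopf("r2_max must lie in (0, 1]")
  rec <- as.data.frame(records)
  if (nrow(rec) == 0L) return(character(0))
  ord <- order(rec$pval, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  kept_id <- character(0); kept_pos <- numeric(0)
  missing_ld <- FALSE
  rmat <- if (is.null(ld)) NULL else unclass(ld)
  for (k in seq_len(nrow(rec))) {
    id <- rec$variant_id[k]; pos <- rec$pos[k]
    in_window <- which(abs(kept_pos - pos) <= window_kb * 1000)
    ok <- TRUE
    for (j in in_window) {
      if (is.null(rmat) || !(id %in% rownames(rmat)) ||
          !(kept_id[j] %in% rownames(rmat))) {
        missing_ld <- missing_ld || !is.null(rmat)
        next  # absent pair: r = 0
      }
      if (rmat[id, kept_id[j]]^2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) { kept_id <- c(kept_id, id); kept_pos <- c(kept_pos, pos) }
  }
  if (missing_ld)
    warnf("variant pairs absent from the LD matrix treated as r = 0")
  kept_id
}

#' Instrument sets
#'
#' Container for harmonized instrument pairs surviving selection, clumping and
#' strength filtering, with per-instrument F statistics.
#'
#' @param pairs kept rows of a [harmonize()] result.
#' @param exposure_id,outcome_id trait labels carried into reports.
#' @return object of class `instrument_set`: the pairs data.frame plus
#'   attributes `f_per_snp`, `f_mean`, `exposure_id`, `outcome_id`.
#' @export
instrument_set <- function(pairs, exposure_id = "exposure",
                           outcome_id = "outcome") {
  pairs <- kept_pairs(pairs)
  f <- (pairs$beta_exp / pairs$se_exp)^2
  structure(as.data.frame(pairs),
            f_per_snp = f,
            f_mean = if (length(f)) mean(f) else NA_real_,
            exposure_id = exposure_id, outcome_id = outcome_id,
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set %s -> %s: %d instruments (mean F = %.1f)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x),
              attr(x, "f_mean")))
  print(as.data.frame(x)[, c("variant_id", "beta_exp", "se_exp", "beta_out",
                             "se_out", "action")], ...)
  invisible(x)
}

#' Select genetic instruments for two-sample MR
#'
#' Filters the exposure to genome-wide-significant variants, clumps them for
#' linkage disequilibrium, harmonizes against the outcome, and computes
#' per-instrument F statistics (squared exposure z, `(beta/se)^2`).
#'
#' @inheritParams harmonize
#' @param ld an [ld_matrix] or `NULL`.
#' @param p_threshold exposure p-value threshold (default 5e-8).
#' @param r2_max,window_kb clumping parameters (defaults 0.01 and 10000 kb).
#' @param f_min instruments with F below this are dropped (default 10);
#'   set to 0 to keep all.
#' @return An [instrument_set]; empty (zero rows) with a warning when no
#'   instrument survives.
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               p_threshold = 5e-8, r2_max = 0.01,
                               window_kb = 10000, palindrome_eaf_window = 0.08,
                               f_min = 10) {
  hits <- as.data.frame(exposure)[exposure$pval < p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warnf("no valid instruments: no exposure variant passes p < %g", p_threshold)
    return(instrument_set(empty_pairs(), attr(exposure, "trait_id"),
                          attr(outcome, "trait_id")))
  }
  keep <- clump_variants(hits, ld, r2_max = r2_max, window_kb = window_kb)
  sub <- sumstats(hits[match(keep, hits$variant_id), , drop = FALSE],
                  trait_id = attr(exposure, "trait_id"),
                  trait_type = attr(exposure, "trait_type"))
  pairs <- harmonize(sub, outcome, palindrome_eaf_window = palindrome_eaf_window)
  iv <- instrument_set(pairs, attr(exposure, "trait_id"),
                       attr(outcome, "trait_id"))
  if (f_min > 0 && nrow(iv) > 0L) {
    f <- attr(iv, "f_per_snp")
    iv <- instrument_set(iv[f > f_min, , drop = FALSE],
                         attr(iv, "exposure_id"), attr(iv, "outcome_id"))
  }
  if (nrow(iv) == 0L) warnf("no valid instruments after harmonization/filters")
  iv
}
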