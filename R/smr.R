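#' Summary-data-based MR test
#'
#' Tests whether a trait effect is mediated by a molecular exposure (e.g.
#' gene expression) through its top cis-QTL. With `z_x = beta_exp/se_exp` and
#' `z_y = beta_out/se_out`, the statistic is
#' `T_SMR = z_x^2 z_y^2 / (z_x^2 + z_y^2)`, chi-square on 1 df. The effect
#' estimate is the ratio `beta_out/beta_exp` with standard error
#' `|b_smr| * sqrt(1/z_x^2 + 1/z_y^2)`.
#'
#' Vectorized over SNPs.
#'
#' @param beta_exp,se_exp exposure (QTL) effect and standard error.
#' @param beta_out,se_out outcome (GWAS) effect and standard error.
#' @return list with `b_smr`, `se_smr`, `p_smr`, `t_smr`.
#' @export
smr_test <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stopf("undefined SMR ratio: exposure effect is zero")
  zx2 <- (beta_exp / se_exp)^2
  zy2 <- (beta_out / se_out)^2
  t_smr <- ifelse(zx2 + zy2 == 0, 0, zx2 * zy2 / (zx2 + zy2))
  b <- beta_out / beta_exp
  list(b_smr = b,
       se_smr = abs(b) * sqrt(1 / zx2 + 1 / zy2),
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
       t_smr = t_smr)
}

# tail probability of sum(lam_k * chisq_1) by moment matching: a shifted,
# scaled (possibly non-central) chi-square matched to the first three moments
# (Liu, Tang & Zhang); falls back to two-moment Satterthwaite when the
# skewness relation is degenerate
pwsumchisq <- function(t, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  if (c2 == 0) return(as.numeric(t <= 0))
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    df <- a^2
  }
  tstar <- (t - c1) / sqrt(2 * c2)
  q <- tstar * sqrt(2 * (df + 2 * delta)) + df + delta
  stats::pchisq(max(q, 0), df = df, ncp = delta, lower.tail = FALSE)
}

# delta-method covariance of the per-SNP ratio estimates b_i = by_i/bx_i,
# given LD correlations r (shared across the two independent samples)
smr_ratio_cov <- function(bx, sx, by, sy, r) {
  gy <- 1 / bx                 # d(b)/d(by)
  gx <- -by / bx^2             # d(b)/d(bx)
  covy <- r * tcrossprod(sy)   # cov(by_i, by_j)
  covx <- r * tcrossprod(sx)
  tcrossprod(gy) * covy + tcrossprod(gx) * covx
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (SMR ratio constant across
#' SNPs in LD with the top QTL) from linkage of distinct variants. Candidate
#' SNPs are those with QTL `|z| >= z_min` and squared correlation with the top
#' SNP in `[r2_low, r2_high]`, capped at `max_snps` by descending `|z|`. For
#' each candidate the deviation `d_i = b_smr(i) - b_smr(top)` is standardized
#' using a delta-method covariance propagated from the LD matrix;
#' `T_HEIDI = sum(z_d^2)` follows a weighted sum of chi-squares (weights: the
#' eigenvalues of the correlation matrix of d) whose tail is approximated by
#' moment matching a scaled non-central chi-square to the mixture's first
#' three moments.
#'
#' @param region_pairs harmonized QTL/GWAS pairs for the region (kept rows of
#'   [harmonize()], or an [instrument_set]).
#' @param ld an [ld_matrix] covering the used variants.
#' @param top_id variant id of the top QTL SNP (must be in `region_pairs`).
#' @param z_min minimum absolute QTL z of candidate SNPs (default 3.16,
#'   i.e. p about 1.6e-3).
#' @param r2_low,r2_high LD window with the top SNP (defaults 0.05 and 0.9).
#' @param max_snps candidate cap (default 20).
#' @return list with `t_heidi`, `n_used`, `p_heidi` (`NA` when fewer than 3
#'   candidates), `candidate_ids`, the two-moment (Satterthwaite) `scale` and
#'   `df` summaries of the null mixture, and its `eigenvalues`.
#' @export
heidi_test <- function(region_pairs, ld, top_id, z_min = 3.16,
                       r2_low = 0.05, r2_high = 0.9, max_snps = 20) {
  pr <- kept_pairs(region_pairs)
  if (!top_id %in% pr$variant_id) stopf("top_id '%s' not in region", top_id)
  rmat <- unclass(ld)
  if (!all(pr$variant_id %in% rownames(rmat)))
    stopf("LD matrix must cover all region variants")
  zx <- abs(pr$beta_exp / pr$se_exp)
  r2_top <- rmat[pr$variant_id, top_id]^2
  cand <- pr$variant_id != top_id & zx >= z_min &
    r2_top >= r2_low & r2_top <= r2_high
  ids <- pr$variant_id[cand][order(-zx[cand])]
  if (length(ids) > max_snps) ids <- ids[seq_len(max_snps)]
  n_used <- length(ids)
  if (n_used < 3L)
    return(list(t_heidi = NA_real_, n_used = n_used, p_heidi = NA_real_,
                candidate_ids = ids, scale = NA_real_, df = NA_real_,
                eigenvalues = numeric(0)))

  use <- c(top_id, ids)
  i <- match(use, pr$variant_id)
  bx <- pr$beta_exp[i]; sx <- pr$se_exp[i]
  by <- pr$beta_out[i]; sy <- pr$se_out[i]
  r <- rmat[use, use]
  b <- by / bx
  cv <- smr_ratio_cov(bx, sx, by, sy, r)
  k <- seq_along(ids) + 1L
  # cov of d_i = b_i - b_top
  vd <- cv[k, k, drop = FALSE] -
    matrix(cv[k, 1L], n_used, n_used) -
    matrix(cv[k, 1L], n_used, n_used, byrow = TRUE) + cv[1L, 1L]
  d <- b[k] - b[1L]
  sd_d <- sqrt(diag(vd))
  zd <- d / sd_d
  t_heidi <- sum(zd^2)
  rd <- vd / tcrossprod(sd_d)
  lam <- eigen(rd, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  scale <- sum(lam^2) / sum(lam)
  df <- sum(lam)^2 / sum(lam^2)
  p <- pwsumchisq(t_heidi, lam)
  list(t_heidi = t_heidi, n_used = n_used, p_heidi = p,
       candidate_ids = ids, scale = scale, df = df, eigenvalues = lam)
}

#' Run SMR + HEIDI for one gene region
#'
#' Harmonizes the QTL (exposure) against the GWAS (outcome) over the region,
#' takes the top cis-QTL by smallest exposure p-value, computes the SMR test
#' at that SNP and the HEIDI test over the region.
#'
#' @param exposure QTL [sumstats] for the gene's cis region.
#' @param outcome GWAS [sumstats].
#' @param ld an [ld_matrix] covering the region.
#' @param gene_id gene label.
#' @param ... passed to [heidi_test()].
#' @return object of class `smr_result`: list with `gene_id`, `top_id`,
#'   `b_smr`, `se_smr`, `p_smr`, `p_smr_fdr` (`NA` until [smr_fdr()]),
#'   `p_heidi`, `n_heidi_snps`.
#' @export
run_smr <- function(exposure, outcome, ld, gene_id = attr(exposure, "trait_id"),
                    ...) {
  pairs <- kept_pairs(harmonize(exposure, outcome))
  if (nrow(pairs) == 0L) stopf("no shared variants for gene %s", gene_id)
  top <- pairs$variant_id[which.min(pairs$pval_exp)]
  tp <- pairs[pairs$variant_id == top, ]
  s <- smr_test(tp$beta_exp, tp$se_exp, tp$beta_out, tp$se_out)
  h <- heidi_test(pairs, ld, top, ...)
  structure(list(gene_id = gene_id, top_id = top, b_smr = s$b_smr,
                 se_smr = s$se_smr, p_smr = s$p_smr, p_smr_fdr = NA_real_,
                 p_heidi = h$p_heidi, n_heidi_snps = h$n_used),
            class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR %s (top SNP %s): b = %.4g (se %.4g), p = %.3g%s; HEIDI p = %s (%d SNPs)\n",
              x$gene_id, x$top_id, x$b_smr, x$se_smr, x$p_smr,
              if (is.na(x$p_smr_fdr)) "" else sprintf(" (FDR %.3g)", x$p_smr_fdr),
              if (is.na(x$p_heidi)) "NA" else sprintf("%.3g", x$p_heidi),
              x$n_heidi_snps))
  invisible(x)
}

#' Benjamini-Hochberg correction across genes of one SMR analysis
#'
#' Fills `p_smr_fdr` across the genes of a single analysis (one tissue/cohort
#' at a time). Never decreases a p-value and is invariant to input order.
#'
#' @param results list of `smr_result` objects, or a data.frame with a
#'   `p_smr` column.
#' @return same collection with `p_smr_fdr` filled.
#' @export
smr_fdr <- function(results) {
  if (is.data.frame(results)) {
    results$p_smr_fdr <- bh_adjust(results$p_smr)
    return(results)
  }
  stopifnot(length(results) >= 1L)
  q <- bh_adjust(vapply(results, `[[`, numeric(1), "p_smr"))
  for (i in seq_along(results)) results[[i]]$p_smr_fdr <- q[i]
  results
}

#' Flatten SMR results to the output table layout
#'
#' @param results list of `smr_result` objects.
#' @return data.frame with columns gene, probe_snp, b_smr, se_smr, p_smr,
#'   p_smr_fdr, p_heidi, n_heidi_snps.
#' @export
smr_table <- function(results) {
  do.call(rbind, lapply(results, function(x)
    data.frame(gene = x$gene_id, probe_snp = x$top_id, b_smr = x$b_smr,
               se_smr = x$se_smr, p_smr = x$p_smr, p_smr_fdr = x$p_smr_fdr,
               p_heidi = x$p_heidi, n_heidi_snps = x$n_heidi_snps,
               stringsAsFactors = FALSE)))
}
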