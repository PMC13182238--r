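#' Simulate an LD reference panel
#'
#' Builds a panel of `m_snps` variants whose population linkage-disequilibrium
#' correlation follows an AR(1) target `r_ij = rho^|i-j|`. The panel's
#' published LD (`$ld`, what downstream analyses consume) is the empirical
#' correlation of `n_ref` Gaussian haplotype vectors drawn with the target
#' correlation, i.e. the target perturbed by reference-panel sampling noise;
#' the exact target is kept as `$ld_true` and is what [simulate_gwas()]
#' generates from. Negative eigenvalues of the empirical matrix (possible
#' only when `n_ref < m_snps`) are clipped to zero; generation fails if this
#' nearest-PSD repair moves the matrix by more than 1e-6 in Frobenius norm.
#'
#' @param m_snps number of variants (>= 1).
#' @param n_ref reference-panel size (default 5000 haplotypes).
#' @param rho AR(1) decay of the target LD, in \[0, 1).
#' @param maf_range range of minor-allele frequencies, within (0, 0.5\].
#' @param seed RNG seed (mandatory).
#' @return object of class `reference_panel`: list with `variant_ids`,
#'   `positions` (1-based bp), `mafs`, `ld` (an [ld_matrix], empirical),
#'   `ld_true` (the AR(1) target), `n_ref`.
#' @export
simulate_panel <- function(m_snps, n_ref = 5000, rho = 0, maf_range = c(0.05, 0.5),
                           seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) stopf("rho must lie in [0, 1)")
  if (!is_count(m_snps)) stopf("m_snps must be a positive integer")
  target <- rho^abs(outer(seq_len(m_snps), seq_len(m_snps), `-`))
  withr_seed(seed, {
    hap <- rmvnorm_chol(n_ref, rep(0, m_snps), target)
    r <- stats::cor(hap)
    mafs <- stats::runif(m_snps, maf_range[1], maf_range[2])
    positions <- cumsum(sample(1000:10000, m_snps, replace = TRUE))
  })
  ids <- sprintf("snp%03d", seq_len(m_snps))
  ev <- eigen(r, symmetric = TRUE)
  if (any(ev$values < 0)) {
    vals <- pmax(ev$values, 0)
    r_fix <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r_fix)); r_fix <- r_fix / tcrossprod(d)
    if (sqrt(sum((r_fix - r)^2)) > 1e-6)
      stopf("nearest-PSD repair moved the LD matrix by > 1e-6; increase n_ref")
    r <- (r_fix + t(r_fix)) / 2; diag(r) <- 1
  }
  structure(list(variant_ids = ids, positions = positions, mafs = mafs,
                 ld = ld_matrix(r, ids), ld_true = ld_matrix(target, ids),
                 n_ref = n_ref),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d variants over %.0f kb (n_ref = %d)\n",
              length(x$variant_ids), max(x$positions) / 1000, x$n_ref))
  invisible(x)
}

#' Simulate GWAS summary statistics from a reference panel
#'
#' Draws marginal per-SNP statistics directly from the multivariate-normal
#' model for GWAS z-scores: with standardized joint (causal) effects `lambda`
#' and the panel's population LD `R` (`$ld_true`), the observed z vector is
#' drawn from `MVN(sqrt(n) R lambda, R)`; the analyst-facing empirical panel
#' LD plays no part in generation. Standardized effects `z/sqrt(n)` are
#' back-transformed to the allelic scale via `1/sqrt(2 maf (1-maf))`;
#' p-values come from the normal tail. Deterministic under `seed`.
#'
#' @param panel a [simulate_panel()] result.
#' @param effects standardized joint effects, length `m_snps` (or named by
#'   variant id with omitted entries zero).
#' @param n GWAS sample size (> 1).
#' @param seed RNG seed (mandatory).
#' @param trait_id,trait_type passed to [sumstats()].
#' @return A [sumstats] object (effect allele `A`, other allele `G`).
#' @export
simulate_gwas <- function(panel, effects, n, seed, trait_id = "trait",
                          trait_type = "quantitative") {
  if (missing(seed)) stopf("seed is mandatory")
  if (!is.numeric(n) || n <= 1) stopf("sample size n must exceed 1")
  m <- length(panel$variant_ids)
  lam <- rep(0, m)
  if (!is.null(names(effects))) {
    idx <- match(names(effects), panel$variant_ids)
    if (anyNA(idx)) stopf("effect names must be panel variant ids")
    lam[idx] <- effects
  } else {
    stopifnot(length(effects) == m)
    lam <- as.numeric(effects)
  }
  r <- unclass(panel$ld_true %||% panel$ld)
  mu <- sqrt(n) * drop(r %*% lam)
  z <- withr_seed(seed, drop(rmvnorm_chol(1, mu, r)))
  se_std <- 1 / sqrt(n)
  scale <- 1 / sqrt(2 * panel$mafs * (1 - panel$mafs))
  rec <- data.frame(
    variant_id = panel$variant_ids, chrom = "1", pos = panel$positions,
    effect_allele = "A", other_allele = "G", eaf = panel$mafs,
    beta = z * se_std * scale, se = se_std * scale,
    pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = n,
    stringsAsFactors = FALSE)
  sumstats(rec, trait_id = trait_id, trait_type = trait_type)
}

#' Simulation configuration
#'
#' Bundles and validates the settings consumed by [make_scenario()]. Defaults
#' are the package's reference study conditions: 50 independent instruments at
#' biobank-scale sample sizes for instrument-level scenarios, and a 30-SNP
#' AR(1) cis region with a strong molecular-QTL signal for region-level
#' scenarios.
#'
#' @param scenario one of `causal`, `pleiotropy`, `linkage`, `shared`,
#'   `mediation`, `null`.
#' @param m_snps region/instrument count.
#' @param n_exposure,n_outcome GWAS sample sizes; default 50000/50000 for
#'   instrument-level scenarios and 3000/20000 (QTL cohort vs disease GWAS)
#'   for the region-level `shared`/`linkage` scenarios.
#' @param beta_xy true causal effect of exposure on outcome (instrument-level
#'   scenarios).
#' @param pleiotropy_offset constant directional per-allele effect added to
#'   every instrument's outcome effect (pleiotropy scenario).
#' @param rho AR(1) LD decay of the panel.
#' @param n_ref reference-panel haplotypes.
#' @param exposure_effect_range range of standardized per-instrument exposure
#'   effects (instrument-level scenarios).
#' @param qtl_effect standardized molecular-QTL effect at the causal variant
#'   (region-level scenarios).
#' @param gwas_effect standardized outcome effect at the outcome causal
#'   variant (region-level scenarios).
#' @param ld_between target LD correlation between the two causal variants of
#'   the linkage scenario.
#' @param beta_xm,beta_my,direct mediation-chain coefficients (exposure to
#'   mediator, mediator to outcome, direct exposure-outcome effect).
#' @param seed RNG seed (mandatory).
#' @return classed list `simulation_config`.
#' @export
simulation_config <- function(scenario = c("causal", "pleiotropy", "linkage",
                                           "shared", "mediation", "null"),
                              m_snps = NULL, n_exposure = NULL,
                              n_outcome = NULL, beta_xy = 0.2,
                              pleiotropy_offset = 0.05, rho = NULL,
                              n_ref = 5000,
                              exposure_effect_range = c(0.03, 0.08),
                              qtl_effect = 0.5, gwas_effect = 0.05,
                              ld_between = 0.6,
                              beta_xm = 0.3, beta_my = 0.5, direct = 0.1,
                              seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stopf("seed is mandatory")
  region_level <- scenario %in% c("shared", "linkage")
  if (is.null(m_snps)) m_snps <- if (region_level) 30L else 50L
  if (is.null(rho)) rho <- if (region_level) 0.8 else 0
  # region scenarios emulate molecular-QTL (cohort-scale) exposures against a
  # disease GWAS; instrument-level scenarios emulate biobank-scale traits
  if (is.null(n_exposure)) n_exposure <- if (region_level) 3000 else 50000
  if (is.null(n_outcome)) n_outcome <- if (region_level) 20000 else 50000
  if (scenario == "null") beta_xy <- 0
  if (!is_count(m_snps)) stopf("m_snps must be a positive integer")
  structure(list(scenario = scenario, m_snps = as.integer(m_snps),
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 beta_xy = beta_xy, pleiotropy_offset = pleiotropy_offset,
                 rho = rho, n_ref = n_ref,
                 exposure_effect_range = exposure_effect_range,
                 qtl_effect = qtl_effect, gwas_effect = gwas_effect,
                 ld_between = ld_between, beta_xm = beta_xm,
                 beta_my = beta_my, direct = direct, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a ground-truth scenario bundle
#'
#' Produces exposure/outcome (and for mediation, mediator) summary-statistic
#' sets with a known causal architecture, the LD matrix used, and a truth
#' record for assertions:
#'
#' * `causal` / `null`: independent instruments, outcome effects
#'   `beta_xy` times the exposure effects (zero for `null`).
#' * `pleiotropy`: as `causal` plus a constant directional offset on every
#'   instrument's outcome effect.
#' * `shared`: one causal variant in an LD region drives both the molecular
#'   exposure and the outcome.
#' * `linkage`: distinct causal variants for the two traits, chosen so their
#'   panel LD is closest to `ld_between`.
#' * `mediation`: an exposure-mediator-outcome chain over two disjoint
#'   instrument blocks (exposure's own instruments and the mediator's).
#'
#' @param config a [simulation_config()].
#' @return list with elements among `exposure`, `outcome`, `mediator`,
#'   `panel`, `ld`, and `truth` (a list recording the generating parameters).
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  seed <- cfg$seed
  panel_seed <- seed
  exp_seed <- seed + 1L
  out_seed <- seed + 2L
  med_seed <- seed + 3L

  if (cfg$scenario %in% c("causal", "pleiotropy", "null")) {
    panel <- simulate_panel(cfg$m_snps, cfg$n_ref, cfg$rho, seed = panel_seed)
    lam_x <- withr_seed(seed + 7L,
      stats::runif(cfg$m_snps, cfg$exposure_effect_range[1],
                   cfg$exposure_effect_range[2]))
    offset <- if (cfg$scenario == "pleiotropy") cfg$pleiotropy_offset else 0
    # offset is a constant per-allele effect; convert to the standardized
    # scale so it stays constant on the allelic scale the analyst sees
    maf <- panel$mafs
    lam_y <- cfg$beta_xy * lam_x + offset * sqrt(2 * maf * (1 - maf))
    exposure <- simulate_gwas(panel, lam_x, cfg$n_exposure, exp_seed,
                              trait_id = "exposure")
    outcome <- simulate_gwas(panel, lam_y, cfg$n_outcome, out_seed,
                             trait_id = "outcome", trait_type = "binary")
    return(list(exposure = exposure, outcome = outcome, panel = panel,
                ld = panel$ld,
                truth = list(scenario = cfg$scenario, beta_xy = cfg$beta_xy,
                             pleiotropy_offset = offset, lambda_exp = lam_x)))
  }

  if (cfg$scenario %in% c("shared", "linkage")) {
    panel <- simulate_panel(cfg$m_snps, cfg$n_ref, cfg$rho, seed = panel_seed)
    causal1 <- as.integer(ceiling(cfg$m_snps / 2))
    if (cfg$scenario == "shared") {
      causal2 <- causal1
    } else {
      r_to_c1 <- unclass(panel$ld)[, causal1]
      cand <- setdiff(seq_len(cfg$m_snps), causal1)
      causal2 <- cand[which.min(abs(abs(r_to_c1[cand]) - cfg$ld_between))]
    }
    lam1 <- rep(0, cfg$m_snps); lam1[causal1] <- cfg$qtl_effect
    lam2 <- rep(0, cfg$m_snps); lam2[causal2] <- cfg$gwas_effect
    exposure <- simulate_gwas(panel, lam1, cfg$n_exposure, exp_seed,
                              trait_id = "eqtl")
    outcome <- simulate_gwas(panel, lam2, cfg$n_outcome, out_seed,
                             trait_id = "gwas", trait_type = "binary")
    return(list(exposure = exposure, outcome = outcome, panel = panel,
                ld = panel$ld,
                truth = list(scenario = cfg$scenario,
                             causal_exposure = panel$variant_ids[causal1],
                             causal_outcome = panel$variant_ids[causal2],
                             ld_between = unclass(panel$ld)[causal1, causal2],
                             qtl_effect = cfg$qtl_effect,
                             gwas_effect = cfg$gwas_effect)))
  }

  # mediation: two disjoint instrument blocks (exposure's, mediator's)
  m_each <- cfg$m_snps
  panel <- simulate_panel(2L * m_each, cfg$n_ref, 0, seed = panel_seed)
  ix <- seq_len(m_each); im <- m_each + seq_len(m_each)
  lam <- withr_seed(seed + 7L,
    stats::runif(2L * m_each, cfg$exposure_effect_range[1],
                 cfg$exposure_effect_range[2]))
  lam_x <- replace(rep(0, 2L * m_each), ix, lam[ix])
  lam_m <- cfg$beta_xm * lam_x
  lam_m[im] <- lam[im]
  total <- cfg$direct + cfg$beta_xm * cfg$beta_my
  lam_y <- replace(rep(0, 2L * m_each), ix, total * lam[ix])
  lam_y[im] <- cfg$beta_my * lam[im]
  exposure <- simulate_gwas(panel, lam_x, cfg$n_exposure, exp_seed,
                            trait_id = "exposure")
  mediator <- simulate_gwas(panel, lam_m, cfg$n_exposure, med_seed,
                            trait_id = "mediator")
  outcome <- simulate_gwas(panel, lam_y, cfg$n_outcome, out_seed,
                           trait_id = "outcome", trait_type = "binary")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       panel = panel, ld = panel$ld,
       truth = list(scenario = "mediation", beta_xm = cfg$beta_xm,
                    beta_my = cfg$beta_my, direct = cfg$direct,
                    indirect = cfg$beta_xm * cfg$beta_my, total = total,
                    proportion = cfg$beta_xm * cfg$beta_my / total,
                    exposure_block = panel$variant_ids[ix],
                    mediator_block = panel$variant_ids[im]))
}
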