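# Orchestration layer: thin file-in/file-out wrappers over the analysis
# modules, used by the command-line dispatcher (inst/cli/mrpipe.R) and by
# end-to-end tests. Every command writes a structured run-log JSON alongside
# its outputs so a run can be reproduced byte-identically.

write_run_log <- function(dir, command, params, files) {
  log <- list(command = command,
              package_version = as.character(utils::packageVersion("mrtier")),
              r_version = as.character(getRversion()),
              params = params,
              outputs = lapply(files, function(f)
                list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, paste0(command, "_runlog.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a scenario bundle to disk
#'
#' Wraps [make_scenario()]: writes each summary-statistic set, the LD matrix,
#' the truth record (JSON) and a manifest listing every emitted file with its
#' MD5 checksum. Rerunning with the same configuration produces byte-identical
#' tables.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stopf("output directory not writable: %s", out_dir)
  bundle <- make_scenario(config)
  files <- character(0)
  for (nm in intersect(c("exposure", "mediator", "outcome"), names(bundle))) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_sumstats(bundle[[nm]], f)
    files <- c(files, f)
  }
  f_ld <- file.path(out_dir, "ld.tsv")
  write_ld_matrix(bundle$ld, f_ld)
  f_truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(bundle$truth, f_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f_ld, f_truth)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE)
  write_run_log(out_dir, "simulate", unclass(config),
                c(files, file.path(out_dir, "manifest.tsv")))
  invisible(manifest)
}

#' Two-sample MR from summary-statistic files
#'
#' Reads exposure and outcome tables (and optionally an LD matrix), selects
#' instruments and fits the MR report, writing `mr_report.tsv` and
#' `mr_report.json` plus a run-log under `out_dir`.
#'
#' @param exposure_path,outcome_path summary-statistic TSVs.
#' @param ld_path optional LD matrix TSV.
#' @param out_dir output directory.
#' @param p_threshold,r2_max,window_kb instrument selection settings.
#' @param seed RNG seed for bootstrap/outlier simulations.
#' @return the `mr_report`, invisibly.
#' @export
cmd_mr <- function(exposure_path, outcome_path, ld_path = NULL, out_dir,
                   p_threshold = 5e-8, r2_max = 0.01, window_kb = 10000,
                   seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exposure <- read_sumstats(exposure_path)
  outcome <- read_sumstats(outcome_path, trait_type = "binary")
  ld <- if (!is.null(ld_path)) read_ld_matrix(ld_path) else NULL
  iv <- select_instruments(exposure, outcome, ld, p_threshold = p_threshold,
                           r2_max = r2_max, window_kb = window_kb)
  if (nrow(iv) == 0L) stopf("no valid instruments")
  report <- run_mr(iv, seed = seed)
  tsv <- file.path(out_dir, "mr_report.tsv")
  json <- file.path(out_dir, "mr_report.json")
  write_mr_report(report, tsv = tsv, json = json)
  write_run_log(out_dir, "mr",
                list(p_threshold = p_threshold, r2_max = r2_max,
                     window_kb = window_kb, seed = seed), c(tsv, json))
  invisible(report)
}

#' SMR + HEIDI from summary-statistic files
#'
#' @param exposure_path QTL summary statistics for one gene's cis region.
#' @param outcome_path GWAS summary statistics.
#' @param ld_path LD matrix TSV covering the region.
#' @param out_dir output directory (writes `smr.tsv` and a run-log).
#' @param gene_id gene label.
#' @param ... passed to [heidi_test()] via [run_smr()].
#' @return the `smr_result`, invisibly.
#' @export
cmd_smr <- function(exposure_path, outcome_path, ld_path, out_dir,
                    gene_id = "gene", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_smr(read_sumstats(exposure_path),
                 read_sumstats(outcome_path, trait_type = "binary"),
                 read_ld_matrix(ld_path), gene_id = gene_id, ...)
  res <- smr_fdr(list(res))[[1L]]
  tsv <- file.path(out_dir, "smr.tsv")
  data.table::fwrite(smr_table(list(res)), tsv, sep = "\t", na = "NA",
                     quote = FALSE)
  write_run_log(out_dir, "smr", list(gene_id = gene_id), tsv)
  invisible(res)
}

#' Colocalization from summary-statistic files
#'
#' @param trait1_path,trait2_path region-restricted summary-statistic TSVs.
#' @param out_dir output directory (writes `coloc.json` and a run-log).
#' @param priors a [coloc_priors()].
#' @param w1,w2 prior effect variances.
#' @return the `coloc_result`, invisibly.
#' @export
cmd_coloc <- function(trait1_path, trait2_path, out_dir,
                      priors = coloc_priors(), w1 = 0.04, w2 = 0.04) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- coloc_abf(read_sumstats(trait1_path),
                   read_sumstats(trait2_path, trait_type = "binary"),
                   priors = priors, w1 = w1, w2 = w2)
  json <- file.path(out_dir, "coloc.json")
  write_coloc_result(res, json)
  write_run_log(out_dir, "coloc", c(unclass(priors), w1 = w1, w2 = w2), json)
  invisible(res)
}

#' Mediation MR from a simulated chain bundle
#'
#' Runs the three MR legs of an exposure-mediator-outcome chain from
#' summary-statistic files (exposure instruments for the exposure legs,
#' mediator instruments — excluding the exposure's — for the mediator leg)
#' and combines them with [two_step_mediation()].
#'
#' @param exposure_path,mediator_path,outcome_path summary-statistic TSVs.
#' @param out_dir output directory (writes `mediation.tsv` and a run-log).
#' @param p_threshold instrument p-value threshold.
#' @param seed RNG seed.
#' @return the `mediation_result`, invisibly.
#' @export
cmd_mediate <- function(exposure_path, mediator_path, outcome_path, out_dir,
                        p_threshold = 5e-8, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exposure <- read_sumstats(exposure_path)
  mediator <- read_sumstats(mediator_path)
  outcome <- read_sumstats(outcome_path, trait_type = "binary")
  res <- mediation_chain(exposure, mediator, outcome,
                         p_threshold = p_threshold, seed = seed)
  tsv <- file.path(out_dir, "mediation.tsv")
  data.table::fwrite(
    data.frame(mediator = res$mediator_id, b_xm = res$beta_xm,
               se_xm = res$se_xm, b_my = res$beta_my, se_my = res$se_my,
               b_total = res$beta_total, indirect = res$indirect,
               se_indirect = res$se_indirect, p_indirect = res$pval,
               proportion_pct = 100 * res$proportion,
               note = res$proportion_note),
    tsv, sep = "\t", na = "NA", quote = FALSE)
  write_run_log(out_dir, "mediate",
                list(p_threshold = p_threshold, seed = seed), tsv)
  invisible(res)
}

#' Estimate a full mediation chain from three summary-statistic sets
#'
#' Exposure-to-mediator and exposure-to-outcome (total) legs use the
#' exposure's genome-wide-significant instruments; the mediator-to-outcome leg
#' uses the mediator's own instruments, excluding any that also instrument the
#' exposure.
#'
#' @param exposure,mediator,outcome [sumstats] objects.
#' @param p_threshold instrument threshold (default 5e-8).
#' @param seed RNG seed for bootstrap components.
#' @return a `mediation_result` (see [two_step_mediation()]).
#' @export
mediation_chain <- function(exposure, mediator, outcome, p_threshold = 5e-8,
                            seed = 1) {
  iv_xm <- select_instruments(exposure, mediator, p_threshold = p_threshold)
  iv_xy <- select_instruments(exposure, outcome, p_threshold = p_threshold)
  x_ids <- as.data.frame(exposure)$variant_id[exposure$pval < p_threshold]
  med_only <- sumstats(as.data.frame(mediator)[!mediator$variant_id %in% x_ids, ],
                       attr(mediator, "trait_id"), attr(mediator, "trait_type"))
  iv_my <- select_instruments(med_only, outcome, p_threshold = p_threshold)
  if (nrow(iv_xm) == 0L || nrow(iv_my) == 0L || nrow(iv_xy) == 0L)
    stopf("a mediation leg has no valid instruments")
  fit <- function(iv) run_mr(iv, seed = seed, run_outlier_screen = FALSE,
                             n_boot = 200)
  xm <- fit(iv_xm); my <- fit(iv_my); xy <- fit(iv_xy)
  two_step_mediation(xm$primary$beta, xm$primary$se,
                     my$primary$beta, my$primary$se,
                     xy$primary$beta, xy$primary$se,
                     mediator_id = attr(mediator, "trait_id") %||% "mediator")
}

#' Tier report from an evidence table
#'
#' Reads a per-gene evidence TSV (printed-style cells allowed, see
#' [read_evidence_table()]), applies the criteria configuration and the tier
#' rule, writes the rendered report, and prints a summary line naming the
#' Tier-1 genes.
#'
#' @param evidence_path evidence TSV.
#' @param criteria_yaml optional YAML criteria/tier-rule config; defaults to
#'   the packaged nine-criterion configuration.
#' @param out_dir optional output directory for `tier_report.tsv` + run-log.
#' @return list with `matrix` (an `evidence_matrix`) and `tiers`.
#' @export
cmd_tier <- function(evidence_path, criteria_yaml = NULL, out_dir = NULL) {
  cfg <- read_criteria_yaml(criteria_yaml %||%
    system.file("extdata", "criteria_default.yaml", package = "mrtier",
                mustWork = TRUE))
  values <- read_evidence_table(evidence_path)
  if (nrow(values) == 0L) stopf("no genes in evidence table")
  mat <- build_matrix(values, cfg$criteria)
  tiers <- assign_tiers(mat, tier2_min = cfg$tier_rule$tier2_min,
                        tier3_exact = cfg$tier_rule$tier3_exact,
                        tier2_strict = cfg$tier_rule$tier2_strict)
  t1 <- tiers$gene[tiers$tier == "tier1"]
  message(sprintf("Tier-1 gene(s): %s",
                  if (length(t1)) paste(t1, collapse = ", ") else "none"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(out_dir, "tier_report.tsv")
    render_report(mat, tiers, format = "tsv", path = tsv)
    write_run_log(out_dir, "tier", cfg$tier_rule, tsv)
  }
  list(matrix = mat, tiers = tiers)
}

#' Simulate a multi-gene prioritization bundle
#'
#' One planted causal gene (a shared-causal-variant region linking its
#' molecular QTL to the outcome) plus `n_decoys` decoy genes whose regions
#' carry an equally strong QTL signal but no outcome effect. Each gene has
#' its own reference panel and region.
#'
#' @param n_decoys number of decoy genes (default 4).
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return named list of per-gene bundles (`exposure`, `outcome`, `ld`,
#'   `truth`), with the planted gene named `"causal_gene"`.
#' @export
simulate_prioritization_bundle <- function(n_decoys = 4, seed, ...) {
  if (missing(seed)) stopf("seed is mandatory")
  bundles <- list()
  cfg <- simulation_config(scenario = "shared", seed = seed, ...)
  bundles[["causal_gene"]] <- make_scenario(cfg)
  for (k in seq_len(n_decoys)) {
    cfg_d <- simulation_config(scenario = "shared", gwas_effect = 0,
                               seed = seed + 101L * k, ...)
    bundles[[sprintf("decoy_%02d", k)]] <- make_scenario(cfg_d)
  }
  bundles
}

#' End-to-end gene prioritization on region bundles
#'
#' For each gene region, runs SMR + HEIDI, two-sample MR on the region's
#' clumped genome-wide-significant QTL instruments, and colocalization; BH-FDR
#' corrects the SMR p-values across genes; builds a four-criterion evidence
#' matrix (SMR FDR < 0.05; HEIDI p > 0.05 given SMR; MR p < 0.05;
#' PP4 > 0.5) and assigns tiers with `tier2_min = 3`, `tier3_exact = 2`
#' scaled to the four available criteria.
#'
#' @param bundles named list of per-gene bundles as from
#'   [simulate_prioritization_bundle()] (elements `exposure`, `outcome`, `ld`).
#' @param p_threshold instrument threshold for the MR stage (default 5e-8).
#' @param seed RNG seed for stochastic components.
#' @return list with `evidence` (per-gene values data.frame), `matrix`,
#'   `tiers`.
#' @export
prioritize <- function(bundles, p_threshold = 5e-8, seed = 1) {
  stopifnot(length(bundles) >= 1L, !is.null(names(bundles)))
  rows <- lapply(names(bundles), function(g) {
    b <- bundles[[g]]
    smr <- run_smr(b$exposure, b$outcome, b$ld, gene_id = g)
    iv <- suppressWarnings(
      select_instruments(b$exposure, b$outcome, b$ld,
                         p_threshold = p_threshold))
    mr_p <- if (nrow(iv) > 0L) {
      run_mr(iv, seed = seed, run_outlier_screen = FALSE,
             n_boot = 200)$primary$pval
    } else NA_real_
    cl <- coloc_abf(b$exposure, b$outcome)
    data.frame(gene = g, p_smr = smr$p_smr, heidi = smr$p_heidi,
               mr_p = mr_p, coloc_pp4 = cl$pp[["PP4"]],
               stringsAsFactors = FALSE)
  })
  evidence <- do.call(rbind, rows)
  evidence$smr_fdr <- bh_adjust(evidence$p_smr)
  criteria <- list(
    criterion("smr", "smr_fdr", 0.05, "below"),
    criterion("heidi", "heidi", 0.05, "above", "smr"),
    criterion("mr", "mr_p", 0.05, "below"),
    criterion("coloc", "coloc_pp4", 0.5, "above"))
  mat <- build_matrix(evidence, criteria)
  tiers <- assign_tiers(mat, tier2_min = 3, tier3_exact = 2)
  list(evidence = evidence, matrix = mat, tiers = tiers)
}
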