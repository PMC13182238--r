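#' Evidence criteria
#'
#' A criterion compares one numeric source column of the per-gene evidence
#' table against a threshold. `direction = "below"` is satisfied when
#' `value < threshold`, `"above"` when `value > threshold`; missing values
#' never satisfy a criterion. A criterion may additionally `require` another
#' criterion: it only counts as satisfied when its companion is (used to pair
#' each HEIDI column with its SMR column, since a non-significant HEIDI
#' p-value is only evidence of a shared causal signal when the SMR test
#' itself is significant).
#'
#' @param name unique criterion name.
#' @param source column of the evidence table holding the value (one of the
#'   SMR-FDR, HEIDI, MR p-value or colocalization-PP4 columns).
#' @param threshold finite numeric threshold.
#' @param direction `"below"` or `"above"`.
#' @param requires optional name of a companion criterion that must also be
#'   satisfied.
#' @return classed list `criterion`.
#' @export
criterion <- function(name, source, threshold, direction = c("below", "above"),
                      requires = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold))
  structure(list(name = name, source = source, threshold = threshold,
                 direction = direction, requires = requires),
            class = "criterion")
}

#' Default nine-criterion evidence configuration
#'
#' The nine columns of the integrated evidence matrix: SMR FDR-corrected
#' p < 0.05 and HEIDI p > 0.05 for the discovery cis-eQTL analysis, the
#' whole-blood analysis and the replication-cohort analysis (each HEIDI
#' criterion requiring its paired SMR criterion), two-sample eQTL-MR p < 0.05
#' against the discovery and replication GWAS, and colocalization PP4 > 0.5.
#'
#' @return list of [criterion()] objects.
#' @export
default_criteria <- function() {
  list(
    criterion("fin_cis_smr",   "smr_fdr_fin",   0.05, "below"),
    criterion("fin_cis_heidi", "heidi_fin",     0.05, "above", "fin_cis_smr"),
    criterion("blood_smr",     "smr_fdr_blood", 0.05, "below"),
    criterion("blood_heidi",   "heidi_blood",   0.05, "above", "blood_smr"),
    criterion("rep_cis_smr",   "smr_fdr_rep",   0.05, "below"),
    criterion("rep_cis_heidi", "heidi_rep",     0.05, "above", "rep_cis_smr"),
    criterion("mr_discovery",  "mr_p_fin",      0.05, "below"),
    criterion("mr_replication","mr_p_8cohort",  0.05, "below"),
    criterion("coloc_pp4",     "coloc_pp4",     0.50, "above"))
}

#' Read criteria (and tier-rule parameters) from a YAML config
#'
#' The file holds a `criteria` list (fields name, source, threshold,
#' direction, optional requires) and optionally `tier_rule` with `tier2_min`,
#' `tier3_exact`, `tier2_strict`.
#'
#' @param path YAML file path.
#' @return list with `criteria` (list of [criterion()]) and `tier_rule`.
#' @export
read_criteria_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$criteria)) stopf("config has no 'criteria' entry")
  crits <- lapply(cfg$criteria, function(x)
    criterion(x$name, x$source, x$threshold, x$direction,
              x$requires %||% NA_character_))
  tier_rule <- list(tier2_min = cfg$tier_rule$tier2_min %||% 4,
                    tier3_exact = cfg$tier_rule$tier3_exact %||% 3,
                    tier2_strict = isTRUE(cfg$tier_rule$tier2_strict))
  list(criteria = crits, tier_rule = tier_rule)
}

# "No" (any case) -> NA; "Weak (0.67)" / "Strong (0.86)" -> parenthesized
# number; otherwise numeric as printed
parse_evidence_cell <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  paren <- grepl("\\(([-0-9.eE+]+)\\)", x)
  out[paren] <- as.numeric(sub(".*\\(([-0-9.eE+]+)\\).*", "\\1", x[paren]))
  plain <- !paren & !is.na(x) & !tolower(x) %in% c("no", "na", "")
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  out
}

#' Read a printed-style evidence table
#'
#' Reads a tab-separated per-gene evidence table whose cells may be plain
#' numbers, `No` (no evidence available, parsed as missing) or graded entries
#' like `Weak (0.67)` / `Strong (0.86)` from which the parenthesized value is
#' extracted. A `gene` column is mandatory; a `category` column, if present,
#' is preserved unparsed.
#'
#' @param path TSV file path.
#' @return data.frame with `gene`, numeric evidence columns, and any
#'   `category` column.
#' @export
read_evidence_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          colClasses = "character")
  if (!"gene" %in% names(dt)) stopf("evidence table needs a 'gene' column")
  out <- data.frame(gene = dt$gene, stringsAsFactors = FALSE)
  for (col in setdiff(names(dt), c("gene", "category")))
    out[[col]] <- parse_evidence_cell(dt[[col]])
  if ("category" %in% names(dt)) out$category <- dt$category
  out
}

#' Build the gene-by-criterion evidence matrix
#'
#' Evaluates every criterion for every gene: a cell is satisfied when its
#' value is present, the threshold comparison holds, and any required
#' companion criterion is itself satisfied.
#'
#' @param per_gene_values data.frame with a `gene` column and one numeric
#'   column per criterion source (e.g. from [read_evidence_table()]).
#' @param criteria list of [criterion()] objects (default [default_criteria()]).
#' @return object of class `evidence_matrix`: list with `genes`, `criteria`,
#'   `values` (gene x criterion numeric matrix), `satisfied` (logical matrix),
#'   `n_satisfied` (per gene).
#' @export
build_matrix <- function(per_gene_values, criteria = default_criteria()) {
  stopifnot("gene" %in% names(per_gene_values))
  cnames <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(cnames)) stopf("criterion names must be unique")
  sources <- vapply(criteria, `[[`, character(1), "source")
  absent <- setdiff(sources, names(per_gene_values))
  if (length(absent))
    stopf("evidence table lacks criterion source column(s): %s",
          paste(absent, collapse = ", "))
  genes <- as.character(per_gene_values$gene)
  values <- matrix(NA_real_, length(genes), length(criteria),
                   dimnames = list(genes, cnames))
  for (j in seq_along(criteria))
    values[, j] <- as.numeric(per_gene_values[[criteria[[j]]$source]])
  satisfied <- matrix(FALSE, length(genes), length(criteria),
                      dimnames = list(genes, cnames))
  for (j in seq_along(criteria)) {
    cr <- criteria[[j]]
    v <- values[, j]
    hit <- !is.na(v) & if (cr$direction == "below") v < cr$threshold else
      v > cr$threshold
    satisfied[, j] <- hit
  }
  # companion requirements; requires may chain, iterate to a fixed point
  for (pass in seq_along(criteria)) {
    changed <- FALSE
    for (j in seq_along(criteria)) {
      req <- criteria[[j]]$requires
      if (is.na(req)) next
      if (!req %in% cnames) stopf("unknown required criterion '%s'", req)
      upd <- satisfied[, j] & satisfied[, req]
      if (!identical(upd, satisfied[, j])) { satisfied[, j] <- upd; changed <- TRUE }
    }
    if (!changed) break
  }
  structure(list(genes = genes, criteria = criteria, values = values,
                 satisfied = satisfied, n_satisfied = rowSums(satisfied)),
            class = "evidence_matrix")
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat(sprintf("Evidence matrix: %d genes x %d criteria\n",
              length(x$genes), length(x$criteria)))
  marks <- ifelse(x$satisfied, "ok", ".")
  print(data.frame(marks, n_satisfied = x$n_satisfied,
                   check.names = FALSE))
  invisible(x)
}

#' Assign evidence tiers
#'
#' Tier 1: all criteria satisfied. Tier 2: at least `tier2_min` (default 4)
#' satisfied, or strictly more than four with `tier2_strict = TRUE`. Tier 3:
#' exactly `tier3_exact` (default 3) satisfied. Anything below is
#' `unclassified`. Output is sorted by tier, then descending satisfied count,
#' then gene name, making the assignment invariant to gene input order.
#'
#' @param matrix an [build_matrix()] result.
#' @param tier2_min minimum satisfied criteria for Tier 2 (inclusive).
#' @param tier3_exact exact satisfied-criteria count defining Tier 3.
#' @param tier2_strict use the strict "more than four" reading, i.e.
#'   `n_satisfied > tier2_min`, instead of `>=`.
#' @return data.frame of class `tier_assignment` with columns `gene`,
#'   `n_satisfied`, `tier` (`tier1`, `tier2`, `tier3`, `unclassified`).
#' @export
assign_tiers <- function(matrix, tier2_min = 4, tier3_exact = 3,
                         tier2_strict = FALSE) {
  stopifnot(inherits(matrix, "evidence_matrix"))
  if (tier2_min <= tier3_exact)
    stopf("tier2_min must exceed tier3_exact")
  n_crit <- length(matrix$criteria)
  n <- matrix$n_satisfied
  tier2_ok <- if (tier2_strict) n > tier2_min else n >= tier2_min
  tier <- ifelse(n == n_crit, "tier1",
                 ifelse(tier2_ok, "tier2",
                        ifelse(n == tier3_exact, "tier3", "unclassified")))
  out <- data.frame(gene = matrix$genes, n_satisfied = as.integer(n),
                    tier = tier, stringsAsFactors = FALSE)
  out <- out[order(out$tier, -out$n_satisfied, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tier_assignment", "data.frame")
  out
}

#' @export
print.tier_assignment <- function(x, ...) {
  t1 <- x$gene[x$tier == "tier1"]
  cat(sprintf("Tier assignment for %d genes; Tier-1: %s\n", nrow(x),
              if (length(t1)) paste(t1, collapse = ", ") else "none"))
  print(as.data.frame(x))
  invisible(x)
}

#' Render the evidence/tier report
#'
#' Produces a deterministic per-gene report: each criterion cell shows the
#' value and a satisfied mark, followed by the satisfied count and tier.
#'
#' @param matrix an `evidence_matrix`.
#' @param tiers matching [assign_tiers()] output.
#' @param format `"tsv"` (machine-readable; parseable back by
#'   [read_evidence_table()] up to the mark annotations) or `"text"`.
#' @param path optional output file.
#' @return the report as a character vector of lines, invisibly when `path`
#'   is given.
#' @export
render_report <- function(matrix, tiers, format = c("tsv", "text"),
                          path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "evidence_matrix"))
  ord <- match(tiers$gene, matrix$genes)
  cnames <- vapply(matrix$criteria, `[[`, character(1), "name")
  fmt_cell <- function(v, s) {
    txt <- ifelse(is.na(v), "No", formatC(v, format = "g", digits = 4))
    paste0(txt, if (format == "text") ifelse(s, " √", " ×") else
      ifelse(s, " [x]", " [ ]"))
  }
  cells <- matrix("", length(ord), length(cnames),
                  dimnames = list(NULL, cnames))
  for (j in seq_along(cnames))
    cells[, j] <- fmt_cell(matrix$values[ord, j], matrix$satisfied[ord, j])
  body <- data.frame(gene = tiers$gene, cells, n_satisfied = tiers$n_satisfied,
                     tier = tiers$tier, check.names = FALSE,
                     stringsAsFactors = FALSE)
  lines <- c(paste(names(body), collapse = "\t"),
             if (nrow(body)) apply(body, 1L, paste, collapse = "\t"))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
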