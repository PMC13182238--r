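#' GWAS summary-statistic sets
#'
#' A `sumstats` object holds one trait's per-variant marginal association
#' records (variant id, position, alleles, effect-allele frequency, effect
#' size, standard error, p-value, sample size) plus trait metadata. Effect
#' sizes for binary traits are interpreted on the log-odds scale.
#'
#' Rows violating the record invariants (non-positive standard error, p-value
#' outside (0, 1], identical or non-ACGT alleles, duplicated variant id) are
#' dropped at construction and counted in `attr(x, "n_dropped")`.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`
#'   (`eaf` and `n` may be `NA`).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return An object of class `sumstats`: the validated records data.frame
#'   with attributes `trait_id`, `trait_type` and `n_dropped`.
#' @seealso [read_sumstats()], [harmonize()], [select_instruments()]
#' @export
sumstats <- function(records, trait_id, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  rec <- as.data.frame(records)[required]
  rec$variant_id <- as.character(rec$variant_id)
  rec$chrom <- as.character(rec$chrom)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))

  acgt <- c("A", "C", "G", "T")
  ok <- !is.na(rec$variant_id) & !is.na(rec$beta) &
    !is.na(rec$se) & rec$se > 0 &
    !is.na(rec$pval) & rec$pval > 0 & rec$pval <= 1 &
    rec$effect_allele %in% acgt & rec$other_allele %in% acgt &
    rec$effect_allele != rec$other_allele &
    (is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1)) &
    (is.na(rec$n) | rec$n > 0)
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(rec$variant_id)
  n_dropped <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec,
            trait_id = as.character(trait_id),
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("Summary statistics for trait '%s' (%s): %d variants (%d dropped at read)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x),
              attr(x, "n_dropped")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pval = "P", n = "N")
}

#' Read a delimited summary-statistic table
#'
#' Reads a tab- (or otherwise) delimited text table with a header row and maps
#' its columns onto the `sumstats` record fields. Rows failing the record
#' invariants are dropped and counted in `attr(, "n_dropped")`.
#'
#' @param path file path.
#' @param column_map named character vector mapping record fields
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. Defaults to the
#'   conventional `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`. `eaf` and `n`
#'   entries may be omitted (filled with `NA`).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_id trait label; defaults to the file name.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("quantitative", "binary"),
                          trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stopf("empty input: %s", path)
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  optional <- c("eaf", "n")
  mandatory <- setdiff(names(cmap), optional)
  absent <- mandatory[!cmap[mandatory] %in% names(dt)]
  if (length(absent))
    stopf("column_map names missing column(s) in %s: %s", path,
          paste(cmap[absent], collapse = ", "))
  rec <- data.frame(row.names = seq_len(nrow(dt)))
  for (field in names(cmap)) {
    rec[[field]] <- if (cmap[[field]] %in% names(dt)) dt[[cmap[[field]]]] else NA
  }
  sumstats(rec, trait_id = trait_id %||% basename(path), trait_type = trait_type)
}

#' Write a summary-statistic table
#'
#' Writes the conventional tab-separated layout (`SNP, CHR, POS, EA, OA, EAF,
#' BETA, SE, P, N`) read back by [read_sumstats()].
#'
#' @param x a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  out <- as.data.frame(x)
  names(out) <- default_column_map()[names(out)]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' LD correlation matrices
#'
#' Constructs a validated linkage-disequilibrium correlation matrix: symmetric,
#' unit diagonal, entries in \[-1, 1\], dimnames set to the variant ids.
#'
#' @param r numeric square matrix of pairwise correlations.
#' @param variant_ids character vector matching the matrix dimension.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) stopf("variant_ids required")
  variant_ids <- as.character(variant_ids)
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids))
    stopf("LD matrix dimensions do not match variant_ids")
  if (max(abs(r - t(r))) > 1e-8) stopf("LD matrix must be symmetric")
  r <- (r + t(r)) / 2
  if (any(abs(diag(r) - 1) > 1e-8)) stopf("LD matrix diagonal must be 1")
  diag(r) <- 1
  if (max(abs(r)) > 1 + 1e-8) stopf("LD correlations must lie in [-1, 1]")
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix
#'
#' Accepts either a square tab-separated matrix with variant ids as header row
#' and first column, or a long-format triplet table with columns
#' `id1, id2, r` (missing pairs filled with 0).
#'
#' @param path file path.
#' @return An [ld_matrix] object.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) == 3L && all(c("id1", "id2", "r") %in% names(dt))) {
    ids <- unique(c(as.character(dt$id1), as.character(dt$id2)))
    r <- diag(1, length(ids))
    dimnames(r) <- list(ids, ids)
    for (k in seq_len(nrow(dt))) {
      i <- as.character(dt$id1[k]); j <- as.character(dt$id2[k])
      r[i, j] <- r[j, i] <- as.numeric(dt$r[k])
    }
    diag(r) <- 1
    return(ld_matrix(r, ids))
  }
  ids <- as.character(dt[[1L]])
  r <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(r) <- "double"
  ld_matrix(r, ids)
}

#' Write an LD matrix as a square TSV
#' @param x an [ld_matrix] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  out <- data.frame(variant_id = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# r2 lookup treating absent pairs as r = 0 (warned once per call site)
ld_r2 <- function(ld, id_a, id_b) {
  if (is.null(ld)) return(0)
  ids <- rownames(ld)
  if (!(id_a %in% ids) || !(id_b %in% ids)) return(NA_real_)
  unclass(ld)[id_a, id_b]^2
}
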