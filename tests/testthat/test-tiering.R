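fixture_path <- function(f) system.file("extdata", f, package = "mrtier",
                                        mustWork = TRUE)

test_that("printed-style evidence cells parse to numbers, missing, or graded PP4", {
  ev <- read_evidence_table(fixture_path("pdr_evidence_matrix.tsv"))
  expect_equal(nrow(ev), 11)
  ctsh <- ev[ev$gene == "CTSH", ]
  expect_equal(ctsh$smr_fdr_fin, 1.88e-2)
  expect_equal(ctsh$coloc_pp4, 0.67)     # extracted from "Weak (0.67)"
  expect_equal(ev$coloc_pp4[ev$gene == "CCNE2"], 0.86)
  expect_true(is.na(ev$mr_p_fin[ev$gene == "MICB"]))  # "No" -> missing
})

test_that("the evidence matrix satisfies each criterion per threshold, pairing and missingness", {
  ev <- read_evidence_table(fixture_path("pdr_evidence_matrix.tsv"))
  mat <- build_matrix(ev)
  sat <- mat$satisfied
  expect_true(all(sat["CTSH", ]))  # all nine satisfied
  # significant SMR but failed HEIDI in the discovery pair
  expect_true(sat["CYP21A2", "fin_cis_smr"])
  expect_false(sat["CYP21A2", "fin_cis_heidi"])
  # HEIDI p above threshold does not count when its SMR criterion failed
  expect_gt(ev$heidi_rep[ev$gene == "CCNE2"], 0.05)
  expect_false(sat["CCNE2", "rep_cis_heidi"])
  # missing PP4 never satisfies
  expect_false(sat["CYP21A2", "coloc_pp4"])
})

test_that("tier assignment reproduces all printed categories and marks", {
  ev <- read_evidence_table(fixture_path("pdr_evidence_matrix.tsv"))
  mat <- build_matrix(ev)
  tiers <- assign_tiers(mat)
  want <- setNames(tolower(gsub(" ", "", ev$category)), ev$gene)
  got <- setNames(tiers$tier, tiers$gene)
  expect_equal(got[names(want)], want)
  expect_equal(tiers$gene[tiers$tier == "tier1"], "CTSH")

  marks <- read.delim(fixture_path("pdr_evidence_marks.tsv"), check.names = FALSE)
  m <- as.matrix(marks[, -1]) == 1
  rownames(m) <- marks$gene
  expect_equal(unname(m[mat$genes, ]), unname(mat$satisfied))
})

test_that("the strict 'more than four' variant demotes the four-criterion genes", {
  ev <- read_evidence_table(fixture_path("pdr_evidence_matrix.tsv"))
  mat <- build_matrix(ev)
  strict <- assign_tiers(mat, tier2_strict = TRUE)
  got <- setNames(strict$tier, strict$gene)
  expect_equal(unname(got[c("CCNE2", "TP53INP1")]),
               c("unclassified", "unclassified"))
  expect_equal(unname(got[c("CYP21A2", "MICB")]), c("tier2", "tier2"))
  expect_error(assign_tiers(mat, tier2_min = 3, tier3_exact = 3), "exceed")
})

test_that("satisfied counts are monotone in thresholds and order-invariant", {
  ev <- read_evidence_table(fixture_path("pdr_evidence_matrix.tsv"))
  base <- build_matrix(ev)$n_satisfied
  # relaxing any single criterion never decreases any gene's count
  for (j in seq_along(default_criteria())) {
    crits <- default_criteria()
    cr <- crits[[j]]
    crits[[j]] <- criterion(cr$name, cr$source,
                            if (cr$direction == "below")
                              cr$threshold * 10 else cr$threshold / 10,
                            cr$direction, cr$requires)
    relaxed <- build_matrix(ev, crits)$n_satisfied
    expect_true(all(relaxed >= base), info = cr$name)
  }
  shuffled <- ev[sample(nrow(ev)), ]
  t1 <- assign_tiers(build_matrix(ev))
  t2 <- assign_tiers(build_matrix(shuffled))
  expect_equal(t1, t2)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  # order preserved, monotone step-up
  p <- c(0.04, 0.001, 0.03, 0.008)
  q <- bh_adjust(p)
  expect_equal(q, p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.1, 0)), "numeric in")
  expect_error(bh_adjust(c(0.1, 1.2)), "numeric in")
})

test_that("rendered reports round-trip to identical tier assignments", {
  ev <- read_evidence_table(fixture_path("pdr_evidence_matrix.tsv"))
  mat <- build_matrix(ev)
  tiers <- assign_tiers(mat)
  f <- tempfile(fileext = ".tsv")
  render_report(mat, tiers, format = "tsv", path = f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), 11)
  # strip the satisfaction marks, map report columns (criterion names) back
  # to their source columns, and re-run the tiering
  vals <- back
  for (col in setdiff(names(vals), c("gene", "n_satisfied", "tier")))
    vals[[col]] <- sub(" \\[.\\]$", "", vals[[col]])
  vals <- vals[setdiff(names(vals), c("n_satisfied", "tier"))]
  lookup <- vapply(default_criteria(), function(cr) c(cr$name, cr$source),
                   character(2))
  names(vals)[match(lookup[1, ], names(vals))] <- lookup[2, ]
  f2 <- tempfile(fileext = ".tsv")
  write.table(vals, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  tiers2 <- assign_tiers(build_matrix(read_evidence_table(f2)))
  expect_equal(tiers2, tiers)

  # empty matrix renders a header-only report
  empty <- build_matrix(data.frame(gene = character(0),
                                   smr_fdr_fin = numeric(0),
                                   heidi_fin = numeric(0),
                                   smr_fdr_blood = numeric(0),
                                   heidi_blood = numeric(0),
                                   smr_fdr_rep = numeric(0),
                                   heidi_rep = numeric(0),
                                   mr_p_fin = numeric(0),
                                   mr_p_8cohort = numeric(0),
                                   coloc_pp4 = numeric(0)))
  lines <- render_report(empty, assign_tiers(empty))
  expect_length(lines, 1)
})

test_that("criteria configs load from YAML with the packaged defaults intact", {
  cfg <- read_criteria_yaml(fixture_path("criteria_default.yaml"))
  expect_length(cfg$criteria, 9)
  expect_equal(cfg$tier_rule$tier2_min, 4)
  expect_false(cfg$tier_rule$tier2_strict)
  names_def <- vapply(default_criteria(), `[[`, character(1), "name")
  names_yaml <- vapply(cfg$criteria, `[[`, character(1), "name")
  expect_equal(names_yaml, names_def)
  # a config missing a source column errors at matrix build
  expect_error(build_matrix(data.frame(gene = "g", x = 1),
                            list(criterion("c1", "absent", 0.05))),
               "lacks")
})
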