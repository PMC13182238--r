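test_that("uncorrelated variants are all retained; correlated pairs pruned by p-value", {
  rec <- toy_records(3, pval = c(1e-10, 1e-9, 1e-8))
  r <- diag(3); dimnames(r) <- list(rec$variant_id, rec$variant_id)
  expect_setequal(clump_variants(sumstats(rec, "t"), ld_matrix(r)),
                  rec$variant_id)

  rec2 <- toy_records(2, pos = c(1000, 2000), pval = c(1e-8, 1e-10))
  r2 <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, 2,
               dimnames = list(rec2$variant_id, rec2$variant_id))
  expect_equal(clump_variants(sumstats(rec2, "t"), ld_matrix(r2),
                              r2_max = 0.01),
               "rs2")  # smaller p retained
})

test_that("clumping respects the window: distant correlated variants both kept", {
  rec <- toy_records(2, pos = c(1000, 1000 + 10000 * 1000 + 1),
                     pval = c(1e-10, 1e-8))
  r <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
              dimnames = list(rec$variant_id, rec$variant_id))
  expect_setequal(clump_variants(sumstats(rec, "t"), ld_matrix(r),
                                 window_kb = 10000),
                  rec$variant_id)
})

test_that("clumping equals the brute-force greedy oracle on random <=12-variant instances", {
  for (s in 1:25) {
    set.seed(s)
    m <- sample(3:12, 1)
    rec <- toy_records(m,
                       pos = sort(sample(1:5e6, m)),
                       pval = signif(runif(m, 1e-12, 1e-4), 3))
    a <- matrix(rnorm(m * m), m)
    r <- cov2cor(crossprod(a) + diag(m) * 0.1)
    dimnames(r) <- list(rec$variant_id, rec$variant_id)
    r2_max <- sample(c(0.01, 0.1, 0.3), 1)
    window_kb <- sample(c(100, 1000, 10000), 1)
    got <- clump_variants(sumstats(rec, "t"), ld_matrix(r),
                          r2_max = r2_max, window_kb = window_kb)
    expect_equal(got, clump_oracle(rec, r, r2_max, window_kb),
                 info = sprintf("seed %d", s))
  }
})

test_that("clump output is invariant to input row order", {
  set.seed(7)
  m <- 10
  rec <- toy_records(m, pos = sort(sample(1:1e6, m)),
                     pval = runif(m, 1e-12, 1e-4))
  rec$pval[2] <- rec$pval[1]  # exercise the lexicographic tie-break
  a <- matrix(rnorm(m * m), m)
  r <- cov2cor(crossprod(a) + diag(m) * 0.1)
  dimnames(r) <- list(rec$variant_id, rec$variant_id)
  ld <- ld_matrix(r)
  base <- clump_variants(sumstats(rec, "t"), ld, r2_max = 0.1)
  for (i in 1:5) {
    shuf <- rec[sample(m), ]
    expect_equal(clump_variants(sumstats(shuf, "t"), ld, r2_max = 0.1), base)
  }
})

test_that("invalid r2_max raises a configuration error; absent LD pairs warn and pass", {
  s <- toy_sumstats(2)
  expect_error(clump_variants(s, NULL, r2_max = 0), "r2_max")
  expect_error(clump_variants(s, NULL, r2_max = 1.5), "r2_max")
  r <- matrix(1, 1, 1, dimnames = list("rs1", "rs1"))
  expect_warning(got <- clump_variants(s, ld_matrix(r)), "treated as r = 0")
  expect_setequal(got, c("rs1", "rs2"))
})

test_that("instrument selection applies threshold, clumping, harmonization and F", {
  # 100-SNP exposure, 5 planted genome-wide hits, no LD
  set.seed(11)
  m <- 100
  hits <- sample(m, 5)
  pv <- runif(m, 1e-4, 1); pv[hits] <- runif(5, 1e-12, 1e-9)
  beta <- rnorm(m, 0, 0.01); beta[hits] <- 0.12
  rec <- toy_records(m, pos = seq_len(m) * 1e4, pval = pv, beta = beta,
                     se = 0.02, effect_allele = "A", other_allele = "G")
  exposure <- sumstats(rec, "exp")
  outcome <- sumstats(toy_records(m, pos = seq_len(m) * 1e4, beta = 0.05,
                                  se = 0.02, effect_allele = "A",
                                  other_allele = "G"), "out")
  iv <- select_instruments(exposure, outcome, ld = NULL)
  expect_setequal(iv$variant_id, rec$variant_id[hits])
  expect_equal(attr(iv, "f_per_snp"), rep((0.12 / 0.02)^2, 5))
  expect_equal(attr(iv, "f_mean"), 36)

  # single-SNP exposure hit
  one <- select_instruments(
    sumstats(toy_records(1, pval = 1e-9, beta = 0.1, se = 0.02), "e"),
    sumstats(toy_records(1, beta = 0.02, se = 0.02), "o"))
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "f_per_snp"), 25)  # (0.1/0.02)^2
})

test_that("removing weak instruments never leaves mean F below the cutoff", {
  set.seed(3)
  for (i in 1:10) {
    bx <- rnorm(20, 0, 0.1); sx <- runif(20, 0.02, 0.2)
    iv <- toy_instruments(bx, bx * 0.2, sx = sx)
    f <- attr(iv, "f_per_snp")
    strong <- instrument_set(iv[f > 10, , drop = FALSE])
    if (nrow(strong) > 0L) expect_gt(attr(strong, "f_mean"), 10)
  }
})
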