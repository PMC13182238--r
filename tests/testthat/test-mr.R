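test_that("Wald ratio reproduces ratio arithmetic and the delta-method se", {
  iv <- toy_instruments(0.5, 0.25, sx = 0.05, sy = 0.1)
  est <- mr_wald_ratio(iv)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)  # 0.1 / |0.5|

  null <- mr_wald_ratio(toy_instruments(1, 0, sy = 0.1))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)

  expect_error(mr_wald_ratio(toy_instruments(0, 0.1)), "zero")

  # second-order se matches the closed-form delta expansion
  est2 <- mr_wald_ratio(iv, second_order = TRUE)
  expect_equal(est2$se, sqrt(0.1^2 / 0.5^2 + 0.25^2 * 0.05^2 / 0.5^4))
})

test_that("IVW matches hand-computed weights and a zero-intercept WLS oracle", {
  iv <- toy_instruments(c(0.5, 0.4), c(0.25, 0.20), sy = c(0.1, 0.1))
  est <- mr_ivw(iv)
  expect_equal(est$beta, 0.5)                 # all ratios equal 0.5
  expect_equal(est$se, sqrt(0.01 / 0.41))     # (sum bx^2/se^2)^(-1/2)

  set.seed(5)
  for (i in 1:5) {
    bx <- rnorm(8, 0.2, 0.05); by <- 0.3 * bx + rnorm(8, 0, 0.02)
    sy <- runif(8, 0.02, 0.1)
    iv <- toy_instruments(bx, by, sy = sy)
    est <- mr_ivw(iv, model = "fixed")
    # independent oracle: weighted no-intercept regression via lm
    or <- summary(lm(by ~ bx + 0, weights = 1 / sy^2))
    expect_equal(est$beta, unname(coef(or)[1, 1]))
    expect_equal(est$se, unname(coef(or)[1, 2] / or$sigma))
  }
})

test_that("single-pair IVW formula collapses to the Wald ratio", {
  bx <- 0.4; by <- 0.1; sy <- 0.05
  w <- run_mr(toy_instruments(bx, by, sy = sy))
  expect_equal(w$primary$method, "wald_ratio")
  # bypass the n>=2 precondition through the internal fit
  fit <- mrtier:::ivw_fit(bx, by, sy)
  expect_equal(fit$beta, by / bx)
  expect_equal(fit$se, sy / abs(bx))
})

test_that("random-effects IVW never reports a smaller se than fixed", {
  set.seed(8)
  for (i in 1:10) {
    bx <- rnorm(10, 0.2, 0.05)
    by <- 0.3 * bx + rnorm(10, 0, 0.05)  # overdispersed
    iv <- toy_instruments(bx, by, sy = rep(0.02, 10))
    expect_gte(mr_ivw(iv, "random")$se, mr_ivw(iv, "fixed")$se)
  }
})

test_that("Egger regression recovers exact lines, affine shifts, and the WLS solution", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  iv <- toy_instruments(bx, 0.4 * bx, sy = rep(0.05, 5))
  eg <- mr_egger(iv)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-10)

  iv2 <- toy_instruments(bx, 0.4 * bx + 0.05, sy = rep(0.05, 5))
  eg2 <- mr_egger(iv2)
  expect_equal(eg2$intercept$estimate, 0.05, tolerance = 1e-10)
  expect_equal(eg2$slope$beta, 0.4, tolerance = 1e-10)

  # normal-equations oracle on a random 10-instrument set
  set.seed(13)
  bx <- abs(rnorm(10, 0.2, 0.08)); by <- 0.3 * bx + rnorm(10, 0.02, 0.03)
  sy <- runif(10, 0.02, 0.1)
  eg3 <- mr_egger(toy_instruments(bx, by, sy = sy))
  w <- 1 / sy^2
  xm <- cbind(1, bx)
  coefs <- unname(solve(t(xm) %*% (w * xm), t(xm) %*% (w * by)))
  expect_equal(eg3$intercept$estimate, coefs[1, 1])
  expect_equal(eg3$slope$beta, coefs[2, 1])

  expect_error(mr_egger(toy_instruments(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("weighted median interpolates the half-weight crossing", {
  # equal weights: the middle of three ratios
  iv <- toy_instruments(c(1, 1, 1), c(0.2, 0.5, 0.9), sy = rep(0.1, 3))
  est <- mr_weighted_median(iv, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.5)

  # identical ratios: the common value with a small, stable bootstrap se
  iv2 <- toy_instruments(rep(1, 4), rep(0.4, 4), sx = rep(0.01, 4),
                         sy = rep(0.01, 4))
  est2 <- mr_weighted_median(iv2, n_boot = 200, seed = 1)
  expect_equal(est2$beta, 0.4)
  expect_lt(est2$se, 0.02)

  # brute-force cumulative-weight scan oracle on a 5-instrument set
  set.seed(21)
  bx <- abs(rnorm(5, 0.3, 0.05)); by <- rnorm(5, 0.1, 0.05)
  sy <- runif(5, 0.02, 0.1)
  iv3 <- toy_instruments(bx, by, sy = sy)
  est3 <- mr_weighted_median(iv3, n_boot = 50, seed = 1)
  ratios <- by / bx; w <- bx^2 / sy^2
  ord <- order(ratios); rs <- ratios[ord]; ws <- w[ord] / sum(w)
  cum <- cumsum(ws) - ws / 2
  k <- max(which(cum < 0.5))
  oracle <- rs[k] + (rs[k + 1] - rs[k]) * (0.5 - cum[k]) / (cum[k + 1] - cum[k])
  expect_equal(est3$beta, oracle)

  # determinism under the bootstrap seed
  expect_identical(mr_weighted_median(iv3, n_boot = 50, seed = 9)$se,
                   mr_weighted_median(iv3, n_boot = 50, seed = 9)$se)
})

test_that("Cochran's Q matches hand sums and is order-invariant", {
  iv <- toy_instruments(c(1, 1), c(0.5, 0.5), sy = c(1, 1))
  q0 <- mr_cochran_q(iv)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pval, 1)

  # unit weights, ratios 0 and 1, reference 0.5 -> Q = 0.25 + 0.25
  iv2 <- toy_instruments(c(1, 1), c(0, 1), sy = c(1, 1))
  expect_equal(mr_cochran_q(iv2, beta_ref = 0.5)$Q, 0.5)

  set.seed(2)
  bx <- rnorm(6, 0.3, 0.05); by <- rnorm(6, 0.1, 0.05)
  iv3 <- toy_instruments(bx, by, sy = runif(6, 0.05, 0.1))
  perm <- sample(6)
  iv4 <- instrument_set(as.data.frame(iv3)[perm, ])
  expect_equal(mr_cochran_q(iv3, 0.2)$Q, mr_cochran_q(iv4, 0.2)$Q)
})

test_that("outlier screen flags a planted pleiotropic instrument and respects preconditions", {
  set.seed(4)
  n <- 12
  bx <- abs(rnorm(n, 0.2, 0.03)); sy <- rep(0.02, n)
  by <- 0.3 * bx
  by[5] <- by[5] + 10 * sy[5]  # 10-se offset on one instrument
  iv <- toy_instruments(bx, by, sx = rep(0.005, n), sy = sy)
  scr <- mr_outlier_screen(iv, n_sim = 300, seed = 2)
  expect_true("rs5" %in% scr$outlier_ids)
  expect_lt(scr$global_pval, 0.05)

  # homogeneous instruments: no outliers, unremarkable global p
  by2 <- 0.3 * bx
  iv2 <- toy_instruments(bx, by2, sx = rep(0.005, n), sy = sy)
  scr2 <- mr_outlier_screen(iv2, n_sim = 300, seed = 2)
  expect_length(scr2$outlier_ids, 0)
  expect_gt(scr2$global_pval, 0.05)

  # 3 instruments: flagging skipped with a warning, global test still runs
  iv3 <- toy_instruments(bx[1:3], by[1:3], sy = sy[1:3])
  expect_warning(scr3 <- mr_outlier_screen(iv3, n_sim = 100, seed = 1),
                 "fewer than 4")
  expect_length(scr3$outlier_ids, 0)
  expect_true(is.finite(scr3$global_pval))
})

test_that("run_mr applies the method-selection policy and OR/CI arithmetic", {
  single <- run_mr(toy_instruments(0.5, 0.25, sy = 0.1))
  expect_equal(single$primary$method, "wald_ratio")
  expect_length(single$sensitivity, 0)

  set.seed(6)
  bx <- abs(rnorm(10, 0.2, 0.05)); by <- 0.3 * bx + rnorm(10, 0, 0.01)
  ten <- run_mr(toy_instruments(bx, by, sy = rep(0.02, 10)),
                n_boot = 100, outlier_n_sim = 100)
  expect_match(ten$primary$method, "^ivw")
  expect_setequal(names(ten$sensitivity), c("egger_slope", "weighted_median"))
  expect_equal(ten$heterogeneity$df, 9)

  two <- run_mr(toy_instruments(bx[1:2], by[1:2], sy = rep(0.02, 2)),
                run_outlier_screen = FALSE)
  expect_match(two$primary$method, "^ivw")
  expect_length(two$sensitivity, 0)

  # OR/CI transform: beta 0.0907 (se 0.0340) -> OR 1.095 [1.024, 1.170]
  est <- mrtier:::mr_estimate("ivw_fixed", 0.0907, 0.0340, 0.0079, 5L)
  expect_equal(round(est$or_, 3), 1.095)
  expect_equal(round(est$ci_low, 3), 1.024)
  expect_equal(round(est$ci_high, 3), 1.170)

  empty <- instrument_set(mrtier:::empty_pairs())
  expect_error(run_mr(empty), "no instruments")
})

test_that("MR reports flatten to the serialization layout and write TSV/JSON", {
  set.seed(6)
  bx <- abs(rnorm(5, 0.2, 0.05)); by <- 0.3 * bx
  rep <- run_mr(toy_instruments(bx, by, sy = rep(0.02, 5)), n_boot = 50,
                outlier_n_sim = 100)
  df <- as.data.frame(rep)
  expect_equal(df$method[1], rep$primary$method)
  expect_equal(nrow(df), 3)
  expect_true(all(c("exposure", "outcome", "method", "nsnp", "b", "se", "pval",
                    "or", "ci_low", "ci_high", "Q", "Q_pval",
                    "egger_intercept", "intercept_pval") %in% names(df)))
  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  write_mr_report(rep, tsv = tsv, json = json)
  back <- read.delim(tsv)
  expect_equal(back$b, df$b, tolerance = 1e-9)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$n_snp, 5)
})
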