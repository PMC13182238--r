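test_that("product of coefficients and delta-method se match hand arithmetic", {
  res <- two_step_mediation(0.5, 0.1, 0.4, 0.1, beta_total = 0.8,
                            se_total = 0.05)
  expect_equal(res$indirect, 0.2)
  expect_equal(res$se_indirect, sqrt(0.4^2 * 0.1^2 + 0.5^2 * 0.1^2))
  expect_equal(res$se_indirect, sqrt(0.0041))
  expect_equal(res$proportion, 0.25)

  # zero exposure-to-mediator effect: indirect 0, p = 1
  z0 <- two_step_mediation(0, 0.1, 0.4, 0.1)
  expect_equal(z0$indirect, 0)
  expect_equal(z0$pval, 1)

  # the se formula is symmetric in which leg carries a zero-se term
  a <- two_step_mediation(0.5, 0, 0.4, 0.1)$se_indirect
  b <- two_step_mediation(0.4, 0.1, 0.5, 0)$se_indirect
  expect_equal(a, b)

  # second-order variant adds the cross term
  res2 <- two_step_mediation(0.5, 0.1, 0.4, 0.1, second_order = TRUE)
  expect_equal(res2$se_indirect, sqrt(0.0041 + 0.1^2 * 0.1^2))
})

test_that("degenerate totals and out-of-range proportions are flagged verbatim", {
  zero_tot <- two_step_mediation(0.5, 0.1, 0.4, 0.1, beta_total = 0,
                                 se_total = 0.1)
  expect_true(is.na(zero_tot$proportion))
  expect_match(zero_tot$proportion_note, "total effect is zero")

  opp <- two_step_mediation(0.5, 0.1, 0.4, 0.1, beta_total = -0.1,
                            se_total = 0.1)
  expect_equal(opp$proportion, -2)  # reported verbatim, never truncated
  expect_match(opp$proportion_note, "opposite signs")
  expect_match(opp$proportion_note, "exceeds 100")

  expect_error(two_step_mediation(0.5, -0.1, 0.4, 0.1), "positive")
})

test_that("mediator screening gates on step-1 FDR then step-2 nominal significance", {
  fake_report <- function(b, se) {
    structure(list(exposure_id = "x", outcome_id = "y",
                   primary = mrtier:::mr_estimate("ivw_fixed", b, se,
                                                  2 * pnorm(-abs(b / se)), 5L),
                   sensitivity = list(), heterogeneity = NULL,
                   pleiotropy = NULL, f_mean = 50, n_snp = 5L),
              class = "mr_report")
  }
  xm <- list(m1 = fake_report(0.5, 0.05),   # both legs significant
             m2 = fake_report(0.5, 0.05),   # step 2 fails
             m3 = fake_report(0.01, 0.05))  # step 1 fails
  my <- list(m1 = fake_report(0.4, 0.05),
             m2 = fake_report(0.01, 0.05),
             m3 = fake_report(0.4, 0.05))
  total <- fake_report(0.8, 0.05)
  scr <- screen_mediators(xm, my, total)
  expect_equal(scr$table$mediator, "m1")
  expect_equal(unname(scr$summary["n_candidates"]), 3)
  expect_equal(unname(scr$summary["n_step1"]), 2)
  expect_equal(unname(scr$summary["n_mediated"]), 1)
  expect_equal(scr$table$proportion_pct, 25)

  none <- screen_mediators(list(mX = fake_report(0.001, 0.1)),
                           list(mX = fake_report(0.4, 0.05)), total)
  expect_equal(nrow(none$table), 0L)
})

test_that("a planted minority of true chains ranks top of a 100-mediator screen", {
  set.seed(47)
  wins <- 0
  for (rep in 1:5) {
    n_med <- 100; true_idx <- 1:5
    mk <- function(b, se) {
      structure(list(exposure_id = "x", outcome_id = "y",
                     primary = mrtier:::mr_estimate("ivw_fixed", b, se,
                                                    2 * pnorm(-abs(b / se)), 5L),
                     sensitivity = list(), heterogeneity = NULL,
                     pleiotropy = NULL, f_mean = 50, n_snp = 5L),
                class = "mr_report")
    }
    ids <- sprintf("m%03d", 1:n_med)
    xm <- my <- setNames(vector("list", n_med), ids)
    for (i in 1:n_med) {
      if (i %in% true_idx) {
        xm[[i]] <- mk(rnorm(1, 0.4, 0.03), 0.03)
        my[[i]] <- mk(rnorm(1, 0.3, 0.03), 0.03)
      } else {
        xm[[i]] <- mk(rnorm(1, 0, 0.03), 0.03)
        my[[i]] <- mk(rnorm(1, 0, 0.03), 0.03)
      }
    }
    total <- mk(0.3, 0.02)
    scr <- screen_mediators(xm, my, total)
    top5 <- scr$table$mediator[1:5]
    if (all(sort(top5) == ids[true_idx])) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("the full chain estimator recovers a simulated mediation proportion", {
  m <- make_scenario(simulation_config("mediation", seed = 88))
  res <- mediation_chain(m$exposure, m$mediator, m$outcome)
  expect_equal(res$proportion, m$truth$proportion, tolerance = 0.25)
  expect_true(res$proportion_ci[1] < m$truth$proportion &&
                m$truth$proportion < res$proportion_ci[2])
})
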