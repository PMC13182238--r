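# Two-sample MR estimators. Throughout, bx/sx are exposure effects and
# standard errors, by/sy outcome effects, one element per instrument.

mr_estimate <- function(method, beta, se, pval, n_snp) {
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or_ = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n_snp = as.integer(n_snp)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%d SNP%s): beta = %.*g (se %.*g), OR = %.*g [%.*g, %.*g], p = %.*g\n",
              x$method, x$n_snp, if (x$n_snp == 1L) "" else "s",
              digits, x$beta, digits, x$se, digits, x$or_,
              digits, x$ci_low, digits, x$ci_high, digits, x$pval))
  invisible(x)
}

iv_columns <- function(instruments) {
  stopifnot(nrow(instruments) > 0L)
  list(bx = instruments$beta_exp, sx = instruments$se_exp,
       by = instruments$beta_out, sy = instruments$se_out,
       id = instruments$variant_id)
}

#' Wald ratio estimate from a single instrument
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect, with a first-order delta-method standard error
#' `se_out / |beta_exp|`. The `second_order` option adds the exposure
#' uncertainty term `beta_out^2 se_exp^2 / beta_exp^4`.
#'
#' @param instruments an [instrument_set] (the first row is used), or a
#'   one-row harmonized-pairs data.frame.
#' @param second_order include the exposure sampling-variance term in the
#'   delta expansion (default `FALSE`).
#' @return An `mr_estimate` (method `"wald_ratio"`).
#' @export
mr_wald_ratio <- function(instruments, second_order = FALSE) {
  v <- iv_columns(instruments)
  bx <- v$bx[1L]; by <- v$by[1L]; sx <- v$sx[1L]; sy <- v$sy[1L]
  if (bx == 0) stopf("undefined Wald ratio: exposure effect is zero")
  beta <- by / bx
  var1 <- sy^2 / bx^2
  if (second_order) var1 <- var1 + by^2 * sx^2 / bx^4
  se <- sqrt(var1)
  mr_estimate("wald_ratio", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Meta-analytic combination of per-instrument Wald ratios with weights
#' `beta_exp^2 / se_out^2`, equivalent to a zero-intercept weighted regression
#' of outcome on exposure effects. The random-effects model inflates the
#' fixed-effect standard error multiplicatively by
#' `max(1, sqrt(Q / (n_snp - 1)))` with Q the IVW Cochran statistic.
#'
#' @param instruments an [instrument_set] with at least 2 rows.
#' @param model `"fixed"` or `"random"`.
#' @return An `mr_estimate` (method `"ivw_fixed"` or `"ivw_random"`).
#' @export
mr_ivw <- function(instruments, model = c("fixed", "random")) {
  model <- match.arg(model)
  v <- iv_columns(instruments)
  if (length(v$bx) < 2L)
    stopf("IVW requires at least 2 instruments; use mr_wald_ratio()")
  est <- ivw_fit(v$bx, v$by, v$sy)
  se <- est$se
  if (model == "random") {
    q <- sum((v$by - est$beta * v$bx)^2 / v$sy^2)
    se <- se * max(1, sqrt(q / (length(v$bx) - 1L)))
  }
  mr_estimate(paste0("ivw_", model), est$beta, se,
              2 * stats::pnorm(-abs(est$beta / se)), length(v$bx))
}

ivw_fit <- function(bx, by, sy) {
  w <- 1 / sy^2
  denom <- sum(bx^2 * w)
  list(beta = sum(bx * by * w) / denom, se = 1 / sqrt(denom))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free intercept
#' (average directional pleiotropy), weights `1/se_out^2`, after orienting
#' every instrument so the exposure effect is positive. Inference uses the
#' t distribution on `n_snp - 2` degrees of freedom.
#'
#' @param instruments an [instrument_set] with at least 3 rows.
#' @return list with `slope` (an `mr_estimate`, method `"egger_slope"`) and
#'   `intercept` (list with `estimate`, `se`, `pval`).
#' @export
mr_egger <- function(instruments) {
  v <- iv_columns(instruments)
  n <- length(v$bx)
  if (n < 3L) stopf("MR-Egger requires at least 3 instruments")
  flip <- sign(v$bx); flip[flip == 0] <- 1
  bx <- v$bx * flip; by <- v$by * flip
  fit <- stats::lm(by ~ bx, weights = 1 / v$sy^2)
  cf <- summary(fit)$coefficients
  slope <- mr_estimate("egger_slope", cf["bx", 1L], cf["bx", 2L],
                       2 * stats::pt(-abs(cf["bx", 1L] / cf["bx", 2L]), n - 2L),
                       n)
  intercept <- list(estimate = cf["(Intercept)", 1L],
                    se = cf["(Intercept)", 2L],
                    pval = 2 * stats::pt(-abs(cf["(Intercept)", 1L] /
                                                cf["(Intercept)", 2L]), n - 2L))
  list(slope = slope, intercept = intercept)
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]; w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (p[1L] >= 0.5) return(b[1L])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  below <- max(which(p < 0.5))
  b[below] + (b[below + 1L] - b[below]) * (0.5 - p[below]) /
    (p[below + 1L] - p[below])
}

#' Weighted median estimate
#'
#' Orders the per-instrument Wald ratios and takes the value at which the
#' cumulative normalized inverse-variance weight crosses one half, with linear
#' interpolation between adjacent ratios. Consistent when instruments carrying
#' more than half the weight are valid. The standard error comes from a
#' parametric bootstrap: exposure and outcome effects are resampled from
#' normal distributions centred on their estimates and the median recomputed.
#'
#' @param instruments an [instrument_set] with at least 3 rows.
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  v <- iv_columns(instruments)
  n <- length(v$bx)
  if (n < 3L) stopf("weighted median requires at least 3 instruments")
  ratios <- v$by / v$bx
  w <- v$bx^2 / v$sy^2  # first-order inverse variance of the ratio
  beta <- weighted_median_point(ratios, w)
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_i <- stats::rnorm(n, v$bx, v$sx)
      by_i <- stats::rnorm(n, v$by, v$sy)
      weighted_median_point(by_i / bx_i, bx_i^2 / v$sy^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se,
              2 * stats::pnorm(-abs(beta / se)), n)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cochran's Q heterogeneity test
#'
#' Q is the weighted sum of squared deviations of the per-instrument Wald
#' ratios from `beta_ref`, with first-order inverse-variance weights
#' `beta_exp^2 / se_out^2`, referred to a chi-square distribution on
#' `n_snp - 1` degrees of freedom.
#'
#' @param instruments an [instrument_set] with at least 2 rows.
#' @param beta_ref reference causal effect; defaults to the fixed-effect IVW
#'   estimate.
#' @return list with `Q`, `df`, `pval`.
#' @export
mr_cochran_q <- function(instruments, beta_ref = NULL) {
  v <- iv_columns(instruments)
  n <- length(v$bx)
  if (n < 2L) stopf("Cochran's Q requires at least 2 instruments")
  if (is.null(beta_ref)) beta_ref <- ivw_fit(v$bx, v$by, v$sy)$beta
  ratios <- v$by / v$bx
  w <- v$bx^2 / v$sy^2
  q <- sum(w * (ratios - beta_ref)^2)
  list(Q = q, df = n - 1L,
       pval = stats::pchisq(q, df = n - 1L, lower.tail = FALSE))
}

#' Pleiotropy outlier screen
#'
#' A simulation-based global heterogeneity test plus leave-one-out outlier
#' flagging, reported together with the MR-Egger intercept. The global test
#' compares the observed weighted residual sum of squares about the IVW fit
#' with its parametric Monte-Carlo null (exposure and outcome effects
#' resimulated under the fitted model). Per-instrument flags use the
#' leave-one-out standardized residual with Bonferroni-corrected two-sided
#' normal p below `alpha`.
#'
#' @param instruments an [instrument_set]; outlier flagging needs at least 4
#'   rows (fewer returns no flags with a warning), the global test at least 2.
#' @param n_sim Monte-Carlo simulations for the global null (default 1000).
#' @param seed RNG seed (default 1).
#' @param alpha family-wise flagging level (default 0.05).
#' @return list with `egger_intercept`, `intercept_se`, `intercept_pval`
#'   (`NA` when n_snp < 3), `outlier_ids`, `global_pval`.
#' @export
mr_outlier_screen <- function(instruments, n_sim = 1000, seed = 1,
                              alpha = 0.05) {
  v <- iv_columns(instruments)
  n <- length(v$bx)
  if (n < 2L) stopf("outlier screen requires at least 2 instruments")
  fit <- ivw_fit(v$bx, v$by, v$sy)
  rss_obs <- sum((v$by - fit$beta * v$bx)^2 / v$sy^2)
  rss_sim <- withr_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      bx_i <- stats::rnorm(n, v$bx, v$sx)
      by_i <- stats::rnorm(n, fit$beta * v$bx, v$sy)
      f <- ivw_fit(bx_i, by_i, v$sy)
      sum((by_i - f$beta * bx_i)^2 / v$sy^2)
    }, numeric(1))
  })
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_ids <- character(0)
  if (n >= 4L) {
    p_loo <- vapply(seq_len(n), function(j) {
      f <- ivw_fit(v$bx[-j], v$by[-j], v$sy[-j])
      z <- (v$by[j] - f$beta * v$bx[j]) /
        sqrt(v$sy[j]^2 + f$beta^2 * v$sx[j]^2)
      2 * stats::pnorm(-abs(z))
    }, numeric(1))
    outlier_ids <- v$id[pmin(p_loo * n, 1) < alpha]
  } else {
    warnf("fewer than 4 instruments: outlier flagging skipped")
  }
  egger <- if (n >= 3L) mr_egger(instruments)$intercept else
    list(estimate = NA_real_, se = NA_real_, pval = NA_real_)
  list(egger_intercept = egger$estimate, intercept_se = egger$se,
       intercept_pval = egger$pval, outlier_ids = outlier_ids,
       global_pval = global_pval)
}
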