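#' Two-step mediation MR
#'
#' Combines an exposure-to-mediator estimate and a mediator-to-outcome
#' estimate into an indirect effect by the product of coefficients, with a
#' first-order delta-method standard error
#' `sqrt(beta_my^2 se_xm^2 + beta_xm^2 se_my^2)` (the `second_order` flag adds
#' the `se_xm^2 se_my^2` cross term). The mediation proportion is the indirect
#' effect over the total exposure-to-outcome effect, reported as a percentage;
#' a note flags proportions whose sign differs from the total effect or whose
#' magnitude exceeds 100 percent, which are reported verbatim, never
#' truncated. A normal-approximation confidence interval for the proportion
#' treats the three inputs as independent.
#'
#' @param beta_xm,se_xm exposure-to-mediator effect and standard error.
#' @param beta_my,se_my mediator-to-outcome effect and standard error.
#' @param beta_total,se_total total exposure-to-outcome effect; when
#'   `beta_total = 0` the proportion is undefined and flagged.
#' @param mediator_id label carried into tables.
#' @param second_order include the delta-method cross term (default `FALSE`).
#' @param level confidence level for the proportion interval (default 0.95).
#' @return object of class `mediation_result`.
#' @export
two_step_mediation <- function(beta_xm, se_xm, beta_my, se_my,
                               beta_total = NA_real_, se_total = NA_real_,
                               mediator_id = "mediator",
                               second_order = FALSE, level = 0.95) {
  if (any(c(se_xm, se_my) < 0, na.rm = TRUE) ||
      (!is.na(se_total) && se_total <= 0))
    stopf("standard errors must be positive")
  indirect <- beta_xm * beta_my
  v <- beta_my^2 * se_xm^2 + beta_xm^2 * se_my^2
  if (second_order) v <- v + se_xm^2 * se_my^2
  se_ind <- sqrt(v)
  z <- if (se_ind > 0) indirect / se_ind else if (indirect == 0) 0 else Inf
  pval <- 2 * stats::pnorm(-abs(z))

  proportion <- NA_real_
  prop_ci <- c(NA_real_, NA_real_)
  note <- ""
  if (!is.na(beta_total)) {
    if (beta_total == 0) {
      note <- "proportion undefined: total effect is zero"
    } else {
      proportion <- indirect / beta_total
      if (sign(indirect) != 0 && sign(indirect) != sign(beta_total))
        note <- "indirect and total effects have opposite signs"
      if (abs(proportion) > 1)
        note <- paste0(note, if (nzchar(note)) "; " else "",
                       "proportion exceeds 100%")
      # delta-method variance of the ratio, legs treated as independent
      rel2 <- (se_ind / indirect)^2 +
        (if (!is.na(se_total)) (se_total / beta_total)^2 else 0)
      if (is.finite(rel2)) {
        zq <- stats::qnorm(1 - (1 - level) / 2)
        sd_prop <- abs(proportion) * sqrt(rel2)
        prop_ci <- proportion + c(-1, 1) * zq * sd_prop
      }
    }
  }
  structure(list(mediator_id = mediator_id,
                 beta_xm = beta_xm, se_xm = se_xm,
                 beta_my = beta_my, se_my = se_my,
                 beta_total = beta_total, se_total = se_total,
                 indirect = indirect, se_indirect = se_ind,
                 z = z, pval = pval,
                 proportion = proportion, proportion_ci = prop_ci,
                 proportion_note = note),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation through %s: indirect = %.4g (se %.4g), p = %.3g\n",
              x$mediator_id, x$indirect, x$se_indirect, x$pval))
  if (!is.na(x$proportion))
    cat(sprintf("  proportion mediated = %.1f%% [%.1f%%, %.1f%%]%s\n",
                100 * x$proportion, 100 * x$proportion_ci[1],
                100 * x$proportion_ci[2],
                if (nzchar(x$proportion_note))
                  paste0(" (", x$proportion_note, ")") else ""))
  else if (nzchar(x$proportion_note)) cat("  ", x$proportion_note, "\n")
  invisible(x)
}

report_beta <- function(report) report$primary$beta
report_se <- function(report) report$primary$se
report_p <- function(report) report$primary$pval

#' Screen many candidate mediators
#'
#' Batch two-step mediation MR across mediators: step-1 (exposure-to-mediator)
#' p-values are BH-FDR corrected and mediators passing `fdr_q` are carried to
#' step 2; mediators whose mediator-to-outcome leg is also nominally
#' significant (`p2_alpha`) enter [two_step_mediation()] against the shared
#' total effect. The output is sorted by absolute mediation proportion,
#' descending.
#'
#' @param xm_reports named list of `mr_report`s, exposure to each mediator.
#' @param my_reports named list of `mr_report`s, each mediator to the outcome;
#'   names matched against `xm_reports`.
#' @param total an `mr_report` for the total exposure-to-outcome effect.
#' @param fdr_q step-1 BH-FDR gate (default 0.05).
#' @param p2_alpha step-2 nominal gate (default 0.05).
#' @return list with `table` (one row per mediated path; columns mediator,
#'   b_xm, se_xm, p_xm, q_xm, b_my, se_my, p_my, b_total, indirect,
#'   se_indirect, p_indirect, proportion_pct, note) and `summary` counts.
#' @export
screen_mediators <- function(xm_reports, my_reports, total,
                             fdr_q = 0.05, p2_alpha = 0.05) {
  ids <- intersect(names(xm_reports), names(my_reports))
  if (length(ids) == 0L) stopf("no mediator ids shared between the two legs")
  p_xm <- vapply(xm_reports[ids], report_p, numeric(1))
  q_xm <- bh_adjust(p_xm)
  step1 <- ids[q_xm <= fdr_q]
  p_my <- vapply(my_reports[ids], report_p, numeric(1))
  names(p_my) <- ids
  step2 <- step1[p_my[step1] < p2_alpha]

  rows <- lapply(step2, function(m) {
    res <- two_step_mediation(
      report_beta(xm_reports[[m]]), report_se(xm_reports[[m]]),
      report_beta(my_reports[[m]]), report_se(my_reports[[m]]),
      report_beta(total), report_se(total), mediator_id = m)
    data.frame(mediator = m,
               b_xm = res$beta_xm, se_xm = res$se_xm,
               p_xm = p_xm[[m]], q_xm = q_xm[[match(m, ids)]],
               b_my = res$beta_my, se_my = res$se_my, p_my = p_my[[m]],
               b_total = res$beta_total,
               indirect = res$indirect, se_indirect = res$se_indirect,
               p_indirect = res$pval,
               proportion_pct = 100 * res$proportion,
               note = res$proportion_note, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mediator = character(0), b_xm = numeric(0), se_xm = numeric(0),
               p_xm = numeric(0), q_xm = numeric(0), b_my = numeric(0),
               se_my = numeric(0), p_my = numeric(0), b_total = numeric(0),
               indirect = numeric(0), se_indirect = numeric(0),
               p_indirect = numeric(0), proportion_pct = numeric(0),
               note = character(0), stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$proportion_pct)), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       summary = c(n_candidates = length(ids),
                   n_step1 = length(step1),
                   n_mediated = nrow(tab)))
}
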