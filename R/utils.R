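# internal numerical helpers

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf (with warning) on cancellation
logdiffexp <- function(a, b) {
  if (b >= a) {
    warning("negative mass from floating cancellation; clamped at 0")
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}

# draw n samples from MVN(mu, sigma) via Cholesky; sigma jittered if needed
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) {
    chol(sigma + diag(1e-8, p))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% ch, 2L, mu, `+`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, applied
#' order-preservingly. A thin validating wrapper around [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as `pvals`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stopf("p-values must be numeric in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
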