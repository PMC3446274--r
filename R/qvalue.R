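#' Storey q-values from a vector of p-values
#'
#' Estimates the proportion of true nulls pi0 with the smoother method
#' (natural cubic spline of `pi0(lambda)` over `lambda = 0.05, ..., 0.95`,
#' evaluated at the largest lambda) and returns
#' `q = min(1, pi0 * p_BH)` where `p_BH` is the Benjamini-Hochberg step-up
#' adjustment. When the pi0 estimate is unstable (fit failure, estimate
#' outside (0, 1]), pi0 falls back to 1, which reduces the q-values to
#' plain Benjamini-Hochberg. q-values never invert the order of p-values,
#' and `NA` p-values propagate `NA` q-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param pi0 Optional fixed null proportion, bypassing estimation.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
estimate_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) abort("empty p-value vector")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(p[ok])
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  q <- rep(NA_real_, length(p))
  q[ok] <- pmin(1, pi0 * p.adjust(p[ok], method = "BH"))
  q
}

# Smoother pi0 estimate; conservative fallback to 1.
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 20) return(1)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- tryCatch(
    smooth.spline(lambda, pi0_lambda, df = 3),
    error = function(e) NULL
  )
  if (is.null(fit)) return(1)
  pi0 <- predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 > 1 || pi0 <= 0) return(1)
  pi0
}
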