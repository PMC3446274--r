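#' Convert methylation values between beta, R and M scales
#'
#' Illumina-style methylation data come as beta-values, the methylated
#' fraction in (0, 1). Two companion scales are in routine use: the ratio
#' scale R = beta/(1 - beta) (the methylated/unmethylated signal ratio) and
#' the M-value, log2 of R, which stabilizes the strong mean-variance
#' dependence (heteroscedasticity) of beta-values. All three are related by
#' strictly monotone, mutually inverse maps on the open interval (0, 1).
#'
#' @param x Numeric vector. For `beta_to_r()` / `beta_to_m()`, beta-values
#'   strictly inside (0, 1); clip first with [clip_beta()] if needed.
#'   For the inverse functions, R-values (> 0) or M-values (any real).
#' @return Numeric vector on the target scale.
#' @examples
#' beta_to_r(0.8)          # 4
#' beta_to_m(0.5)          # 0
#' m_to_beta(beta_to_m(0.3))
#' @export
beta_to_r <- function(x) {
  check_open_unit(x)
  x / (1 - x)
}

#' @rdname beta_to_r
#' @export
beta_to_m <- function(x) {
  check_open_unit(x)
  log2(x / (1 - x))
}

#' @rdname beta_to_r
#' @export
r_to_beta <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) abort("R-values must be positive")
  x / (1 + x)
}

#' @rdname beta_to_r
#' @export
m_to_beta <- function(x) {
  r <- 2^x
  r / (1 + r)
}

check_open_unit <- function(x) {
  bad <- which(x <= 0 | x >= 1)
  if (length(bad)) {
    abort(sprintf(
      "beta-values must lie strictly in (0, 1); clip first (e.g. clip_beta()). First offender at position %d: %g",
      bad[1], x[bad[1]]
    ))
  }
  invisible(x)
}

#' Clip beta-values away from the boundaries 0 and 1
#'
#' Values at exactly 0 or 1 (possible in simulated or externally processed
#' data) make the R and M scales infinite; clipping to
#' `[epsilon, 1 - epsilon]` keeps every downstream transform finite. Values
#' already inside the clipped range are returned unchanged.
#'
#' @param x Numeric vector or matrix of beta-values in `[0, 1]`.
#' @param epsilon Clipping margin (default `1e-6`).
#' @return `x` with boundary values moved to `epsilon` / `1 - epsilon`.
#' @export
clip_beta <- function(x, epsilon = 1e-6) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("beta-values outside [0, 1] found; refusing to clip non-methylation data")
  }
  pmin(pmax(x, epsilon), 1 - epsilon)
}
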