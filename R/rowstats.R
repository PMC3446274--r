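# Row-wise moment and test-statistic machinery. Everything here is
# vectorized across CpGs; missing values are excluded pairwise (per row,
# per group), never imputed.

row_n_mean_var <- function(x) {
  obs <- !is.na(x)
  n <- rowSums(obs)
  x0 <- x
  x0[!obs] <- 0
  s <- rowSums(x0)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(x0^2)
  v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
  # guard tiny negative values from cancellation
  v <- pmax(v, 0)
  list(n = n, mean = m, var = v)
}

# Two-group Bartlett test per row (k = 2). Returns the chi-square statistic
# on 1 df, its p-value, the case/control variance ratio and its log2.
bartlett_rows <- function(x_case, x_ctrl) {
  a <- row_n_mean_var(x_case)
  b <- row_n_mean_var(x_ctrl)
  n1 <- a$n; n2 <- b$n
  v1 <- a$var; v2 <- b$var
  N <- n1 + n2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
  C <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2)) / 3
  stat <- ((N - 2) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)) / C
  untestable <- n1 < 2 | n2 < 2 | (v1 == 0 & v2 == 0)
  stat[untestable] <- NA_real_
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  var_ratio <- v1 / v2
  var_ratio[untestable] <- NA_real_
  list(
    stat = stat, p = p, var_ratio = var_ratio, b_stat = log2(var_ratio),
    mean_case = a$mean, mean_ctrl = b$mean, n_case = n1, n_ctrl = n2
  )
}

# Welch two-sample t per row: unequal variances, Satterthwaite df.
welch_rows <- function(x_case, x_ctrl) {
  a <- row_n_mean_var(x_case)
  b <- row_n_mean_var(x_ctrl)
  se2 <- a$var / a$n + b$var / b$n
  diff <- a$mean - b$mean
  t <- diff / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  # degenerate rows: both groups constant
  zero <- !is.na(se2) & se2 == 0
  t[zero & diff == 0] <- 0
  p[zero & diff == 0] <- 1
  p[zero & diff != 0] <- 0
  untestable <- a$n < 2 | b$n < 2
  t[untestable] <- NA_real_
  p[untestable] <- NA_real_
  list(t = t, p = p, mean_diff = diff, df = df)
}

# Row-wise OLS of Y (rows = CpGs) on a design matrix X (samples x terms).
# Complete rows take the closed-form path; rows with NAs drop the missing
# samples individually. Returns coefficients, their t statistics and
# two-sided p-values.
ols_rows <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  coef <- matrix(NA_real_, nrow(Y), p)
  tval <- matrix(NA_real_, nrow(Y), p)
  pval <- matrix(NA_real_, nrow(Y), p)
  resid_var <- rep(NA_real_, nrow(Y))

  complete <- rowSums(is.na(Y)) == 0L
  if (any(complete)) {
    XtXinv <- solve(crossprod(X))
    H <- X %*% XtXinv            # n x p
    B <- Y[complete, , drop = FALSE] %*% H
    R <- Y[complete, , drop = FALSE] - B %*% t(X)
    s2 <- rowSums(R^2) / (n - p)
    se <- sqrt(outer(s2, diag(XtXinv)))
    coef[complete, ] <- B
    tval[complete, ] <- B / se
    pval[complete, ] <- 2 * pt(abs(B / se), df = n - p, lower.tail = FALSE)
    resid_var[complete] <- s2 * (n - p) / pmax(n - 1, 1)
  }
  for (i in which(!complete)) {
    obs <- !is.na(Y[i, ])
    ni <- sum(obs)
    if (ni <= p) next
    Xi <- X[obs, , drop = FALSE]
    fit <- tryCatch(stats::lm.fit(Xi, Y[i, obs]), error = function(e) NULL)
    if (is.null(fit) || fit$rank < p) next
    XtXinv_i <- chol2inv(chol(crossprod(Xi)))
    s2 <- sum(fit$residuals^2) / (ni - p)
    se <- sqrt(s2 * diag(XtXinv_i))
    coef[i, ] <- fit$coefficients
    tval[i, ] <- fit$coefficients / se
    pval[i, ] <- 2 * pt(abs(tval[i, ]), df = ni - p, lower.tail = FALSE)
    resid_var[i] <- sum(fit$residuals^2) / (ni - 1)
  }
  list(coef = coef, t = tval, p = pval, resid_var = resid_var)
}

# Residualize rows of Y on a covariate design, re-adding the row mean so
# values stay on the original scale.
residualize_rows <- function(Y, X) {
  n <- ncol(Y)
  out <- Y
  complete <- rowSums(is.na(Y)) == 0L
  if (any(complete)) {
    XtXinv <- solve(crossprod(X))
    H <- X %*% XtXinv
    B <- Y[complete, , drop = FALSE] %*% H
    R <- Y[complete, , drop = FALSE] - B %*% t(X)
    out[complete, ] <- R + rowMeans(Y[complete, , drop = FALSE])
  }
  for (i in which(!complete)) {
    obs <- !is.na(Y[i, ])
    if (sum(obs) <= ncol(X)) next
    fit <- tryCatch(stats::lm.fit(X[obs, , drop = FALSE], Y[i, obs]),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    out[i, obs] <- fit$residuals + mean(Y[i, obs])
  }
  out
}
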