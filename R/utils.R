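# Internal numerical helpers shared across modules.

# Ordinary least squares with intercept; returns slope block for column `which`.
# X is the design WITHOUT the intercept column. Inference uses the t reference
# with n - k degrees of freedom.
.ols <- function(y, X, which = 1L) {
  n <- length(y)
  if (NCOL(X) == 1L) {
    # closed-form simple regression (hot path in the simulation studies)
    x <- as.numeric(X)
    df <- n - 2L
    if (df <= 0) stop("not enough observations for OLS inference")
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc * xc)
    beta <- sum(xc * yc) / sxx
    rss <- sum(yc * yc) - beta^2 * sxx
    se <- sqrt(rss / df / sxx)
    tval <- beta / se
    return(list(beta = beta, se = se, statistic = tval,
                p = 2 * stats::pt(-abs(tval), df), df = df, n = n))
  }
  X <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  if (df <= 0) stop("not enough observations for OLS inference")
  s2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  j <- which + 1L
  beta <- unname(fit$coefficients[j])
  se <- sqrt(s2 * XtX_inv[j, j])
  tval <- beta / se
  list(beta = beta, se = se, statistic = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of per-cell seeds below 2^31 from one master seed.
.derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  .with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

.complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.is_palindromic <- function(a1, a2) {
  a1 == .complement_allele(a2)
}
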