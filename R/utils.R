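# Shared numeric helpers.

#' Derive a deterministic child seed from a master seed
#'
#' Every source of randomness in the package takes its seed from a single
#' master seed through this function, so that full runs are reproducible and
#' component seeds never collide. The result is always a positive integer
#' below 2^31.
#'
#' @param seed Master seed (single integer).
#' @param key Character label of the component (e.g. `"genotypes"`).
#' @return A single integer seed.
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 1000003
  as.integer(((abs(seed) %% 1000003) * 2038 + h) %% 2147483629)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (Blom-offset) ranks. Ties get
#' average ranks; `NA`s are preserved.
#'
#' @param x Numeric vector.
#' @param offset Rank offset; default 3/8 (Blom).
#' @return Numeric vector of the same length.
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  r <- rank(x, ties.method = "average", na.last = "keep")
  n <- sum(!is.na(x))
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

# Build a design matrix (with intercept) from named columns of a data frame.
.design_matrix <- function(data, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  missing_cols <- setdiff(covariates, colnames(data))
  if (length(missing_cols) > 0L) {
    stop("covariate columns not found: ", paste(missing_cols, collapse = ", "))
  }
  f <- stats::reformulate(covariates)
  mf <- stats::model.frame(f, data = data, na.action = stats::na.pass)
  stats::model.matrix(f, mf)
}

# Error if X is rank deficient, naming the aliased columns.
.check_full_rank <- function(X, context = "design matrix") {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop(sprintf("collinear covariates in %s: %s", context,
                 paste(aliased, collapse = ", ")))
  }
  invisible(TRUE)
}

# Vectorized OLS of many outcomes on one exposure plus shared covariates,
# via Frisch-Waugh residualization. Y is n x m, x length n, C a design matrix
# that includes the intercept.
.ols_multi <- function(Y, x, C) {
  n <- nrow(Y)
  qrC <- qr(C)
  xr <- qr.resid(qrC, x)
  Yr <- qr.resid(qrC, Y)
  sxx <- sum(xr^2)
  if (sxx < 1e-12) stop("exposure is collinear with the covariates")
  beta <- as.vector(crossprod(Yr, xr)) / sxx
  df <- n - ncol(C) - 1L
  rss <- pmax(colSums(Yr^2) - beta^2 * sxx, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(estimate = beta, se = se, stat = tstat, p = p, df = df, n = n)
}

# Mean-impute missing entries of a dosage matrix, column-wise.
.impute_dosage <- function(G) {
  if (!anyNA(G)) return(G)
  cm <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- cm[idx[, 2L]]
  G
}

# Empirical allele frequency of the ALT allele from dosages in [0, 2].
.alt_freq <- function(G) colMeans(G, na.rm = TRUE) / 2
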