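# Transcriptome-wide association of log expression with SDB exposures:
# per-transcript OLS, permutation-pooled empirical p-values, joint
# multivariate Wald test, BH FDR, and effect-correlation summaries.

# Align an expr_matrix with a phenotype table; complete cases on the model
# variables. Returns t(Y) (samples x transcripts), the phenotype subset, and
# the number of rows dropped.
.align_expr_pheno <- function(expr, pheno, vars) {
  stopifnot(inherits(expr, "expr_matrix"))
  common <- intersect(expr$sample_ids, pheno$sample_id)
  if (length(common) == 0) stop("no overlapping samples between expression and phenotypes")
  ph <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  cc <- stats::complete.cases(ph[, vars, drop = FALSE])
  n_dropped <- sum(!cc)
  ph <- ph[cc, , drop = FALSE]
  Y <- t(expr$values[, match(ph$sample_id, expr$sample_ids), drop = FALSE])
  list(Y = Y, pheno = ph, n_dropped = n_dropped)
}

.twas_covariates <- function(covariates, adjust_bmi) {
  if (adjust_bmi && !("BMI" %in% covariates)) c(covariates, "BMI") else covariates
}

#' Per-transcript association of log expression with one SDB exposure
#'
#' Ordinary least squares of log2 expression on the exposure plus
#' covariates, one model per transcript. The reported estimate (`AdjLogFC`)
#' is the covariate-adjusted log2-fold change per 1 unit of exposure.
#' Rows with missing model variables are dropped listwise (count recorded
#' in attribute `n_dropped`).
#'
#' @param expr An `expr_matrix` at stage `logged`.
#' @param pheno Phenotype/covariate data frame with a `sample_id` column.
#' @param exposure Name of the exposure column.
#' @param covariates Character vector of covariate column names.
#' @param adjust_bmi Add BMI to the covariates?
#' @return A data frame (class `assoc_result`) with one row per transcript:
#'   `feature_id`, `exposure_id`, `estimate`, `se`, `stat`, `p_nominal`,
#'   `n`, `cell_type`, `bmi_adjusted`.
#' @export
transcript_association <- function(expr, pheno, exposure,
                                   covariates = c("age", "sex", "site", "background"),
                                   adjust_bmi = FALSE) {
  if (expr$stage != "logged") stop("transcript_association expects logged expression")
  covariates <- .twas_covariates(covariates, adjust_bmi)
  al <- .align_expr_pheno(expr, pheno, c(exposure, covariates))
  C <- .design_matrix(al$pheno, covariates)
  x <- al$pheno[[exposure]]
  .check_full_rank(cbind(C, exposure = x), "transcript_association")
  fit <- .ols_multi(al$Y, x, C)
  out <- data.frame(feature_id = expr$transcript_ids,
                    exposure_id = exposure,
                    estimate = fit$estimate, se = fit$se, stat = fit$stat,
                    p_nominal = fit$p, n = fit$n,
                    cell_type = expr$cell_type,
                    bmi_adjusted = adjust_bmi,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "n_dropped") <- al$n_dropped
  out
}

#' Permutation-based empirical p-values
#'
#' Accounts for skewed exposure distributions. The exposure is residualized
#' on the covariates (Freedman-Lane style); the residuals are permuted `B`
#' times, all transcripts are re-tested per permutation, and the null
#' p-values are pooled across transcripts and permutations. The empirical
#' p-value is `(1 + #\{null p <= observed p\}) / (1 + N_null)`, which is
#' valid and never zero.
#'
#' @param assoc Result of [transcript_association()] for the same model.
#' @param expr,pheno,exposure,covariates,adjust_bmi As in
#'   [transcript_association()].
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @return `assoc` with a `p_empirical` column added; the pooled null size
#'   and scheme are in attribute `null_pool`.
#' @export
empirical_pvalues <- function(assoc, expr, pheno, exposure,
                              covariates = c("age", "sex", "site", "background"),
                              adjust_bmi = FALSE, B = 100, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  covariates <- .twas_covariates(covariates, adjust_bmi)
  al <- .align_expr_pheno(expr, pheno, c(exposure, covariates))
  C <- .design_matrix(al$pheno, covariates)
  qrC <- qr(C)
  xr <- qr.resid(qrC, al$pheno[[exposure]])
  Yr <- qr.resid(qrC, al$Y)
  n <- nrow(Yr)
  df <- n - ncol(C) - 1L
  ycss <- colSums(Yr^2)
  set.seed(seed)
  null_p <- matrix(NA_real_, ncol(Yr), B)
  for (b in seq_len(B)) {
    e <- sample(xr)
    r <- as.vector(crossprod(Yr, e)) / sqrt(ycss * sum(e^2))
    tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))
    null_p[, b] <- 2 * stats::pt(-abs(tstat), df)
  }
  pool <- sort(as.vector(null_p))
  n_null <- length(pool)
  cnt <- findInterval(assoc$p_nominal, pool)
  assoc$p_empirical <- (1 + cnt) / (1 + n_null)
  attr(assoc, "null_pool") <- list(B = B, n_null = n_null,
                                   scheme = "pooled covariate-residual permutation",
                                   seed = seed)
  assoc
}

#' Joint multivariate Wald test across three exposures
#'
#' Per transcript, tests the 3-vector of exposure coefficients from one
#' model containing all exposures, against zero, using the estimated
#' coefficient covariance. No empirical p-values are computed for the joint
#' test (the permutation scheme applies to a single exposure).
#'
#' @param expr An `expr_matrix` at stage `logged`.
#' @param pheno Phenotype data frame.
#' @param exposures Character vector of exposure columns (typically 3).
#' @param covariates,adjust_bmi As in [transcript_association()].
#' @return Data frame with `feature_id`, `stat`, `df`, `p_nominal`, `n`.
#' @export
joint_wald <- function(expr, pheno, exposures,
                       covariates = c("age", "sex", "site", "background"),
                       adjust_bmi = FALSE) {
  covariates <- .twas_covariates(covariates, adjust_bmi)
  al <- .align_expr_pheno(expr, pheno, c(exposures, covariates))
  C <- .design_matrix(al$pheno, covariates)
  E <- as.matrix(al$pheno[, exposures, drop = FALSE])
  .check_full_rank(cbind(C, E), "joint_wald")
  qrC <- qr(C)
  Er <- qr.resid(qrC, E)
  if (qr(Er)$rank < ncol(Er)) stop("exposures are collinear")
  Yr <- qr.resid(qrC, al$Y)
  n <- nrow(Yr)
  k <- ncol(Er)
  M <- crossprod(Er)
  Bmat <- solve(M, crossprod(Er, Yr))           # k x m coefficients
  quad <- colSums(Bmat * (M %*% Bmat))           # b' M b per transcript
  df_res <- n - ncol(C) - k
  sigma2 <- pmax(colSums(Yr^2) - quad, 0) / df_res
  stat <- quad / sigma2
  out <- data.frame(feature_id = expr$transcript_ids, stat = stat, df = k,
                    p_nominal = stats::pchisq(stat, df = k, lower.tail = FALSE),
                    n = n, cell_type = expr$cell_type,
                    bmi_adjusted = adjust_bmi,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- al$n_dropped
  out
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up BH adjustment, applied within each family (e.g. one SDB exposure
#' by cell type) when `family` is given.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family Optional vector defining adjustment families.
#' @return Vector of adjusted p-values.
#' @export
bh_fdr <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Spearman R-squared matrix of effect estimates across analysis families
#'
#' Correlates the per-transcript effect estimates (log2-fold changes)
#' between families (cell type x exposure), over the union of features
#' passing the FDR threshold in at least one family. AHI estimates are
#' sign-flipped before correlation so their direction matches the oximetry
#' traits (for which lower values are worse); squared Spearman correlations
#' are reported.
#'
#' @param assoc An `assoc_result`-style data frame with columns
#'   `feature_id`, `exposure_id`, `cell_type`, `estimate`, and `p_fdr`.
#' @param fdr_threshold FDR threshold selecting the feature union.
#' @param flip_exposures Exposures whose estimates are sign-flipped.
#' @param min_overlap Minimum shared features for a matrix cell.
#' @return A symmetric matrix of squared Spearman correlations; cells with
#'   fewer than `min_overlap` shared features are `NA` (with a warning).
#' @export
effect_correlation_matrix <- function(assoc, fdr_threshold = 0.1,
                                      flip_exposures = "AHI",
                                      min_overlap = 3) {
  stopifnot(all(c("feature_id", "exposure_id", "cell_type", "estimate", "p_fdr")
                %in% colnames(assoc)))
  assoc$family <- paste(assoc$cell_type, assoc$exposure_id, sep = ".")
  sel_features <- unique(assoc$feature_id[!is.na(assoc$p_fdr) &
                                            assoc$p_fdr < fdr_threshold])
  if (length(sel_features) < min_overlap) {
    stop("fewer than ", min_overlap, " features pass the FDR threshold")
  }
  assoc <- assoc[assoc$feature_id %in% sel_features, , drop = FALSE]
  assoc$estimate[assoc$exposure_id %in% flip_exposures] <-
    -assoc$estimate[assoc$exposure_id %in% flip_exposures]
  fams <- sort(unique(assoc$family))
  E <- matrix(NA_real_, length(sel_features), length(fams),
              dimnames = list(sel_features, fams))
  for (i in seq_len(nrow(assoc))) {
    E[assoc$feature_id[i], assoc$family[i]] <- assoc$estimate[i]
  }
  R2 <- matrix(NA_real_, length(fams), length(fams),
               dimnames = list(fams, fams))
  for (a in seq_along(fams)) {
    for (b in seq_len(a)) {
      ok <- stats::complete.cases(E[, c(a, b), drop = FALSE])
      if (sum(ok) < min_overlap) {
        warning("fewer than ", min_overlap, " overlapping features for ",
                fams[a], " vs ", fams[b])
        next
      }
      r <- stats::cor(E[ok, a], E[ok, b], method = "spearman")
      R2[a, b] <- R2[b, a] <- r^2
    }
  }
  R2
}
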