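# Metabolite preparation (limit-of-detection minimum-value imputation, rank
# normalization, missingness filter) and survey-design weighted regression
# with a stratified cluster sandwich variance estimator.

#' Survey design descriptor
#'
#' @param weight Positive sampling weight per sample.
#' @param cluster Primary sampling unit (cluster) id per sample.
#' @param stratum Stratum id per sample.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(weight, cluster, stratum) {
  n <- length(weight)
  stopifnot(length(cluster) == n, length(stratum) == n)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("sampling weights must be positive")
  }
  structure(list(weight = weight, cluster = as.character(cluster),
                 stratum = as.character(stratum), n = n),
            class = "survey_design")
}

#' Prepare one metabolite for association analysis
#'
#' Missing values (assumed below the detection limit) are imputed with the
#' metabolite's minimum observed value, then the full vector is transformed
#' with the rank-based inverse normal transform; the tied imputed block
#' receives average ranks, so it sits at the bottom of the distribution.
#'
#' @param x Numeric vector with `NA` for missing values.
#' @return Transformed vector; the imputed count is attribute `n_imputed`.
#' @export
prepare_metabolite <- function(x) {
  if (all(is.na(x))) stop("metabolite has no observed values")
  miss <- is.na(x)
  x[miss] <- min(x, na.rm = TRUE)
  out <- rank_inverse_normal(x)
  attr(out, "n_imputed") <- sum(miss)
  out
}

#' Survey-weighted regression with stratified cluster sandwich errors
#'
#' Point estimates are weighted least squares. Variances use the
#' design-based linearization estimator: weighted score contributions are
#' summed within clusters, centered within strata, and their between-
#' cluster covariance forms the sandwich meat. By default no small-sample
#' cluster factor is applied, so with unit weights, singleton clusters and
#' one stratum the standard errors reduce exactly to HC0 robust OLS
#' standard errors; `small_sample = "clusters"` applies the conventional
#' `n_h / (n_h - 1)` factor per stratum.
#'
#' @param y Numeric response.
#' @param X Design matrix (with intercept).
#' @param design A `survey_design`.
#' @param small_sample `"none"` (default) or `"clusters"`.
#' @return A list with `coefficients` (term, estimate, se, stat, p),
#'   `vcov`, `df` (clusters minus strata), and `n`.
#' @export
survey_glm <- function(y, X, design, small_sample = c("none", "clusters")) {
  small_sample <- match.arg(small_sample)
  stopifnot(inherits(design, "survey_design"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, design$n == n)
  .check_full_rank(X, "survey_glm")
  per_stratum <- tapply(design$cluster, design$stratum,
                        function(cl) length(unique(cl)))
  lonely <- names(per_stratum)[per_stratum < 2]
  if (length(lonely) > 0) {
    stop("stratum with a single cluster: ", paste(lonely, collapse = ", "))
  }
  w <- design$weight
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * y))
  resid <- y - as.vector(X %*% beta)
  S <- X * (w * resid)                    # per-observation weighted scores
  meat <- matrix(0, ncol(X), ncol(X))
  for (h in unique(design$stratum)) {
    rows <- design$stratum == h
    Eh <- rowsum(S[rows, , drop = FALSE], design$cluster[rows])
    n_h <- nrow(Eh)
    Ehc <- sweep(Eh, 2, colMeans(Eh))
    g <- if (small_sample == "clusters") n_h / (n_h - 1) else 1
    meat <- meat + g * crossprod(Ehc)
  }
  bread <- solve(XtWX)
  V <- bread %*% meat %*% bread
  se <- sqrt(diag(V))
  est <- as.vector(beta)
  df <- length(unique(design$cluster)) - length(unique(design$stratum))
  stat <- est / se
  p <- 2 * stats::pt(-abs(stat), df = max(df, 1))
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      stat = stat, p = p, stringsAsFactors = FALSE,
                      row.names = NULL)
  list(coefficients = coefs, vcov = V, df = df, n = n)
}

# Shared worker: survey regression of a prepared metabolite on one exposure
# plus covariates; returns the exposure row.
.survey_assoc_row <- function(outcome, exposure, exposure_name, pheno,
                              covariates, design) {
  C <- .design_matrix(pheno, covariates)
  X <- cbind(C, exposure)
  colnames(X)[ncol(X)] <- exposure_name
  fit <- survey_glm(outcome, X, design)
  row <- fit$coefficients[fit$coefficients$term == exposure_name, ]
  data.frame(estimate = row$estimate, se = row$se, stat = row$stat,
             p_nominal = row$p, n = fit$n, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Scan metabolites for association with a validated tPRS
#'
#' For each identified (named) metabolite with fewer than 25% missing
#' values: minimum-value imputation, rank normalization, then
#' survey-weighted regression of the metabolite on the standardized tPRS
#' and covariates. P-values are BH-adjusted within this transcript's
#' metabolite family.
#'
#' @param score Standardized tPRS vector aligned with the metabolite
#'   columns.
#' @param metabolites Metabolite-by-sample matrix with `NA` for missing.
#' @param metabolite_info Data frame with `metabolite_id` and `named`.
#' @param pheno Phenotype data frame (covariates).
#' @param design A `survey_design`.
#' @param covariates Covariate column names.
#' @param adjust_bmi Add BMI to the covariates?
#' @param max_missing Missingness filter (exclusive).
#' @return Data frame with one row per tested metabolite: estimate, se,
#'   `p_nominal`, `p_fdr`, `missing_fraction`.
#' @export
tprs_metabolite_scan <- function(score, metabolites, metabolite_info, pheno,
                                 design,
                                 covariates = c("age", "sex", "site",
                                                "background", paste0("PC", 1:5)),
                                 adjust_bmi = FALSE, max_missing = 0.25) {
  if (adjust_bmi) covariates <- unique(c(covariates, "BMI"))
  miss_frac <- rowMeans(is.na(metabolites))
  named <- metabolite_info$named[match(rownames(metabolites),
                                       metabolite_info$metabolite_id)]
  test <- which(named & miss_frac < max_missing)
  rows <- vector("list", length(test))
  for (i in seq_along(test)) {
    m <- test[i]
    ym <- prepare_metabolite(metabolites[m, ])
    r <- .survey_assoc_row(ym, as.vector(scale(score)), "tPRS", pheno,
                           covariates, design)
    rows[[i]] <- cbind(data.frame(metabolite_id = rownames(metabolites)[m],
                                  missing_fraction = miss_frac[m],
                                  stringsAsFactors = FALSE), r)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(metabolite_id = character(0), missing_fraction = numeric(0),
                      estimate = numeric(0), se = numeric(0), stat = numeric(0),
                      p_nominal = numeric(0))
  }
  out$p_fdr <- bh_fdr(out$p_nominal)
  rownames(out) <- NULL
  out
}

#' Association of an SDB trait with one metabolite
#'
#' Survey-weighted regression of the prepared metabolite on the trait and
#' covariates; significance rule `p < 0.05`. Run with BMI in the model when
#' the upstream chain is BMI-adjusted.
#'
#' @param trait Numeric trait values.
#' @param metabolite Numeric metabolite values with `NA` for missing.
#' @param pheno Phenotype data frame.
#' @param design A `survey_design`.
#' @param covariates Covariate column names.
#' @param adjust_bmi Add BMI?
#' @return One-row data frame with estimate, se, stat, `p_nominal`, n.
#' @export
trait_metabolite_assoc <- function(trait, metabolite, pheno, design,
                                   covariates = c("age", "sex", "site",
                                                  "background"),
                                   adjust_bmi = FALSE) {
  if (adjust_bmi) covariates <- unique(c(covariates, "BMI"))
  ym <- prepare_metabolite(metabolite)
  .survey_assoc_row(ym, trait, "trait", pheno, covariates, design)
}
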