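# Linear mixed models with arbitrary sparse covariance structures
# (kinship, household, sampling block), estimated by average-information
# REML with step-halving, for tPRS validation and tPRS-trait association.

# Coerce one random-effect specification to a sparse symmetric n x n
# covariance matrix: either a covariance matrix as given, or a grouping
# vector expanded to an indicator-product (block-membership) matrix.
.re_covariance <- function(r, n) {
  if (is.matrix(r) || inherits(r, "Matrix")) {
    if (nrow(r) != n || ncol(r) != n) stop("covariance matrix has wrong dimension")
    M <- Matrix::forceSymmetric(methods::as(methods::as(r, "generalMatrix"), "CsparseMatrix"))
    if (!Matrix::isSymmetric(M)) stop("covariance matrix must be symmetric")
    if (any(Matrix::diag(M) < 0)) stop("covariance matrix is not positive semidefinite")
    ok <- tryCatch({
      suppressWarnings(
        Matrix::Cholesky(M + Matrix::Diagonal(n, 1e-6 * max(Matrix::diag(M), 1)),
                         LDL = FALSE, perm = TRUE))
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("covariance matrix is not positive semidefinite")
    M
  } else {
    if (length(r) != n) stop("grouping vector has wrong length")
    f <- factor(r)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                              dims = c(n, nlevels(f)))
    Matrix::forceSymmetric(Matrix::tcrossprod(Z))
  }
}

# Evaluate REML quantities at variance components s (length k+1, residual
# last). When full=TRUE also return score, AI, and fixed-effect results.
.lmm_eval <- function(s, y, X, A, full = FALSE) {
  n <- length(y)
  k <- length(A)
  V <- Matrix::Diagonal(n, s[k + 1L])
  for (i in seq_len(k)) if (s[i] > 0) V <- V + s[i] * A[[i]]
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(V), LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ViX <- as.matrix(Matrix::solve(ch, X))
  Viy <- as.vector(Matrix::solve(ch, y))
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  XtViX_inv <- tryCatch(solve(XtViX), error = function(e) NULL)
  if (is.null(XtViX_inv)) return(NULL)
  beta <- as.vector(XtViX_inv %*% XtViy)
  Py <- Viy - ViX %*% (XtViX_inv %*% XtViy)
  yPy <- sum(y * Py)
  ldV <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  ldX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  ll <- -0.5 * (ldV + ldX + yPy)
  out <- list(ll = ll, beta = beta, XtViX_inv = XtViX_inv, Py = as.vector(Py),
              ch = ch, ViX = ViX)
  if (!full) return(out)

  U <- matrix(0, n, k + 1L)
  trPA <- numeric(k + 1L)
  for (i in seq_len(k)) {
    AiViX <- as.matrix(A[[i]] %*% ViX)
    trVA <- sum(Matrix::diag(Matrix::solve(ch, A[[i]])))
    trPA[i] <- trVA - sum(XtViX_inv * crossprod(ViX, AiViX))
    U[, i] <- as.vector(A[[i]] %*% out$Py)
  }
  trV <- sum(Matrix::diag(Matrix::solve(ch, Matrix::Diagonal(n))))
  trPA[k + 1L] <- trV - sum(XtViX_inv * crossprod(ViX))
  U[, k + 1L] <- out$Py
  yPAPy <- as.vector(crossprod(out$Py, U))
  score <- -0.5 * (trPA - yPAPy)
  ViU <- as.matrix(Matrix::solve(ch, U))
  PU <- ViU - ViX %*% (XtViX_inv %*% crossprod(ViX, U))
  AI <- 0.5 * crossprod(U, PU)
  out$score <- score
  out$AI <- AI
  out
}

#' Fit a linear mixed model by AI-REML
#'
#' Estimates nonnegative variance components for an arbitrary set of
#' covariance structures (e.g. a genetic relatedness matrix `2 * kinship`,
#' household and sampling-block membership) plus a residual, by
#' average-information REML with step-halving, so the restricted
#' log-likelihood is nondecreasing over accepted iterations. Components are
#' kept nonnegative by projection. Fixed effects are estimated by GLS at
#' the final components, with Wald t-tests on `n - ncol(X)` degrees of
#' freedom (which reduce exactly to OLS tests when all structured
#' components vanish).
#'
#' @param y Numeric response (complete cases; no `NA`).
#' @param X Fixed-effect design matrix including the intercept.
#' @param random Named list of random-effect structures: each element an
#'   n x n symmetric covariance matrix (dense or `Matrix`) or a grouping
#'   vector of length n.
#' @param fix_varcomp Optional numeric vector of variance components
#'   (structured components in `random` order, residual last); when given,
#'   REML iteration is skipped and GLS at these components is returned.
#' @param max_iter,tol Iteration controls.
#' @return An object of class `lmm_fit`: `varcomp`, `fixef` (estimate, se,
#'   stat, p), `loglik_trace`, `iterations`, `converged`, `n`.
#' @export
fit_lmm <- function(y, X, random = list(), fix_varcomp = NULL,
                    max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y), !anyNA(X))
  .check_full_rank(X, "fit_lmm fixed effects")
  k <- length(random)
  A <- lapply(random, .re_covariance, n = n)
  vnames <- c(if (k > 0) paste0("sigma2_", names(A) %||% seq_len(k)) else character(0),
              "sigma2_residual")

  ols <- stats::lm.fit(X, y)
  vy <- sum(ols$residuals^2) / (n - ncol(X))

  finalize <- function(s, trace, iter, converged) {
    ev <- .lmm_eval(s, y, X, A, full = FALSE)
    if (is.null(ev)) stop("mixed model evaluation failed at final components")
    se <- sqrt(diag(ev$XtViX_inv))
    stat <- ev$beta / se
    p <- 2 * stats::pt(-abs(stat), df = n - ncol(X))
    fixef <- data.frame(term = colnames(X), estimate = ev$beta, se = se,
                        stat = stat, p = p, stringsAsFactors = FALSE,
                        row.names = NULL)
    structure(list(varcomp = stats::setNames(s, vnames), fixef = fixef,
                   loglik = ev$ll, loglik_trace = trace, iterations = iter,
                   converged = converged, n = n,
                   vcov = ev$XtViX_inv),
              class = "lmm_fit")
  }

  if (k == 0L && is.null(fix_varcomp)) {
    return(finalize(vy, numeric(0), 0L, TRUE))
  }
  if (!is.null(fix_varcomp)) {
    stopifnot(length(fix_varcomp) == k + 1L)
    return(finalize(as.numeric(fix_varcomp), numeric(0), 0L, TRUE))
  }

  s <- rep(vy / (k + 1), k + 1L)
  floor_res <- max(1e-8 * vy, 1e-12)
  floors <- c(rep(0, k), floor_res)
  ev <- .lmm_eval(s, y, X, A, full = TRUE)
  if (is.null(ev)) stop("mixed model failed to initialize")
  trace <- ev$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # active set: components pinned at their floor with an outward-pointing
    # score stay frozen; the Newton direction uses the reduced AI matrix
    free <- !(s <= floors & ev$score < 0)
    if (!any(free)) {
      converged <- TRUE
      break
    }
    delta <- numeric(k + 1L)
    AIf <- ev$AI[free, free, drop = FALSE]
    AIf <- AIf + diag(1e-8 * max(diag(AIf), 1), sum(free))
    delta[free] <- tryCatch(solve(AIf, ev$score[free]),
                            error = function(e) ev$score[free] / max(diag(AIf)))
    step <- 1
    repeat {
      s_new <- pmax(s + step * delta, floors)
      ev_new <- .lmm_eval(s_new, y, X, A, full = TRUE)
      if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) {
        ev_new <- ev
        s_new <- s
        break
      }
    }
    improved <- ev_new$ll - ev$ll
    s <- s_new
    ev <- ev_new
    trace <- c(trace, ev$ll)
    if (improved < tol * (1 + abs(ev$ll))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter) {
    stop("fit_lmm did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", "))
  }
  # boundary polish: AI steps approach a zero component only linearly, so a
  # small remaining value is snapped to the floor whenever that does not
  # lower the restricted likelihood (at a boundary optimum it raises it)
  for (i in seq_len(k + 1L)) {
    if (s[i] > floors[i] && s[i] < 1e-3 * vy) {
      s_try <- s
      s_try[i] <- floors[i]
      ev_try <- .lmm_eval(s_try, y, X, A, full = FALSE)
      if (!is.null(ev_try) && ev_try$ll >= ev$ll - 1e-10 * (1 + abs(ev$ll))) {
        s <- s_try
        ev <- ev_try
        trace <- c(trace, ev$ll)
      }
    }
  }
  finalize(s, trace, iter, converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print lmm_fit
print.lmm_fit <- function(x, ...) {
  cat("AI-REML linear mixed model (n =", x$n, ")\n")
  cat("variance components:\n")
  print(x$varcomp)
  print(x$fixef)
  invisible(x)
}

# Build the random-effect list used for a cohort with relatedness and
# survey structure: GRM = 2 * kinship with small entries zeroed (sparse
# kinship), household and block-unit membership.
.cohort_random <- function(kinship_structure, sparse_threshold = 0.022,
                           use = c("kinship", "household", "block")) {
  ks <- kinship_structure
  out <- list()
  if ("kinship" %in% use) {
    K <- methods::as(methods::as(ks$kinship, "generalMatrix"), "CsparseMatrix")
    K@x[K@x < sparse_threshold] <- 0
    K <- Matrix::drop0(K)
    out$kinship <- Matrix::forceSymmetric(2 * K)
  }
  if ("household" %in% use) out$household <- ks$household_id
  if ("block" %in% use) out$block <- ks$block_unit
  out
}

#' Association of a standardized tPRS with an SDB trait
#'
#' Fits a linear mixed model of the two-stage rank-normalized trait on the
#' standardized tPRS, covariates (including the log of the sampling
#' weights), and random effects for kinship (sparse GRM), household, and
#' sampling block. The reported effect is per 1 SD of the tPRS.
#'
#' @param score Numeric tPRS (any scale; standardized internally).
#' @param trait Name of the trait column in `pheno`.
#' @param pheno Phenotype data frame (must contain the covariates and
#'   `sampling_weight`).
#' @param kinship_structure A `kinship_structure` for the cohort.
#' @param covariates Covariate column names.
#' @param adjust_bmi Add BMI (used when the upstream discovery association
#'   was BMI-adjusted)?
#' @param sparse_threshold Kinship entries below this are zeroed.
#' @return One-row `assoc_result` data frame with the per-SD estimate, SE,
#'   Wald statistic and p-value; variance components in attribute
#'   `varcomp`.
#' @export
assoc_tprs_trait <- function(score, trait, pheno, kinship_structure,
                             covariates = c("age", "sex", "site", "background",
                                            paste0("PC", 1:5)),
                             adjust_bmi = FALSE, sparse_threshold = 0.022) {
  if (adjust_bmi) covariates <- unique(c(covariates, "BMI"))
  keep <- stats::complete.cases(pheno[, c(trait, covariates, "sampling_weight"),
                                      drop = FALSE]) & !is.na(score)
  ph <- pheno[keep, , drop = FALSE]
  C <- .design_matrix(ph, covariates)
  C <- cbind(C, log_sampling_weight = log(ph$sampling_weight))
  y <- two_stage_rank_normalize(ph[[trait]], C)
  s_std <- as.vector(scale(score[keep]))
  X <- cbind(C, tPRS = s_std)
  .check_full_rank(X, "assoc_tprs_trait")
  idx <- which(keep)
  random <- .cohort_random(kinship_structure, sparse_threshold)
  random$kinship <- random$kinship[idx, idx, drop = FALSE]
  random$household <- random$household[idx]
  random$block <- random$block[idx]
  fit <- fit_lmm(y, X, random = random)
  row <- fit$fixef[fit$fixef$term == "tPRS", ]
  out <- data.frame(exposure_id = "tPRS", feature_id = trait,
                    estimate = row$estimate, se = row$se, stat = row$stat,
                    p_nominal = row$p, n = fit$n, bmi_adjusted = adjust_bmi,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "varcomp") <- fit$varcomp
  attr(out, "n_dropped") <- sum(!keep)
  out
}
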