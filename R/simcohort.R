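# Synthetic three-cohort generator with planted causal structure.
#
# Three linked cohorts share one variant panel and one generative model:
#   - a discovery cohort with cell-type-resolved expression and sleep traits,
#   - a validation cohort with whole-blood expression,
#   - a target cohort with sleep traits, metabolites, household/block survey
#     structure and probability-sampling weights.
# Planted scenarios give every downstream stage a ground truth.

#' Specification of the synthetic study
#'
#' Collects all generator parameters: the shared variant panel (LD blocks
#' with AR(1) within-block correlation on the copula scale), the trait,
#' transcript and metabolite layers, relatedness, and measurement ranges.
#' The defaults are the documented study conditions used throughout the
#' package's own simulations.
#'
#' @param n_samples Named integer vector with cohort sizes for
#'   `discovery`, `validation`, and `target`.
#' @param n_variants Total number of variants in the shared panel.
#' @param n_blocks Number of LD blocks; must not exceed `n_variants`.
#' @param rho Within-block AR(1) correlation of the latent Gaussian copula,
#'   in `[0, 1)`.
#' @param maf_range Interval within `(0, 0.5]` from which per-variant minor
#'   allele frequencies are drawn.
#' @param n_transcripts Number of transcripts (before the low-expression
#'   decoys added by `n_low_transcripts`).
#' @param n_low_transcripts Number of additional lowly expressed decoy
#'   transcripts that the expression QC filter is expected to remove.
#' @param n_celltypes,celltype_labels Cell types measured in the discovery
#'   cohort.
#' @param n_metabolites Number of metabolites in the target cohort.
#' @param frac_unknown_metabolites Fraction of metabolites flagged as
#'   unidentified (excluded from association scans).
#' @param frac_sibpairs Fraction of samples arranged in full-sibling pairs.
#' @param qual_range Uniform range for per-variant imputation quality.
#' @param miss_range Uniform range for per-variant missingness rates.
#' @param lod_quantile Limit-of-detection quantile at which metabolite
#'   values are left-censored to missing.
#' @param trait_cor Shared-variance fraction of the three trait latents
#'   (controls the correlation between AHI-like and oximetry-like traits).
#' @param eqtl_per_transcript Number of causal cis variants per transcript.
#' @param seed Default master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = c(discovery = 800, validation = 1200, target = 3000),
                        n_variants = 200, n_blocks = 20, rho = 0.6,
                        maf_range = c(0.1, 0.5),
                        n_transcripts = 6, n_low_transcripts = 2,
                        n_celltypes = 3,
                        celltype_labels = c("PBMC", "Mono", "Tcell"),
                        n_metabolites = 30, frac_unknown_metabolites = 0.1,
                        frac_sibpairs = 0.2,
                        qual_range = c(0.78, 1), miss_range = c(0, 0.011),
                        lod_quantile = 0.2, trait_cor = 0.3,
                        eqtl_per_transcript = 2, seed = 1L) {
  stopifnot(all(c("discovery", "validation", "target") %in% names(n_samples)),
            all(n_samples > 0), n_variants > 0, n_blocks > 0,
            n_transcripts > 0, n_metabolites > 0, n_celltypes >= 1,
            length(celltype_labels) == n_celltypes,
            frac_sibpairs >= 0, frac_sibpairs < 1,
            lod_quantile >= 0, lod_quantile < 1,
            trait_cor >= 0, trait_cor < 1)
  if (!(rho >= 0 && rho < 1)) stop("rho must be in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (n_variants < n_blocks) stop("n_variants must be >= n_blocks")
  spec <- list(n_samples = n_samples, n_variants = as.integer(n_variants),
               n_blocks = as.integer(n_blocks), rho = rho,
               maf_range = maf_range,
               n_transcripts = as.integer(n_transcripts),
               n_low_transcripts = as.integer(n_low_transcripts),
               n_celltypes = as.integer(n_celltypes),
               celltype_labels = celltype_labels,
               n_metabolites = as.integer(n_metabolites),
               frac_unknown_metabolites = frac_unknown_metabolites,
               frac_sibpairs = frac_sibpairs,
               qual_range = qual_range, miss_range = miss_range,
               lod_quantile = lod_quantile, trait_cor = trait_cor,
               eqtl_per_transcript = as.integer(eqtl_per_transcript),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Planted ground-truth scenario for one transcript
#'
#' Encodes one causal scenario linking a trait, a transcript, and optionally
#' a metabolite. Scenario-specific zero constraints are enforced:
#' `a1_trait_to_transcript` forbids a transcript-to-trait path,
#' `a3_transcript_to_trait` forbids the reverse path,
#' `a4_bmi_confounded` forbids both direct paths but requires BMI paths,
#' `complete_chain` is `a3` plus a transcript-to-metabolite path, and
#' `null` forbids every path (the transcript may still have eQTLs).
#'
#' @param scenario One of `a1_trait_to_transcript`, `a2_bidirectional`,
#'   `a3_transcript_to_trait`, `a4_bmi_confounded`, `complete_chain`, `null`.
#' @param transcript_id,trait_id,metabolite_id Feature identifiers;
#'   `metabolite_id` may be `NA`.
#' @param eqtl_h2 Variance fraction of the transcript's physiological level
#'   explained by its causal variants, in `[0, 1]`.
#' @param beta_transcript_trait,beta_trait_transcript,beta_transcript_metabolite,beta_bmi_trait,beta_bmi_transcript
#'   Standardized path coefficients of the structural model.
#' @return A one-row `data.frame` of class `truth_record`.
#' @export
truth_record <- function(scenario, transcript_id, trait_id,
                         metabolite_id = NA_character_,
                         eqtl_h2 = 0.3,
                         beta_transcript_trait = 0,
                         beta_trait_transcript = 0,
                         beta_transcript_metabolite = 0,
                         beta_bmi_trait = 0,
                         beta_bmi_transcript = 0) {
  scenarios <- c("a1_trait_to_transcript", "a2_bidirectional",
                 "a3_transcript_to_trait", "a4_bmi_confounded",
                 "complete_chain", "null")
  scenario <- match.arg(scenario, scenarios)
  if (eqtl_h2 < 0 || eqtl_h2 > 1) stop("eqtl_h2 must be in [0, 1]")
  ok <- switch(scenario,
    a1_trait_to_transcript = beta_transcript_trait == 0 && beta_trait_transcript != 0,
    a2_bidirectional = beta_transcript_trait != 0 && beta_trait_transcript != 0,
    a3_transcript_to_trait = beta_transcript_trait != 0 && beta_trait_transcript == 0,
    a4_bmi_confounded = beta_transcript_trait == 0 && beta_trait_transcript == 0 &&
      beta_bmi_trait != 0 && beta_bmi_transcript != 0,
    complete_chain = beta_transcript_trait != 0 && beta_trait_transcript == 0 &&
      beta_transcript_metabolite != 0,
    null = beta_transcript_trait == 0 && beta_trait_transcript == 0 &&
      beta_transcript_metabolite == 0 && beta_bmi_trait == 0 &&
      beta_bmi_transcript == 0)
  if (!ok) stop("path coefficients violate the zero constraints of scenario ", scenario)
  out <- data.frame(scenario = scenario, transcript_id = transcript_id,
                    trait_id = trait_id, metabolite_id = metabolite_id,
                    eqtl_h2 = eqtl_h2,
                    beta_transcript_trait = beta_transcript_trait,
                    beta_trait_transcript = beta_trait_transcript,
                    beta_transcript_metabolite = beta_transcript_metabolite,
                    beta_bmi_trait = beta_bmi_trait,
                    beta_bmi_transcript = beta_bmi_transcript,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_record", "data.frame")
  out
}

#' Standard scenario battery
#'
#' One transcript per scenario: trait-to-transcript (`a1`, AHI),
#' transcript-to-trait (`a3`, MinO2), BMI confounding (`a4`, AvgO2),
#' a complete trait-transcript-metabolite chain (AvgO2, `met_01`), and a
#' pure-eQTL null. Effect sizes are the documented study conditions.
#'
#' @param spec A `cohort_spec` (checked for enough transcripts/metabolites).
#' @return A `truth_record` data frame (one row per scenario).
#' @export
default_truth <- function(spec = cohort_spec()) {
  stopifnot(spec$n_transcripts >= 5, spec$n_metabolites >= 1)
  rbind(
    truth_record("a1_trait_to_transcript", "tr_01", "AHI",
                 beta_trait_transcript = 0.25),
    truth_record("a3_transcript_to_trait", "tr_02", "MinO2",
                 beta_transcript_trait = 0.25),
    truth_record("a4_bmi_confounded", "tr_03", "AvgO2",
                 metabolite_id = "met_02",
                 beta_bmi_trait = 0.35, beta_bmi_transcript = 0.35),
    truth_record("complete_chain", "tr_04", "AvgO2", metabolite_id = "met_01",
                 beta_transcript_trait = 0.25,
                 beta_transcript_metabolite = 0.45),
    truth_record("null", "tr_05", "AHI")
  )
}

# Per-variant LD-block assignment and genomic coordinates. Blocks are laid
# out on chromosomes 1..22 with ~1 Mb between block starts so that the
# +/-250 kb clump window and the +/-1 Mb cis window behave realistically.
.variant_panel <- function(spec) {
  p <- spec$n_variants
  nb <- spec$n_blocks
  base <- rep(p %/% nb, nb)
  extra <- p %% nb
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  block <- rep(seq_len(nb), base)
  chr <- ((seq_len(nb) - 1L) %% 22L) + 1L
  ord_in_chr <- ave(seq_len(nb), chr, FUN = seq_along)
  within <- unlist(lapply(base, seq_len))
  pos <- (ord_in_chr[block] - 1L) * 1000000L + within * 5000L
  list(block = block, chr = chr[block], pos = pos, block_sizes = base)
}

# One haplotype matrix (n x p): latent AR(1) Gaussians within LD blocks,
# thresholded so that P(alt allele) = maf.
.sim_haplotypes <- function(n, maf, block, rho) {
  p <- length(maf)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (p > 1L && rho > 0) {
    for (j in 2:p) {
      if (block[j] == block[j - 1L]) {
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
      }
    }
  }
  q <- stats::qnorm(maf)
  z < rep(q, each = n)
}

#' Simulate genotypes and relatedness for one cohort
#'
#' Dosages come from a Gaussian copula with AR(1) correlation `rho` inside
#' each LD block, independence across blocks, thresholded to haplotype
#' alleles by per-variant MAF; each individual is the sum of two haplotypes.
#' Sibling pairs share parental transmissions block-wise (expected kinship
#' 0.25). Households contain sibling pairs and a fraction of unrelated
#' pairs; households nest in sampling block units, block units in strata,
#' and strata determine inverse-probability sampling weights.
#'
#' @param spec A `cohort_spec`.
#' @param n Number of samples (defaults to the discovery cohort size).
#' @param seed Integer seed.
#' @param id_prefix Prefix for sample identifiers.
#' @return A list with elements `genotypes` (class `genotype_data`: `dosages`
#'   n x p matrix with optional `NA`s, `variants` metadata data frame,
#'   `sample_ids`) and `kinship` (class `kinship_structure`: sparse kinship
#'   matrix with 0.5 diagonal, `household_id`, `block_unit`, `stratum`,
#'   `sampling_weight`, `sib_pairs`).
#' @export
simulate_genotypes <- function(spec, n = spec$n_samples[["discovery"]],
                               seed = spec$seed, id_prefix = "S") {
  stopifnot(inherits(spec, "cohort_spec"), n >= 2)
  p <- spec$n_variants
  panel <- .variant_panel(spec)
  # variant panel metadata is shared across cohorts: it depends only on the
  # spec (own seed stream), never on the cohort seed
  set.seed(child_seed(spec$seed, "panel"))
  maf <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, p, replace = TRUE)
  alt <- vapply(ref, function(a) sample(setdiff(alleles, a), 1L), character(1))

  set.seed(seed)
  n_pairs <- floor(spec$frac_sibpairs * n / 2)
  n_sib <- 2L * n_pairs
  n_unrel <- n - n_sib

  dos <- matrix(0L, n, p)
  if (n_pairs > 0) {
    # four parental haplotypes per pair; block-wise transmission to two sibs
    P <- lapply(1:4, function(k) .sim_haplotypes(n_pairs, maf, panel$block, spec$rho))
    for (child in 1:2) {
      pick_pat <- matrix(stats::runif(n_pairs * spec$n_blocks) < 0.5,
                         n_pairs, spec$n_blocks)[, panel$block, drop = FALSE]
      pick_mat <- matrix(stats::runif(n_pairs * spec$n_blocks) < 0.5,
                         n_pairs, spec$n_blocks)[, panel$block, drop = FALSE]
      hap_p <- ifelse(pick_pat, P[[1]], P[[2]])
      hap_m <- ifelse(pick_mat, P[[3]], P[[4]])
      rows <- seq.int(child, by = 2L, length.out = n_pairs)
      dos[rows, ] <- hap_p + hap_m
    }
  }
  if (n_unrel > 0) {
    hapA <- .sim_haplotypes(n_unrel, maf, panel$block, spec$rho)
    hapB <- .sim_haplotypes(n_unrel, maf, panel$block, spec$rho)
    dos[(n_sib + 1L):n, ] <- hapA + hapB
  }
  storage.mode(dos) <- "double"

  imputation_quality <- stats::runif(p, spec$qual_range[1], spec$qual_range[2])
  missingness <- stats::runif(p, spec$miss_range[1], spec$miss_range[2])
  if (any(missingness > 0)) {
    for (j in which(missingness > 0)) {
      miss <- stats::runif(n) < missingness[j]
      if (any(miss)) dos[miss, j] <- NA_real_
    }
  }

  variant_id <- sprintf("v%05d", seq_len(p))
  sample_ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  dimnames(dos) <- list(sample_ids, variant_id)

  variants <- data.frame(variant_id = variant_id, chr = panel$chr,
                         pos = panel$pos, ref = ref, alt = alt, maf = maf,
                         block = panel$block,
                         imputation_quality = imputation_quality,
                         missingness = missingness, stringsAsFactors = FALSE)

  genotypes <- structure(list(dosages = dos, variants = variants,
                              sample_ids = sample_ids),
                         class = "genotype_data")

  # households: sib pairs live together; ~30% of unrelated samples pair up
  household <- integer(n)
  hh <- 0L
  if (n_pairs > 0) {
    for (k in seq_len(n_pairs)) {
      hh <- hh + 1L
      household[c(2L * k - 1L, 2L * k)] <- hh
    }
  }
  rest <- if (n_sib < n) (n_sib + 1L):n else integer(0)
  n_extra_pairs <- floor(0.15 * length(rest))
  if (n_extra_pairs > 0) {
    paired <- sample(rest, 2L * n_extra_pairs)
    for (k in seq_len(n_extra_pairs)) {
      hh <- hh + 1L
      household[paired[c(2L * k - 1L, 2L * k)]] <- hh
    }
    rest <- setdiff(rest, paired)
  }
  for (i in rest) {
    hh <- hh + 1L
    household[i] <- hh
  }

  # block units of ~5 households, four strata of block units
  hh_ids <- sort(unique(household))
  hh_block <- ((seq_along(hh_ids) - 1L) %/% 5L) + 1L
  block_unit <- hh_block[match(household, hh_ids)]
  n_bu <- max(block_unit)
  stratum <- pmin(((block_unit - 1L) %/% max(1L, ceiling(n_bu / 4))) + 1L, 4L)
  prob <- c(0.6, 0.45, 0.3, 0.15)[stratum]
  sampling_weight <- (1 / prob) * stats::runif(n, 0.9, 1.1)

  if (n_pairs > 0) {
    i1 <- seq.int(1L, by = 2L, length.out = n_pairs)
    kin <- Matrix::sparseMatrix(i = i1, j = i1 + 1L, x = 0.25,
                                dims = c(n, n), symmetric = TRUE)
  } else {
    kin <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n), symmetric = TRUE)
  }
  kin <- kin + Matrix::Diagonal(n, 0.5)
  dimnames(kin) <- list(sample_ids, sample_ids)
  sib_pairs <- if (n_pairs > 0) {
    data.frame(id1 = sample_ids[seq.int(1L, by = 2L, length.out = n_pairs)],
               id2 = sample_ids[seq.int(2L, by = 2L, length.out = n_pairs)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(id1 = character(0), id2 = character(0))
  }

  kinship <- structure(list(kinship = Matrix::forceSymmetric(kin),
                            sample_ids = sample_ids,
                            household_id = household,
                            block_unit = block_unit,
                            stratum = stratum,
                            sampling_weight = sampling_weight,
                            sib_pairs = sib_pairs),
                       class = "kinship_structure")
  list(genotypes = genotypes, kinship = kinship)
}

# Deterministic cis-eQTL architecture: transcript t lives in LD block
# ((t-1) mod n_blocks)+1; its causal variants are evenly spaced inside that
# block with alternating-sign weights. No RNG so all cohorts share it.
.transcript_architecture <- function(spec, variants) {
  n_tr <- spec$n_transcripts
  blocks <- split(seq_len(nrow(variants)), variants$block)
  out <- vector("list", n_tr)
  for (t in seq_len(n_tr)) {
    b <- ((t - 1L) %% spec$n_blocks) + 1L
    idx <- blocks[[b]]
    k <- min(spec$eqtl_per_transcript, length(idx))
    sel <- idx[unique(pmax(1L, round(seq(0.25, 0.75, length.out = k) * length(idx))))]
    w <- rep(c(1, -0.8), length.out = length(sel))
    mid <- variants$pos[sel[1L]]
    out[[t]] <- list(transcript_id = sprintf("tr_%02d", t),
                     causal = variants$variant_id[sel], weights = w,
                     chr = variants$chr[sel[1L]],
                     start = max(1L, mid - 50000L), end = mid + 50000L)
  }
  names(out) <- vapply(out, `[[`, character(1), "transcript_id")
  out
}

#' Annotated transcript spans of the synthetic panel
#'
#' @param spec A `cohort_spec`.
#' @param variants Variant metadata from [simulate_genotypes()].
#' @return Data frame with transcript_id, chr, start, end and causal variants.
#' @export
transcript_annotation <- function(spec, variants) {
  arch <- .transcript_architecture(spec, variants)
  data.frame(transcript_id = names(arch),
             chr = vapply(arch, `[[`, numeric(1), "chr"),
             start = vapply(arch, `[[`, numeric(1), "start"),
             end = vapply(arch, `[[`, numeric(1), "end"),
             causal_variants = vapply(arch, function(a) paste(a$causal, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Simulate phenotypes, expression, and metabolites on top of genotypes
#'
#' Implements the structural model of the planted scenarios. For each
#' transcript, a physiological level `T = sqrt(h2) * g + sqrt(1-h2) * e`
#' combines the (standardized) causal-dosage burden `g` and environment.
#' Trait latents are standardized sums of transcript paths, a BMI path, and
#' correlated noise; AHI is a floored shifted lognormal of its latent
#' (right-skewed, zero-inflated), MinO2/AvgO2 are bounded Gaussians on
#' [70, 100]. Measured expression adds a trait path (scenarios a1/a2), a BMI
#' path, cell-type noise, and negative-binomial counting. Metabolites are
#' lognormal with planted transcript paths, left-censored at the
#' limit-of-detection quantile.
#'
#' @param genotypes,kinship Output of [simulate_genotypes()].
#' @param truth A `truth_record` data frame.
#' @param spec The `cohort_spec`.
#' @param seed Integer seed.
#' @param cell_types Character vector of expression layers to generate
#'   (`NULL` for none, e.g. the target cohort).
#' @param with_metabolites Generate the metabolite layer?
#' @param lod_quantile Left-censoring quantile, defaults to the spec value.
#' @param keep_latent Attach the latent generative components as attribute
#'   `latent` (used by variance-decomposition checks).
#' @return A list with `expression` (named list of `expr_matrix` raw counts),
#'   `phenotypes` (data frame with traits, covariates, genetic PCs, survey
#'   fields), `metabolites` (matrix with `NA` for censored values),
#'   `metabolite_info`, and the `truth` used.
#' @export
simulate_omics <- function(genotypes, kinship, truth, spec,
                           seed = spec$seed + 1L,
                           cell_types = spec$celltype_labels,
                           with_metabolites = FALSE,
                           lod_quantile = spec$lod_quantile,
                           keep_latent = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "data.frame"))
  traits <- c("AHI", "MinO2", "AvgO2")
  if (!all(truth$trait_id %in% traits)) stop("unknown trait_id in truth")
  tr_ids <- sprintf("tr_%02d", seq_len(spec$n_transcripts))
  if (!all(truth$transcript_id %in% tr_ids)) stop("unknown transcript_id in truth")
  met_ids <- sprintf("met_%02d", seq_len(spec$n_metabolites))
  if (!all(is.na(truth$metabolite_id) | truth$metabolite_id %in% met_ids)) {
    stop("unknown metabolite_id in truth")
  }

  set.seed(seed)
  D <- .impute_dosage(genotypes$dosages)
  n <- nrow(D)
  arch <- .transcript_architecture(spec, genotypes$variants)

  # genetic principal components of the standardized dosage matrix
  Z <- scale(D)
  Z[, which(apply(D, 2, stats::sd) == 0)] <- 0
  k_pc <- min(11L, n - 1L, ncol(Z))
  ev <- eigen(crossprod(Z) / n, symmetric = TRUE)
  pcs <- Z %*% ev$vectors[, seq_len(k_pc), drop = FALSE]
  pcs <- scale(pcs)
  colnames(pcs) <- paste0("PC", seq_len(k_pc))

  age <- round(stats::runif(n, 40, 80))
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  site <- factor(sample(paste0("site", 1:4), n, replace = TRUE))
  background <- factor(sample(paste0("bg", 1:3), n, replace = TRUE))
  bmi <- 28 + 0.03 * (age - 60) + stats::rnorm(n, 0, 4)
  bmi_z <- as.vector(scale(bmi))

  # transcript physiological levels
  g_std <- matrix(0, n, spec$n_transcripts)
  Tcore <- matrix(0, n, spec$n_transcripts)
  h2 <- stats::setNames(rep(0, spec$n_transcripts), tr_ids)
  h2[truth$transcript_id] <- truth$eqtl_h2
  for (t in seq_len(spec$n_transcripts)) {
    a <- arch[[t]]
    g <- as.vector(D[, a$causal, drop = FALSE] %*% a$weights)
    g_std[, t] <- if (stats::sd(g) > 0) as.vector(scale(g)) else 0
    Tcore[, t] <- sqrt(h2[t]) * g_std[, t] + sqrt(1 - h2[t]) * stats::rnorm(n)
  }
  colnames(Tcore) <- colnames(g_std) <- tr_ids

  # trait latents (higher latent = worse SDB)
  common <- stats::rnorm(n)
  Ylat <- matrix(0, n, 3, dimnames = list(NULL, traits))
  for (tr in traits) {
    rows <- truth[truth$trait_id == tr, , drop = FALSE]
    planted <- sum(rows$beta_transcript_trait^2) + sum(rows$beta_bmi_trait)^2
    if (planted > 1) {
      stop("planted variance fractions sum above 1 for trait ", tr)
    }
    eff <- rep(0, n)
    for (i in seq_len(nrow(rows))) {
      eff <- eff + rows$beta_transcript_trait[i] * Tcore[, rows$transcript_id[i]]
    }
    eff <- eff + sum(rows$beta_bmi_trait) * bmi_z
    eps <- sqrt(spec$trait_cor) * common +
      sqrt(1 - spec$trait_cor) * stats::rnorm(n)
    Ylat[, tr] <- eff + sqrt(max(1 - planted, 0)) * eps
  }
  AHI <- pmax(exp(1.6 + 0.8 * Ylat[, "AHI"]) - 3, 0)
  MinO2 <- pmin(pmax(87 - 2.5 * Ylat[, "MinO2"], 70), 100)
  AvgO2 <- pmin(pmax(96 - 1.5 * Ylat[, "AvgO2"], 70), 100)

  # measured expression latent per transcript
  Ylat_std <- scale(Ylat)
  expr_latent <- matrix(0, n, spec$n_transcripts, dimnames = list(NULL, tr_ids))
  for (t in seq_len(spec$n_transcripts)) {
    id <- tr_ids[t]
    rows <- truth[truth$transcript_id == id, , drop = FALSE]
    lat <- Tcore[, t]
    if (nrow(rows) > 0) {
      r <- rows[1L, ]
      planted <- h2[id] + r$beta_trait_transcript^2 + r$beta_bmi_transcript^2
      if (planted > 1) {
        stop("planted variance fractions sum above 1 for transcript ", id)
      }
      lat <- lat + r$beta_trait_transcript * Ylat_std[, r$trait_id] +
        r$beta_bmi_transcript * bmi_z
    }
    expr_latent[, t] <- lat
  }

  expression <- NULL
  if (length(cell_types) > 0) {
    n_all <- spec$n_transcripts + spec$n_low_transcripts
    low_ids <- if (spec$n_low_transcripts > 0) {
      sprintf("lowtr_%02d", seq_len(spec$n_low_transcripts))
    } else {
      character(0)
    }
    expression <- stats::setNames(vector("list", length(cell_types)), cell_types)
    for (ct in cell_types) {
      meas <- expr_latent + 0.4 * matrix(stats::rnorm(n * spec$n_transcripts),
                                         n, spec$n_transcripts)
      mu <- exp(log(200) + 0.7 * meas)
      counts <- matrix(stats::rnbinom(n * spec$n_transcripts,
                                      mu = as.vector(mu), size = 60),
                       n, spec$n_transcripts)
      if (spec$n_low_transcripts > 0) {
        low <- matrix(stats::rnbinom(n * spec$n_low_transcripts, mu = 0.6, size = 5),
                      n, spec$n_low_transcripts)
        counts <- cbind(counts, low)
      }
      counts <- t(counts)
      dimnames(counts) <- list(c(tr_ids, low_ids), genotypes$sample_ids)
      expression[[ct]] <- expr_matrix(counts, cell_type = ct, visit = "visit1",
                                      stage = "raw")
    }
  }

  metabolites <- NULL
  metabolite_info <- NULL
  if (with_metabolites) {
    n_unknown <- floor(spec$frac_unknown_metabolites * spec$n_metabolites)
    named <- c(rep(TRUE, spec$n_metabolites - n_unknown), rep(FALSE, n_unknown))
    logM <- matrix(stats::rnorm(spec$n_metabolites * n), spec$n_metabolites, n)
    for (i in seq_len(nrow(truth))) {
      m_id <- truth$metabolite_id[i]
      if (is.na(m_id)) next
      m <- match(m_id, met_ids)
      b <- truth$beta_transcript_metabolite[i]
      if (truth$scenario[i] == "a4_bmi_confounded") {
        # confounded path: BMI drives the metabolite, not the transcript
        b_bmi <- truth$beta_bmi_trait[i]
        logM[m, ] <- b_bmi * bmi_z + sqrt(1 - b_bmi^2) * stats::rnorm(n)
      } else if (b != 0) {
        logM[m, ] <- b * Tcore[, truth$transcript_id[i]] +
          sqrt(1 - b^2) * stats::rnorm(n)
      }
    }
    metabolites <- exp(1 + 0.8 * logM)
    dimnames(metabolites) <- list(met_ids, genotypes$sample_ids)
    if (lod_quantile > 0) {
      for (m in seq_len(nrow(metabolites))) {
        lod <- stats::quantile(metabolites[m, ], lod_quantile, type = 7)
        metabolites[m, metabolites[m, ] < lod] <- NA_real_
      }
    }
    metabolite_info <- data.frame(metabolite_id = met_ids, named = named,
                                  stringsAsFactors = FALSE)
  }

  phenotypes <- data.frame(sample_id = genotypes$sample_ids,
                           AHI = AHI, MinO2 = MinO2, AvgO2 = AvgO2,
                           BMI = bmi, age = age, sex = sex, site = site,
                           background = background,
                           stringsAsFactors = FALSE)
  phenotypes <- cbind(phenotypes, as.data.frame(pcs))
  phenotypes$sampling_weight <- kinship$sampling_weight
  phenotypes$household_id <- kinship$household_id
  phenotypes$block_unit <- kinship$block_unit
  phenotypes$stratum <- kinship$stratum

  out <- list(expression = expression, phenotypes = phenotypes,
              metabolites = metabolites, metabolite_info = metabolite_info,
              truth = truth)
  if (keep_latent) {
    attr(out, "latent") <- list(Tcore = Tcore, g_std = g_std,
                                expr_latent = expr_latent, Ylat = Ylat,
                                bmi_z = bmi_z)
  }
  out
}

#' Simulate the full three-cohort study
#'
#' Draws the discovery, validation, and target cohorts from one generative
#' model with one shared variant panel. Expression is generated for the
#' configured cell types in discovery and for whole blood in validation;
#' sleep traits and metabolites are generated in the target cohort (traits
#' are generated everywhere; each analysis uses the layers it needs).
#'
#' @param spec A `cohort_spec`.
#' @param truth A `truth_record` data frame; defaults to [default_truth()].
#' @param seed Master seed; per-cohort child seeds are derived from it.
#' @return A list with elements `discovery`, `validation`, `target` (each a
#'   list of `genotypes`, `kinship`, `omics`), plus `spec`, `truth`, and the
#'   transcript `annotation`.
#' @export
simulate_study <- function(spec = cohort_spec(), truth = default_truth(spec),
                           seed = spec$seed) {
  cohorts <- list()
  plans <- list(
    discovery = list(n = spec$n_samples[["discovery"]], prefix = "D",
                     cells = spec$celltype_labels, metab = FALSE),
    validation = list(n = spec$n_samples[["validation"]], prefix = "V",
                      cells = "WholeBlood", metab = FALSE),
    target = list(n = spec$n_samples[["target"]], prefix = "T",
                  cells = character(0), metab = TRUE)
  )
  for (nm in names(plans)) {
    pl <- plans[[nm]]
    gk <- simulate_genotypes(spec, n = pl$n,
                             seed = child_seed(seed, paste0("geno_", nm)),
                             id_prefix = pl$prefix)
    om <- simulate_omics(gk$genotypes, gk$kinship, truth, spec,
                         seed = child_seed(seed, paste0("omics_", nm)),
                         cell_types = pl$cells, with_metabolites = pl$metab)
    cohorts[[nm]] <- list(genotypes = gk$genotypes, kinship = gk$kinship,
                          omics = om)
  }
  cohorts$spec <- spec
  cohorts$truth <- truth
  cohorts$annotation <- transcript_annotation(spec,
                                              cohorts$discovery$genotypes$variants)
  class(cohorts) <- "sdb_study"
  cohorts
}
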