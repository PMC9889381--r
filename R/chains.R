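# End-to-end pipeline across the three cohorts, the association-chain
# decision rules, classification, and reporting.

#' Decision thresholds of the chain pipeline
#'
#' Defaults are the study's decision rules: discovery FDR < 0.1 carried
#' forward, validation p < 0.05/3 (strict, unrounded), tPRS-trait p < 0.05,
#' tPRS-metabolite FDR < 0.05, trait-metabolite p < 0.05. All comparisons
#' are strict.
#'
#' @param fdr_discovery,alpha_validation,m_validation,p_trait,fdr_metabolite,p_trait_metabolite
#'   Stage thresholds.
#' @return A named list of class `chain_thresholds`.
#' @export
chain_thresholds <- function(fdr_discovery = 0.1, alpha_validation = 0.05,
                             m_validation = 3, p_trait = 0.05,
                             fdr_metabolite = 0.05,
                             p_trait_metabolite = 0.05) {
  structure(list(fdr_discovery = fdr_discovery,
                 alpha_validation = alpha_validation,
                 m_validation = m_validation, p_trait = p_trait,
                 fdr_metabolite = fdr_metabolite,
                 p_trait_metabolite = p_trait_metabolite),
            class = "chain_thresholds")
}

#' Classify one association chain
#'
#' Pure rule cascade over the stage statistics of one
#' (trait, transcript, cell type, metabolite) tuple:
#' discovery must pass FDR and the tPRS must be validated for any chain;
#' a significant tPRS-trait association evidences the transcript upstream
#' of the trait; a significant tPRS-metabolite association without a
#' tPRS-trait association is a transcript-to-metabolite link; all links
#' significant form a complete chain - unless the trait-metabolite link
#' disappears after BMI adjustment, in which case the record is classified
#' `bmi_driven`. Direction concordance (sign of the tPRS-trait effect vs
#' the discovery trait-transcript estimate) is reported, never enforced.
#'
#' @param stage_stats Named list with (possibly `NA`) entries
#'   `discovery_p_fdr`, `discovery_estimate`, `validated`, `tprs_trait_p`,
#'   `tprs_trait_beta`, `tprs_metabolite_p_fdr`, `trait_metabolite_p`,
#'   `trait_metabolite_p_bmi`.
#' @param thresholds A `chain_thresholds`.
#' @return A list with `classification`, `direction_concordant`,
#'   `bmi_driven`, and `reason` (for `no_chain`).
#' @export
classify_chain <- function(stage_stats, thresholds = chain_thresholds()) {
  g <- function(nm) {
    v <- stage_stats[[nm]]
    if (is.null(v) || length(v) != 1L) NA else v
  }
  th <- thresholds
  disc <- g("discovery_p_fdr")
  validated <- g("validated")
  if (is.na(disc) || is.na(validated)) {
    return(list(classification = "no_chain", direction_concordant = NA,
                bmi_driven = FALSE, reason = "missing required stage statistic"))
  }
  tp <- g("tprs_trait_p")
  mp <- g("tprs_metabolite_p_fdr")
  tm <- g("trait_metabolite_p")
  tmb <- g("trait_metabolite_p_bmi")
  tprs_sig <- !is.na(tp) && tp < th$p_trait
  met_sig <- !is.na(mp) && mp < th$fdr_metabolite
  tm_sig <- !is.na(tm) && tm < th$p_trait_metabolite
  bmi_driven <- tm_sig && !is.na(tmb) && tmb >= th$p_trait_metabolite
  concordant <- if (!is.na(g("tprs_trait_beta")) && !is.na(g("discovery_estimate"))) {
    sign(g("tprs_trait_beta")) == sign(g("discovery_estimate"))
  } else {
    NA
  }
  if (!(disc < th$fdr_discovery)) {
    return(list(classification = "no_chain", direction_concordant = concordant,
                bmi_driven = bmi_driven, reason = "discovery FDR above threshold"))
  }
  classification <- if (!isTRUE(validated)) {
    "trait_to_transcript_only"
  } else if (tprs_sig && met_sig && tm_sig) {
    if (bmi_driven) "bmi_driven" else "complete_chain"
  } else if (!tprs_sig && met_sig) {
    "transcript_to_metabolite"
  } else if (tprs_sig) {
    "transcript_upstream_of_trait"
  } else {
    "trait_to_transcript_only"
  }
  list(classification = classification, direction_concordant = concordant,
       bmi_driven = bmi_driven, reason = NULL)
}

# Run expression QC and TWAS (with empirical p-values and per-family FDR)
# for one cell type and analysis track.
.discovery_twas <- function(expr_raw, pheno, exposures, covariates,
                            adjust_bmi, B, seed) {
  norm <- median_normalize(expr_raw)
  filt <- filter_transcripts(norm)
  logged <- log_transform(filt$expression)
  out <- list()
  for (ex in exposures) {
    a <- transcript_association(logged, pheno, ex, covariates,
                                adjust_bmi = adjust_bmi)
    a <- empirical_pvalues(a, logged, pheno, ex, covariates,
                           adjust_bmi = adjust_bmi, B = B,
                           seed = child_seed(seed, paste("perm", expr_raw$cell_type,
                                                         ex, adjust_bmi)))
    out[[ex]] <- a
  }
  assoc <- do.call(rbind, out)
  rownames(assoc) <- NULL
  list(assoc = assoc, logged = logged, report = filt$report)
}

#' Run the full association-chain pipeline
#'
#' Executes, on a (simulated or supplied) three-cohort study:
#' expression QC and TWAS with empirical p-values in the discovery cohort
#' (FDR < `fdr_discovery` carried forward), per-transcript GWAS on
#' relatedness-pruned discovery samples, clump-and-threshold tPRS
#' construction, tPRS validation in the validation cohort, target-cohort
#' variant QC and scoring, tPRS-trait mixed-model association,
#' tPRS-metabolite survey scans, trait-metabolite verification, and chain
#' classification. BMI-adjusted and unadjusted analyses run as parallel
#' tracks when `bmi_track` is `TRUE`.
#'
#' @param spec A `cohort_spec`.
#' @param truth A `truth_record` data frame.
#' @param seed Master seed; all stage seeds derive from it.
#' @param thresholds A `chain_thresholds`.
#' @param exposures SDB trait columns to test.
#' @param cell_types Discovery cell types to analyze.
#' @param covariates Discovery TWAS covariates.
#' @param n_pcs Number of genetic PCs used in the GWAS and target models.
#' @param B Number of permutations for empirical p-values.
#' @param bmi_track Also run the BMI-adjusted track?
#' @param study Optional pre-simulated study (from [simulate_study()]);
#'   when supplied, `spec`/`truth`/`seed` are taken from it for simulation
#'   but stage seeds still derive from `seed`.
#' @param out_dir Optional directory; when given, all stage tables are
#'   written as TSV plus a JSON manifest.
#' @return A list of class `chain_run`: `discovery` (assoc table),
#'   `tprs` (per-candidate validation tables), `tprs_trait`,
#'   `tprs_metabolite`, `trait_metabolite`, `chains` (chain records),
#'   `log`, and the `thresholds` used.
#' @export
run_pipeline <- function(spec = cohort_spec(), truth = default_truth(spec),
                         seed = spec$seed, thresholds = chain_thresholds(),
                         exposures = c("AHI", "MinO2", "AvgO2"),
                         cell_types = spec$celltype_labels,
                         covariates = c("age", "sex", "site", "background"),
                         n_pcs = 5, B = 100, bmi_track = TRUE,
                         study = NULL, out_dir = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.null(study)) {
    study <- simulate_study(spec, truth, seed = seed)
  } else {
    spec <- study$spec
    truth <- study$truth
  }
  tracks <- if (bmi_track) c(FALSE, TRUE) else FALSE
  disc <- study$discovery
  anno <- study$annotation

  # --- discovery TWAS ---------------------------------------------------
  assoc_list <- list()
  logged_by_ct <- list()
  for (ct in cell_types) {
    for (adj in tracks) {
      tw <- .discovery_twas(disc$omics$expression[[ct]], disc$omics$phenotypes,
                            exposures, covariates, adj, B, seed)
      assoc_list[[paste(ct, adj)]] <- tw$assoc
      if (!adj) logged_by_ct[[ct]] <- tw$logged
    }
  }
  assoc <- do.call(rbind, assoc_list)
  rownames(assoc) <- NULL
  fam <- paste(assoc$cell_type, assoc$exposure_id, assoc$bmi_adjusted)
  assoc$p_fdr <- bh_fdr(assoc$p_empirical, family = fam)
  hits <- assoc[assoc$p_fdr < thresholds$fdr_discovery, , drop = FALSE]
  note("discovery: %d transcript-trait associations at FDR < %g",
       nrow(hits), thresholds$fdr_discovery)

  # --- tPRS construction (discovery) and validation ---------------------
  pruned <- prune_related(disc$kinship)
  note("discovery GWAS sample after relatedness pruning: %d of %d",
       length(pruned), length(disc$genotypes$sample_ids))
  prune_idx <- match(pruned, disc$genotypes$sample_ids)
  geno_pruned <- structure(list(dosages = disc$genotypes$dosages[prune_idx, , drop = FALSE],
                                variants = disc$genotypes$variants,
                                sample_ids = pruned),
                           class = "genotype_data")
  gwas_pcs <- paste0("PC", seq_len(n_pcs))
  ph_d <- disc$omics$phenotypes[prune_idx, , drop = FALSE]
  Xg <- .design_matrix(ph_d, c(covariates, gwas_pcs))

  val <- study$validation
  val_norm <- median_normalize(val$omics$expression[["WholeBlood"]])
  val_logged <- log_transform(val_norm)
  ph_v <- val$omics$phenotypes
  Xv <- .design_matrix(ph_v, c(covariates, gwas_pcs))

  units <- unique(hits[, c("feature_id", "cell_type")])
  tprs_tables <- list()
  validated_models <- list()
  for (i in seq_len(nrow(units))) {
    feature <- units$feature_id[i]
    ct <- units$cell_type[i]
    logged <- logged_by_ct[[ct]]
    yi <- logged$values[feature, pruned]
    stats <- gwas_per_transcript(geno_pruned, yi, Xg)
    cands <- build_tprs(stats, geno_pruned, transcript_id = feature,
                        cell_type = ct)
    if (!(feature %in% val_logged$transcript_ids)) {
      note("validation: transcript %s not measured in whole blood; skipped", feature)
      next
    }
    yv <- val_logged$values[feature, ]
    sel <- select_validated(cands, val$genotypes, yv, Xv,
                            kinship = val$kinship,
                            alpha = thresholds$alpha_validation,
                            m_tests = thresholds$m_validation)
    key <- paste(feature, ct, sep = "|")
    tprs_tables[[key]] <- cbind(data.frame(feature_id = feature, cell_type = ct,
                                           stringsAsFactors = FALSE), sel$table)
    if (!is.null(sel$model)) validated_models[[key]] <- sel$model
  }
  note("validated tPRS: %d of %d transcript/cell-type units",
       length(validated_models), nrow(units))

  # --- target cohort ----------------------------------------------------
  tgt <- study$target
  tgt_geno <- qc_target_variants(tgt$genotypes)
  note("target variant QC: %d of %d variants retained",
       ncol(tgt_geno$dosages), ncol(tgt$genotypes$dosages))
  ph_t <- tgt$omics$phenotypes
  design <- survey_design(ph_t$sampling_weight, ph_t$block_unit, ph_t$stratum)
  tgt_cov <- c(covariates, paste0("PC", seq_len(n_pcs)))

  scores <- lapply(validated_models, function(m) {
    tryCatch(tprs_score(m, tgt_geno), error = function(e) {
      note("target scoring failed for %s: %s", m$transcript_id, conditionMessage(e))
      NULL
    })
  })

  tprs_trait <- list()
  tprs_metab <- list()
  trait_metab <- list()
  chains <- list()
  have_metab <- !is.null(tgt$omics$metabolites) &&
    nrow(tgt$omics$metabolites) > 0
  if (!have_metab) note("no metabolite data in target cohort; metabolite stages skipped")

  for (i in seq_len(nrow(hits))) {
    feature <- hits$feature_id[i]
    ct <- hits$cell_type[i]
    trait <- hits$exposure_id[i]
    adj <- hits$bmi_adjusted[i]
    key <- paste(feature, ct, sep = "|")
    model <- validated_models[[key]]
    s <- scores[[key]]
    stage <- list(discovery_p_fdr = hits$p_fdr[i],
                  discovery_estimate = hits$estimate[i],
                  validated = !is.null(model),
                  tprs_trait_p = NA_real_, tprs_trait_beta = NA_real_,
                  tprs_metabolite_p_fdr = NA_real_,
                  trait_metabolite_p = NA_real_,
                  trait_metabolite_p_bmi = NA_real_)
    met_id <- NA_character_
    if (!is.null(model) && !is.null(s)) {
      tt <- assoc_tprs_trait(s, trait, ph_t, tgt$kinship,
                             covariates = tgt_cov, adjust_bmi = adj)
      stage$tprs_trait_p <- tt$p_nominal
      stage$tprs_trait_beta <- tt$estimate
      tprs_trait[[length(tprs_trait) + 1L]] <-
        cbind(data.frame(feature_id = feature, cell_type = ct, trait_id = trait,
                         stringsAsFactors = FALSE), tt)
      if (have_metab) {
        mkey <- paste(key, adj)
        if (is.null(tprs_metab[[mkey]])) {
          scan <- tprs_metabolite_scan(s, tgt$omics$metabolites,
                                       tgt$omics$metabolite_info, ph_t, design,
                                       covariates = tgt_cov, adjust_bmi = adj)
          scan <- cbind(data.frame(feature_id = feature, cell_type = ct,
                                   bmi_adjusted = adj, stringsAsFactors = FALSE),
                        scan)
          tprs_metab[[mkey]] <- scan
        }
        scan <- tprs_metab[[mkey]]
        top <- scan[!is.na(scan$p_fdr) & scan$p_fdr < thresholds$fdr_metabolite, ,
                    drop = FALSE]
        if (nrow(top) > 0) {
          top <- top[order(top$p_fdr), , drop = FALSE]
          met_id <- top$metabolite_id[1L]
          stage$tprs_metabolite_p_fdr <- top$p_fdr[1L]
          tm <- trait_metabolite_assoc(ph_t[[trait]],
                                       tgt$omics$metabolites[met_id, ],
                                       ph_t, design, covariates = covariates,
                                       adjust_bmi = adj)
          tm_bmi <- trait_metabolite_assoc(ph_t[[trait]],
                                           tgt$omics$metabolites[met_id, ],
                                           ph_t, design, covariates = covariates,
                                           adjust_bmi = TRUE)
          stage$trait_metabolite_p <- tm$p_nominal
          stage$trait_metabolite_p_bmi <- tm_bmi$p_nominal
          trait_metab[[length(trait_metab) + 1L]] <-
            cbind(data.frame(feature_id = feature, trait_id = trait,
                             metabolite_id = met_id, bmi_adjusted = adj,
                             stringsAsFactors = FALSE), tm,
                  data.frame(p_bmi_adjusted = tm_bmi$p_nominal))
        }
      }
    }
    cls <- classify_chain(stage, thresholds)
    chains[[length(chains) + 1L]] <- data.frame(
      trait_id = trait, transcript_id = feature, cell_type = ct,
      metabolite_id = met_id, bmi_adjusted = adj,
      discovery_estimate = stage$discovery_estimate,
      discovery_p_fdr = stage$discovery_p_fdr,
      validated = stage$validated,
      tprs_trait_beta = stage$tprs_trait_beta,
      tprs_trait_p = stage$tprs_trait_p,
      tprs_metabolite_p_fdr = stage$tprs_metabolite_p_fdr,
      trait_metabolite_p = stage$trait_metabolite_p,
      trait_metabolite_p_bmi = stage$trait_metabolite_p_bmi,
      direction_concordant = cls$direction_concordant,
      bmi_driven = cls$bmi_driven,
      classification = cls$classification,
      stringsAsFactors = FALSE)
  }

  run <- structure(list(
    discovery = assoc,
    hits = hits,
    tprs = if (length(tprs_tables)) do.call(rbind, c(tprs_tables, make.row.names = FALSE)) else NULL,
    validated_models = validated_models,
    tprs_trait = if (length(tprs_trait)) do.call(rbind, c(tprs_trait, make.row.names = FALSE)) else NULL,
    tprs_metabolite = if (length(tprs_metab)) do.call(rbind, c(tprs_metab, make.row.names = FALSE)) else NULL,
    trait_metabolite = if (length(trait_metab)) do.call(rbind, c(trait_metab, make.row.names = FALSE)) else NULL,
    chains = if (length(chains)) do.call(rbind, c(chains, make.row.names = FALSE)) else NULL,
    thresholds = thresholds, seed = seed, log = log,
    truth = truth), class = "chain_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
#' @method print chain_run
print.chain_run <- function(x, ...) {
  cat("association-chain pipeline run (seed", x$seed, ")\n")
  for (l in x$log) cat(" -", l, "\n")
  if (!is.null(x$chains)) {
    cat("chain classifications:\n")
    print(table(x$chains$classification))
  }
  invisible(x)
}

#' Report tables, heatmap matrix, and chain diagram for a completed run
#'
#' Builds a top-hit table (log2-fold change, empirical and FDR p-values by
#' trait and cell type), the Spearman R-squared matrix of effect estimates
#' across analysis families, a Graphviz dot rendering of the identified
#' chains, and a machine-readable summary.
#'
#' @param run A `chain_run`.
#' @param fdr_top FDR threshold of the top-hit table.
#' @return A list with `top_table`, `r2_matrix` (or `NULL` when too few
#'   features pass), `dot`, and `summary`.
#' @export
report_run <- function(run, fdr_top = 0.05) {
  stopifnot(inherits(run, "chain_run"))
  a <- run$discovery
  top <- a[!is.na(a$p_fdr) & a$p_fdr < fdr_top,
           c("feature_id", "estimate", "p_empirical", "p_fdr", "exposure_id",
             "cell_type", "bmi_adjusted"), drop = FALSE]
  top <- top[order(top$p_empirical), , drop = FALSE]
  names(top)[names(top) == "estimate"] <- "AdjLogFC"
  rownames(top) <- NULL
  r2 <- tryCatch(suppressWarnings(
    effect_correlation_matrix(a, fdr_threshold = run$thresholds$fdr_discovery)),
    error = function(e) NULL)
  dot <- chain_dot(run$chains)
  summary <- list(
    n_discovery_hits = nrow(run$hits),
    n_validated_tprs = length(run$validated_models),
    n_reverse_associations = if (is.null(run$chains)) 0L else
      sum(!is.na(run$chains$tprs_trait_p) &
            run$chains$tprs_trait_p < run$thresholds$p_trait &
            !run$chains$bmi_adjusted),
    n_complete_chains = if (is.null(run$chains)) 0L else
      sum(run$chains$classification == "complete_chain"),
    classifications = if (is.null(run$chains)) list() else
      as.list(table(run$chains$classification)))
  list(top_table = top, r2_matrix = r2, dot = dot, summary = summary)
}

#' Graphviz dot rendering of identified chains
#'
#' @param chains Chain-record data frame from [run_pipeline()].
#' @return A character scalar with a dot-format digraph.
#' @export
chain_dot <- function(chains) {
  lines <- c("digraph chains {", "  rankdir=LR;")
  if (!is.null(chains) && nrow(chains) > 0) {
    keep <- chains$classification %in%
      c("transcript_upstream_of_trait", "transcript_to_metabolite",
        "complete_chain", "bmi_driven")
    for (i in which(keep)) {
      r <- chains[i, ]
      node_tr <- sprintf("\"%s (%s)\"", r$transcript_id, r$cell_type)
      if (r$classification %in% c("transcript_upstream_of_trait", "complete_chain")) {
        lines <- c(lines, sprintf("  %s -> \"%s\";", node_tr, r$trait_id))
      }
      if (!is.na(r$metabolite_id) &&
          r$classification %in% c("transcript_to_metabolite", "complete_chain",
                                  "bmi_driven")) {
        lines <- c(lines, sprintf("  %s -> \"%s\";", node_tr, r$metabolite_id))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
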