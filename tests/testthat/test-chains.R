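# Chain classification rules, threshold monotonicity, degraded modes, and an
# end-to-end run with a strongly planted complete chain.

stage_template <- function(...) {
  s <- list(discovery_p_fdr = 0.01, discovery_estimate = 0.1,
            validated = TRUE, tprs_trait_p = 0.01, tprs_trait_beta = 0.2,
            tprs_metabolite_p_fdr = 0.01, trait_metabolite_p = 0.01,
            trait_metabolite_p_bmi = 0.01)
  mods <- list(...)
  s[names(mods)] <- mods
  s
}

test_that("the classification cascade follows the decision rules", {
  expect_equal(classify_chain(stage_template())$classification, "complete_chain")
  # all stage p-values at 1: nothing survives
  expect_equal(classify_chain(stage_template(
    discovery_p_fdr = 1, tprs_trait_p = 1, tprs_metabolite_p_fdr = 1,
    trait_metabolite_p = 1, validated = FALSE))$classification, "no_chain")
  # discovery + validation pass, no tPRS-trait link, tPRS-metabolite hit:
  # the transcript-to-metabolite pattern
  expect_equal(classify_chain(stage_template(
    tprs_trait_p = 0.2, tprs_metabolite_p_fdr = 0.01,
    trait_metabolite_p = NA))$classification, "transcript_to_metabolite")
  # tPRS-trait link only
  expect_equal(classify_chain(stage_template(
    tprs_metabolite_p_fdr = NA, trait_metabolite_p = NA))$classification,
    "transcript_upstream_of_trait")
  # not validated: only the discovery association stands
  expect_equal(classify_chain(stage_template(validated = FALSE))$classification,
               "trait_to_transcript_only")
  # missing required stage
  out <- classify_chain(list(discovery_p_fdr = NA, validated = NA))
  expect_equal(out$classification, "no_chain")
  expect_match(out$reason, "missing")
})

test_that("a trait-metabolite link that vanishes under BMI adjustment is flagged", {
  out <- classify_chain(stage_template(trait_metabolite_p = 0.01,
                                       trait_metabolite_p_bmi = 0.4))
  expect_true(out$bmi_driven)
  expect_equal(out$classification, "bmi_driven")
})

test_that("direction concordance is reported but never excludes a record", {
  disc <- classify_chain(stage_template(discovery_estimate = -0.1,
                                        tprs_trait_beta = 0.2))
  expect_false(disc$direction_concordant)
  expect_equal(disc$classification, "complete_chain")
})

test_that("classification is a pure function and monotone in the thresholds", {
  s <- stage_template(discovery_p_fdr = 0.05, tprs_trait_p = 0.03,
                      tprs_metabolite_p_fdr = 0.04, trait_metabolite_p = 0.04)
  a <- classify_chain(s)
  b <- classify_chain(s)
  expect_identical(a, b)
  chain_classes <- c("transcript_upstream_of_trait", "transcript_to_metabolite",
                     "complete_chain", "bmi_driven")
  loose <- chain_thresholds()
  strict <- chain_thresholds(fdr_discovery = 0.04, p_trait = 0.02,
                             fdr_metabolite = 0.02, p_trait_metabolite = 0.02)
  set.seed(1)
  for (r in 1:200) {
    s <- stage_template(discovery_p_fdr = runif(1, 0, 0.15),
                        tprs_trait_p = runif(1), tprs_metabolite_p_fdr = runif(1),
                        trait_metabolite_p = runif(1),
                        validated = runif(1) < 0.8)
    in_strict <- classify_chain(s, strict)$classification %in% chain_classes
    in_loose <- classify_chain(s, loose)$classification %in% chain_classes
    if (in_strict) expect_true(in_loose)
  }
})

test_that("the pipeline completes without metabolite data, skipping those stages", {
  spec <- cohort_spec(n_samples = c(discovery = 250, validation = 300, target = 400),
                      n_variants = 60, n_blocks = 6, n_transcripts = 5,
                      n_metabolites = 5, seed = 3)
  truth <- truth_record("a3_transcript_to_trait", "tr_02", "MinO2",
                        beta_transcript_trait = 0.35, eqtl_h2 = 0.4)
  study <- simulate_study(spec, truth, seed = 3)
  study$target$omics$metabolites <- NULL
  msgs <- capture_messages(
    run <- run_pipeline(study = study, seed = 3, B = 30, bmi_track = FALSE,
                        cell_types = "PBMC", exposures = "MinO2"))
  expect_true(any(grepl("metabolite stages skipped", msgs)))
  if (!is.null(run$chains)) {
    expect_true(all(is.na(run$chains$metabolite_id)))
    expect_true(all(is.na(run$chains$tprs_metabolite_p_fdr)))
  }
  expect_null(run$tprs_metabolite)
})

test_that("a strongly planted complete chain is recovered end to end", {
  spec <- cohort_spec(n_samples = c(discovery = 500, validation = 600, target = 1200),
                      n_variants = 80, n_blocks = 8, n_transcripts = 5,
                      n_metabolites = 10, seed = 4)
  truth <- rbind(
    truth_record("complete_chain", "tr_04", "AvgO2", metabolite_id = "met_01",
                 eqtl_h2 = 0.4, beta_transcript_trait = 0.4,
                 beta_transcript_metabolite = 0.6),
    truth_record("null", "tr_05", "AHI", eqtl_h2 = 0.4))
  run <- suppressMessages(
    run_pipeline(spec, truth, seed = 4, B = 60, bmi_track = FALSE,
                 cell_types = "PBMC", exposures = "AvgO2"))
  expect_false(is.null(run$chains))
  planted <- run$chains[run$chains$transcript_id == "tr_04" &
                          run$chains$trait_id == "AvgO2", ]
  expect_gte(nrow(planted), 1)
  expect_equal(planted$classification[1], "complete_chain")
  expect_equal(planted$metabolite_id[1], "met_01")
  # reporting artifacts are internally consistent with the stage tables
  rep <- report_run(run)
  expect_equal(rep$summary$n_complete_chains,
               sum(run$chains$classification == "complete_chain"))
  expect_true(all(rep$top_table$p_fdr < 0.05))
  expect_match(rep$dot, "digraph")
  expect_match(rep$dot, "met_01")
})

test_that("run directories contain the stage tables and a valid manifest", {
  spec <- cohort_spec(n_samples = c(discovery = 250, validation = 300, target = 400),
                      n_variants = 60, n_blocks = 6, n_transcripts = 5,
                      n_metabolites = 6, seed = 5)
  truth <- truth_record("a3_transcript_to_trait", "tr_02", "MinO2",
                        beta_transcript_trait = 0.35, eqtl_h2 = 0.4)
  td <- withr::local_tempdir()
  run <- suppressMessages(
    run_pipeline(spec, truth, seed = 5, B = 30, bmi_track = FALSE,
                 cell_types = "PBMC", exposures = "MinO2", out_dir = td))
  expect_true(file.exists(file.path(td, "discovery_assoc.tsv")))
  expect_true(file.exists(file.path(td, "manifest.json")))
  man <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_equal(man$seed, 5)
  disc <- read.delim(file.path(td, "discovery_assoc.tsv"))
  expect_equal(nrow(disc), nrow(run$discovery))
})

test_that("genotype containers round-trip through VCF dosage files", {
  spec <- cohort_spec(n_variants = 20, n_blocks = 2, miss_range = c(0, 0.05),
                      seed = 6)
  g <- simulate_genotypes(spec, n = 30, seed = 6)
  td <- withr::local_tempdir()
  path <- file.path(td, "geno.vcf")
  write_vcf_dosage(g$genotypes, path)
  back <- read_vcf_dosage(path)
  expect_equal(back$sample_ids, g$genotypes$sample_ids)
  expect_equal(back$variants$variant_id, g$genotypes$variants$variant_id)
  expect_equal(unname(back$dosages), unname(g$genotypes$dosages),
               tolerance = 1e-5)
  write_dosage_tsv(g$genotypes, file.path(td, "geno.tsv"))
  tab <- read.delim(file.path(td, "geno.tsv"))
  expect_equal(nrow(tab), 20)
})
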