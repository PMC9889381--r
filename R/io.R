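# Plain-text input/output: TSV tables, VCF dosage export, and run
# directories.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a dosage matrix as TSV
#'
#' Variants as rows (first column `variant_id`), samples as columns; empty
#' cells encode missing dosages.
#'
#' @param genotypes A `genotype_data`.
#' @param path Output file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  out <- cbind(data.frame(variant_id = genotypes$variants$variant_id,
                          stringsAsFactors = FALSE),
               as.data.frame(t(genotypes$dosages)))
  .write_tsv(out, path)
}

#' Write genotypes as a VCF with DS dosage FORMAT field
#'
#' Emits a minimal VCF v4.2 with one `DS` (alternate-allele dosage) value
#' per sample; missing dosages are written as `.`.
#'
#' @param genotypes A `genotype_data`.
#' @param path Output file.
#' @export
write_vcf_dosage <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$sample_ids),
                     collapse = "\t")), con)
  D <- t(genotypes$dosages)                      # variants x samples
  for (i in seq_len(nrow(v))) {
    ds <- formatC(D[i, ], format = "g", digits = 6)
    ds[is.na(D[i, ])] <- "."
    writeLines(paste(c(v$chr[i], v$pos[i], v$variant_id[i], v$ref[i],
                       v$alt[i], ".", "PASS", ".", "DS", ds),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a DS-dosage VCF into a `genotype_data`
#'
#' Minimal reader for VCFs written by [write_vcf_dosage()] (single DS
#' FORMAT field). MAF, imputation quality and missingness metadata are
#' recomputed or set to defaults since a plain VCF does not carry them.
#'
#' @param path VCF file.
#' @return A `genotype_data`.
#' @export
read_vcf_dosage <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  stopifnot(header[1L] == "#CHROM", length(header) > 9L)
  sample_ids <- header[-(1:9)]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  p <- length(rows)
  D <- matrix(NA_real_, length(sample_ids), p)
  v <- data.frame(variant_id = character(p), chr = integer(p), pos = integer(p),
                  ref = character(p), alt = character(p),
                  stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    r <- rows[[i]]
    v$chr[i] <- as.integer(r[1L]); v$pos[i] <- as.integer(r[2L])
    v$variant_id[i] <- r[3L]; v$ref[i] <- r[4L]; v$alt[i] <- r[5L]
    ds <- r[-(1:9)]
    ds[ds == "."] <- NA
    D[, i] <- as.numeric(ds)
  }
  dimnames(D) <- list(sample_ids, v$variant_id)
  f <- .alt_freq(D)
  v$maf <- pmin(f, 1 - f)
  v$imputation_quality <- 1
  v$missingness <- colMeans(is.na(D))
  structure(list(dosages = D, variants = v, sample_ids = sample_ids),
            class = "genotype_data")
}

#' Write PGS-Catalog-style scoring file for a tPRS model
#'
#' Columns: `rsID`, `chr_name`, `chr_position`, `effect_allele`,
#' `other_allele`, `effect_weight`.
#'
#' @param model A `tprs_model`.
#' @param path Output file.
#' @export
write_tprs_weights <- function(model, path) {
  w <- model$weights
  .write_tsv(data.frame(rsID = w$variant_id, chr_name = w$chr,
                        chr_position = w$pos,
                        effect_allele = w$effect_allele,
                        other_allele = w$other_allele,
                        effect_weight = w$beta, stringsAsFactors = FALSE),
             path)
}

#' Write all stage tables of a pipeline run as TSV plus a manifest
#'
#' @param run A `chain_run`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(run$discovery, file.path(out_dir, "discovery_assoc.tsv"))
  tables <- list(tprs_validation = run$tprs, tprs_trait = run$tprs_trait,
                 tprs_metabolite = run$tprs_metabolite,
                 trait_metabolite = run$trait_metabolite,
                 chains = run$chains)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      .write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  rep <- report_run(run)
  jsonlite::write_json(list(seed = run$seed, log = run$log,
                            summary = rep$summary),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(rep$dot, file.path(out_dir, "chains.dot"))
  invisible(out_dir)
}
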