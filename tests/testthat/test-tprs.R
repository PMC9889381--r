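# Two-stage rank normalization, transcript GWAS, relatedness pruning,
# clumping against an oracle, model construction, target QC, scoring, and
# the validation selection rule.

test_that("the inverse normal transform is rank-invariant with moments near (0, 1)", {
  set.seed(1)
  n <- 1000
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  a <- two_stage_rank_normalize(y, X)
  b <- two_stage_rank_normalize(exp(y), cbind(rep(1, n)))   # monotone map of y
  expect_equal(two_stage_rank_normalize(y, cbind(rep(1, n))), b)
  expect_lt(abs(mean(a)), 0.01)
  expect_lt(abs(var(a) - 1), 0.05)
  expect_gt(cor(a, y), 0.99)
  expect_warning(two_stage_rank_normalize(c(rep(0, 8), 1, 2), cbind(rep(1, 10))),
                 "tied")
})

test_that("a planted eQTL attains the smallest p in its LD block", {
  spec <- cohort_spec(n_variants = 30, n_blocks = 3, rho = 0.5,
                      frac_sibpairs = 0, miss_range = c(0, 0), seed = 2)
  wins <- 0
  for (r in 1:40) {
    g <- simulate_genotypes(spec, n = 1000, seed = 100 + r)
    D <- g$genotypes$dosages
    causal <- 5
    gstd <- scale(D[, causal])
    y <- sqrt(0.10) * gstd + sqrt(0.90) * rnorm(1000)
    st <- gwas_per_transcript(g$genotypes, as.vector(y),
                              cbind(rep(1, 1000)), maf_min = 0.05)
    blk <- g$genotypes$variants$block[match(st$variant_id,
                                            g$genotypes$variants$variant_id)]
    in_block <- which(blk == g$genotypes$variants$block[causal])
    best <- st$variant_id[in_block[which.min(st$p[in_block])]]
    if (best == g$genotypes$variants$variant_id[causal]) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})

test_that("the GWAS is calibrated under a skewed null expression", {
  spec <- cohort_spec(n_variants = 200, n_blocks = 200, rho = 0,
                      frac_sibpairs = 0, miss_range = c(0, 0), seed = 3)
  g <- simulate_genotypes(spec, n = 800, seed = 3)
  set.seed(4)
  reject <- c()
  for (r in 1:10) {
    y <- exp(rnorm(800))   # skewed, independent of genotype
    st <- gwas_per_transcript(g$genotypes, y, cbind(rep(1, 800)))
    reject <- c(reject, st$p < 0.05)
  }
  expect_gt(mean(reject), 0.04)
  expect_lt(mean(reject), 0.06)
})

test_that("repeated visits with zero between-visit variance reduce to OLS", {
  spec <- cohort_spec(n_variants = 20, n_blocks = 2, frac_sibpairs = 0,
                      miss_range = c(0, 0), seed = 5)
  g <- simulate_genotypes(spec, n = 150, seed = 5)
  set.seed(6)
  y1 <- rnorm(150)
  # duplicate every observation: identical values per individual, so the
  # whitened GLS must equal single-visit OLS on the transformed outcome
  obs <- c(g$genotypes$sample_ids, g$genotypes$sample_ids)
  X2 <- cbind(rep(1, 300))
  st2 <- gwas_per_transcript(g$genotypes, c(y1, y1), X2, obs_sample = obs)
  yt <- two_stage_rank_normalize(c(y1, y1), X2)[1:150]
  G <- g$genotypes$dosages[, st2$variant_id, drop = FALSE]
  beta_ols <- apply(G, 2, function(gv) coef(lm.fit(cbind(1, gv), yt))[2])
  expect_equal(st2$beta, unname(beta_ols), tolerance = 1e-6)
})

test_that("relatedness pruning removes one member per sibling pair and nothing else", {
  spec <- cohort_spec(frac_sibpairs = 0.2, seed = 7)
  g <- simulate_genotypes(spec, n = 100, seed = 7)
  kept <- prune_related(g$kinship)
  sp <- g$kinship$sib_pairs
  expect_equal(length(kept), 100 - nrow(sp))
  expect_true(all(!(sp$id1 %in% kept & sp$id2 %in% kept)))
  # no relationships: identity
  K <- Matrix::Diagonal(5, 0.5)
  dimnames(K) <- list(letters[1:5], letters[1:5])
  expect_equal(prune_related(K), letters[1:5])
})

test_that("greedy pruning stays near the brute-force maximum independent set", {
  set.seed(8)
  for (r in 1:10) {
    n <- sample(10:18, 1)
    adj <- matrix(FALSE, n, n)
    edges <- which(upper.tri(adj), arr.ind = TRUE)
    pick <- edges[runif(nrow(edges)) < 0.15, , drop = FALSE]
    adj[pick] <- TRUE
    adj <- adj | t(adj)
    K <- Matrix::Matrix(ifelse(adj, 0.25, 0), sparse = TRUE)
    Matrix::diag(K) <- 0.5
    ids <- sprintf("s%02d", 1:n)
    dimnames(K) <- list(ids, ids)
    kept <- prune_related(K, threshold = 0.0884)
    ki <- match(kept, ids)
    expect_true(all(!adj[ki, ki]))
    expect_gte(length(kept), oracle_mis_size(adj) - 2)
  }
})

test_that("clumping handles perfect LD and independence correctly", {
  spec <- cohort_spec(n_variants = 6, n_blocks = 6, rho = 0,
                      frac_sibpairs = 0, miss_range = c(0, 0), seed = 9)
  g <- simulate_genotypes(spec, n = 300, seed = 9)
  geno <- g$genotypes
  # perfect LD: duplicate a column
  geno$dosages[, 2] <- geno$dosages[, 1]
  geno$variants$pos[2] <- geno$variants$pos[1] + 1000
  geno$variants$chr[2] <- geno$variants$chr[1]
  st <- data.frame(variant_id = geno$variants$variant_id,
                   chr = geno$variants$chr, pos = geno$variants$pos,
                   effect_allele = geno$variants$alt,
                   other_allele = geno$variants$ref,
                   beta = 0.1, se = 0.01,
                   p = c(1e-10, 1e-9, 0.5, 0.6, 0.7, 0.8), n = 300,
                   maf = geno$variants$maf)
  out <- clump(st, geno, p_threshold = 1e-8)
  expect_equal(out$variant_id, "v00001")
  # independence across blocks: everything below threshold survives
  out2 <- clump(st[3:6, ], geno, p_threshold = 1)
  expect_equal(sort(out2$variant_id), sprintf("v%05d", 3:6))
})

test_that("clumping matches the independent greedy oracle on random instances", {
  set.seed(10)
  for (r in 1:30) {
    nv <- sample(10:50, 1)
    nb <- sample(2:5, 1)
    spec <- cohort_spec(n_variants = nv, n_blocks = nb,
                        rho = runif(1, 0, 0.9), frac_sibpairs = 0,
                        miss_range = c(0, 0), seed = 200 + r)
    g <- simulate_genotypes(spec, n = 150, seed = 200 + r)
    st <- data.frame(variant_id = g$genotypes$variants$variant_id,
                     chr = g$genotypes$variants$chr,
                     pos = g$genotypes$variants$pos,
                     effect_allele = g$genotypes$variants$alt,
                     other_allele = g$genotypes$variants$ref,
                     beta = rnorm(nv), se = 0.1, p = runif(nv), n = 150,
                     maf = g$genotypes$variants$maf)
    thr <- runif(1, 0.3, 1)
    ours <- clump(st, g$genotypes, p_threshold = thr)
    orc <- oracle_clump(st, g$genotypes$dosages, p_threshold = thr)
    expect_equal(sort(ours$variant_id), orc)
    # row-order invariance
    perm <- st[sample(nv), ]
    ours2 <- clump(perm, g$genotypes, p_threshold = thr)
    expect_equal(ours$variant_id, ours2$variant_id)
  }
})

test_that("candidate models nest across thresholds and respect cis restriction", {
  spec <- cohort_spec(n_variants = 40, n_blocks = 4, frac_sibpairs = 0,
                      miss_range = c(0, 0), seed = 11)
  g <- simulate_genotypes(spec, n = 1200, seed = 11)
  D <- g$genotypes$dosages
  y <- sqrt(0.3) * as.vector(scale(D %*% ifelse(seq_len(40) %in% c(5, 35), 1, 0))) +
    sqrt(0.7) * rnorm(1200)
  st <- gwas_per_transcript(g$genotypes, y, cbind(rep(1, 1200)))
  cands <- build_tprs(st, g$genotypes, transcript_id = "tr_x")
  ids <- lapply(cands, function(m) m$weights$variant_id)
  expect_true(all(ids[[1]] %in% ids[[2]]))
  expect_true(all(ids[[2]] %in% ids[[3]]))
  # no variant below genome-wide significance: empty candidate
  st_null <- st
  st_null$p <- pmax(st_null$p, 1e-6)
  c_null <- build_tprs(st_null, g$genotypes)
  expect_true(c_null[[1]]$empty)
  # cis restriction to the block of variant 5 excludes the trans signal
  v5 <- g$genotypes$variants[5, ]
  c_cis <- build_tprs(st, g$genotypes, cis_only = TRUE, gene_chr = v5$chr,
                      gene_start = v5$pos, gene_end = v5$pos,
                      cis_window = 1e6)
  genome_wide <- cands[[3]]$weights$variant_id
  cis_ids <- c_cis[[3]]$weights$variant_id
  expect_true(length(cis_ids) < length(genome_wide) || c_cis[[3]]$empty)
  expect_error(build_tprs(st, g$genotypes, cis_only = TRUE), "span")
})

test_that("target variant QC applies the three rules from a hand-built table", {
  dos <- matrix(1, 4, 6, dimnames = list(paste0("s", 1:4), paste0("v", 1:6)))
  variants <- data.frame(variant_id = paste0("v", 1:6), chr = 1,
                         pos = 1:6 * 1000, ref = "A", alt = "G",
                         maf = c(0.3, 0.3, 0.04, 0.3, 0.3, 0.2),
                         imputation_quality = c(0.95, 0.79, 0.9, 0.9, 0.99, 0.85),
                         missingness = c(0, 0, 0, 0.02, 0.005, 0.01))
  geno <- structure(list(dosages = dos, variants = variants,
                         sample_ids = paste0("s", 1:4)),
                    class = "genotype_data")
  out <- qc_target_variants(geno)
  expect_equal(out$variants$variant_id, c("v1", "v5", "v6"))
})

test_that("scoring respects allele orientation, missingness, and standardization", {
  dos <- rbind(c(0, 2, 1, 0, 2),
               c(1, 1, 2, 0, 0),
               c(2, 0, 0, 1, 1),
               c(1, 2, 1, 2, NA))
  dimnames(dos) <- list(paste0("s", 1:4), paste0("v", 1:5))
  variants <- data.frame(variant_id = paste0("v", 1:5), chr = 1,
                         pos = 1:5 * 1000, ref = c("A", "A", "C", "G", "T"),
                         alt = c("G", "C", "T", "A", "C"),
                         maf = 0.3, imputation_quality = 1, missingness = 0)
  geno <- structure(list(dosages = dos, variants = variants,
                         sample_ids = paste0("s", 1:4)),
                    class = "genotype_data")
  w <- data.frame(variant_id = paste0("v", 1:5),
                  chr = 1, pos = 1:5 * 1000,
                  effect_allele = c("G", "C", "T", "A", "C"),
                  other_allele = c("A", "A", "C", "G", "T"),
                  beta = c(0.5, -0.2, 0.1, 0.3, 0.4), p = 1e-9)
  model <- sdbchains:::.tprs_model("tr", "PBMC", 5e-8, w, 0.1, 250, FALSE, 1e6)
  s <- tprs_score(model, geno)
  D <- dos
  D[4, 5] <- mean(dos[1:3, 5])   # mean imputation
  raw <- as.vector(D %*% w$beta)
  expect_equal(unname(as.vector(s)), as.vector(scale(raw)), tolerance = 1e-12)
  expect_equal(unname(attr(s, "standardization")["mean"]), mean(raw))
  # single-variant model: standardized dosage of that variant
  w1 <- w[1, ]; w1$beta <- 1
  m1 <- sdbchains:::.tprs_model("tr", "PBMC", 5e-8, w1, 0.1, 250, FALSE, 1e6)
  s1 <- tprs_score(m1, geno)
  expect_equal(unname(as.vector(s1)), as.vector(scale(dos[, 1])))
  # flipping alleles and negating the weight leaves the score unchanged
  wf <- w
  wf$effect_allele <- w$other_allele
  wf$other_allele <- w$effect_allele
  wf$beta <- -w$beta
  mf <- sdbchains:::.tprs_model("tr", "PBMC", 5e-8, wf, 0.1, 250, FALSE, 1e6)
  sf <- tprs_score(mf, geno)
  expect_equal(as.vector(sf), as.vector(s), tolerance = 1e-12)
  # mismatching alleles are dropped with a warning; none left is an error
  wbad <- w
  wbad$effect_allele <- "T"; wbad$other_allele <- "T"
  mbad <- sdbchains:::.tprs_model("tr", "PBMC", 5e-8, wbad, 0.1, 250, FALSE, 1e6)
  expect_warning(expect_error(tprs_score(mbad, geno), "no overlapping"),
                 "neither orientation")
})

test_that("the selection rule validates only below the unrounded Bonferroni bound", {
  expect_equal(sdbchains:::.select_rule(c(0.5, 0.02, 0.001))$selected, 3L)
  expect_true(sdbchains:::.select_rule(c(0.5, 0.02, 0.001))$validated)
  expect_false(sdbchains:::.select_rule(c(0.5, 0.02, 0.02))$validated)
  expect_true(sdbchains:::.select_rule(c(0.0166, 1, 1))$validated)
  expect_false(sdbchains:::.select_rule(c(0.0167, 1, 1))$validated)
})

test_that("planted eQTL instruments validate; broken instruments do not", {
  spec <- cohort_spec(n_variants = 40, n_blocks = 4, frac_sibpairs = 0.1,
                      miss_range = c(0, 0), seed = 12)
  validated <- 0
  broken_validated <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    gd <- simulate_genotypes(spec, n = 600, seed = 300 + r, id_prefix = "D")
    gv <- simulate_genotypes(spec, n = 1200, seed = 400 + r, id_prefix = "V")
    causal <- c(5, 8)
    make_y <- function(D, h2) {
      gval <- as.vector(scale(D %*% ifelse(seq_len(40) %in% causal, c(1, -0.8), 0)))
      sqrt(h2) * gval + sqrt(1 - h2) * rnorm(nrow(D))
    }
    yd <- make_y(gd$genotypes$dosages, 0.3)
    st <- gwas_per_transcript(gd$genotypes, yd, cbind(rep(1, 600)))
    cands <- build_tprs(st, gd$genotypes, transcript_id = "tr_x")
    yv <- make_y(gv$genotypes$dosages, 0.3)
    sel <- select_validated(cands, gv$genotypes, yv, cbind(rep(1, 1200)),
                            kinship = gv$kinship)
    if (!is.null(sel$model)) validated <- validated + 1
    # broken instrument: validation expression independent of genotype
    sel0 <- select_validated(cands, gv$genotypes, rnorm(1200),
                             cbind(rep(1, 1200)), kinship = gv$kinship)
    if (!is.null(sel0$model)) broken_validated <- broken_validated + 1
  }
  expect_gte(validated / reps, 0.8)
  expect_lte(broken_validated / reps, 0.25)   # ~alpha = 0.0167 per candidate
})

test_that("a validated instrument keeps its sign in a fresh cohort", {
  spec <- cohort_spec(n_variants = 40, n_blocks = 4, frac_sibpairs = 0,
                      miss_range = c(0, 0), seed = 13)
  concord <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    gd <- simulate_genotypes(spec, n = 600, seed = 500 + r, id_prefix = "D")
    gt <- simulate_genotypes(spec, n = 1500, seed = 600 + r, id_prefix = "T")
    causal <- c(5, 8)
    make_core <- function(D) {
      as.vector(scale(D %*% ifelse(seq_len(40) %in% causal, c(1, -0.8), 0)))
    }
    yd <- sqrt(0.3) * make_core(gd$genotypes$dosages) + sqrt(0.7) * rnorm(600)
    st <- gwas_per_transcript(gd$genotypes, yd, cbind(rep(1, 600)))
    cands <- build_tprs(st, gd$genotypes, transcript_id = "tr_x")
    nonempty <- which(!vapply(cands, `[[`, logical(1), "empty"))
    if (length(nonempty) == 0) next
    s <- tprs_score(cands[[max(nonempty)]], gt$genotypes)
    ytrue <- sqrt(0.3) * make_core(gt$genotypes$dosages) + sqrt(0.7) * rnorm(1500)
    if (cor(as.vector(s), ytrue) > 0) concord <- concord + 1
  }
  expect_gte(concord / reps, 0.9)
})
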