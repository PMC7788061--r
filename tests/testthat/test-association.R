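# Single-variant tests, FDR, set/gene level aggregation, elimination, meta.

test_that("allelic fallback odds ratio matches the hand-computed 2x2 value", {
  # allele counts: cases 3 minor / 17 major, controls 2 / 18 -- the same
  # 1.588 odds ratio as 30/170 vs 20/180, at a size where an expected
  # cell drops below 5 and the allelic fallback engages
  status <- rep(c("case", "control"), each = 10)
  d <- c(rep(1, 3), rep(0, 7), rep(1, 2), rep(0, 8))
  D <- cbind(v1 = d)
  rownames(D) <- sprintf("s%03d", seq_along(d))
  clinical <- data.frame(sample_id = rownames(D), status = status)
  res <- single_variant_assoc(genotype_matrix(D), clinical)
  expect_equal(res$method, "allelic")
  expect_equal(exp(res$effect), (3 * 18) / (17 * 2), tolerance = 1e-10)
  expect_equal(round(exp(res$effect), 3), 1.588)
  # and the large-sample version of the same table uses the logistic fit
  status2 <- rep(c("case", "control"), each = 100)
  d2 <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
  D2 <- cbind(v1 = d2)
  rownames(D2) <- sprintf("t%03d", seq_along(d2))
  res2 <- single_variant_assoc(genotype_matrix(D2),
                               data.frame(sample_id = rownames(D2),
                                          status = status2))
  expect_equal(res2$method, "logistic")
})

test_that("equal case and control frequencies give OR 1; monomorphic variants are skipped", {
  status <- rep(c("case", "control"), each = 60)
  d_eq <- rep(c(rep(1, 24), rep(0, 36)), 2)
  D <- cbind(v_eq = d_eq, v_mono = 0)
  rownames(D) <- sprintf("s%03d", 1:120)
  clinical <- data.frame(sample_id = rownames(D), status = status)
  res <- single_variant_assoc(genotype_matrix(D), clinical)
  expect_equal(res$effect[res$unit_id == "v_eq"], 0, tolerance = 1e-8)
  mono <- res[res$unit_id == "v_mono", ]
  expect_true(is.na(mono$p_value))
  expect_equal(mono$note, "monomorphic")
})

test_that("BH adjustment matches hand computation and a brute-force step-up oracle", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  # brute-force step-up: q_i = min over j with p_j >= p_i of p_j * m / rank_j
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    sorted <- p[o] * m / seq_len(m)
    q[o] <- rev(cummin(rev(sorted)))
    pmin(q, 1)
  }
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("set-level testing filters strata, counts units and applies BH across sets", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_genes = 10,
                    n_pathways = 5, variants_per_gene = 8, seed = 17)
  coh <- simulate_cohort(cfg)
  gsc <- gene_set_collection(list(
    A = coh$genesets$sets$P1,
    B = coh$genesets$sets$P2,
    empty_genes = c("NOPE1", "NOPE2")))
  res <- set_assoc(coh$genotypes, coh$variants, gsc, coh$clinical,
                   config = set_test_config(moment_correction = FALSE))
  expect_equal(res$genes_in_test[res$unit_id == "empty_genes"], 0L)
  expect_equal(res$note[res$unit_id == "empty_genes"], "genes in test = 0")
  tested <- !is.na(res$p_value)
  expect_equal(res$fdr_q[tested], bh_fdr(res$p_value[tested]))
  # a rare-only stratum on common-only variants is skipped with a reason
  common_ids <- coh$variants$variant_id[coh$variants$maf > 0.05]
  vsub <- coh$variants[coh$variants$variant_id %in% common_ids, ]
  gsub <- subset_genotypes(coh$genotypes, variants = common_ids)
  res_rare <- set_assoc(gsub, vsub, gsc, coh$clinical,
                        config = set_test_config(maf_stratum = "rare"))
  expect_true(all(is.na(res_rare$p_value)))
  expect_true(all(grepl("no rare variants|genes in test",
                        res_rare$note)))
})

test_that("one-variant gene reduces to the single-variant score test; duplicate genes error", {
  fx <- make_cc_fixture(23, n = 250, m = 3)
  variants <- data.frame(variant_id = fx$gm$variant_ids, chrom = "1",
                         pos = c(100L, 200L, 300L), ref = "A", alt = "T",
                         maf = fx$maf, gene_id = c("G1", "G2", "G2"))
  res <- gene_assoc(fx$gm, variants, fx$clinical,
                    config = set_test_config(moment_correction = FALSE))
  one <- skat_o_test(subset_genotypes(fx$gm, variants = "v1"),
                     fx$clinical,
                     config = set_test_config(moment_correction = FALSE))
  expect_equal(res$p_value[res$unit_id == "G1"], one$p_value,
               tolerance = 1e-10)
  expect_error(gene_assoc(fx$gm, variants, fx$clinical,
                          genes = c("G1", "G1")), "duplicate gene ids")
})

test_that("no significant pathway at round one yields an empty elimination list", {
  cfg <- sim_config(n_cases = 120, n_controls = 120, n_genes = 8,
                    n_pathways = 4, variants_per_gene = 6, seed = 29)
  coh <- simulate_cohort(cfg)
  out <- sequential_elimination(coh$genotypes, coh$variants, coh$genesets,
                                coh$clinical, fdr_threshold = 1e-6)
  expect_equal(nrow(out), 0)
})

test_that("fully overlapping causal genes leave only one pathway after elimination", {
  # plant all effects in shared genes; P_a and P_b both contain them plus
  # private null fillers, so eliminating the first strips the second
  gids <- sprintf("G%04d", 1:30)
  gmap <- list(SHARED = gids[1:6],
               P_a = c(gids[1:6], gids[7:16]),
               P_b = c(gids[1:6], gids[17:26]))
  cfg <- sim_config(n_cases = 600, n_controls = 600, n_genes = 30,
                    genes_per_pathway = gmap, variants_per_gene = 10,
                    causal_pathways = list(causal_pathway("SHARED", 0.4,
                                                          0.4)),
                    disease_model = "logistic",
                    prevalence_or_intercept = -0.5, seed = 31)
  coh <- simulate_cohort(cfg)
  gsc <- gene_set_collection(gmap[c("P_a", "P_b")])
  out <- sequential_elimination(coh$genotypes, coh$variants, gsc,
                                coh$clinical,
                                config = set_test_config(
                                  weight_scheme = "flat"))
  expect_equal(nrow(out), 1)
  expect_true(out$pathway_id %in% c("P_a", "P_b"))
})

test_that("fixed-effect meta-analysis matches the closed form", {
  one <- fixed_effect_meta(0.4, 0.1)
  expect_equal(one$beta, 0.4, tolerance = 1e-10)
  expect_equal(one$se, 0.1, tolerance = 1e-10)
  two <- fixed_effect_meta(c(0.3, 0.3), c(0.2, 0.2))
  expect_equal(two$beta, 0.3, tolerance = 1e-10)
  expect_equal(two$se, 0.2 / sqrt(2), tolerance = 1e-10)
  # hand inverse-variance computation: (w1 b1 + w2 b2)/(w1 + w2)
  mix <- fixed_effect_meta(c(log(2), 0), c(0.2, 0.4))
  w <- 1 / c(0.2, 0.4)^2
  expect_equal(mix$beta, sum(w * c(log(2), 0)) / sum(w), tolerance = 1e-9)
  expect_equal(round(mix$beta, 4), 0.5545)
  expect_equal(mix$p_value,
               2 * pnorm(-abs(mix$beta / mix$se)), tolerance = 1e-8)
  expect_error(fixed_effect_meta(c(1, 2), c(0.1, 0)), "positive")
})

test_that("null aggregate p-values are roughly uniform across replicate sets", {
  set.seed(71)
  ps <- replicate(60, {
    fx <- make_cc_fixture(sample.int(1e6, 1), n = 150, m = 8,
                          maf_lo = 0.1, maf_hi = 0.45)
    skat_o_test(fx$gm, fx$clinical,
                config = set_test_config(moment_correction = FALSE))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
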