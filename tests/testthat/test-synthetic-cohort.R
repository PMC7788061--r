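# Synthetic case-control cohort generator.

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_cases = 40, n_controls = 50, n_genes = 8,
                    variants_per_gene = 6, caseonly_injection = 2,
                    seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$genotypes$missing, b$genotypes$missing)
  expect_identical(a$variants, b$variants)
  expect_identical(a$clinical, b$clinical)
})

test_that("fixed MAF is recovered within binomial sampling error", {
  # 1000 individuals = 2000 haplotype draws per variant at target MAF 0.3
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_genes = 5,
                    variants_per_gene = 4,
                    maf_spectrum = list(shape1 = 1, shape2 = 1,
                                        max = 0.3, min = 0.2999),
                    missing_rate = 0, seed = 3)
  sim <- simulate_genotypes(cfg)
  emp <- dosage_maf(sim$genotypes)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_true(all(abs(emp - 0.3) < 3.5 * se))
  # and over replicate draws the mean empirical MAF is centred on target
  reps <- sapply(1:30, function(s) {
    cfg$seed <- 100 + s
    mean(dosage_maf(simulate_genotypes(cfg)$genotypes))
  })
  expect_lt(abs(mean(reps) - 0.3), 3 * se / sqrt(30))
})

test_that("independent variants have near-zero pairwise correlation, LD blocks do not", {
  base <- list(n_cases = 400, n_controls = 400, n_genes = 4,
               variants_per_gene = 6,
               maf_spectrum = list(shape1 = 1, shape2 = 1, max = 0.4,
                                   min = 0.2),
               missing_rate = 0, seed = 5)
  cfg0 <- do.call(sim_config, c(base, list(ld_block_size = 1, ld_r2 = 0)))
  g0 <- simulate_genotypes(cfg0)$genotypes
  r2 <- cor(g0$dosage)^2
  expect_lt(max(r2[upper.tri(r2)]), 0.02)
  cfg1 <- do.call(sim_config, c(base, list(ld_block_size = 3, ld_r2 = 0.5)))
  g1 <- simulate_genotypes(cfg1)$genotypes
  # adjacent within-block pairs approach the target r2
  blocks <- split(seq_len(24), rep(1:8, each = 3))
  r2b <- unlist(lapply(blocks, function(ix) {
    cc <- cor(g1$dosage[, ix])^2
    cc[upper.tri(cc)]
  }))
  expect_gt(mean(r2b), 0.3)
  expect_lt(mean(r2b), 0.7)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(ld_r2 = 1.5), "ld_r2")
  expect_error(sim_config(n_cases = 0), "positive")
  expect_error(sim_config(n_genes = 3,
                          genes_per_pathway = list(P1 = c("G0001", "G9999"))),
               "undefined genes")
  expect_error(sim_config(causal_pathways =
                            list(causal_pathway("P9", 0.3, 0.2))),
               "causal pathway not defined")
})

test_that("null model yields status independent of genotype with ORs centred on 1", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_genes = 6,
                    variants_per_gene = 8,
                    maf_spectrum = list(shape1 = 1, shape2 = 1, max = 0.4,
                                        min = 0.1),
                    seed = 21)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$betas == 0))
  sv <- single_variant_assoc(coh$genotypes, coh$clinical)
  ok <- !is.na(sv$effect)
  expect_gt(sum(ok), 40)
  # mean ln-OR near 0 and p-values not enriched for significance
  expect_lt(abs(mean(sv$effect[ok])), 0.05)
  expect_gt(suppressWarnings(ks.test(sv$p_value[ok], "punif"))$p.value,
            0.01)
})

test_that("zero clinical coefficients break the damage-burden link", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_genes = 10,
                    variants_per_gene = 6,
                    causal_pathways = list(causal_pathway("P1", 0.4, 0.5)),
                    clinical_model = list(damage_intercept = 0,
                                          damage_slope = 0,
                                          ab_intercept = -0.6,
                                          ab_slope = 0),
                    seed = 33)
  coh <- simulate_cohort(cfg)
  expect_gt(cor(coh$clinical$true_liability,
                as.vector(coh$genotypes$dosage %*% coh$betas)), 0.99)
  expect_gt(cor.test(coh$clinical$damage_index,
                     coh$clinical$true_liability)$p.value, 0.001)
})

test_that("planted ln-OR at a common SNV is recovered by the logistic fit", {
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_genes = 4,
                    n_pathways = 2, variants_per_gene = 1,
                    maf_spectrum = list(shape1 = 5, shape2 = 12, max = 0.5,
                                        min = 0.05),
                    causal_pathways = list(causal_pathway("P1",
                                                          logor = log(1.5),
                                                          fraction = 0.25)),
                    disease_model = "logistic",
                    prevalence_or_intercept = 0, seed = 44)
  coh <- simulate_cohort(cfg)
  causal <- names(coh$betas)[coh$betas != 0]
  expect_length(causal, 1)
  sv <- single_variant_assoc(coh$genotypes, coh$clinical)
  row <- sv[sv$unit_id == causal, ]
  expect_lt(abs(row$effect - log(1.5)), 3 * row$se)
})

test_that("injected case-only variants carry alleles in cases only", {
  cfg <- sim_config(n_cases = 50, n_controls = 60, n_genes = 6,
                    variants_per_gene = 5, caseonly_injection = 4,
                    seed = 8)
  coh <- simulate_cohort(cfg)
  inj <- grep("^CO", coh$variants$variant_id, value = TRUE)
  expect_length(inj, 4)
  ctrl <- coh$clinical$sample_id[coh$clinical$status == "control"]
  expect_true(all(coh$genotypes$dosage[ctrl, inj] == 0))
  expect_true(all(colSums(coh$genotypes$dosage[, inj]) >= 1))
  expect_false(any(coh$variants$panel_swegen[
    coh$variants$variant_id %in% inj]))
})
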