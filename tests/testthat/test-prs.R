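# Pathway polygenic risk scores: pruning, weights, scoring, positivity.

test_that("LD pruning keeps independent variants and drops duplicated columns", {
  set.seed(12)
  n <- 120
  ind <- sapply(runif(4, 0.2, 0.4), function(f) rbinom(n, 2, f))
  D <- cbind(ind, dup = ind[, 1])
  colnames(D) <- c(paste0("v", 1:4), "v_dup")
  rownames(D) <- sprintf("s%03d", 1:n)
  gm <- genotype_matrix(D)
  variants <- data.frame(variant_id = colnames(D), chrom = "1",
                         pos = c(100L, 200L, 300L, 400L, 150L),
                         ref = "A", alt = "T", maf = 0.3)
  # duplicated column has the larger p, so the original is retained
  p <- c(v1 = 0.001, v2 = 0.2, v3 = 0.3, v4 = 0.4, v_dup = 0.01)
  kept <- ld_prune(gm, variants, p)
  expect_true("v1" %in% kept)
  expect_false("v_dup" %in% kept)
  # independent variants (empirical r2 below threshold) all retained
  expect_true(all(paste0("v", 1:4) %in% kept))
})

test_that("greedy pruning matches a brute-force oracle on random fixtures", {
  brute <- function(D, variants, p, r2 = 0.2, win = 500000) {
    ord <- order(p)
    kept <- integer(0)
    for (j in ord) {
      ok <- TRUE
      for (k in kept) {
        if (variants$chrom[k] != variants$chrom[j]) next
        if (abs(variants$pos[k] - variants$pos[j]) > win) next
        r <- suppressWarnings(cor(D[, j], D[, k]))
        if (!is.na(r) && r^2 >= r2) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, j)
    }
    sort(colnames(D)[kept])
  }
  for (s in 1:5) {
    set.seed(s)
    n <- 80
    base <- rbinom(n, 2, 0.3)
    D <- sapply(1:10, function(i)
      if (i %% 3 == 0) pmin(2, pmax(0, base + rbinom(n, 1, 0.15) -
                                      rbinom(n, 1, 0.15)))
      else rbinom(n, 2, runif(1, 0.1, 0.4)))
    colnames(D) <- sprintf("v%02d", 1:10)
    rownames(D) <- sprintf("s%03d", 1:n)
    variants <- data.frame(variant_id = colnames(D),
                           chrom = rep(c("1", "2"), each = 5),
                           pos = rep(seq(1e5, 5e5, 1e5), 2),
                           ref = "A", alt = "T", maf = 0.3)
    p <- setNames(runif(10), colnames(D))
    gm <- genotype_matrix(D)
    expect_equal(sort(ld_prune(gm, variants, p)),
                 brute(D, variants, p))
  }
})

test_that("weight construction: threshold, signed protective weights, pathway fan-out", {
  assoc <- data.frame(unit_id = c("v1", "v2", "v3", "v4"),
                      level = "variant",
                      effect = c(log(2), log(0.5), log(1.8), log(3)),
                      se = 0.1,
                      p_value = c(0.01, 0.02, 0.2, 0.04),
                      stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                         gene_id = c("GA", "GA", "GB", NA))
  gsc <- gene_set_collection(list(P1 = c("GA", "GB"), P2 = "GA"))
  w <- build_prs_weights(assoc, pruned_ids = c("v1", "v2", "v3", "v4"),
                         gsc, variants)
  # v1: ln 2 in both pathways containing gene GA
  expect_equal(sort(w$pathway_id[w$variant_id == "v1"]), c("P1", "P2"))
  expect_equal(unique(w$weight[w$variant_id == "v1"]), log(2),
               tolerance = 1e-12)
  expect_equal(round(unique(w$weight[w$variant_id == "v1"]), 4), 0.6931)
  # protective minor allele keeps its signed weight
  expect_equal(unique(w$weight[w$variant_id == "v2"]), log(0.5),
               tolerance = 1e-12)
  # p above alpha excluded; unmapped variant counted
  expect_false("v3" %in% w$variant_id)
  expect_false("v4" %in% w$variant_id)
  expect_equal(attr(w, "n_unmapped"), 1L)
  # risk orientation flips protective variants positive
  wr <- build_prs_weights(assoc, c("v1", "v2"), gsc, variants,
                          orientation = "risk")
  expect_true(all(wr$weight > 0))
  expect_true(all(wr$flip[wr$variant_id == "v2"]))
})

test_that("scores follow the weighted minor-allele sum exactly", {
  D <- rbind(zero = c(0, 0), hom = c(2, 0), mix = c(1, 2))
  colnames(D) <- c("v1", "v2")
  gm <- genotype_matrix(D)
  w <- data.frame(variant_id = c("v1", "v2"), pathway_id = "P1",
                  weight = c(log(2), log(1.5)), p_value = 0.01,
                  flip = FALSE)
  prs <- suppressWarnings(compute_pathway_prs(gm, w,
                                              warn_in_sample = FALSE))
  expect_equal(unname(prs$scores["zero", "P1"]), 0)
  expect_equal(unname(prs$scores["hom", "P1"]), 2 * log(2))
  expect_equal(round(2 * log(2), 4), 1.3863)
  expect_equal(unname(prs$scores["mix", "P1"]),
               1 * log(2) + 2 * log(1.5))
  expect_equal(round(1 * log(2) + 2 * log(1.5), 4), 1.5041)
  # missing dosage imputes to the cohort mean dosage of the variant
  miss <- matrix(c(FALSE, FALSE, TRUE, rep(FALSE, 3)), nrow = 3,
                 dimnames = dimnames(D))
  gm2 <- genotype_matrix(D, miss)
  prs2 <- suppressWarnings(compute_pathway_prs(gm2, w,
                                               warn_in_sample = FALSE))
  expect_equal(unname(prs2$scores["mix", "P1"]),
               1 * log(2) + 2 * log(1.5))
  expect_equal(unname(prs2$scores["zero", "P1"]), 0 * log(2))
})

test_that("positivity: interpolated percentile, strict inequality, tie at threshold", {
  set.seed(5)
  ctrl_scores <- sort(rnorm(40))
  scores <- matrix(c(ctrl_scores, 1.5, max(ctrl_scores)), ncol = 1,
                   dimnames = list(c(sprintf("c%02d", 1:40), "caseA",
                                     "caseB"), "P1"))
  prs <- structure(list(scores = scores, weights = NULL,
                        empty_pathways = character(0)),
                   class = "pathway_prs")
  clinical <- data.frame(sample_id = rownames(scores),
                         status = c(rep("control", 40), "case", "case"))
  out <- classify_positivity(prs, clinical)
  # interpolated 97.5th percentile of 40 distinct values lies between the
  # 39th and 40th order statistics: exactly one control is positive
  expect_equal(sum(out$positive[1:40, 1]), 1)
  # a case sitting exactly at the threshold value is not positive
  thr <- out$control_threshold["P1"]
  scores2 <- scores; scores2["caseA", 1] <- thr
  prs2 <- structure(list(scores = scores2, weights = NULL,
                         empty_pathways = character(0)),
                    class = "pathway_prs")
  out2 <- classify_positivity(prs2, clinical)
  expect_false(out2$positive["caseA", 1])
  expect_equal(out$n_positive_pathways, rowSums(out$positive))
  # fewer than 20 controls is an error
  expect_error(classify_positivity(prs, clinical[c(1:10, 41:42), ]),
               "20 control")
})

test_that("scores are linear in the weights and positivity is scale-invariant", {
  fx <- make_cc_fixture(9, n = 100, m = 6)
  variants <- data.frame(variant_id = fx$gm$variant_ids,
                         gene_id = rep(c("GA", "GB"), 3))
  gsc <- gene_set_collection(list(P1 = "GA", P2 = "GB"))
  w <- data.frame(variant_id = fx$gm$variant_ids,
                  pathway_id = rep(c("P1", "P2"), 3),
                  weight = rnorm(6), p_value = 0.01, flip = FALSE)
  prs1 <- suppressWarnings(compute_pathway_prs(fx$gm, w,
                                               warn_in_sample = FALSE))
  w2 <- w; w2$weight <- 3 * w$weight
  prs2 <- suppressWarnings(compute_pathway_prs(fx$gm, w2,
                                               warn_in_sample = FALSE))
  expect_equal(prs2$scores, 3 * prs1$scores, tolerance = 1e-12)
  p1 <- classify_positivity(prs1, fx$clinical)
  p2 <- classify_positivity(prs2, fx$clinical)
  expect_identical(p1$positive, p2$positive)
})
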