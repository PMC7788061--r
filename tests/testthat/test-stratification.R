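# Normalisation, hierarchical clustering and clinical group comparisons.

test_that("control standardisation is the identity on standard controls and matches hand z-scores", {
  set.seed(4)
  ctrl <- matrix(rnorm(4000), 2000, 2)
  ctrl <- scale(ctrl)          # exactly mean 0, sd 1 in controls
  cases <- matrix(c(1, 2, 3, 4), 2, 2)
  scores <- rbind(ctrl, cases)
  rownames(scores) <- sprintf("S%04d", seq_len(nrow(scores)))
  colnames(scores) <- c("P1", "P2")
  clinical <- data.frame(sample_id = rownames(scores),
                         status = rep(c("control", "case"), c(2000, 2)))
  nz <- normalize_prs(scores, clinical)
  expect_equal(nz[1:2000, ], ctrl[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # hand 3 x 2 example
  s <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
              dimnames = list(c("a", "b", "c"), c("P1", "P2")))
  cl <- data.frame(sample_id = c("a", "b", "c"),
                   status = c("control", "control", "case"))
  nz2 <- normalize_prs(s, cl)
  mu <- c(1.5, 15); sd <- c(sd(c(1, 2)), sd(c(10, 20)))
  expect_equal(unname(nz2), sweep(sweep(unname(s), 2, mu), 2, sd, `/`),
               tolerance = 1e-12)
  # constant pathway column dropped with a warning
  s3 <- cbind(s, P3 = 1)
  expect_warning(nz3 <- normalize_prs(s3, cl), "zero-variance")
  expect_equal(colnames(nz3), c("P1", "P2"))
  s_const <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "P1"))
  expect_error(normalize_prs(s_const, cl), "zero control variance")
})

test_that("clustering: k = 1 collapses, k > n errors, labels ordered by size", {
  set.seed(6)
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("s%02d", 1:10), NULL))
  expect_equal(unique(cluster_patients(x, k = 1)$cluster), 1L)
  expect_error(cluster_patients(x, k = 11), "exceeds")
  expect_error(cluster_patients(rbind(x, NA)[1:10, ] * NA, k = 2),
               "non-finite")
  big <- rbind(matrix(rnorm(60, 0), 15, 4), matrix(rnorm(20, 8), 5, 4))
  rownames(big) <- sprintf("s%02d", 1:20)
  cl <- cluster_patients(big, k = 2)
  expect_equal(sum(cl$cluster == 1), 15)  # label 1 = largest cluster
})

test_that("well-separated blobs are recovered exactly and labels are permutation-equivariant", {
  set.seed(13)
  centers <- diag(12, 4)
  truth <- rep(1:4, each = 25)
  x <- centers[truth, ] + matrix(rnorm(400), 100, 4)
  rownames(x) <- sprintf("s%03d", 1:100)
  cl <- cluster_patients(x, k = 4)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
  perm <- sample(nrow(x))
  cl2 <- cluster_patients(x[perm, ], k = 4)
  expect_equal(mclust::adjustedRandIndex(
    cl2$cluster[match(rownames(x), cl2$sample_id)], cl$cluster), 1)
})

test_that("group comparisons choose tests correctly and apply the family threshold", {
  set.seed(8)
  n <- 120
  clinical <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    status = "case",
    damage_index = rpois(n, 2),
    SSA_or_SSB = rbinom(n, 1, 0.4) == 1,
    constant = 1,
    stringsAsFactors = FALSE)
  groups <- setNames(rep(1:2, n / 2), clinical$sample_id)
  out <- compare_groups_clinical(groups, clinical,
                                 c("damage_index", "SSA_or_SSB",
                                   "constant"),
                                 family_size = 35)
  expect_equal(out$test[out$variable == "damage_index"], "mann-whitney")
  expect_true(out$test[out$variable == "SSA_or_SSB"] %in%
                c("chi-square", "fisher"))
  expect_equal(out$p_value[out$variable == "constant"], 1)
  expect_equal(out$note[out$variable == "constant"], "constant variable")
  # the 35-test family threshold is 0.05 / 35 = 0.00143 (3 s.f.)
  expect_equal(unique(out$bonferroni_threshold), 0.05 / 35)
  expect_equal(signif(unique(out$bonferroni_threshold), 3), 0.00143)
  # three or more groups switch to Kruskal-Wallis
  g3 <- setNames(rep(1:3, each = 40), clinical$sample_id)
  out3 <- compare_groups_clinical(g3, clinical, "damage_index")
  expect_equal(out3$test, "kruskal-wallis")
  # identical group distributions are not flagged
  clinical$same <- rep(c(0, 1), each = n / 2)
  gsame <- setNames(rep(1:2, times = n / 2), clinical$sample_id)
  out_same <- compare_groups_clinical(gsame, clinical, "same")
  expect_false(out_same$significant)
})

test_that("2x2 chi-square equals the textbook uncorrected statistic", {
  clinical <- data.frame(
    sample_id = sprintf("s%03d", 1:200),
    status = "case",
    flag = c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 40), rep(FALSE, 60)),
    stringsAsFactors = FALSE)
  groups <- setNames(rep(1:2, each = 100), clinical$sample_id)
  out <- compare_groups_clinical(groups, clinical, "flag")
  expect_equal(out$test, "chi-square")
  # N (ad - bc)^2 / (row and column products) = 9.524
  expect_equal(round(out$statistic, 3), 9.524)
  expect_equal(out$p_value,
               pchisq(200 * (20 * 60 - 80 * 40)^2 /
                        (100 * 100 * 60 * 140), 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("per-pathway case-control PRS comparison returns one test per pathway", {
  set.seed(14)
  scores <- matrix(rnorm(300), 100, 3,
                   dimnames = list(sprintf("s%03d", 1:100),
                                   c("P1", "P2", "P3")))
  scores[1:50, 1] <- scores[1:50, 1] + 1   # cases shifted on P1
  prs <- structure(list(scores = scores), class = "pathway_prs")
  clinical <- data.frame(sample_id = rownames(scores),
                         status = rep(c("case", "control"), each = 50))
  out <- prs_case_control_test(prs, clinical)
  expect_equal(out$pathway_id, c("P1", "P2", "P3"))
  expect_lt(out$p_value[1], 0.01)
  expect_equal(out$fdr_q, bh_fdr(out$p_value))
})
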