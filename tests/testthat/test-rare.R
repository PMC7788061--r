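# Rare-variant burden, case-only cataloguing and the homozygous screen.

test_that("per-individual burden counts qualifying variants only", {
  fx <- make_annotated_fixture()
  b <- per_individual_burden(fx$gm, fx$variants)
  # sA: v_rare1 (het missense) + v_rare2 (het splice) + v_hom (hom
  # missense) qualify; v_com is common, v_syn synonymous
  expect_equal(unname(b["sA"]), 3L)
  expect_equal(unname(b["sE"]), 0L)            # zero alt alleles
  # sC carries v_rare2 and the synonymous v_syn: only one qualifies
  expect_equal(unname(b["sC"]), 1L)
  # allele counting doubles the homozygote
  ba <- per_individual_burden(fx$gm, fx$variants, count = "alleles")
  expect_equal(unname(ba["sA"]), 4L)
  # unknown consequence vocabulary is an error naming the offender
  bad <- fx$variants
  bad$consequence[1] <- "nonsense-word"
  expect_error(per_individual_burden(fx$gm, bad), "nonsense-word")
})

test_that("burden summed over samples equals carrier-weighted variant totals", {
  cfg <- sim_config(n_cases = 80, n_controls = 80, n_genes = 10,
                    variants_per_gene = 8, rare_nonsyn_rate = 3, seed = 41)
  coh <- simulate_cohort(cfg)
  b <- per_individual_burden(coh$genotypes, coh$variants)
  sel <- coh$variants$maf < 0.01 &
    coh$variants$consequence %in% nonsynonymous_classes()
  carriers <- colSums((coh$genotypes$dosage *
                         !coh$genotypes$missing)[, sel, drop = FALSE] >= 1)
  expect_equal(sum(b), sum(carriers))
})

test_that("case-only catalogue excludes control carriers and panel members, orders by count", {
  fx <- make_annotated_fixture()
  cat0 <- case_only_catalogue(fx$gm, fx$variants, fx$clinical)
  # v_ctrl has a control carrier; v_com is in panels (and common/non-coding)
  expect_false("v_ctrl" %in% cat0$variant_id)
  expect_false("v_com" %in% cat0$variant_id)
  expect_false("v_syn" %in% cat0$variant_id)   # synonymous
  expect_true(all(c("v_rare1", "v_rare2") %in% cat0$variant_id))
  expect_equal(cat0$carrier_count[cat0$variant_id == "v_rare1"], 2L)
  # explicit panel subtraction: flag one catalogue member as panel-present
  v2 <- fx$variants
  v2$panel_gnomad[v2$variant_id == "v_rare1"] <- TRUE
  cat1 <- case_only_catalogue(fx$gm, v2, fx$clinical)
  expect_false("v_rare1" %in% cat1$variant_id)
  # ordering: descending carrier count, then position
  expect_true(!is.unsorted(rev(cat0$carrier_count)))
})

test_that("planted recurrent counts give the expected recurrent view in order", {
  dosage <- matrix(0, nrow = 12, ncol = 3,
                   dimnames = list(sprintf("s%02d", 1:12),
                                   c("vA", "vB", "vC")))
  dosage[1:5, "vA"] <- 1
  dosage[1:4, "vB"] <- 1
  dosage[1, "vC"] <- 1
  gm <- genotype_matrix(dosage)
  variants <- data.frame(variant_id = c("vA", "vB", "vC"), chrom = "1",
                         pos = c(300L, 100L, 200L), ref = "G", alt = "A",
                         maf = 0.02, gene_id = "GX",
                         consequence = "missense",
                         stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = rownames(dosage),
                         status = rep(c("case", "control"), c(8, 4)))
  cat0 <- case_only_catalogue(gm, variants, clinical)
  rec <- recurrent_case_only(cat0)
  expect_equal(rec$variant_id, c("vA", "vB"))
  expect_equal(rec$carrier_count, c(5L, 4L))
  expect_equal(attr(cat0, "subtraction"), "in-study-only subtraction")
})

test_that("catalogue is invariant to sample order and never contains control carriers", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_genes = 8,
                    variants_per_gene = 6, caseonly_injection = 3,
                    seed = 47)
  coh <- simulate_cohort(cfg)
  cat0 <- case_only_catalogue(coh$genotypes, coh$variants, coh$clinical)
  expect_true(all(grepl("^CO", cat0$variant_id) |
                    cat0$variant_id %in% coh$variants$variant_id))
  ctrl <- coh$clinical$sample_id[coh$clinical$status == "control"]
  D <- coh$genotypes$dosage * !coh$genotypes$missing
  expect_true(all(D[ctrl, cat0$variant_id] == 0))
  perm <- sample(coh$genotypes$sample_ids)
  cat1 <- case_only_catalogue(subset_genotypes(coh$genotypes,
                                               samples = perm),
                              coh$variants, coh$clinical)
  expect_equal(cat0$variant_id, cat1$variant_id)
  expect_equal(cat0$carrier_count, cat1$carrier_count)
})

test_that("homozygous rare screen returns planted pairs and respects the filters", {
  fx <- make_annotated_fixture()
  # sA is homozygous for the rare missense v_hom in the monogenic gene
  hits <- homozygous_rare_screen(fx$gm, fx$variants, "MONO1", fx$clinical)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$sample_id, "sA")
  expect_equal(hits$variant_id, "v_hom")
  # common homozygote (sB at v_com, MAF 0.3) is never returned
  hits2 <- homozygous_rare_screen(fx$gm, fx$variants,
                                  unique(fx$variants$gene_id),
                                  fx$clinical)
  expect_false("v_com" %in% hits2$variant_id)
  # empty result is valid
  expect_equal(nrow(homozygous_rare_screen(fx$gm, fx$variants, "GENE3",
                                           fx$clinical)), 0)
  expect_error(homozygous_rare_screen(fx$gm, fx$variants, character(0)),
               "non-empty")
})
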