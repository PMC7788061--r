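# Small in-code fixtures shared across test files.

# genotype matrix + balanced case/control labels with common variants
make_cc_fixture <- function(seed, n = 300, m = 5, maf_lo = 0.15,
                            maf_hi = 0.45) {
  set.seed(seed)
  maf <- runif(m, maf_lo, maf_hi)
  D <- sapply(maf, function(f) rbinom(n, 2, f))
  rownames(D) <- sprintf("s%04d", seq_len(n))
  colnames(D) <- sprintf("v%d", seq_len(m))
  gm <- genotype_matrix(D)
  clinical <- data.frame(sample_id = rownames(D),
                         status = sample(rep(c("case", "control"), n / 2)),
                         stringsAsFactors = FALSE)
  list(gm = gm, clinical = clinical, maf = maf)
}

# hand-built annotated variant table for rare/case-only tests
make_annotated_fixture <- function() {
  dosage <- rbind(
    #        v_com v_rare1 v_rare2 v_syn v_hom v_ctrl
    sA    = c(1,    1,      1,      1,    2,    0),
    sB    = c(2,    1,      0,      0,    0,    0),
    sC    = c(0,    0,      1,      1,    0,    0),
    sD    = c(1,    0,      0,      0,    0,    1),
    sE    = c(0,    0,      0,      0,    0,    0),
    sF    = c(1,    0,      0,      1,    0,    0))
  colnames(dosage) <- c("v_com", "v_rare1", "v_rare2", "v_syn", "v_hom",
                        "v_ctrl")
  gm <- genotype_matrix(dosage)
  variants <- data.frame(
    variant_id = colnames(dosage),
    chrom = c("1", "1", "2", "2", "3", "3"),
    pos = c(100L, 200L, 100L, 200L, 100L, 200L),
    ref = "A", alt = "T", minor_allele = "T",
    maf = c(0.3, 0.005, 0.005, 0.004, 0.003, 0.004),
    gene_id = c("GENE1", "GENE1", "GENE2", "GENE2", "MONO1", "GENE3"),
    consequence = c("non-coding", "missense", "splice-region",
                    "synonymous", "missense", "missense"),
    sift_label = NA_character_,
    panel_swegen = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    panel_gnomad = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  clinical <- data.frame(
    sample_id = rownames(dosage),
    status = c("case", "case", "case", "control", "control", "case"),
    stringsAsFactors = FALSE)
  list(gm = gm, variants = variants, clinical = clinical)
}
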