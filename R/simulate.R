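#' Simulation configuration for a synthetic case-control cohort
#'
#' Describes a sequencing-style case-control cohort with a realistic MAF
#' spectrum, optional LD blocks, rare coding variants, planted per-pathway
#' log-odds effects, case-only variant injection and a clinical model
#' linking genetic burden to a damage index and autoantibody status. The
#' defaults give a desk-scale cohort; the published reference scale
#' (958 cases / 1026 controls, ~287k SNVs over 1832 genes and 35 pathways)
#' is reachable by configuration.
#'
#' @param n_cases,n_controls sample sizes (positive).
#' @param n_genes number of gene regions.
#' @param n_pathways number of pathways used for the default disjoint
#'   gene-to-pathway partition; ignored when `genes_per_pathway` is given.
#' @param genes_per_pathway named list mapping pathway id to member gene
#'   ids; default partitions genes round-robin over `n_pathways` pathways
#'   "P1".."Pk".
#' @param variants_per_gene variants simulated per gene.
#' @param maf_spectrum list with `shape1`, `shape2` (Beta shape of the
#'   spectrum), `max` (upper bound, <= 0.5) and `min` (lower truncation).
#' @param ld_block_size variants per correlated block within a gene
#'   (1 = independent).
#' @param ld_r2 target within-block squared dosage correlation in [0, 1].
#' @param causal_pathways list of [causal_pathway()] specs planting per-SNV
#'   ln-OR effects in named pathways.
#' @param disease_model `"liability"` (standard-normal polygenic liability
#'   plus planted effects; cases are the top quantile matching the
#'   requested case fraction) or `"logistic"` (Bernoulli case status at
#'   `plogis(intercept + G beta)`, with quota resampling to reach the
#'   requested counts).
#' @param prevalence_or_intercept logistic intercept (log-odds scale) for
#'   the logistic model; unused under the liability model.
#' @param rare_nonsyn_rate expected number of rare (MAF < 0.01)
#'   non-synonymous variants per gene.
#' @param caseonly_injection number of singleton/doubleton variants to
#'   plant in cases only (absent from controls and all external panels).
#' @param clinical_model list of coefficients linking the standardised true
#'   genetic burden to clinical outcomes: `damage_intercept`/`damage_slope`
#'   (Poisson log-link damage index) and `ab_intercept`/`ab_slope`
#'   (logistic autoantibody flag).
#' @param missing_rate per-call genotype missingness probability.
#' @param seed integer seed; identical config + seed reproduces identical
#'   output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 150, n_controls = 150, n_genes = 25,
                       n_pathways = 5, genes_per_pathway = NULL,
                       variants_per_gene = 10,
                       maf_spectrum = list(shape1 = 0.3, shape2 = 1.4,
                                           max = 0.5, min = 0.002),
                       ld_block_size = 1, ld_r2 = 0,
                       causal_pathways = list(),
                       disease_model = c("liability", "logistic"),
                       prevalence_or_intercept = -1,
                       rare_nonsyn_rate = 2,
                       caseonly_injection = 0,
                       clinical_model = list(damage_intercept = 0,
                                             damage_slope = 0.4,
                                             ab_intercept = -0.6,
                                             ab_slope = 0.5),
                       missing_rate = 0.002,
                       seed = 1L) {
  disease_model <- match.arg(disease_model)
  counts <- c(n_cases, n_controls, n_genes, variants_per_gene)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must lie in [0, 1]")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (maf_spectrum$max > 0.5 || maf_spectrum$min <= 0)
    stop("MAF spectrum must be bounded in (0, 0.5]")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(genes_per_pathway)) {
    pw <- sprintf("P%d", ((seq_len(n_genes) - 1) %% n_pathways) + 1)
    genes_per_pathway <- split(gene_ids, pw)[paste0("P", seq_len(n_pathways))]
  } else {
    undef <- setdiff(unlist(genes_per_pathway), gene_ids)
    if (length(undef))
      stop("genes_per_pathway references undefined genes: ",
           paste(utils::head(undef, 5), collapse = ", "))
  }
  for (cp in causal_pathways) {
    if (!cp$pathway_id %in% names(genes_per_pathway))
      stop("causal pathway not defined: ", cp$pathway_id)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 genes_per_pathway = genes_per_pathway,
                 variants_per_gene = as.integer(variants_per_gene),
                 maf_spectrum = maf_spectrum,
                 ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
                 causal_pathways = causal_pathways,
                 disease_model = disease_model,
                 prevalence_or_intercept = prevalence_or_intercept,
                 rare_nonsyn_rate = rare_nonsyn_rate,
                 caseonly_injection = as.integer(caseonly_injection),
                 clinical_model = clinical_model,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted causal pathway specification
#'
#' @param pathway_id pathway to receive effects.
#' @param logor mean per-SNV ln-OR of the minor allele.
#' @param fraction fraction of the pathway's SNVs made causal.
#' @param logor_sd standard deviation of per-SNV ln-ORs around `logor`
#'   (0 = fixed effect).
#' @return list usable in `sim_config(causal_pathways = list(...))`.
#' @export
causal_pathway <- function(pathway_id, logor = 0.3, fraction = 0.2,
                           logor_sd = 0) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  list(pathway_id = pathway_id, logor = logor, fraction = fraction,
       logor_sd = logor_sd)
}

# latent Gaussian-copula correlation achieving a target binary (allele)
# correlation at threshold qnorm(maf): solved by 1-d integration + uniroot
latent_rho_for <- function(target_r, maf) {
  if (target_r <= 0) return(0)
  t <- stats::qnorm(maf)
  binary_corr <- function(rho) {
    if (rho >= 1) return(1)
    p11 <- stats::integrate(function(z)
      stats::dnorm(z) * stats::pnorm((t - rho * z) / sqrt(1 - rho^2)),
      -Inf, t, rel.tol = 1e-9)$value
    (p11 - maf^2) / (maf * (1 - maf))
  }
  if (binary_corr(0.9999) < target_r) return(0.9999)
  stats::uniroot(function(r) binary_corr(r) - target_r, c(0, 0.9999),
                 tol = 1e-6)$root
}

# draw per-variant metadata (positions, alleles, target MAFs, consequences,
# panel flags) for a configured cohort; called once so repeated genotype
# draws share one variant universe
draw_variant_defs <- function(config) {
  n_var <- config$n_genes * config$variants_per_gene
  ms <- config$maf_spectrum
  maf <- pmin(pmax(stats::rbeta(n_var, ms$shape1, ms$shape2) * ms$max,
                   ms$min), ms$max)
  gene_idx <- rep(seq_len(config$n_genes), each = config$variants_per_gene)
  chrom <- as.character(((gene_idx - 1) %% 22) + 1)
  gene_on_chrom <- ((gene_idx - 1) %/% 22)
  within <- (seq_len(n_var) - 1) %% config$variants_per_gene
  pos <- as.integer(1e6 + gene_on_chrom * 1e6 + within * 150 + 1)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  consequence <- rep("non-coding", n_var)
  rare <- maf < 0.01
  for (g in seq_len(config$n_genes)) {
    idx <- which(gene_idx == g & rare)
    if (length(idx)) {
      p_ns <- min(1, config$rare_nonsyn_rate / length(idx))
      ns <- idx[stats::runif(length(idx)) < p_ns]
      consequence[ns] <- sample(
        c("missense", "stop-gained", "splice-region", "frameshift"),
        length(ns), replace = TRUE, prob = c(0.8, 0.06, 0.1, 0.04))
      syn <- setdiff(idx, ns)
      consequence[syn] <- sample(c("synonymous", "non-coding"),
                                 length(syn), replace = TRUE,
                                 prob = c(0.3, 0.7))
    }
    idx_c <- which(gene_idx == g & !rare)
    consequence[idx_c] <- sample(c("non-coding", "synonymous", "missense"),
                                 length(idx_c), replace = TRUE,
                                 prob = c(0.85, 0.08, 0.07))
  }
  sift <- ifelse(consequence == "missense",
                 sample(c("Deleterious(0.01)", "Tolerated(0.30)"),
                        n_var, replace = TRUE, prob = c(0.4, 0.6)),
                 NA_character_)
  # presence in external panels: probability a variant is seen at least
  # once among 2N panel chromosomes at its population frequency
  p_swegen <- 1 - (1 - maf)^(2 * 1000)
  p_gnomad <- 1 - (1 - maf)^(2 * 32000)
  data.frame(variant_id = sprintf("%s_v%02d", config$gene_ids[gene_idx],
                                  within + 1),
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             minor_allele = alt, maf = NA_real_, true_maf = maf,
             gene_id = config$gene_ids[gene_idx],
             consequence = consequence, sift_label = sift,
             panel_swegen = stats::runif(n_var) < p_swegen,
             panel_gnomad = stats::runif(n_var) < p_gnomad,
             stringsAsFactors = FALSE)
}

# draw dosages for n individuals given variant defs; continues the RNG
# stream of the caller
draw_dosages <- function(defs, config, n, id_offset = 0) {
  n_var <- nrow(defs)
  hap <- function() {
    H <- matrix(0L, nrow = 2 * n, ncol = n_var)
    block <- config$ld_block_size
    j <- 1
    while (j <= n_var) {
      # blocks never span genes
      gene_end <- max(which(defs$gene_id == defs$gene_id[j]))
      jj <- min(j + block - 1, gene_end, n_var)
      cols <- j:jj
      if (length(cols) == 1 || config$ld_r2 == 0) {
        for (cc in cols)
          H[, cc] <- stats::rbinom(2 * n, 1, defs$true_maf[cc])
      } else {
        rl <- latent_rho_for(sqrt(config$ld_r2), mean(defs$true_maf[cols]))
        w0 <- stats::rnorm(2 * n)
        for (cc in cols) {
          z <- sqrt(rl) * w0 + sqrt(1 - rl) * stats::rnorm(2 * n)
          H[, cc] <- as.integer(z < stats::qnorm(defs$true_maf[cc]))
        }
      }
      j <- jj + 1
    }
    H
  }
  H <- hap()
  D <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
       H[seq(2, 2 * n, by = 2), , drop = FALSE]
  miss <- matrix(stats::runif(n * n_var) < config$missing_rate,
                 nrow = n, ncol = n_var)
  D[miss] <- 0L
  rownames(D) <- sprintf("S%05d", id_offset + seq_len(n))
  colnames(D) <- defs$variant_id
  dimnames(miss) <- dimnames(D)
  list(dosage = D, missing = miss)
}

# orient every variant so the stored/written ALT is the minor allele on the
# realised sample, and record the empirical MAF (tie at 0.5 broken
# lexicographically by allele string, matching the VCF reader)
orient_minor <- function(dosage, missing, defs) {
  n_called <- colSums(!missing)
  f_alt <- ifelse(n_called > 0, colSums(dosage * !missing) / (2 * n_called), 0)
  flip <- f_alt > 0.5 | (f_alt == 0.5 & defs$ref < defs$alt)
  if (any(flip)) {
    dosage[, flip] <- 2 - dosage[, flip, drop = FALSE]
    dosage[missing] <- 0
    tmp <- defs$ref[flip]
    defs$ref[flip] <- defs$alt[flip]
    defs$alt[flip] <- tmp
    f_alt[flip] <- 1 - f_alt[flip]
  }
  defs$minor_allele <- defs$alt
  defs$maf <- f_alt
  list(dosage = dosage, defs = defs)
}

#' Simulate genotypes for a configured cohort
#'
#' Draws the variant universe (positions, alleles, MAF spectrum,
#' consequence labels, panel-presence flags) and a dosage matrix for
#' `n_cases + n_controls` individuals. Within an LD block, haplotypes are
#' generated from a one-factor Gaussian copula calibrated so adjacent
#' variants reach approximately the target squared correlation. Dosages
#' are oriented to the minor allele on the realised sample and the
#' empirical MAF is recorded alongside the target (`true_maf`).
#'
#' @param config a [sim_config()].
#' @param n_individuals optional override of the number of individuals.
#' @return list with `genotypes` (a [genotype_matrix()]) and `variants`.
#' @export
simulate_genotypes <- function(config,
                               n_individuals = config$n_cases +
                                 config$n_controls) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  defs <- draw_variant_defs(config)
  dr <- draw_dosages(defs, config, n_individuals)
  ori <- orient_minor(dr$dosage, dr$missing, defs)
  list(genotypes = genotype_matrix(ori$dosage, dr$missing),
       variants = validate_variant_table(ori$defs))
}

# draw per-variant causal ln-ORs for the configured causal pathways
draw_betas <- function(variants, config) {
  beta <- stats::setNames(rep(0, nrow(variants)), variants$variant_id)
  for (cp in config$causal_pathways) {
    genes <- config$genes_per_pathway[[cp$pathway_id]]
    cand <- which(variants$gene_id %in% genes)
    n_causal <- max(1L, round(cp$fraction * length(cand)))
    chosen <- sample(cand, min(n_causal, length(cand)))
    beta[chosen] <- stats::rnorm(length(chosen), cp$logor, cp$logor_sd)
  }
  beta
}

#' Simulate case/control status and clinical outcomes
#'
#' Assigns causal ln-ORs to the configured fraction of SNVs in each causal
#' pathway, computes the true per-individual genetic liability
#' `G %*% beta`, and labels cases either by the liability-threshold model
#' (cases = top quantile matching the requested case fraction) or the
#' logistic model (Bernoulli at `plogis(intercept + G beta)`). Clinical
#' outcomes are generated from the standardised genetic burden: a Poisson
#' log-link damage index and a logistic autoantibody flag.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants matching variant table.
#' @param config a [sim_config()].
#' @return Clinical data.frame (`sample_id`, `status`, `damage_index`,
#'   `SSA_or_SSB`, `true_liability`) with the per-variant causal ln-ORs
#'   in attribute `betas`.
#' @export
simulate_phenotypes <- function(genotypes, variants, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  beta <- draw_betas(variants, config)
  D <- genotypes$dosage * !genotypes$missing
  gscore <- as.vector(D %*% beta[genotypes$variant_ids])
  n <- length(gscore)
  if (config$disease_model == "liability") {
    L <- gscore + stats::rnorm(n)
    frac <- config$n_cases / (config$n_cases + config$n_controls)
    status <- ifelse(rank(-L, ties.method = "first") <= round(frac * n),
                     "case", "control")
  } else {
    # centre the genetic load so the intercept keeps its baseline meaning
    mu_g <- sum(beta * 2 * variants$true_maf[match(names(beta),
                                                  variants$variant_id)])
    p <- stats::plogis(config$prevalence_or_intercept + gscore - mu_g)
    status <- ifelse(stats::rbinom(n, 1, p) == 1, "case", "control")
  }
  z <- if (stats::sd(gscore) > 0) as.vector(scale(gscore)) else rep(0, n)
  cm <- config$clinical_model
  damage <- stats::rpois(n, exp(cm$damage_intercept + cm$damage_slope * z))
  ab <- stats::rbinom(n, 1, stats::plogis(cm$ab_intercept +
                                            cm$ab_slope * z)) == 1
  out <- data.frame(sample_id = genotypes$sample_ids, status = status,
                    damage_index = damage, SSA_or_SSB = ab,
                    true_liability = gscore, stringsAsFactors = FALSE)
  attr(out, "betas") <- beta
  out
}

# plant `config$caseonly_injection` singleton/doubleton variants carried by
# cases only: het carriers, absent from in-study controls and all panels
inject_case_only <- function(genotypes, variants, clinical, config) {
  k <- config$caseonly_injection
  if (k == 0) return(list(genotypes = genotypes, variants = variants))
  set.seed(config$seed + 2L)
  cases <- clinical$sample_id[clinical$status == "case"]
  n <- length(genotypes$sample_ids)
  add_d <- matrix(0, nrow = n, ncol = k,
                  dimnames = list(genotypes$sample_ids,
                                  sprintf("CO%03d", seq_len(k))))
  add_m <- matrix(FALSE, nrow = n, ncol = k, dimnames = dimnames(add_d))
  rows <- vector("list", k)
  base_pos <- max(variants$pos)
  for (i in seq_len(k)) {
    carriers <- sample(cases, sample(1:2, 1))
    add_d[carriers, i] <- 1
    gene <- sample(variants$gene_id, 1)
    gv <- variants[variants$gene_id == gene, ][1, ]
    rows[[i]] <- data.frame(
      variant_id = colnames(add_d)[i], chrom = gv$chrom,
      pos = as.integer(base_pos + i * 7L), ref = "G", alt = "A",
      minor_allele = "A", maf = sum(add_d[, i]) / (2 * n),
      true_maf = 1 / (4 * n), gene_id = gene, consequence = "missense",
      sift_label = "Deleterious(0.01)", panel_swegen = FALSE,
      panel_gnomad = FALSE, stringsAsFactors = FALSE)
  }
  gm <- genotype_matrix(cbind(genotypes$dosage, add_d),
                        cbind(genotypes$missing, add_m))
  list(genotypes = gm, variants = rbind(variants, do.call(rbind, rows)))
}

#' Simulate a complete case-control cohort
#'
#' End-to-end generator: genotypes, phenotypes/clinical outcomes,
#' gene-set collection from the configured pathway map, and planted
#' case-only variants. Under the logistic disease model the genotype pool
#' is resampled in bounded rounds until the requested case and control
#' quotas are met (the variant universe is drawn once); under the
#' liability model the quota is exact by construction.
#'
#' @param config a [sim_config()].
#' @param max_rounds bound on logistic-model resampling rounds.
#' @return list with `genotypes`, `variants`, `clinical`, `genesets`,
#'   `betas` (the planted per-variant ln-ORs) and `config`.
#' @export
simulate_cohort <- function(config, max_rounds = 25L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$disease_model == "liability") {
    sim <- simulate_genotypes(config)
    clinical <- simulate_phenotypes(sim$genotypes, sim$variants, config)
    betas <- attr(clinical, "betas")
    gm <- sim$genotypes; variants <- sim$variants
  } else {
    set.seed(config$seed)
    defs <- draw_variant_defs(config)
    set.seed(config$seed + 1L)
    beta <- draw_betas(defs, config)
    need_cases <- config$n_cases; need_controls <- config$n_controls
    total <- need_cases + need_controls
    got_d <- got_m <- NULL; got_status <- character(0)
    offset <- 0
    mu_g <- sum(beta * 2 * defs$true_maf)
    for (r in seq_len(max_rounds)) {
      batch <- max(total, 500L)
      dr <- draw_dosages(defs, config, batch, id_offset = offset)
      offset <- offset + batch
      D <- dr$dosage * !dr$missing
      p <- stats::plogis(config$prevalence_or_intercept +
                           as.vector(D %*% beta) - mu_g)
      st <- ifelse(stats::rbinom(batch, 1, p) == 1, "case", "control")
      keep_case <- which(st == "case")[
        seq_len(min(sum(st == "case"),
                    need_cases - sum(got_status == "case")))]
      keep_ctrl <- which(st == "control")[
        seq_len(min(sum(st == "control"),
                    need_controls - sum(got_status == "control")))]
      keep <- sort(c(keep_case, keep_ctrl))
      got_d <- rbind(got_d, dr$dosage[keep, , drop = FALSE])
      got_m <- rbind(got_m, dr$missing[keep, , drop = FALSE])
      got_status <- c(got_status, st[keep])
      if (sum(got_status == "case") >= need_cases &&
          sum(got_status == "control") >= need_controls) break
    }
    if (sum(got_status == "case") < need_cases ||
        sum(got_status == "control") < need_controls)
      stop("disease model yielded fewer cases/controls than requested ",
           "after ", max_rounds, " sampling rounds")
    ori <- orient_minor(got_d, got_m, defs)
    gm <- genotype_matrix(ori$dosage, got_m)
    variants <- validate_variant_table(ori$defs)
    gscore <- as.vector((gm$dosage * !gm$missing) %*%
                          beta[gm$variant_ids])
    z <- if (stats::sd(gscore) > 0) as.vector(scale(gscore)) else
      rep(0, length(gscore))
    cm <- config$clinical_model
    clinical <- data.frame(
      sample_id = gm$sample_ids, status = got_status,
      damage_index = stats::rpois(length(z), exp(cm$damage_intercept +
                                                   cm$damage_slope * z)),
      SSA_or_SSB = stats::rbinom(length(z), 1,
                                 stats::plogis(cm$ab_intercept +
                                                 cm$ab_slope * z)) == 1,
      true_liability = gscore, stringsAsFactors = FALSE)
    betas <- beta
  }
  inj <- inject_case_only(gm, variants, clinical, config)
  genesets <- gene_set_collection(config$genes_per_pathway,
                                  provenance = "kegg_pathway")
  list(genotypes = inj$genotypes, variants = inj$variants,
       clinical = clinical, genesets = genesets, betas = betas,
       config = config)
}
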