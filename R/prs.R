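#' Greedy LD pruning of variants by ascending p-value
#'
#' Clumping-style independence construction: variants are processed in
#' ascending p-value order, and a variant is retained iff its dosage
#' squared correlation with every already-retained variant on the same
#' chromosome within `window_kb` is below `r2_threshold`. Ties in p are
#' broken by variant-table order for determinism.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table with `chrom` and `pos`.
#' @param p_values named numeric vector (or vector aligned with
#'   `genotypes$variant_ids`) of per-variant p-values; every candidate must
#'   have one.
#' @param r2_threshold squared-correlation threshold (default 0.2).
#' @param window_kb pruning window in kilobases (default 500).
#' @return Character vector of retained variant ids (empty input gives an
#'   empty output).
#' @export
ld_prune <- function(genotypes, variants, p_values, r2_threshold = 0.2,
                     window_kb = 500) {
  ids <- genotypes$variant_ids
  if (length(ids) == 0) return(character(0))
  if (!is.null(names(p_values))) p_values <- p_values[ids]
  if (length(p_values) != length(ids) || any(is.na(p_values)))
    stop("a p-value is required for every candidate variant")
  vt <- variants[match(ids, variants$variant_id), ]
  D <- impute_mean_dosage(genotypes)
  ord <- order(p_values)  # stable: ties keep input order
  kept <- integer(0)
  win <- window_kb * 1000
  for (j in ord) {
    ok <- TRUE
    for (k in kept) {
      if (vt$chrom[k] != vt$chrom[j]) next
      if (abs(vt$pos[k] - vt$pos[j]) > win) next
      r <- suppressWarnings(stats::cor(D[, j], D[, k]))
      if (is.na(r)) r <- 0
      if (r^2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  ids[sort(kept)]
}

#' Build pathway PRS weights from single-variant results
#'
#' Weights are the natural-log odds ratio of the minor allele for every
#' LD-pruned variant with `p_value < alpha`, mapped to each pathway that
#' contains the variant's gene (a variant in several pathways contributes
#' to each). With `orientation = "signed"` (default) the weight is the
#' signed ln-OR exactly as estimated, protective minor alleles included;
#' with `orientation = "risk"` weights are made positive by flipping the
#' dosage coding of protective variants to count the major (risk) allele.
#'
#' @param assoc `assoc_result` from [single_variant_assoc()].
#' @param pruned_ids variant ids retained by [ld_prune()].
#' @param genesets a [gene_set_collection()].
#' @param variants variant table with `gene_id` (the variant-to-gene map).
#' @param alpha nominal significance threshold (default 0.05).
#' @param orientation `"signed"` or `"risk"` (see above).
#' @return data.frame of class `prs_weights`: `variant_id`, `pathway_id`,
#'   `weight`, `p_value`, `flip` (TRUE when the dosage is risk-recoded).
#'   The number of candidates dropped for lacking a gene annotation is
#'   recorded in attribute `n_unmapped`.
#' @export
build_prs_weights <- function(assoc, pruned_ids, genesets, variants,
                              alpha = 0.05,
                              orientation = c("signed", "risk")) {
  orientation <- match.arg(orientation)
  a <- assoc[assoc$unit_id %in% pruned_ids & !is.na(assoc$p_value) &
               assoc$p_value < alpha, ]
  gene <- variants$gene_id[match(a$unit_id, variants$variant_id)]
  unmapped <- sum(is.na(gene))
  a <- a[!is.na(gene), ]; gene <- gene[!is.na(gene)]
  rows <- list()
  for (i in seq_len(nrow(a))) {
    in_sets <- names(genesets$sets)[vapply(genesets$sets,
                                           function(g) gene[i] %in% g,
                                           logical(1))]
    if (length(in_sets) == 0) next
    w <- a$effect[i]; flip <- FALSE
    if (orientation == "risk" && w < 0) { w <- -w; flip <- TRUE }
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = a$unit_id[i], pathway_id = in_sets, weight = w,
      p_value = a$p_value[i], flip = flip, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), pathway_id = character(0),
               weight = numeric(0), p_value = numeric(0),
               flip = logical(0))
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- unmapped
  attr(out, "alpha") <- alpha
  attr(out, "orientation") <- orientation
  class(out) <- c("prs_weights", class(out))
  out
}

#' Per-individual pathway polygenic risk scores
#'
#' For each individual and pathway, the score is the sum over the pathway's
#' weighted variants of `weight * minor-allele dosage` (major-allele dosage
#' for risk-recoded variants). Missing dosages are replaced by the cohort
#' mean dosage of the variant. A pathway with zero weighted variants gets a
#' column of exact zeros and is flagged.
#'
#' Note: when weights are estimated on the same cohort that is scored, the
#' scores are in-sample and optimistically biased; a warning is emitted.
#' Use a split-sample design for unbiased scores.
#'
#' @param genotypes a [genotype_matrix()] for the individuals to score.
#' @param weights a `prs_weights` table from [build_prs_weights()].
#' @param pathway_ids pathways to score (default: all in `weights` plus
#'   none); pass the full pathway universe to keep zero columns for
#'   weightless pathways.
#' @param warn_in_sample emit the in-sample weighting warning
#'   (default TRUE).
#' @return Object of class `pathway_prs`: list with `scores`
#'   (samples x pathways matrix), `weights`, and empty slots for
#'   thresholds/positivity until [classify_positivity()] is applied.
#' @export
compute_pathway_prs <- function(genotypes, weights, pathway_ids = NULL,
                                warn_in_sample = TRUE) {
  if (nrow(weights) == 0 && is.null(pathway_ids))
    stop("no weighted variants for any pathway")
  if (is.null(pathway_ids)) pathway_ids <- unique(weights$pathway_id)
  if (warn_in_sample)
    warning("pathway PRS computed with in-sample weights is optimistically ",
            "biased; prefer split-sample weighting for inference",
            call. = FALSE)
  D <- impute_mean_dosage(genotypes)
  scores <- matrix(0, nrow = length(genotypes$sample_ids),
                   ncol = length(pathway_ids),
                   dimnames = list(genotypes$sample_ids, pathway_ids))
  empty <- character(0)
  for (p in pathway_ids) {
    wp <- weights[weights$pathway_id == p, ]
    wp <- wp[wp$variant_id %in% genotypes$variant_ids, ]
    if (nrow(wp) == 0) { empty <- c(empty, p); next }
    Dp <- D[, wp$variant_id, drop = FALSE]
    if (any(wp$flip)) Dp[, wp$flip] <- 2 - Dp[, wp$flip, drop = FALSE]
    scores[, p] <- as.vector(Dp %*% wp$weight)
  }
  if (length(empty))
    warning("pathway(s) with zero weighted variants scored as 0: ",
            paste(empty, collapse = ", "), call. = FALSE)
  structure(list(scores = scores, weights = weights,
                 empty_pathways = empty, control_threshold = NULL,
                 positive = NULL, n_positive_pathways = NULL,
                 percentile = NULL),
            class = "pathway_prs")
}

#' @export
print.pathway_prs <- function(x, ...) {
  cat(sprintf("pathway_prs: %d samples x %d pathways%s\n",
              nrow(x$scores), ncol(x$scores),
              if (is.null(x$positive)) " (positivity not yet classified)"
              else sprintf(", positivity at %.1fth control percentile",
                           x$percentile)))
  invisible(x)
}

#' Classify pathway positivity against the control distribution
#'
#' The per-pathway positivity threshold is the 97.5th percentile (linear
#' interpolation between order statistics) of the control individuals'
#' scores; an individual is positive for a pathway iff their score is
#' strictly greater than the threshold. The per-sample count of positive
#' pathways is recorded for every individual, cases and controls alike.
#'
#' @param prs a [compute_pathway_prs()] result.
#' @param clinical clinical table with `sample_id` and `status`; at least
#'   20 controls are required (the percentile is unstable below that).
#' @param percentile control percentile defining positivity (default 97.5).
#' @return The `pathway_prs` object with `control_threshold`, `positive`
#'   and `n_positive_pathways` filled in.
#' @export
classify_positivity <- function(prs, clinical, percentile = 97.5) {
  stopifnot(inherits(prs, "pathway_prs"))
  ctrl <- clinical$sample_id[clinical$status == "control"]
  ctrl <- intersect(ctrl, rownames(prs$scores))
  if (length(ctrl) < 20)
    stop("need at least 20 control individuals to fit positivity thresholds")
  thr <- apply(prs$scores[ctrl, , drop = FALSE], 2, stats::quantile,
               probs = percentile / 100, type = 7, names = FALSE)
  const <- apply(prs$scores[ctrl, , drop = FALSE], 2,
                 function(x) length(unique(x)) == 1)
  if (any(const))
    warning("constant control scores for pathway(s): ",
            paste(colnames(prs$scores)[const], collapse = ", "),
            "; threshold equals the constant and nobody is positive",
            call. = FALSE)
  positive <- sweep(prs$scores, 2, thr, `>`)
  prs$control_threshold <- thr
  prs$positive <- positive
  prs$n_positive_pathways <- rowSums(positive)
  prs$percentile <- percentile
  prs
}
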