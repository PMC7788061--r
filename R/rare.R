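#' Per-individual rare coding variant burden
#'
#' Counts, for each sample, the variants with MAF below `maf_lt`, a
#' consequence in the non-synonymous class (missense, stop-gained/lost,
#' start-lost, frameshift, splice-region) and at least one carried minor
#' allele. Missing genotypes contribute 0. With `count = "alleles"` the
#' minor-allele dosage is summed instead (homozygotes count twice).
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table with `maf` and `consequence`.
#' @param maf_lt MAF upper bound, strict (default 0.01).
#' @param consequence_class which consequences qualify; the default
#'   `"non-synonymous"` uses [nonsynonymous_classes()]. A character vector
#'   of consequence labels may be given instead.
#' @param count `"variants"` (dosage >= 1 counts once, default) or
#'   `"alleles"` (sum of dosages).
#' @return Named integer vector of per-sample counts.
#' @export
per_individual_burden <- function(genotypes, variants, maf_lt = 0.01,
                                  consequence_class = "non-synonymous",
                                  count = c("variants", "alleles")) {
  count <- match.arg(count)
  vt <- variants[match(genotypes$variant_ids, variants$variant_id), ]
  if (!"consequence" %in% names(vt) || any(is.na(vt$consequence)))
    stop("consequence annotations are required for every variant")
  bad <- setdiff(unique(vt$consequence), consequence_vocabulary())
  if (length(bad))
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "))
  classes <- if (identical(consequence_class, "non-synonymous"))
    nonsynonymous_classes() else consequence_class
  sel <- vt$maf < maf_lt & vt$consequence %in% classes
  D <- genotypes$dosage * !genotypes$missing
  D <- D[, sel, drop = FALSE]
  if (count == "variants") D <- D >= 1
  stats::setNames(as.integer(round(rowSums(D))), genotypes$sample_ids)
}

#' Catalogue of case-only variants
#'
#' Variants carried by at least one case, by zero in-study controls
#' (missing control genotypes do not count as presence), and absent from
#' every supplied external control panel (`panel_*` logical columns of the
#' variant table, where presence at any allele count excludes the
#' variant). The catalogue is restricted to non-synonymous consequences
#' and sorted by descending case carrier count, then chromosome and
#' position. The recurrent view (`carrier_count >= 2`) mirrors the
#' published recurrent-variant table semantics.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table with `consequence` and any `panel_*`
#'   flags.
#' @param clinical clinical table with `sample_id` and `status`.
#' @param external_panels character vector of panel column names to
#'   subtract; `NULL` uses every `panel_*` column present. If the table
#'   has none, the output is labelled "in-study-only subtraction".
#' @return data.frame of class `case_only_catalogue`: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `carrier_count`, `gene_id`,
#'   `consequence`, plus `aa_change`/`sift_label` passthrough when
#'   present. Attributes: `subtraction` (panel columns used or
#'   "in-study-only subtraction"), `control_missing_rate` (per-variant
#'   missingness among controls for the catalogued variants).
#' @export
case_only_catalogue <- function(genotypes, variants, clinical,
                                external_panels = NULL) {
  vt <- variants[match(genotypes$variant_ids, variants$variant_id), ]
  st <- clinical$status[match(genotypes$sample_ids, clinical$sample_id)]
  if (any(is.na(st))) stop("every genotyped sample needs a status")
  is_case <- st == "case"
  D <- genotypes$dosage * !genotypes$missing
  case_carriers <- colSums(D[is_case, , drop = FALSE] >= 1)
  ctrl_carriers <- colSums(D[!is_case, , drop = FALSE] >= 1)
  if (is.null(external_panels))
    external_panels <- grep("^panel_", names(vt), value = TRUE)
  in_panel <- rep(FALSE, nrow(vt))
  for (pn in external_panels) {
    if (!pn %in% names(vt)) stop("unknown panel column: ", pn)
    in_panel <- in_panel | (vt[[pn]] %in% TRUE)
  }
  keep <- case_carriers >= 1 & ctrl_carriers == 0 & !in_panel &
    !is.na(vt$consequence) & vt$consequence %in% nonsynonymous_classes()
  out <- data.frame(variant_id = vt$variant_id[keep],
                    chrom = vt$chrom[keep], pos = vt$pos[keep],
                    ref = vt$ref[keep], alt = vt$alt[keep],
                    carrier_count = as.integer(case_carriers[keep]),
                    gene_id = vt$gene_id[keep],
                    consequence = vt$consequence[keep],
                    stringsAsFactors = FALSE)
  for (extra in c("aa_change", "sift_label"))
    if (extra %in% names(vt)) out[[extra]] <- vt[[extra]][keep]
  ord <- order(-out$carrier_count, out$chrom, out$pos)
  out <- out[ord, ]
  rownames(out) <- NULL
  ctrl_missing <- stats::setNames(
    colMeans(genotypes$missing[!is_case, keep, drop = FALSE]),
    vt$variant_id[keep])
  attr(out, "subtraction") <- if (length(external_panels))
    external_panels else "in-study-only subtraction"
  attr(out, "control_missing_rate") <- ctrl_missing[out$variant_id]
  class(out) <- c("case_only_catalogue", class(out))
  out
}

#' Recurrent case-only variants
#'
#' @param catalogue a [case_only_catalogue()] result.
#' @param min_carriers minimum case carrier count (default 2).
#' @return The catalogue restricted to recurrent variants, order
#'   preserved.
#' @export
recurrent_case_only <- function(catalogue, min_carriers = 2) {
  catalogue[catalogue$carrier_count >= min_carriers, ]
}

#' Homozygous rare non-synonymous screen over a gene set
#'
#' Lists every (case sample, variant) pair with dosage 2 at a rare
#' (MAF < 0.01) non-synonymous variant in a gene of interest (e.g. genes
#' for monogenic SLE and lupus-like disease). An empty result is valid and
#' expected for a healthy screen.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table with `maf`, `consequence`, `gene_id`.
#' @param gene_set character vector of gene ids (non-empty).
#' @param clinical optional clinical table; when given, only case samples
#'   are screened.
#' @return data.frame: `sample_id`, `variant_id`, `gene_id`,
#'   `consequence`, `maf`.
#' @export
homozygous_rare_screen <- function(genotypes, variants, gene_set,
                                   clinical = NULL) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  vt <- variants[match(genotypes$variant_ids, variants$variant_id), ]
  sel <- !is.na(vt$gene_id) & vt$gene_id %in% gene_set &
    vt$maf < 0.01 & vt$consequence %in% nonsynonymous_classes()
  samples <- genotypes$sample_ids
  if (!is.null(clinical)) {
    st <- clinical$status[match(samples, clinical$sample_id)]
    samples <- samples[st == "case"]
  }
  D <- genotypes$dosage * !genotypes$missing
  D <- D[samples, sel, drop = FALSE]
  hits <- which(D == 2, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(sample_id = character(0), variant_id = character(0),
                      gene_id = character(0), consequence = character(0),
                      maf = numeric(0)))
  vs <- vt[sel, ][hits[, 2], ]
  out <- data.frame(sample_id = samples[hits[, 1]],
                    variant_id = vs$variant_id, gene_id = vs$gene_id,
                    consequence = vs$consequence, maf = vs$maf,
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$variant_id), , drop = FALSE]
}
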