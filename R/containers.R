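#' Construct a genotype matrix
#'
#' The canonical genotype container used throughout the package: an
#' individuals x variants matrix of minor-allele dosages in \{0, 1, 2\},
#' together with a missingness mask of the same shape. Dosages always count
#' copies of the *minor* allele, where the minor allele is determined on the
#' combined case-control sample (frequency ties broken lexicographically by
#' allele string).
#'
#' @param dosage numeric matrix, samples in rows, variants in columns, values
#'   in \{0, 1, 2\}. Must carry rownames (sample ids) and colnames (variant
#'   ids).
#' @param missing logical matrix of the same shape; `TRUE` marks a missing
#'   genotype call. Dosage values under the mask are arbitrary and ignored.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `missing`, `sample_ids`, `variant_ids`.
#' @export
genotype_matrix <- function(dosage, missing = NULL) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("`dosage` must have sample rownames and variant colnames")
  if (anyDuplicated(rownames(dosage))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(dosage))) stop("duplicate variant ids")
  if (is.null(missing)) {
    missing <- is.na(dosage)
  }
  if (!identical(dim(missing), dim(dosage)))
    stop("`missing` must have the same shape as `dosage`")
  storage.mode(missing) <- "logical"
  bad <- !missing & (!dosage %in% c(0, 1, 2))
  if (any(bad, na.rm = TRUE))
    stop("non-missing dosages must be 0, 1 or 2")
  dosage[missing] <- 0  # masked entries normalised to 0 for determinism
  dimnames(missing) <- dimnames(dosage)
  structure(
    list(dosage = dosage, missing = missing,
         sample_ids = rownames(dosage), variant_ids = colnames(dosage)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.3f%% missing)\n",
              length(x$sample_ids), length(x$variant_ids),
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a [genotype_matrix()].
#' @param samples,variants character vectors of ids (or indices) to keep;
#'   `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  i <- if (is.null(samples)) seq_along(gm$sample_ids) else samples
  j <- if (is.null(variants)) seq_along(gm$variant_ids) else variants
  genotype_matrix(gm$dosage[i, j, drop = FALSE],
                  gm$missing[i, j, drop = FALSE])
}

#' Per-variant minor allele frequency from dosages
#'
#' MAF recomputed over non-missing calls. By construction dosages are
#' minor-allele counts, so the value lies in \[0, 0.5\] up to subsetting
#' (a subsample can push a frequency above 0.5; it is then folded).
#'
#' @param gm a [genotype_matrix()].
#' @param fold fold frequencies above 0.5 back to `1 - f` (default `TRUE`).
#' @return Named numeric vector of frequencies per variant.
#' @export
dosage_maf <- function(gm, fold = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_called <- colSums(!gm$missing)
  ac <- colSums(gm$dosage * !gm$missing)
  f <- ifelse(n_called > 0, ac / (2 * n_called), NA_real_)
  if (fold) f <- pmin(f, 1 - f)
  names(f) <- gm$variant_ids
  f
}

#' Mean-imputed dosage matrix
#'
#' Missing entries replaced by the per-variant mean dosage over non-missing
#' calls (the standard score-statistic convention). All-missing variants
#' impute to 0.
#'
#' @param gm a [genotype_matrix()].
#' @return A plain numeric matrix.
#' @export
impute_mean_dosage <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  m <- gm$missing
  if (any(m)) {
    n_called <- colSums(!m)
    mu <- ifelse(n_called > 0, colSums(d * !m) / n_called, 0)
    idx <- which(m, arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Construct a gene-set collection
#'
#' Named sets of gene identifiers (KEGG-style pathways or literature
#' gene-sets) with display names and a provenance label.
#'
#' @param sets named list of character vectors (member gene ids). Members are
#'   deduplicated; empty sets are an error.
#' @param display_name character vector parallel to `sets` (defaults to ids).
#' @param provenance per-set label, e.g. `"kegg_pathway"` or
#'   `"literature_set"`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, display_name = NULL,
                                provenance = "kegg_pathway") {
  if (length(sets) == 0) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set ids")
  sets <- lapply(sets, function(g) {
    g <- unique(as.character(g))
    if (length(g) == 0) stop("gene sets must be non-empty")
    g
  })
  if (is.null(display_name)) display_name <- names(sets)
  display_name <- rep_len(display_name, length(sets))
  provenance <- rep_len(provenance, length(sets))
  structure(
    list(sets = sets,
         info = data.frame(set_id = names(sets),
                           display_name = display_name,
                           provenance = provenance,
                           n_genes = lengths(sets),
                           stringsAsFactors = FALSE)),
    class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%s)\n", length(x$sets),
              paste(unique(x$info$provenance), collapse = ", ")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Validate a variant annotation table
#'
#' Checks the per-variant metadata table used across the pipeline:
#' `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `minor_allele`,
#' `maf` in \[0, 0.5\], and optionally `gene_id`, `consequence`,
#' `sift_label` and `panel_*` logical presence flags.
#'
#' @param variants data.frame.
#' @return The table, invisibly, after validation.
#' @export
validate_variant_table <- function(variants) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "maf")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant ids")
  if (any(variants$pos <= 0)) stop("positions must be positive (1-based)")
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  invisible(variants)
}

#' Controlled consequence vocabulary
#'
#' The consequence values the pipeline understands, and the subset counted
#' as non-synonymous (protein-altering) for burden and case-only analyses.
#' Splice-region is included in the non-synonymous class.
#'
#' @return Character vector of all recognised consequence labels.
#' @export
consequence_vocabulary <- function() {
  c("missense", "stop-gained", "stop-lost", "start-lost", "frameshift",
    "splice-region", "synonymous", "non-coding")
}

#' @rdname consequence_vocabulary
#' @export
nonsynonymous_classes <- function() {
  c("missense", "stop-gained", "stop-lost", "start-lost", "frameshift",
    "splice-region")
}
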