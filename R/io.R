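#' Read genotypes from a VCF file
#'
#' Parses GT fields from a VCF 4.2 file (diploid; unphased or phased
#' separators accepted) into a [genotype_matrix()] of minor-allele dosages
#' plus a skeleton variant table. The minor allele is determined from the
#' allele frequency in the combined sample; a frequency tie at 0.5 is broken
#' lexicographically by allele string. Multi-allelic records are split into
#' one bi-allelic variant per ALT allele (each scored as that ALT vs all
#' other alleles). A missing GT (any "." allele) sets the missingness mask
#' and is excluded from frequency computation.
#'
#' @param path VCF file path (plain text).
#' @param sample_subset optional character vector of sample ids to keep.
#' @return A list with `genotypes` (a `genotype_matrix`) and `variants`
#'   (a data.frame with `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `minor_allele`, `maf`).
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    keep <- samples %in% sample_subset
    if (!any(keep)) stop("no requested samples present in VCF")
    gt <- gt[, keep, drop = FALSE]
    samples <- colnames(gt)
  }
  n_rec <- nrow(fix)
  rows <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    id <- fix[r, "ID"]
    if (is.na(id) || id == ".")
      id <- paste0(fix[r, "CHROM"], ":", fix[r, "POS"])
    # split genotype strings once per record
    parts <- strsplit(gt[r, ], "[/|]")
    alt_counts <- matrix(0L, nrow = length(alts), ncol = length(samples))
    missing <- vapply(parts, function(p)
      length(p) == 0 || any(is.na(p)) || any(p == "."), logical(1))
    for (k in seq_along(alts)) {
      alt_counts[k, !missing] <- vapply(parts[!missing], function(p)
        sum(p == as.character(k)), integer(1))
    }
    ids <- if (length(alts) > 1) paste0(id, "_", seq_along(alts)) else id
    rows[[r]] <- list(chrom = fix[r, "CHROM"],
                      pos = as.integer(fix[r, "POS"]),
                      ref = fix[r, "REF"], alts = alts, ids = ids,
                      counts = alt_counts, missing = missing)
  }
  variant_id <- unlist(lapply(rows, `[[`, "ids"))
  if (anyDuplicated(variant_id))
    stop("duplicated variant id after multi-allelic splitting: ",
         paste(unique(variant_id[duplicated(variant_id)]), collapse = ", "))
  n_var <- length(variant_id)
  dosage <- matrix(0, nrow = length(samples), ncol = n_var,
                   dimnames = list(samples, variant_id))
  miss <- matrix(FALSE, nrow = length(samples), ncol = n_var,
                 dimnames = list(samples, variant_id))
  vt <- data.frame(variant_id = variant_id,
                   chrom = character(n_var), pos = integer(n_var),
                   ref = character(n_var), alt = character(n_var),
                   minor_allele = character(n_var), maf = numeric(n_var),
                   stringsAsFactors = FALSE)
  j <- 0L
  for (rec in rows) {
    for (k in seq_along(rec$alts)) {
      j <- j + 1L
      d <- rec$counts[k, ]
      m <- rec$missing
      n_called <- sum(!m)
      f_alt <- if (n_called > 0) sum(d[!m]) / (2 * n_called) else 0
      minor <- rec$alts[k]
      if (f_alt > 0.5 ||
          (f_alt == 0.5 && rec$ref < rec$alts[k])) {
        d <- 2 - d
        minor <- rec$ref
        f_alt <- 1 - f_alt
      }
      d[m] <- 0
      dosage[, j] <- d
      miss[, j] <- m
      vt$chrom[j] <- rec$chrom; vt$pos[j] <- rec$pos
      vt$ref[j] <- rec$ref; vt$alt[j] <- rec$alts[k]
      vt$minor_allele[j] <- minor
      vt$maf[j] <- f_alt
    }
  }
  list(genotypes = genotype_matrix(dosage, miss), variants = vt)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT. Dosages are written against
#' the stored `ref`/`alt` alleles with `alt` as the counted (minor) allele:
#' 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, masked -> `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param variants variant table with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` (rows matching `gm$variant_ids`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, variants, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  variants <- variants[match(gm$variant_ids, variants$variant_id), ]
  if (any(is.na(variants$variant_id)))
    stop("variant table does not cover all genotype columns")
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  # records are written in input column order so that a write/read round
  # trip preserves variant order; coordinate-sort upstream if an indexed
  # workflow needs it
  for (j in seq_along(gm$variant_ids)) {
    g <- gt_code[gm$dosage[, j] + 1]
    g[gm$missing[, j]] <- "./."
    writeLines(paste(c(variants$chrom[j], variants$pos[j],
                       variants$variant_id[j], variants$ref[j],
                       variants$alt[j], ".", "PASS", ".", "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Plain-matrix TSV genotype exchange format
#'
#' A simple alternative to binary genotype containers: a tab-separated
#' table with samples in rows (first column `sample_id`) and variants in
#' columns, holding minor-allele dosages 0/1/2 with `NA` for missing
#' calls.
#'
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @return `path` (writer) or a `genotype_matrix` (reader).
#' @export
write_dosage_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  d[gm$missing] <- NA
  utils::write.table(data.frame(sample_id = gm$sample_ids, d,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be sample_id")
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$sample_id
  genotype_matrix(d)
}

#' Read a GMT gene-set file
#'
#' Tab-separated GMT: set id, description/display name, then member genes.
#' One set per non-empty line; duplicate members are deduplicated with a
#' warning; a line with fewer than three fields is an error.
#'
#' @param path GMT file path.
#' @param provenance provenance label stored on every set (default
#'   `"kegg_pathway"`; use `"literature_set"` for curated lists).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, provenance = "kegg_pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(short, collapse = ", "))
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  members <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(members, anyDuplicated, integer(1)) > 0
  if (any(dup))
    warning("duplicate members deduplicated in set(s): ",
            paste(ids[dup], collapse = ", "))
  names(members) <- ids
  gene_set_collection(members, display_name = desc, provenance = provenance)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(seq_along(gsc$sets), function(i)
    paste(c(gsc$info$set_id[i], gsc$info$display_name[i], gsc$sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' TSV with header. Requires `sample_id` and `status` ("case"/"control",
#' case-insensitive). `damage_index` (if present) is parsed as non-negative
#' integer with NA allowed; columns whose values are all in
#' \{TRUE, FALSE, 0, 1, NA\} are parsed as logical flags. Unknown columns are
#' carried through as opaque covariates. A duplicated sample row is an error.
#'
#' @param path TSV path.
#' @return A data.frame with typed columns.
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(cl)) stop("clinical table lacks sample_id")
  if (!"status" %in% names(cl)) stop("clinical table lacks status column")
  if (anyDuplicated(cl$sample_id))
    stop("duplicated sample row(s): ",
         paste(unique(cl$sample_id[duplicated(cl$sample_id)]), collapse = ", "))
  st <- tolower(trimws(cl$status))
  if (any(is.na(st)) || !all(st %in% c("case", "control")))
    stop("status must be 'case' or 'control' for every sample")
  cl$status <- st
  if ("damage_index" %in% names(cl)) {
    di <- suppressWarnings(as.integer(cl$damage_index))
    if (any(di < 0, na.rm = TRUE)) stop("damage_index must be non-negative")
    cl$damage_index <- di
  }
  for (nm in setdiff(names(cl), c("sample_id", "status", "damage_index"))) {
    v <- cl[[nm]]
    if (all(v %in% c("TRUE", "FALSE", "0", "1", TRUE, FALSE, 0, 1, NA))) {
      cl[[nm]] <- as.logical(ifelse(v %in% c("1", 1, TRUE, "TRUE"), TRUE,
                                    ifelse(v %in% c("0", 0, FALSE, "FALSE"),
                                           FALSE, NA)))
    }
  }
  cl
}

#' Read BED-like gene region definitions
#'
#' Columns: chrom, start, end, gene_id — BED convention, 0-based half-open.
#'
#' @param path file path (tab-separated, no header).
#' @return data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_regions <- function(path) {
  rg <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id"))
  if (any(rg$end <= rg$start)) stop("gene regions must satisfy end > start")
  rg
}

#' Assign variants to gene regions
#'
#' Annotates a variant table with `gene_id` by overlap with BED-like regions
#' (variant positions are VCF 1-based; regions 0-based half-open, so a
#' variant at `pos` overlaps a region iff `start < pos <= end`). A variant
#' overlapping several regions takes the first by file order; a variant
#' overlapping none keeps `gene_id = NA` and is thereby excluded from all
#' gene/pathway sets while remaining in single-variant analyses.
#'
#' @param variants variant table.
#' @param regions data.frame as from [read_gene_regions()].
#' @return The variant table with a `gene_id` column.
#' @export
assign_genes <- function(variants, regions) {
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  rr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(vr, rr, select = "first")
  variants$gene_id <- ifelse(is.na(hits), NA_character_,
                             regions$gene_id[hits])
  variants
}

#' Write a complete simulated-cohort fixture bundle
#'
#' Emits the on-disk representation of an in-memory cohort: a VCF of
#' genotypes, a GMT of gene sets, TSVs for the variant and clinical tables,
#' a BED-like gene-region file, and the flattened configuration used. The
#' round trip through the package readers reproduces the in-memory objects.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table.
#' @param genesets a [gene_set_collection()].
#' @param clinical clinical data.frame.
#' @param outdir output directory (created if absent).
#' @param config optional simulation config to record.
#' @param regions optional gene-region data.frame; derived from the variant
#'   table when omitted.
#' @return Named list of written file paths.
#' @export
write_fixture_bundle <- function(genotypes, variants, genesets, clinical,
                                 outdir, config = NULL, regions = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!setequal(clinical$sample_id, genotypes$sample_ids))
    stop("clinical table and genotype samples disagree")
  paths <- list(
    vcf = file.path(outdir, "cohort.vcf"),
    gmt = file.path(outdir, "genesets.gmt"),
    variants = file.path(outdir, "variants.tsv"),
    clinical = file.path(outdir, "clinical.tsv"),
    regions = file.path(outdir, "regions.bed"),
    config = file.path(outdir, "config.txt"))
  write_vcf_genotypes(genotypes, variants, paths$vcf)
  write_gmt(genesets, paths$gmt)
  utils::write.table(variants, paths$variants, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(clinical, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is.null(regions)) regions <- regions_from_variants(variants)
  utils::write.table(regions, paths$regions, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(config)) {
    flat <- flatten_config(config)
    writeLines(paste0(names(flat), "=", unlist(flat)), paths$config)
  } else {
    writeLines(character(0), paths$config)
  }
  paths
}

# derive minimal 0-based half-open regions spanning each gene's variants
regions_from_variants <- function(variants) {
  v <- variants[!is.na(variants$gene_id), ]
  if (nrow(v) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0)))
  sp <- split(v, v$gene_id)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(chrom = g$chrom[1], start = min(g$pos) - 1L,
               end = max(g$pos), gene_id = g$gene_id[1],
               stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

flatten_config <- function(config) {
  scalars <- Filter(function(x) is.atomic(x) && length(x) == 1, config)
  lapply(scalars, function(x) format(x, digits = 15))
}
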