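#' Pipeline configuration
#'
#' Collects the paths and stage parameters for an end-to-end run. Either
#' supply input paths (`vcf`, `gmt`, `regions`, `clinical`) or a
#' [sim_config()] via `simulate`, in which case the cohort is generated
#' and written under `outdir/simulated` first.
#'
#' @param outdir output directory.
#' @param vcf,gmt,regions,clinical input file paths (ignored when
#'   `simulate` is given). `variants` may point to a variant annotation
#'   TSV carrying gene/consequence/panel columns; otherwise annotation is
#'   derived from `regions`.
#' @param variants optional variant annotation TSV path.
#' @param simulate optional [sim_config()].
#' @param set_test a [set_test_config()].
#' @param fdr_threshold sequential-elimination selection threshold.
#' @param prs_alpha nominal significance threshold for PRS weights.
#' @param prs_percentile control percentile for pathway positivity.
#' @param ld_r2,ld_window_kb LD pruning parameters.
#' @param n_clusters number of patient clusters.
#' @param clinical_variables clinical columns compared across groups.
#' @param seed global seed recorded in the run manifest.
#' @param stages character vector of stages to run; subset of
#'   `c("assoc", "pathways", "eliminate", "prs", "stratify", "rare")`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, vcf = NULL, gmt = NULL, regions = NULL,
                            clinical = NULL, variants = NULL,
                            simulate = NULL,
                            set_test = set_test_config(),
                            fdr_threshold = 0.05, prs_alpha = 0.05,
                            prs_percentile = 97.5, ld_r2 = 0.2,
                            ld_window_kb = 500, n_clusters = 4,
                            clinical_variables = c("damage_index",
                                                   "SSA_or_SSB"),
                            seed = 1L,
                            stages = c("assoc", "pathways", "eliminate",
                                       "prs", "stratify", "rare")) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    for (p in c("vcf", "gmt", "clinical")) {
      if (is.null(cfg[[p]]))
        stop("pipeline config needs either `simulate` or a `", p, "` path")
      if (!file.exists(cfg[[p]]))
        stop("input path does not exist: ", cfg[[p]])
    }
    if (is.null(cfg$variants) && is.null(cfg$regions))
      stop("need `variants` annotation or `regions` for gene assignment")
  } else if (!inherits(cfg$simulate, "sim_config")) {
    stop("`simulate` must be a sim_config object")
  }
  invisible(cfg)
}

#' Read a flat key=value pipeline configuration file
#'
#' Recognised keys mirror the [pipeline_config()] arguments that are
#' scalars or paths; unknown keys are an error.
#'
#' @param path config file path.
#' @param outdir output directory (overrides any `outdir` key).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  args <- list()
  numeric_keys <- c("fdr_threshold", "prs_alpha", "prs_percentile",
                    "ld_r2", "ld_window_kb", "n_clusters", "seed")
  path_keys <- c("outdir", "vcf", "gmt", "regions", "clinical", "variants")
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% numeric_keys) args[[k]] <- as.numeric(vals[i])
    else if (k %in% path_keys) args[[k]] <- vals[i]
    else if (k == "stages")
      args[[k]] <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    else if (k == "clinical_variables")
      args[[k]] <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    else stop("unknown pipeline config key: ", k)
  }
  if (!is.null(outdir)) args$outdir <- outdir
  if (is.null(args$outdir)) stop("config must provide outdir")
  do.call(pipeline_config, args)
}

log_event <- function(con, stage, message, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, message = message), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message(sprintf("[%s] %s", stage, message))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> input parsing -> single-variant
#' association -> pathway/gene aggregate tests -> sequential elimination
#' -> pathway PRS and positivity -> normalisation, clustering and clinical
#' comparisons -> rare-variant reports. Each stage writes TSV outputs under
#' the configured `outdir`, a JSON-lines event log records progress, and a
#' manifest captures the seed, parameters and md5 hashes of all outputs.
#' A stage failure aborts with the failing stage named; outputs of earlier
#' stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return Named list (the manifest), invisibly written to
#'   `outdir/manifest.json`.
#' @export
run_full_pipeline <- function(config) {
  validate_pipeline_config(config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logcon <- file(file.path(outdir, "run_log.jsonl"), "w")
  on.exit(close(logcon))
  outputs <- list()
  stage <- "setup"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      log_event(logcon, stage, "generating synthetic cohort",
                seed = config$simulate$seed)
      cohort <- simulate_cohort(config$simulate)
      simdir <- file.path(outdir, "simulated")
      paths <- write_fixture_bundle(cohort$genotypes, cohort$variants,
                                    cohort$genesets, cohort$clinical,
                                    simdir, config = config$simulate)
      outputs$simulated <- unlist(paths)
      gm <- cohort$genotypes; variants <- cohort$variants
      clinical <- cohort$clinical; genesets <- cohort$genesets
    } else {
      stage <- "io"
      log_event(logcon, stage, "reading inputs", vcf = config$vcf)
      vr <- read_vcf_genotypes(config$vcf)
      gm <- vr$genotypes
      if (!is.null(config$variants)) {
        variants <- utils::read.delim(config$variants,
                                      stringsAsFactors = FALSE)
        validate_variant_table(variants)
      } else {
        variants <- assign_genes(vr$variants,
                                 read_gene_regions(config$regions))
      }
      clinical <- read_clinical_table(config$clinical)
      genesets <- read_gmt(config$gmt)
      common <- intersect(gm$sample_ids, clinical$sample_id)
      if (length(common) < length(gm$sample_ids))
        log_event(logcon, stage, "dropping genotyped samples without clinical data",
                  n_dropped = length(gm$sample_ids) - length(common))
      gm <- subset_genotypes(gm, samples = common)
    }

    sv <- NULL
    if ("assoc" %in% config$stages) {
      stage <- "assoc"
      log_event(logcon, stage, "single-variant association",
                n_variants = length(gm$variant_ids))
      sv <- single_variant_assoc(gm, clinical)
      outputs$single_variant <- write_tsv(sv,
        file.path(outdir, "single_variant_assoc.tsv"))
    }

    pw <- NULL
    if ("pathways" %in% config$stages) {
      stage <- "pathways"
      log_event(logcon, stage, "pathway and gene aggregate tests",
                n_sets = length(genesets))
      pw <- set_assoc(gm, variants, genesets, clinical,
                      config = config$set_test)
      outputs$pathway_assoc <- write_tsv(pw,
        file.path(outdir, "pathway_assoc.tsv"))
      ga <- gene_assoc(gm, variants, clinical, config = config$set_test)
      outputs$gene_assoc <- write_tsv(ga,
        file.path(outdir, "gene_assoc.tsv"))
    }

    if ("eliminate" %in% config$stages) {
      stage <- "eliminate"
      log_event(logcon, stage, "sequential pathway elimination")
      elim <- sequential_elimination(gm, variants, genesets, clinical,
                                     config = config$set_test,
                                     fdr_threshold = config$fdr_threshold)
      outputs$elimination <- write_tsv(elim,
        file.path(outdir, "sequential_elimination.tsv"))
    }

    prs <- NULL
    if ("prs" %in% config$stages) {
      stage <- "prs"
      if (is.null(sv)) sv <- single_variant_assoc(gm, clinical)
      pvals <- stats::setNames(sv$p_value, sv$unit_id)
      cand <- sv$unit_id[!is.na(sv$p_value)]
      pruned <- ld_prune(subset_genotypes(gm, variants = cand), variants,
                         pvals[cand], r2_threshold = config$ld_r2,
                         window_kb = config$ld_window_kb)
      weights <- build_prs_weights(sv, pruned, genesets, variants,
                                   alpha = config$prs_alpha)
      log_event(logcon, stage, "pathway PRS",
                n_weighted_variants = length(unique(weights$variant_id)))
      prs <- suppressWarnings(
        compute_pathway_prs(gm, weights,
                            pathway_ids = genesets$info$set_id))
      prs <- classify_positivity(prs, clinical,
                                 percentile = config$prs_percentile)
      outputs$prs_weights <- write_tsv(weights,
        file.path(outdir, "prs_weights.tsv"))
      outputs$prs_scores <- write_tsv(
        data.frame(sample_id = rownames(prs$scores), prs$scores,
                   check.names = FALSE),
        file.path(outdir, "prs_scores.tsv"))
      outputs$prs_positive <- write_tsv(
        data.frame(sample_id = rownames(prs$positive), prs$positive,
                   n_positive_pathways = prs$n_positive_pathways,
                   check.names = FALSE),
        file.path(outdir, "prs_positivity.tsv"))
    }

    if ("stratify" %in% config$stages && !is.null(prs)) {
      stage <- "stratify"
      log_event(logcon, stage, "normalisation, clustering, group tests")
      nz <- tryCatch(suppressWarnings(normalize_prs(prs, clinical)),
                     error = function(e) NULL)
      if (!is.null(nz)) {
        cases <- clinical$sample_id[clinical$status == "case"]
        ncase <- nz[intersect(rownames(nz), cases), , drop = FALSE]
        if (nrow(ncase) >= config$n_clusters) {
          cl <- cluster_patients(ncase, k = config$n_clusters)
          outputs$clusters <- write_tsv(cl,
            file.path(outdir, "cluster_assignments.tsv"))
          grp <- stats::setNames(cl$cluster, cl$sample_id)
          cmp <- compare_groups_clinical(grp, clinical,
                                         config$clinical_variables)
          outputs$cluster_clinical <- write_tsv(cmp,
            file.path(outdir, "cluster_clinical_tests.tsv"))
        }
        outputs$prs_case_control <- write_tsv(
          prs_case_control_test(prs, clinical),
          file.path(outdir, "prs_case_control.tsv"))
      }
    }

    if ("rare" %in% config$stages) {
      stage <- "rare"
      log_event(logcon, stage, "rare and case-only variant reports")
      burden <- per_individual_burden(gm, variants)
      outputs$burden <- write_tsv(
        data.frame(sample_id = names(burden),
                   rare_nonsyn_burden = as.integer(burden)),
        file.path(outdir, "rare_burden.tsv"))
      cat_all <- case_only_catalogue(gm, variants, clinical)
      outputs$case_only <- write_tsv(cat_all,
        file.path(outdir, "case_only_catalogue.tsv"))
      outputs$case_only_recurrent <- write_tsv(
        recurrent_case_only(cat_all),
        file.path(outdir, "case_only_recurrent.tsv"))
    }
    TRUE
  }, error = function(e) {
    log_event(logcon, stage, paste("stage failed:", conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("slepath")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(fdr_threshold = config$fdr_threshold,
                      prs_alpha = config$prs_alpha,
                      prs_percentile = config$prs_percentile,
                      ld_r2 = config$ld_r2,
                      ld_window_kb = config$ld_window_kb,
                      n_clusters = config$n_clusters),
    outputs = lapply(outputs, function(p)
      list(path = unname(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_event(logcon, "done", "pipeline complete",
            n_outputs = length(outputs))
  invisible(manifest)
}
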