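#' Control-standardised pathway PRS matrix
#'
#' Standardises each pathway's scores against the control distribution:
#' subtract the control mean and divide by the control standard deviation.
#' Zero-variance pathways are dropped with a warning; if every pathway has
#' zero control variance this is an error.
#'
#' @param prs a [compute_pathway_prs()] result (or a plain samples x
#'   pathways matrix).
#' @param clinical clinical table with `sample_id` and `status`; controls
#'   must be non-empty.
#' @return Numeric matrix of normalised scores (all samples x retained
#'   pathways).
#' @export
normalize_prs <- function(prs, clinical) {
  scores <- if (inherits(prs, "pathway_prs")) prs$scores else as.matrix(prs)
  ctrl <- clinical$sample_id[clinical$status == "control"]
  ctrl <- intersect(ctrl, rownames(scores))
  if (length(ctrl) == 0) stop("control group is empty")
  mu <- colMeans(scores[ctrl, , drop = FALSE])
  sd <- apply(scores[ctrl, , drop = FALSE], 2, stats::sd)
  drop <- !is.finite(sd) | sd == 0
  if (all(drop)) stop("all pathways have zero control variance")
  if (any(drop))
    warning("dropping zero-variance pathway(s): ",
            paste(colnames(scores)[drop], collapse = ", "), call. = FALSE)
  sweep(sweep(scores[, !drop, drop = FALSE], 2, mu[!drop], `-`),
        2, sd[!drop], `/`)
}

#' Hierarchical clustering of patients on pathway risk profiles
#'
#' Agglomerative clustering of the (typically control-normalised) pathway
#' PRS matrix, cut to exactly `k` clusters. Default is Ward linkage on
#' Euclidean distances. Cluster labels are renumbered by descending
#' cluster size (ties by first occurrence) for reproducible reporting; the
#' tree itself is deterministic given the input order.
#'
#' @param x numeric matrix, samples x pathways (e.g. the case rows of
#'   [normalize_prs()]).
#' @param k number of clusters (default 4); must not exceed the number of
#'   samples.
#' @param linkage `"ward"` (Ward's criterion on squared Euclidean
#'   distances, i.e. `hclust` method `ward.D2`), or any method name
#'   `stats::hclust` accepts.
#' @param metric distance metric for `stats::dist` (default
#'   `"euclidean"`).
#' @return data.frame of class `cluster_assignment`: `sample_id`,
#'   `cluster` (integer in 1..k). The dendrogram and parameters are
#'   attached as attributes `tree`, `k`, `linkage`, `metric`.
#' @export
cluster_patients <- function(x, k = 4, linkage = "ward",
                             metric = "euclidean") {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in score matrix")
  if (nrow(x) < k) stop("k exceeds the number of samples")
  method <- if (identical(linkage, "ward")) "ward.D2" else linkage
  tree <- stats::hclust(stats::dist(x, method = metric), method = method)
  raw <- stats::cutree(tree, k = k)
  # relabel by descending size, ties by first occurrence
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_len(k), names(sizes)[ord])
  lab <- unname(relabel[as.character(raw)])
  out <- data.frame(sample_id = rownames(x), cluster = lab,
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "k") <- k
  attr(out, "linkage") <- method
  attr(out, "metric") <- metric
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Compare clinical variables across patient groups
#'
#' Nonparametric group comparisons with a family-wise Bonferroni
#' threshold: two groups with an ordinal/continuous variable use the
#' Mann-Whitney U test; more than two groups use Kruskal-Wallis;
#' categorical variables use the chi-square test (Fisher's exact test when
#' any expected cell is below 5). Raw p-values are reported together with
#' the Bonferroni threshold `0.05 / family_size` and a
#' significant-at-threshold flag. A variable constant within the compared
#' samples is reported with p = 1 and a note.
#'
#' @param groups named vector (names = sample ids) or two-column
#'   data.frame (`sample_id`, group) assigning each sample to a group;
#'   at least two non-empty groups required.
#' @param clinical clinical table containing the variables.
#' @param variables character vector of clinical column names to test.
#' @param family_size size of the test family defining the Bonferroni
#'   threshold (default: `length(variables)`). E.g. a 35-pathway family
#'   gives 0.05 / 35.
#' @return data.frame: `variable`, `test`, `statistic`, `p_value`,
#'   `bonferroni_threshold`, `significant`, `note`.
#' @export
compare_groups_clinical <- function(groups, clinical, variables,
                                    family_size = length(variables)) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups[[2]], groups[[1]])
  ids <- intersect(names(groups), clinical$sample_id)
  if (length(ids) == 0) stop("no overlap between groups and clinical table")
  g <- factor(groups[ids])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least two non-empty groups")
  cl <- clinical[match(ids, clinical$sample_id), ]
  thr <- 0.05 / family_size
  rows <- lapply(variables, function(v) {
    if (!v %in% names(cl)) stop("unknown clinical variable: ", v)
    x <- cl[[v]]
    keep <- !is.na(x)
    xv <- x[keep]; gv <- droplevels(g[keep])
    note <- NA_character_
    if (length(xv) == 0 || nlevels(gv) < 2) {
      return(data.frame(variable = v, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        bonferroni_threshold = thr, significant = FALSE,
                        note = "insufficient data",
                        stringsAsFactors = FALSE))
    }
    if (length(unique(xv)) < 2) {
      return(data.frame(variable = v, test = "none",
                        statistic = NA_real_, p_value = 1,
                        bonferroni_threshold = thr, significant = FALSE,
                        note = "constant variable",
                        stringsAsFactors = FALSE))
    }
    if (is.numeric(xv) && !is.factor(xv)) {
      if (nlevels(gv) == 2) {
        tst <- suppressWarnings(
          stats::wilcox.test(xv ~ gv, exact = FALSE))
        test <- "mann-whitney"
      } else {
        tst <- stats::kruskal.test(xv, gv)
        test <- "kruskal-wallis"
      }
      stat <- unname(tst$statistic); p <- tst$p.value
    } else {
      tab <- table(factor(xv), gv)
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 5)) {
        tst <- stats::fisher.test(tab)
        test <- "fisher"; stat <- NA_real_
      } else {
        tst <- stats::chisq.test(tab, correct = FALSE)
        test <- "chi-square"; stat <- unname(tst$statistic)
      }
      p <- tst$p.value
    }
    data.frame(variable = v, test = test, statistic = stat, p_value = p,
               bonferroni_threshold = thr,
               significant = is.finite(p) && p < thr, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-pathway case vs control PRS comparison
#'
#' Mann-Whitney U test of pathway PRS between cases and controls, one test
#' per pathway, with Benjamini-Hochberg q-values across pathways.
#'
#' @param prs a [compute_pathway_prs()] result.
#' @param clinical clinical table with `sample_id` and `status`.
#' @return data.frame: `pathway_id`, `statistic`, `p_value`, `fdr_q`.
#' @export
prs_case_control_test <- function(prs, clinical) {
  scores <- prs$scores
  st <- clinical$status[match(rownames(scores), clinical$sample_id)]
  if (length(unique(st)) < 2) stop("need both cases and controls")
  res <- lapply(colnames(scores), function(p) {
    x <- scores[, p]
    if (length(unique(x)) < 2)
      return(data.frame(pathway_id = p, statistic = NA_real_, p_value = 1,
                        stringsAsFactors = FALSE))
    tst <- suppressWarnings(stats::wilcox.test(x[st == "case"],
                                               x[st == "control"],
                                               exact = FALSE))
    data.frame(pathway_id = p, statistic = unname(tst$statistic),
               p_value = tst$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_q <- bh_fdr(out$p_value)
  out
}
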