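# Fisher-based TF binding-site enrichment over a unit background (extended
# array probes or bisulfite tiles), the sample-category ("categorized
# catalog") variant, cross-platform validation, pairwise co-localization and
# binding-site methylation summaries.

#' One-sided Fisher's exact test (enrichment)
#'
#' P(X >= a) under the hypergeometric distribution with the margins of the
#' 2x2 table fixed, i.e. the classical one-sided Fisher test with
#' alternative "greater" for the top-left cell.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = target and bound,
#'   `b` = target not bound, `c` = bound outside target, `d` = the rest.
#' @return One-sided p-value.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' TF binding-site enrichment in a target unit set
#'
#' For each transcription factor in the catalog, a one-sided Fisher test on
#' the 2x2 table of background units cross-classified by membership in the
#' target set and by TF binding (>= 1 bp overlap with any site of that TF).
#' P-values are BH-adjusted across the TFs of the run. TFs with no site on
#' the genome are omitted with a warning.
#'
#' @param target_units `GRanges`, a subset (by coordinate identity) of
#'   `background_units`.
#' @param background_units `GRanges` of all units (extended probes or tiles).
#' @param catalog `GRanges` of binding sites with metadata `tf` (and
#'   optionally `category`).
#' @param category A category label to subset the catalog, or `"all"`.
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return `data.frame` with tf, category, a, b, c, d, p, adj_p, significant.
#' @export
enrich_tf_sets <- function(target_units, background_units, catalog,
                           category = "all", alpha = 0.05) {
  tk <- interval_key(target_units); bk <- interval_key(background_units)
  if (!all(tk %in% bk)) stop("target units must be a subset of the background")
  in_target <- bk %in% tk
  if (category != "all")
    catalog <- catalog[S4Vectors::mcols(catalog)$category == category]
  tfs <- sort(unique(as.character(S4Vectors::mcols(catalog)$tf)))
  rows <- lapply(tfs, function(tf) {
    sites <- catalog[S4Vectors::mcols(catalog)$tf == tf]
    if (length(sites) == 0) return(NULL)
    bound <- GenomicRanges::countOverlaps(background_units, sites,
                                          ignore.strand = TRUE) > 0
    if (!any(bound)) { warning("TF ", tf, " has no site on the genome; omitted")
      return(NULL) }
    a <- sum(in_target & bound); b <- sum(in_target & !bound)
    cc <- sum(!in_target & bound); d <- sum(!in_target & !bound)
    data.frame(tf = tf, category = category, a = a, b = b, c = cc, d = d,
               p = fisher_one_sided(a, b, cc, d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(tf = character(), category = character(),
                                      a = integer(), b = integer(), c = integer(),
                                      d = integer(), p = numeric(),
                                      adj_p = numeric(), significant = logical()))
  res$adj_p <- adjust_bh(res$p)
  res$significant <- res$adj_p < alpha
  res
}

#' Cross-platform validation of enriched TFs
#'
#' A TF is validated for a (cancer, direction) region class when it is
#' significantly enriched in the analogous class on both platforms.
#'
#' @param results_array,results_tiles Named lists (one element per
#'   (cancer, direction) class) of [enrich_tf_sets()] tables.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Named list of validated TF name vectors, one per shared class.
#' @export
validate_across_platforms <- function(results_array, results_tiles,
                                      alpha = 0.05) {
  shared <- intersect(names(results_array), names(results_tiles))
  out <- lapply(shared, function(k) {
    sa <- results_array[[k]]; st <- results_tiles[[k]]
    intersect(sa$tf[sa$adj_p < alpha], st$tf[st$adj_p < alpha])
  })
  stats::setNames(out, shared)
}

#' Categorized TF enrichment
#'
#' Runs the enrichment once per sample-category subset of the binding-site
#' catalog (the categorized-catalog analysis). (TF, category) pairs with no
#' measured site in that category are flagged `measured = FALSE` rather than
#' tested.
#'
#' @inheritParams enrich_tf_sets
#' @param categories Category labels to test; defaults to all labels in the
#'   catalog.
#' @return `data.frame` as [enrich_tf_sets()] plus a `measured` flag, with
#'   one row per (TF, category) pair.
#' @export
categorized_enrichment <- function(target_units, background_units, catalog,
                                   categories = NULL, alpha = 0.05) {
  all_tfs <- sort(unique(as.character(S4Vectors::mcols(catalog)$tf)))
  if (is.null(categories))
    categories <- sort(unique(as.character(S4Vectors::mcols(catalog)$category)))
  out <- lapply(categories, function(cat) {
    res <- suppressWarnings(
      enrich_tf_sets(target_units, background_units, catalog, cat, alpha))
    res$measured <- TRUE
    missing_tfs <- setdiff(all_tfs, res$tf)
    if (length(missing_tfs))
      res <- rbind(res, data.frame(tf = missing_tfs, category = cat,
                                   a = NA_integer_, b = NA_integer_,
                                   c = NA_integer_, d = NA_integer_,
                                   p = NA_real_, adj_p = NA_real_,
                                   significant = NA, measured = FALSE))
    res
  })
  do.call(rbind, out)
}

#' Pairwise TF co-localization matrix
#'
#' For each unordered TF pair, target regions are cross-classified by
#' binding of the two TFs (both, only first, only second, neither) and
#' co-occurrence is tested with a one-sided Fisher test; BH correction is
#' applied over the unique pairs and the adjusted p-values are mirrored into
#' a symmetric matrix with zero diagonal.
#'
#' @param tf_names TFs to test pairwise (>= 2).
#' @param target_regions `GRanges` of target regions.
#' @param catalog Binding-site `GRanges` with metadata `tf`.
#' @return List with `adj_p` (symmetric matrix) and `p` (raw, symmetric).
#' @export
colocalization_matrix <- function(tf_names, target_regions, catalog) {
  if (length(tf_names) < 2) stop("need at least 2 TFs")
  bound <- vapply(tf_names, function(tf)
    GenomicRanges::countOverlaps(
      target_regions, catalog[S4Vectors::mcols(catalog)$tf == tf],
      ignore.strand = TRUE) > 0,
    logical(length(target_regions)))
  k <- length(tf_names)
  pm <- matrix(NA_real_, k, k, dimnames = list(tf_names, tf_names))
  pairs <- which(upper.tri(pm), arr.ind = TRUE)
  praw <- apply(pairs, 1, function(ij) {
    x <- bound[, ij[1]]; y <- bound[, ij[2]]
    fisher_one_sided(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  })
  padj <- adjust_bh(praw)
  pm[upper.tri(pm)] <- praw; pm <- pmin(pm, t(pm), na.rm = TRUE)
  am <- matrix(NA_real_, k, k, dimnames = list(tf_names, tf_names))
  am[upper.tri(am)] <- padj; am <- pmin(am, t(am), na.rm = TRUE)
  diag(pm) <- 0; diag(am) <- 0
  list(p = pm, adj_p = am)
}

#' Methylation near the binding sites of one TF
#'
#' Selects probes at most `max_gap` bp from any binding site of the TF
#' (boundary inclusive) and aggregates their beta values probewise by the
#' mean within each sample group, for violin-style summaries.
#'
#' @param probe_se `RangedSummarizedExperiment` with a `beta` assay and
#'   `group` in `colData`.
#' @param catalog Binding-site `GRanges` with metadata `tf`.
#' @param tf TF name (must exist in the catalog).
#' @param max_gap Maximum probe-to-site gap in bp (default 500).
#' @return `data.frame` with probe index, group, and mean beta; zero rows
#'   (with a warning) when no probe is near any site.
#' @export
binding_site_methylation <- function(probe_se, catalog, tf, max_gap = 500) {
  sites <- catalog[S4Vectors::mcols(catalog)$tf == tf]
  if (length(sites) == 0) stop("TF not in catalog: ", tf)
  probes <- SummarizedExperiment::rowRanges(probe_se)
  dtn <- GenomicRanges::distanceToNearest(probes, sites, ignore.strand = TRUE)
  sel <- S4Vectors::queryHits(dtn)[S4Vectors::mcols(dtn)$distance <= max_gap]
  if (length(sel) == 0) {
    warning("no probes within ", max_gap, " bp of any ", tf, " site")
    return(data.frame(probe = integer(), group = character(), beta = numeric()))
  }
  beta <- SummarizedExperiment::assay(probe_se, "beta")[sel, , drop = FALSE]
  groups <- as.character(SummarizedExperiment::colData(probe_se)$group)
  out <- lapply(unique(groups), function(g)
    data.frame(probe = sel, group = g,
               beta = rowMeans(beta[, groups == g, drop = FALSE], na.rm = TRUE)))
  do.call(rbind, out)
}

#' Clusterwise TF enrichment
#'
#' Enrichment run per k-means cluster of the cancer-specific DMRs: the
#' target units of a cluster are the background units overlapping that
#' cluster's regions, and BH correction is applied within each cluster's
#' run.
#'
#' @param regions `GRanges` of DMR regions.
#' @param cluster_labels Integer cluster label per region.
#' @param background_units `GRanges` of all (autosomal) units.
#' @param catalog Binding-site `GRanges` with metadata `tf`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return `data.frame` as [enrich_tf_sets()] plus a `cluster` column.
#' @export
clusterwise_enrichment <- function(regions, cluster_labels, background_units,
                                   catalog, alpha = 0.05) {
  if (length(cluster_labels) != length(regions))
    stop("one label per region required")
  out <- lapply(sort(unique(cluster_labels)), function(cl) {
    target <- subset_by_overlap(background_units, regions[cluster_labels == cl])
    if (length(target) == 0) return(NULL)
    res <- suppressWarnings(
      enrich_tf_sets(target, background_units, catalog, alpha = alpha))
    if (nrow(res)) res$cluster <- cl
    res
  })
  do.call(rbind, out)
}
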