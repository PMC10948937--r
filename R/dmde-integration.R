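# Methylation-expression integration: differential expression (simplified
# per-gene test), DMR-to-gene linking through promoters, enhancers and
# genomic neighborhoods, cross-platform validation, the TAD-boundary filter,
# and DM-DE classification.

#' Call differentially expressed genes
#'
#' Per-gene two-group Welch t-test on log-scale expression, a light stand-in
#' for the moderated/negative-binomial models used on real cohorts.
#' Sequencing-type counts are library-size normalized to log2 counts per
#' million first; array-type input is assumed log2 already. Rows sharing a
#' gene name (multi-probe genes) are collapsed by their mean before testing.
#' Significant genes have BH-adjusted p below `max_adj_p` and
#' |log2 fold change| of at least `min_abs_lfc`.
#'
#' @param expr Numeric matrix, genes x samples; row names are gene symbols.
#' @param groups Group label per column.
#' @param comparison Ordered group pair (log2FC is group1 - group2).
#' @param platform `"array"` (log-intensity input) or `"seq"` (count input).
#' @param max_adj_p Adjusted-p threshold (default 0.05; the stricter 0.01
#'   preset matches the headline analysis).
#' @param min_abs_lfc Minimum |log2FC| (default 1).
#' @return `data.frame` with gene, log2fc, p, adj_p, significant, platform,
#'   comparison.
#' @export
call_de_genes <- function(expr, groups, comparison,
                          platform = c("array", "seq"),
                          max_adj_p = 0.05, min_abs_lfc = 1) {
  platform <- match.arg(platform)
  groups <- as.character(groups)
  if (platform == "seq") {
    cpm <- t(t(expr) / pmax(1, colSums(expr))) * 1e6
    expr <- log2(cpm + 1)
  }
  if (anyDuplicated(rownames(expr))) {
    expr <- rowsum(expr, rownames(expr)) /
      as.vector(table(rownames(expr))[unique(rownames(expr))])
    expr <- expr[order(rownames(expr)), , drop = FALSE]
  }
  idx1 <- which(groups == comparison[1]); idx2 <- which(groups == comparison[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("each group needs at least 2 samples")
  tw <- row_welch(expr, idx1, idx2)
  adj <- adjust_bh(tw$p)
  data.frame(gene = rownames(expr), log2fc = tw$diff, p = tw$p, adj_p = adj,
             significant = adj < max_adj_p & abs(tw$diff) >= min_abs_lfc,
             platform = platform,
             comparison = paste(comparison, collapse = "_vs_"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build transcript promoters
#'
#' Promoter of a transcript: `up` bp upstream to `down` bp downstream of the
#' TSS, strand-aware, clipped at the chromosome origin. Unknown strands are
#' treated as `+` with a warning.
#'
#' @param gene_models `data.frame` with columns gene, transcript, chrom,
#'   tss (1-based position of the first transcribed base), strand.
#' @param up,down Extent in bp (defaults 2000 and 500).
#' @return `GRanges` with metadata gene, transcript.
#' @export
build_promoters <- function(gene_models, up = 2000, down = 500) {
  strand <- gene_models$strand
  if (any(!strand %in% c("+", "-"))) {
    warning("unknown strand treated as '+'")
    strand[!strand %in% c("+", "-")] <- "+"
  }
  tss <- gene_models$tss
  start <- ifelse(strand == "+", tss - up, tss - down)
  end <- ifelse(strand == "+", tss + down - 1, tss + up - 1)
  GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(pmax(1L, as.integer(start)), as.integer(end)),
    strand = strand, gene = gene_models$gene,
    transcript = gene_models$transcript)
}

#' Link DMRs to genes through a regulatory mode
#'
#' * `promoter`: the DMR overlaps (>= 1 bp) a transcript promoter;
#' * `enhancer`: the DMR overlaps an enhancer linked to the gene, with
#'   genehancer-like links pre-filtered to confidence >= `min_confidence`
#'   (fantom-like links carry no confidence filter);
#' * `neighborhood`: the DMR lies within +/- `neighborhood` bp of a TSS.
#'
#' @param dmrs `GRanges` of DMRs with metadata `direction` (and anything
#'   else, carried along by index).
#' @param gene_models `data.frame` as in [build_promoters()].
#' @param enhancers `data.frame` with chrom, start, end (1-based closed),
#'   gene, source (`"fantom"`/`"genehancer"`), confidence. May be `NULL`
#'   for non-enhancer modes.
#' @param mode One of `"promoter"`, `"enhancer"`, `"neighborhood"`.
#' @param neighborhood Half-width of the TSS neighborhood (default 200000).
#' @param min_confidence GeneHancer-like confidence cutoff (default 5).
#' @return `data.frame` with gene, transcript (NA for enhancer mode), mode,
#'   dmr (index into `dmrs`), dmr coordinates, direction, tss.
#' @export
link_dmrs_to_genes <- function(dmrs, gene_models, enhancers = NULL,
                               mode = c("promoter", "enhancer", "neighborhood"),
                               neighborhood = 200000, min_confidence = 5) {
  mode <- match.arg(mode)
  empty <- data.frame(gene = character(), transcript = character(),
                      mode = character(), dmr = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      direction = character(), tss = integer(),
                      stringsAsFactors = FALSE)
  pairs <- switch(mode,
    promoter = {
      prom <- build_promoters(gene_models)
      h <- GenomicRanges::findOverlaps(dmrs, prom, ignore.strand = TRUE)
      if (!length(h)) return(empty)
      j <- S4Vectors::subjectHits(h)
      data.frame(gene = prom$gene[j], transcript = prom$transcript[j],
                 dmr = S4Vectors::queryHits(h),
                 tss = gene_models$tss[j], stringsAsFactors = FALSE)
    },
    enhancer = {
      keep <- enhancers$source != "genehancer" |
        enhancers$confidence >= min_confidence
      enh <- enhancers[keep, , drop = FALSE]
      if (!nrow(enh)) return(empty)
      egr <- GenomicRanges::GRanges(enh$chrom,
                                    IRanges::IRanges(enh$start, enh$end))
      h <- GenomicRanges::findOverlaps(dmrs, egr, ignore.strand = TRUE)
      if (!length(h)) return(empty)
      j <- S4Vectors::subjectHits(h)
      tss_of <- gene_models$tss[match(enh$gene[j], gene_models$gene)]
      data.frame(gene = enh$gene[j], transcript = NA_character_,
                 dmr = S4Vectors::queryHits(h), tss = tss_of,
                 stringsAsFactors = FALSE)
    },
    neighborhood = {
      tss1 <- gene_models$tss
      win <- GenomicRanges::GRanges(
        gene_models$chrom,
        IRanges::IRanges(pmax(1L, as.integer(tss1 - neighborhood)),
                         as.integer(tss1 + neighborhood - 1)))
      h <- GenomicRanges::findOverlaps(dmrs, win, ignore.strand = TRUE)
      if (!length(h)) return(empty)
      j <- S4Vectors::subjectHits(h)
      data.frame(gene = gene_models$gene[j],
                 transcript = gene_models$transcript[j],
                 dmr = S4Vectors::queryHits(h), tss = tss1[j],
                 stringsAsFactors = FALSE)
    })
  pairs <- unique(pairs)
  i <- pairs$dmr
  data.frame(gene = pairs$gene, transcript = pairs$transcript, mode = mode,
             dmr = i, chrom = as.character(GenomicRanges::seqnames(dmrs))[i],
             start = GenomicRanges::start(dmrs)[i],
             end = GenomicRanges::end(dmrs)[i],
             direction = as.character(dmrs$direction)[i], tss = pairs$tss,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-platform validation of gene-DMR pairs
#'
#' An array pair (gene, DMR) is validated when the tile platform links a
#' same-direction DMR to the same gene within `max_gap` bp of the array DMR
#' (boundary inclusive; overlapping DMRs have gap 0), and vice versa.
#'
#' @param pairs_array,pairs_tiles Pair tables from [link_dmrs_to_genes()]
#'   for the same comparison.
#' @param max_gap Maximum bp gap between the two platforms' DMRs
#'   (default 5000).
#' @return The validated rows of both tables, combined, with a `platform`
#'   column.
#' @export
cross_platform_validate <- function(pairs_array, pairs_tiles, max_gap = 5000) {
  gr <- function(p) GenomicRanges::GRanges(p$chrom,
                                           IRanges::IRanges(p$start, p$end))
  validate <- function(p, q) {
    if (!nrow(p) || !nrow(q)) return(p[0, , drop = FALSE])
    keep <- logical(nrow(p))
    gp <- gr(p); gq <- gr(q)
    h <- GenomicRanges::findOverlaps(gp, gq, maxgap = max_gap,
                                     ignore.strand = TRUE)
    if (length(h)) {
      i <- S4Vectors::queryHits(h); j <- S4Vectors::subjectHits(h)
      ok <- p$gene[i] == q$gene[j] & p$direction[i] == q$direction[j]
      keep[unique(i[ok])] <- TRUE
    }
    p[keep, , drop = FALSE]
  }
  va <- validate(pairs_array, pairs_tiles)
  vt <- validate(pairs_tiles, pairs_array)
  if (nrow(va)) va$platform <- "array"
  if (nrow(vt)) vt$platform <- "tiles"
  out <- rbind(va, vt)
  if (!nrow(out)) out$platform <- character(0)
  out
}

#' TAD-boundary filter on TSS-DMR spans
#'
#' For each (transcript TSS, DMR) pair, counts TAD boundaries (TAD starts
#' and ends) strictly inside the open span between the TSS and the DMR edge
#' closest to it, in every supplied TAD set. In `"literal"` mode a gene is
#' retained only when none of its pairs contains a boundary in any TAD set;
#' `"any_pair"` mode retains a gene with at least one boundary-free pair.
#'
#' @param pairs Pair table from [link_dmrs_to_genes()] /
#'   [cross_platform_validate()].
#' @param tad_sets Named list of `GRanges` TAD sets (e.g. five cell types).
#' @param mode `"literal"` (default) or `"any_pair"`.
#' @return List with `pairs` (input plus `n_boundaries`) and `genes`
#'   (retained gene names).
#' @export
tad_boundary_filter <- function(pairs, tad_sets, mode = c("literal", "any_pair")) {
  mode <- match.arg(mode)
  if (!length(tad_sets)) stop("at least one TAD set required")
  if (!nrow(pairs)) return(list(pairs = pairs, genes = character()))
  near_edge <- ifelse(pairs$start > pairs$tss, pairs$start,
                      ifelse(pairs$end < pairs$tss, pairs$end, pairs$tss))
  lo <- pmin(pairs$tss, near_edge); hi <- pmax(pairs$tss, near_edge)
  nb <- integer(nrow(pairs))
  for (tads in tad_sets) {
    tchr <- as.character(GenomicRanges::seqnames(tads))
    bpos <- c(GenomicRanges::start(tads), GenomicRanges::end(tads))
    bchr <- c(tchr, tchr)
    for (ch in unique(pairs$chrom)) {
      pb <- sort(bpos[bchr == ch])
      if (!length(pb)) next
      ri <- which(pairs$chrom == ch)
      # boundaries strictly inside the open span (touching endpoints ignored)
      nb[ri] <- nb[ri] + (findInterval(hi[ri] - 1L, pb) -
                            findInterval(lo[ri], pb))
    }
  }
  pairs$n_boundaries <- nb
  genes <- if (mode == "literal") {
    setdiff(unique(pairs$gene), unique(pairs$gene[nb > 0]))
  } else {
    unique(pairs$gene[nb == 0])
  }
  list(pairs = pairs, genes = sort(genes))
}

#' Classify DM-DE genes
#'
#' Keeps genes differentially expressed with the same sign on both
#' expression platforms, then classifies each (gene, comparison) by the
#' relation between the linked DMRs' methylation direction and the
#' expression change: `opposite` when every supporting DMR changes against
#' the expression sign (the DM-DE genes), `parallel` when every DMR changes
#' with it, `mixed` (excluded from both lists) otherwise.
#'
#' @param validated_pairs Pair table from [cross_platform_validate()]
#'   (any number of modes, `rbind`-ed).
#' @param de_array,de_seq DE tables from [call_de_genes()] for the same
#'   comparison.
#' @return `data.frame` with gene, comparison, relation, modes, n_dmrs,
#'   log2fc (array platform).
#' @export
classify_dm_de <- function(validated_pairs, de_array, de_seq) {
  sa <- de_array[de_array$significant, ]
  ss <- de_seq[de_seq$significant, ]
  genes <- intersect(sa$gene, ss$gene)
  genes <- genes[sign(sa$log2fc[match(genes, sa$gene)]) ==
                   sign(ss$log2fc[match(genes, ss$gene)])]
  vp <- validated_pairs[validated_pairs$gene %in% genes, , drop = FALSE]
  if (!nrow(vp))
    return(data.frame(gene = character(), comparison = character(),
                      relation = character(), modes = character(),
                      n_dmrs = integer(), log2fc = numeric(),
                      stringsAsFactors = FALSE))
  cmp <- unique(de_array$comparison)
  out <- lapply(unique(vp$gene), function(g) {
    rows <- vp[vp$gene == g, , drop = FALSE]
    lfc <- sa$log2fc[match(g, sa$gene)]
    dm_sign <- ifelse(rows$direction == "hyper", 1, -1)
    rel <- if (all(dm_sign == -sign(lfc))) "opposite"
      else if (all(dm_sign == sign(lfc))) "parallel" else "mixed"
    data.frame(gene = g, comparison = cmp, relation = rel,
               modes = paste(sort(unique(rows$mode)), collapse = "+"),
               n_dmrs = length(unique(paste(rows$chrom, rows$start, rows$end))),
               log2fc = lfc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
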