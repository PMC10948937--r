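# Two-platform DMR calling, control filtering and cancer-specific extraction.
#
# A DMRSet bundles the called regions, the member units (probes or tiles)
# backing each region, and the platform/comparison labels that the
# downstream overlap rules key on.

#' Construct a DMRSet
#'
#' @param regions `GRanges` with metadata `delta_beta`, `q`, `direction`
#'   (`"hyper"`/`"hypo"` with respect to the first group of the comparison)
#'   and `n_units`.
#' @param units `GRanges` of member probes/tiles with a `region` index into
#'   `regions` and the region-level `delta_beta` copied onto each unit.
#' @param platform `"array"` or `"tiles"`.
#' @param comparison Character vector of length 2, ordered group pair.
#' @return An object of class `DMRSet`.
#' @export
dmr_set <- function(regions, units, platform, comparison) {
  structure(list(regions = regions, units = units,
                 platform = match.arg(platform, c("array", "tiles")),
                 comparison = comparison),
            class = "DMRSet")
}

#' @export
print.DMRSet <- function(x, ...) {
  cat(sprintf("DMRSet: %d regions (%s, %s vs %s; %d hyper / %d hypo)\n",
              length(x$regions), x$platform, x$comparison[1], x$comparison[2],
              sum(x$regions$direction == "hyper"),
              sum(x$regions$direction == "hypo")))
  invisible(x)
}

#' @export
length.DMRSet <- function(x) length(x$regions)

#' Call DMRs on bisulfite-sequencing tiles
#'
#' Per-tile two-group comparison of methylation proportions from
#' (methylated, total) read counts in 1,000-bp tiles. Tiles with any sample
#' below `min_coverage` reads, or lying outside the canonical autosomes
#' (scaffolds, sex chromosomes, mitochondria), are removed before testing.
#' The test is a two-proportion z-test on pooled counts whose variance is
#' inflated by a method-of-moments overdispersion factor
#' phi = max(1, Pearson chi-square / df) estimated across samples, and
#' referred to a t distribution with n1 + n2 - 2 degrees of freedom to
#' account for phi being estimated. P-values are BH-adjusted across tiles;
#' tiles with q < `max_q` and |delta beta| >= `min_delta` are reported as
#' single-tile DMRs.
#'
#' @param tile_se `RangedSummarizedExperiment` with `meth` and `total`
#'   count assays and a `group` column in `colData`.
#' @param comparison Character vector of length 2: groups to compare
#'   (direction is with respect to the first).
#' @param min_coverage Minimum reads per sample per tile (default 10).
#' @param min_delta Minimum |delta beta| (default 0.25).
#' @param max_q FDR threshold (default 0.05).
#' @param canonical Chromosomes retained (default `chr1`..`chr22`).
#' @param all_tested Also return the per-tile test table (for calibration
#'   checks).
#' @return A `DMRSet` (platform `"tiles"`); with `all_tested = TRUE`, a list
#'   with elements `dmrs` and `tests`.
#' @export
call_dmrs_tiles <- function(tile_se, comparison, min_coverage = 10,
                            min_delta = 0.25, max_q = 0.05,
                            canonical = paste0("chr", 1:22),
                            all_tested = FALSE) {
  groups <- as.character(SummarizedExperiment::colData(tile_se)$group)
  idx1 <- which(groups == comparison[1]); idx2 <- which(groups == comparison[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("each group needs at least 2 samples")
  tiles <- SummarizedExperiment::rowRanges(tile_se)
  meth <- SummarizedExperiment::assay(tile_se, "meth")[, c(idx1, idx2), drop = FALSE]
  total <- SummarizedExperiment::assay(tile_se, "total")[, c(idx1, idx2), drop = FALSE]
  i1 <- seq_along(idx1); i2 <- length(idx1) + seq_along(idx2)

  keep <- is_canonical(tiles, canonical) & rowSums(total < min_coverage) == 0
  tiles <- tiles[keep]; meth <- meth[keep, , drop = FALSE]
  total <- total[keep, , drop = FALSE]
  empty <- dmr_set(interval_set("chr1", 1, 1)[0], interval_set("chr1", 1, 1)[0],
                   "tiles", comparison)
  S4Vectors::mcols(empty$regions) <- S4Vectors::DataFrame(
    delta_beta = numeric(0), q = numeric(0), direction = character(0),
    n_units = integer(0))
  if (nrow(meth) == 0) return(if (all_tested) list(dmrs = empty, tests = NULL) else empty)

  M1 <- rowSums(meth[, i1, drop = FALSE]); N1 <- rowSums(total[, i1, drop = FALSE])
  M2 <- rowSums(meth[, i2, drop = FALSE]); N2 <- rowSums(total[, i2, drop = FALSE])
  p1 <- M1 / N1; p2 <- M2 / N2
  pp <- (M1 + M2) / (N1 + N2)
  # per-sample Pearson residuals against the group-pooled proportion
  pg <- cbind(matrix(p1, nrow(meth), length(i1)),
              matrix(p2, nrow(meth), length(i2)))
  ev <- total * pg * (1 - pg)
  chi2 <- rowSums(ifelse(ev > 0, (meth - total * pg)^2 / ev, 0))
  phi <- pmax(1, chi2 / (ncol(meth) - 2))
  v <- phi * pp * (1 - pp) * (1 / N1 + 1 / N2)
  z <- ifelse(v > 0, (p1 - p2) / sqrt(v), 0)
  p <- 2 * stats::pt(-abs(z), df = ncol(meth) - 2)
  q <- adjust_bh(p)

  beta <- meth / total
  delta <- rowMeans(beta[, i1, drop = FALSE]) - rowMeans(beta[, i2, drop = FALSE])
  tests <- data.frame(p = p, q = q, delta_beta = delta)
  sel <- which(q < max_q & abs(delta) >= min_delta)
  regions <- tiles[sel]
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    delta_beta = delta[sel], q = q[sel],
    direction = ifelse(delta[sel] > 0, "hyper", "hypo"),
    n_units = rep(1L, length(sel)))
  units <- regions
  S4Vectors::mcols(units)$region <- seq_along(regions)
  out <- dmr_set(regions, units, "tiles", comparison)
  if (all_tested) list(dmrs = out, tests = tests) else out
}

#' Call DMRs on array probes
#'
#' Probe-level beta values are compared between two groups with a Welch
#' t-test (optionally after regressing out a categorical covariate such as
#' tumor location), BH-adjusted across probes. Significant probes
#' (q < `max_fdr`, |delta beta| >= `betacutoff`) with the same direction are
#' merged into regions when separated by at most `merge_gap` bp; the region
#' delta beta is the mean over member probes and the region q the maximum
#' member q. Regions are retained when |region delta beta| >= `final_delta`
#' (the stringent threshold applied after inspection of the initial calls)
#' and q < `max_fdr`.
#'
#' @param probe_se `RangedSummarizedExperiment` with a `beta` assay and
#'   `group` in `colData`.
#' @param comparison Ordered group pair.
#' @param covariate Optional per-sample categorical covariate (full column
#'   order of `probe_se`); skipped with a warning if it coincides with the
#'   group partition.
#' @param betacutoff Per-probe |delta beta| threshold (default 0.05).
#' @param final_delta Region-level |delta beta| threshold (default 0.20).
#' @param max_fdr FDR threshold (default 0.05).
#' @param merge_gap Maximum gap (bp) between merged probes (default 1000).
#' @param all_tested Also return the per-probe test table.
#' @return A `DMRSet` (platform `"array"`); with `all_tested = TRUE`, a list
#'   with elements `dmrs` and `tests`.
#' @export
call_dmrs_probes <- function(probe_se, comparison, covariate = NULL,
                             betacutoff = 0.05, final_delta = 0.20,
                             max_fdr = 0.05, merge_gap = 1000,
                             all_tested = FALSE) {
  groups <- as.character(SummarizedExperiment::colData(probe_se)$group)
  idx1 <- which(groups == comparison[1]); idx2 <- which(groups == comparison[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("each group needs at least 2 samples")
  probes <- SummarizedExperiment::rowRanges(probe_se)
  beta <- SummarizedExperiment::assay(probe_se, "beta")[, c(idx1, idx2), drop = FALSE]
  grp <- c(rep(comparison[1], length(idx1)), rep(comparison[2], length(idx2)))

  if (!is.null(covariate)) {
    cov <- as.character(covariate[c(idx1, idx2)])
    if (identical(as.integer(factor(cov)), as.integer(factor(grp))) ||
        all(tapply(grp, cov, function(g) length(unique(g))) == 1)) {
      warning("covariate confounded with group; skipping adjustment")
    } else {
      # residualize per probe on covariate level means, keeping the grand mean
      gm <- rowMeans(beta)
      for (lv in unique(cov)) {
        cols <- which(cov == lv)
        lm_ <- rowMeans(beta[, cols, drop = FALSE])
        beta[, cols] <- beta[, cols] - (lm_ - gm)
      }
    }
  }

  tw <- row_welch(beta, seq_along(idx1), length(idx1) + seq_along(idx2))
  tw$q <- adjust_bh(tw$p)
  sig <- which(tw$q < max_fdr & abs(tw$diff) >= betacutoff)

  empty_regions <- probes[0]
  S4Vectors::mcols(empty_regions) <- S4Vectors::DataFrame(
    delta_beta = numeric(0), q = numeric(0), direction = character(0),
    n_units = integer(0))
  if (length(sig) == 0) {
    out <- dmr_set(empty_regions, probes[0], "array", comparison)
    return(if (all_tested) list(dmrs = out, tests = tw) else out)
  }

  reg_list <- list(); unit_list <- list()
  for (dir in c("hyper", "hypo")) {
    ds <- if (dir == "hyper") sig[tw$diff[sig] > 0] else sig[tw$diff[sig] < 0]
    if (length(ds) == 0) next
    pr <- probes[ds]
    merged <- GenomicRanges::reduce(pr, min.gapwidth = merge_gap + 1,
                                    ignore.strand = TRUE)
    h <- GenomicRanges::findOverlaps(pr, merged, ignore.strand = TRUE)
    ri <- S4Vectors::subjectHits(h)
    delta <- as.vector(tapply(tw$diff[ds], ri, mean))
    qv <- as.vector(tapply(tw$q[ds], ri, max))
    nu <- as.vector(table(ri))
    S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
      delta_beta = delta, q = qv, direction = rep(dir, length(merged)),
      n_units = as.integer(nu))
    units <- pr
    S4Vectors::mcols(units) <- S4Vectors::DataFrame(
      region = ri, delta_beta = delta[ri], probe_delta = tw$diff[ds])
    reg_list[[dir]] <- merged; unit_list[[dir]] <- units
  }
  regions <- do.call(c, unname(reg_list))
  units <- do.call(c, unname(unit_list))
  # re-index units after concatenation and final filtering
  offs <- cumsum(c(0, vapply(reg_list, length, 0L)))
  if (length(reg_list) == 2) {
    S4Vectors::mcols(unit_list[[2]])$region <-
      S4Vectors::mcols(unit_list[[2]])$region + offs[2]
    units <- c(unit_list[[1]], unit_list[[2]])
  }
  keep <- which(abs(regions$delta_beta) >= final_delta & regions$q < max_fdr)
  regions_kept <- regions[keep]
  ku <- which(units$region %in% keep)
  units <- units[ku]
  S4Vectors::mcols(units)$region <- match(S4Vectors::mcols(units)$region, keep)
  out <- dmr_set(regions_kept, units, "array", comparison)
  if (all_tested) list(dmrs = out, tests = tw) else out
}

#' Filter main-comparison DMRs by control comparisons
#'
#' Keeps, for each main DMR, only the base pairs shared with at least one
#' control DMR set (e.g. tumor-vs-normal comparisons), emitting the
#' intersected sub-regions with the main DMR's delta beta, q and direction.
#' Main DMRs with no control overlap are dropped.
#'
#' @param main A `DMRSet`.
#' @param controls List of `DMRSet`s on the same platform.
#' @return A `DMRSet` whose regions are the intersection spans.
#' @export
filter_by_controls <- function(main, controls) {
  if (length(controls) == 0) {
    warning("no control DMR sets; returning main comparison unchanged")
    return(main)
  }
  ctrl <- suppressWarnings(do.call(c, unname(
    lapply(controls, function(s) GenomicRanges::granges(s$regions)))))
  spans <- intersect_spans(main$regions, ctrl)
  units <- main$units
  if (length(units)) {
    h <- GenomicRanges::findOverlaps(units, spans, ignore.strand = TRUE)
    units <- units[unique(S4Vectors::queryHits(h))]
    # remap member units to the span containing them (first hit)
    first <- h[!duplicated(S4Vectors::queryHits(h))]
    S4Vectors::mcols(units)$region <- S4Vectors::subjectHits(first)
  }
  dmr_set(spans, units, main$platform, main$comparison)
}

#' Extract cancer-specific hyper/hypomethylated regions
#'
#' Intersects two DMR comparisons sharing a focal cancer (e.g. AT/RT-vs-MB
#' and AT/RT-vs-PLEX) into the regions methylated in a cancer-specific way.
#' Only DMRs with |delta beta| >= `min_input_delta` enter. For the array
#' platform, each member probe is extended by `probe_pad` bp per side and
#' carries its region's delta beta; extended probes from the two comparisons
#' are paired when a same-direction pair overlaps by at least `min_overlap`
#' bp, and the merged pairwise intersections are returned. For tiles the
#' fixed grid makes exact coordinate identity the pairing rule.
#'
#' @param dmrs_ab,dmrs_ac `DMRSet`s with the same first (focal) group.
#' @param probe_pad Probe extension per side, array platform (default 500).
#' @param min_overlap Minimum same-direction overlap, array platform
#'   (default 600).
#' @param min_input_delta Input |delta beta| filter (default 0.25).
#' @return List with `GRanges` elements `hyper` and `hypo`.
#' @export
extract_cancer_specific <- function(dmrs_ab, dmrs_ac, probe_pad = 500,
                                    min_overlap = 600, min_input_delta = 0.25) {
  if (dmrs_ab$comparison[1] != dmrs_ac$comparison[1])
    stop("comparisons must share the focal cancer as first group")
  if (dmrs_ab$platform != dmrs_ac$platform) stop("platform mismatch")
  platform <- dmrs_ab$platform
  out <- list(hyper = NULL, hypo = NULL)
  for (dir in c("hyper", "hypo")) {
    pick <- function(s) {
      keep <- which(abs(s$regions$delta_beta) >= min_input_delta &
                      s$regions$direction == dir)
      if (platform == "array") {
        u <- s$units[s$units$region %in% keep]
        extend_intervals(GenomicRanges::granges(u), probe_pad)
      } else {
        GenomicRanges::granges(s$regions[keep])
      }
    }
    a <- pick(dmrs_ab); b <- pick(dmrs_ac)
    if (platform == "array") {
      h <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                       ignore.strand = TRUE)
      if (length(h) == 0) { out[[dir]] <- a[0]; next }
      spans <- suppressWarnings(
        GenomicRanges::pintersect(a[S4Vectors::queryHits(h)],
                                  b[S4Vectors::subjectHits(h)],
                                  ignore.strand = TRUE))
      out[[dir]] <- merge_intervals(spans, 0)
    } else {
      out[[dir]] <- sort_intervals(a[interval_key(a) %in% interval_key(b)])
    }
  }
  for (dir in c("hyper", "hypo"))
    if (length(out[[dir]])) S4Vectors::mcols(out[[dir]])$direction <- dir
  out
}

#' Tabulate hyper/hypo counts per cancer and platform
#'
#' Four-field style summary of cancer-specific region sets: counts and
#' percentages of hyper- and hypomethylated regions per cancer and platform.
#'
#' @param specific Named list (cancer) of named lists (platform) of
#'   `list(hyper =, hypo =)` `GRanges` as returned by
#'   [extract_cancer_specific()].
#' @return `data.frame` with cancer, platform, direction, n and pct.
#' @export
count_direction_fourfield <- function(specific) {
  rows <- list()
  for (cancer in names(specific)) for (platform in names(specific[[cancer]])) {
    sets <- specific[[cancer]][[platform]]
    n_hyper <- length(sets$hyper); n_hypo <- length(sets$hypo)
    tot <- n_hyper + n_hypo
    rows[[length(rows) + 1]] <- data.frame(
      cancer = cancer, platform = platform,
      direction = c("hyper", "hypo"), n = c(n_hyper, n_hypo),
      pct = if (tot > 0) 100 * c(n_hyper, n_hypo) / tot else c(0, 0))
  }
  do.call(rbind, rows)
}
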