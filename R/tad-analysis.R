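# TAD-scale methylation shifts: TADs carrying several same-direction
# differentially methylated units on both platforms.

#' Detect TADs with large-scale methylation shifts
#'
#' Per TAD and platform, the units (extended probes with delta beta; tiles
#' with delta beta) overlapping the TAD and with |delta beta| >=
#' `min_delta` are counted by direction. A TAD passes one platform when its
#' majority direction has at least `min_hits` units, the opposite-direction
#' fraction of qualifying hits is strictly below `max_opposite`, and the
#' span between the first and last qualifying unit exceeds `min_span` bp
#' (strict). Direction ties fail. A TAD is reported when it passes on both
#' platforms with the same majority direction; passing TADs from all
#' supplied TAD sets (different cell types) are pooled and reduced to
#' single coordinates per direction.
#'
#' @param units_array `GRanges` of extended probes with metadata
#'   `delta_beta`.
#' @param units_tiles `GRanges` of tiles with metadata `delta_beta`.
#' @param tad_sets List of `GRanges` TAD sets (one per cell type).
#' @param min_hits Minimum majority-direction hits per platform (default 5).
#' @param min_delta Minimum |delta beta| per unit (default 0.25).
#' @param max_opposite Maximum opposite-direction hit fraction, strict
#'   (default 1/10).
#' @param min_span Minimum first-to-last unit span in bp, strict
#'   (default 50000).
#' @param comparison Optional comparison label copied onto the output.
#' @return `GRanges` of reduced large-scale TAD coordinates with metadata
#'   `direction` (and `comparison` when given).
#' @export
detect_largescale_tads <- function(units_array, units_tiles, tad_sets,
                                   min_hits = 5, min_delta = 0.25,
                                   max_opposite = 1 / 10, min_span = 50000,
                                   comparison = NULL) {
  if (min_hits < 1) stop("min_hits must be >= 1")
  if (!length(tad_sets)) stop("at least one TAD set required")
  units <- list(array = units_array, tiles = units_tiles)
  units <- lapply(units, function(u) u[abs(u$delta_beta) >= min_delta])

  platform_pass <- function(tads, u) {
    # returns per-TAD direction ("hyper"/"hypo") or NA
    dir <- rep(NA_character_, length(tads))
    h <- GenomicRanges::findOverlaps(tads, u, ignore.strand = TRUE)
    if (length(h) == 0) return(dir)
    byt <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    for (k in names(byt)) {
      i <- as.integer(k); ui <- byt[[k]]
      d <- u$delta_beta[ui]
      n_hyper <- sum(d > 0); n_hypo <- sum(d < 0)
      if (n_hyper == n_hypo) next
      maj <- max(n_hyper, n_hypo); opp <- min(n_hyper, n_hypo)
      if (maj < min_hits) next
      if (opp / (maj + opp) >= max_opposite) next
      span <- max(GenomicRanges::end(u[ui])) - min(GenomicRanges::start(u[ui])) + 1
      if (span <= min_span) next
      dir[i] <- if (n_hyper > n_hypo) "hyper" else "hypo"
    }
    dir
  }

  flagged <- list()
  for (tads in tad_sets) {
    da <- platform_pass(tads, units$array)
    dt <- platform_pass(tads, units$tiles)
    ok <- !is.na(da) & !is.na(dt) & da == dt
    if (any(ok)) {
      g <- GenomicRanges::granges(tads[ok])
      S4Vectors::mcols(g)$direction <- da[ok]
      flagged[[length(flagged) + 1]] <- g
    }
  }
  if (!length(flagged)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$direction <- character(0)
  } else {
    pooled <- suppressWarnings(do.call(c, flagged))
    out <- suppressWarnings(do.call(c, lapply(c("hyper", "hypo"), function(d) {
      r <- merge_intervals(pooled[pooled$direction == d], 0)
      S4Vectors::mcols(r)$direction <- rep(d, length(r))
      r
    })))
    out <- sort_intervals(out)
  }
  if (!is.null(comparison) && length(out))
    S4Vectors::mcols(out)$comparison <- comparison
  out
}

#' Fraction of regions inside large-scale TADs, per category
#'
#' For each region category (e.g. the developmental DMR categories), the
#' fraction of regions overlapping (>= 1 bp) any large-scale TAD.
#'
#' @param regions `GRanges` of categorized regions.
#' @param categories Category label per region.
#' @param largescale `GRanges` of large-scale TADs
#'   (from [detect_largescale_tads()]).
#' @return `data.frame` with category, n, n_largescale, fraction.
#' @export
largescale_fraction_by_category <- function(regions, categories, largescale) {
  if (length(categories) != length(regions))
    stop("one category per region required")
  inside <- GenomicRanges::countOverlaps(regions, largescale,
                                         ignore.strand = TRUE) > 0
  cats <- sort(unique(as.character(categories)))
  data.frame(
    category = cats,
    n = as.integer(vapply(cats, function(k) sum(categories == k), 0L)),
    n_largescale = as.integer(vapply(cats, function(k)
      sum(inside[categories == k]), 0L)),
    fraction = vapply(cats, function(k) mean(inside[categories == k]), 0),
    row.names = NULL)
}
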