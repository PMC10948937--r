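#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#'   findOverlaps countOverlaps pintersect distance distanceToNearest mcols
#'   disjoin granges sort
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols<- DataFrame
#' @importFrom stats p.adjust phyper kmeans wilcox.test pt var median
#'   complete.cases rbinom rnorm rpois runif sd setNames quantile
#' @importFrom utils read.table write.table head
NULL

# Intervals throughout the package are GRanges (1-based, closed), the
# Bioconductor convention. BED files (0-based, half-open) are converted at the
# reader/writer boundary, so all bp arithmetic below matches BED semantics.

#' Construct a genomic interval set
#'
#' Thin constructor for the `GRanges` objects used across the package.
#' Coordinates are 1-based and closed. Intervals are sorted by chromosome
#' (lexicographic), then start, then end, and empty intervals are rejected.
#'
#' @param chrom Character vector of chromosome names (kept verbatim).
#' @param start,end Integer vectors, 1-based closed coordinates, `end >= start`.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unknown). Default `"*"`.
#' @param ... Further metadata columns (e.g. `delta_beta`, `q`, `tf`).
#' @return A sorted `GRanges`.
#' @export
interval_set <- function(chrom, start, end, strand = "*", ...) {
  if (any(end < start)) stop("empty or negative-width intervals are not allowed")
  if (any(start < 1)) stop("start must be >= 1 (1-based coordinates)")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  meta <- list(...)
  if (length(meta)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  sort_intervals(gr)
}

#' Sort intervals deterministically
#'
#' Orders by chromosome name (lexicographic, ignoring any factor level order),
#' then start, then end. Ties beyond that keep input order (stable sort).
#'
#' @param gr A `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sort_intervals <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Merge intervals within a gap
#'
#' Reduces an interval set to pairwise-disjoint intervals per chromosome,
#' joining intervals separated by at most `max_gap` bp. With `max_gap = 0`
#' overlapping or book-ended intervals are unioned and the covered
#' base-pair set is preserved exactly.
#'
#' @param gr A `GRanges`.
#' @param max_gap Maximum gap (bp, >= 0) bridged when joining.
#' @return A reduced `GRanges` (metadata dropped).
#' @export
merge_intervals <- function(gr, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  sort_intervals(GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                                       ignore.strand = TRUE))
}

#' Overlap width between paired intervals
#'
#' Base pairs shared by `a[i]` and `b[i]`; 0 when the chromosomes differ or
#' the intervals are disjoint. `a` and `b` are recycled to a common length.
#'
#' @param a,b `GRanges` objects of equal (or recyclable) length.
#' @return Integer vector of overlap widths in bp.
#' @export
overlap_width <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  w <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  w[as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))] <- 0L
  pmax(0L, w)
}

#' Subset query intervals by overlap with a subject set
#'
#' Keeps query intervals sharing at least `min_overlap` bp with any single
#' subject interval (metadata preserved); `invert = TRUE` returns the
#' complement so that the two calls partition the query exactly.
#'
#' @param query,subject `GRanges`.
#' @param min_overlap Minimum bp shared with one subject interval (>= 1).
#' @param invert Return the non-overlapping complement instead.
#' @return The retained subset of `query`.
#' @export
subset_by_overlap <- function(query, subject, min_overlap = 1, invert = FALSE) {
  if (!is.numeric(min_overlap) || min_overlap < 1)
    stop("min_overlap must be >= 1")
  hits <- GenomicRanges::findOverlaps(query, subject,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  keep <- unique(S4Vectors::queryHits(hits))
  if (invert) query[setdiff(seq_along(query), keep)] else query[sort(keep)]
}

#' Per-bp intersection of two interval sets
#'
#' Returns the maximal runs of base pairs covered by both sets. The subject
#' set is first reduced, so each output interval is a maximal run within one
#' `a` interval and carries that `a` interval's metadata.
#'
#' @param a,b `GRanges`; metadata of `a` is propagated.
#' @return `GRanges` of intersection spans.
#' @export
intersect_spans <- function(a, b) {
  bred <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, bred, ignore.strand = TRUE))
  if (length(hits) == 0) return(a[0])
  out <- suppressWarnings(
    GenomicRanges::pintersect(a[S4Vectors::queryHits(hits)],
                              bred[S4Vectors::subjectHits(hits)],
                              ignore.strand = TRUE))
  S4Vectors::mcols(out)$hit <- NULL
  sort_intervals(out)
}

#' Extend intervals symmetrically
#'
#' Pads each interval by `pad` bp on both sides, clipping at the chromosome
#' origin. No merging is performed and metadata are preserved.
#'
#' @param gr A `GRanges`.
#' @param pad Padding in bp (>= 0).
#' @return Padded `GRanges`.
#' @export
extend_intervals <- function(gr, pad) {
  if (!is.numeric(pad) || length(pad) != 1 || is.na(pad) || pad < 0)
    stop("pad must be a single non-negative number")
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(gr) - as.integer(pad)),
                     GenomicRanges::end(gr) + as.integer(pad)),
    strand = GenomicRanges::strand(gr),
    mcols(gr)
  )
}

# coordinate-identity key; length 0 for empty input (paste0 would recycle)
interval_key <- function(g) {
  if (length(g) == 0) return(character(0))
  paste0(as.character(GenomicRanges::seqnames(g)), ":",
         GenomicRanges::start(g), "-", GenomicRanges::end(g))
}

#' Canonical autosome predicate
#'
#' The analyses repeatedly drop sex chromosomes, mitochondria and scaffolds;
#' this predicate marks intervals on canonical autosomes (default
#' `chr1`..`chr22`). Names are matched verbatim.
#'
#' @param gr A `GRanges`.
#' @param chroms Character vector of allowed chromosome names.
#' @return Logical vector, `TRUE` for intervals on an allowed chromosome.
#' @export
is_canonical <- function(gr, chroms = paste0("chr", 1:22)) {
  as.character(GenomicRanges::seqnames(gr)) %in% chroms
}

#' Read a BED or extended-BED file
#'
#' Tab-separated, 0-based half-open input converted to 1-based closed
#' `GRanges`. Columns beyond the first three are mapped to `name`, `score`,
#' `strand`, and any further columns become metadata named by `extra_cols`
#' (or `V7`, `V8`, ... when unnamed). Gzip input is handled transparently.
#'
#' @param path File path (optionally `.gz`).
#' @param extra_cols Optional names for columns 7+.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  gr <- GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]),
    strand = if (ncol(df) >= 6) ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*") else "*")
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- df[[5]]
  if (ncol(df) > 6) {
    extra <- df[, 7:ncol(df), drop = FALSE]
    names(extra) <- if (!is.null(extra_cols)) extra_cols else names(extra)
    for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  }
  sort_intervals(gr)
}

#' Write intervals as BED / extended BED
#'
#' Writes 0-based half-open coordinates. With `extra_cols`, the named
#' metadata columns are appended after the six standard columns.
#'
#' @param gr A `GRanges`.
#' @param path Output path; a `.gz` suffix writes gzip.
#' @param extra_cols Metadata column names to append.
#' @export
write_bed <- function(gr, path, extra_cols = character()) {
  m <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(m)) m$name else ".",
    score = if ("score" %in% names(m)) m$score else 0,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE)
  for (nm in extra_cols) df[[nm]] <- m[[nm]]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
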