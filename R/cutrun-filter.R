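# CUT&RUN peak post-processing: replicate unification, control subtraction,
# canonical-chromosome filtering, retention by catalog overlap or motif
# presence, and methylation summaries of retained peaks. Motif scanning uses
# an exact p-value threshold computed by dynamic programming over the
# discretized log-odds score distribution (FIMO-style).

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four
#' rows `A [ ... ]` etc.
#'
#' @param path File path.
#' @return List with `name` and `counts` (4 x w matrix, rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- sub("^>", "", lines[1])
  rows <- lapply(lines[2:5], function(l) {
    body <- sub("^\\s*[ACGT]", "", l)
    as.numeric(regmatches(body, gregexpr("[0-9][0-9.eE+-]*", body))[[1]])
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  list(name = header, counts = counts)
}

#' Write a JASPAR-format position frequency matrix
#'
#' @param counts 4 x w count matrix with rows A, C, G, T.
#' @param name Motif identifier for the header line.
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(counts, name, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(paste0(b, "  [ ", paste(counts[b, ], collapse = " "), " ]"), con)
  invisible(path)
}

#' Build a position weight matrix from counts
#'
#' Converts a position frequency matrix to per-position probabilities with
#' a pseudocount and to a log2-odds matrix against the background.
#'
#' @param counts 4 x w count matrix (rows A, C, G, T).
#' @param background Background base probabilities (default uniform),
#'   length 4, summing to 1.
#' @param pseudocount Added to every cell (default 0.25).
#' @return List of class `pwm` with `prob`, `logodds`, `width`,
#'   `background`.
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4),
                            pseudocount = 0.25) {
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  structure(list(prob = prob, logodds = log2(prob / background),
                 width = ncol(counts), background = background),
            class = "pwm")
}

#' Exact motif score threshold at a p-value
#'
#' Discretizes the log-odds matrix to `bin`-sized integer bins and computes
#' the exact distribution of the window score under the background model by
#' dynamic programming (convolution over positions). The threshold is the
#' smallest binned score s with P(score >= s | background) < `p_max`;
#' scanning uses the same binned matrix so threshold and scores are exactly
#' consistent.
#'
#' @param pwm A `pwm` from [pwm_from_counts()].
#' @param p_max Per-window p-value bound (default 0.001).
#' @param bin Discretization bin width in log2-odds units (default 0.001).
#' @return List with `threshold` (integer, binned units), `bin`, and
#'   `p_attained` (tail probability at the threshold).
#' @export
motif_score_threshold <- function(pwm, p_max = 0.001, bin = 0.001) {
  ibo <- round(pwm$logodds / bin)
  offs <- apply(ibo, 2, min)
  span <- apply(ibo, 2, max) - offs
  dist <- 1 # P over shifted scores, starting at 0
  for (j in seq_len(pwm$width)) {
    newd <- numeric(length(dist) + span[j])
    sh <- ibo[, j] - offs[j]
    for (b in 1:4)
      newd[seq_along(dist) + sh[b]] <-
        newd[seq_along(dist) + sh[b]] + dist * pwm$background[b]
    dist <- newd
  }
  scores <- sum(offs) + seq_along(dist) - 1
  tail_p <- rev(cumsum(rev(dist)))
  idx <- which(tail_p < p_max)
  threshold <- if (length(idx)) scores[min(idx)] else max(scores) + 1
  list(threshold = threshold, bin = bin,
       p_attained = if (length(idx)) tail_p[min(idx)] else 0)
}

#' Scan sequences for motif hits
#'
#' Scores every window of each sequence (both strands) with the binned
#' log2-odds matrix and flags a sequence as a hit when any window reaches
#' the exact threshold at `p_max`. An `N` position contributes the
#' column's expected log-odds under the background model (negative for
#' informative columns, so windows of ambiguous sequence never score as
#' matches). Sequences shorter than the motif are never hits.
#'
#' @param sequences Character vector or `Biostrings::DNAStringSet` over
#'   A, C, G, T, N.
#' @param pwm A `pwm` from [pwm_from_counts()].
#' @param p_max Per-window p-value bound (default 0.001).
#' @param bin Discretization bin width (default 0.001).
#' @return Logical vector, one flag per sequence.
#' @export
scan_motif <- function(sequences, pwm, p_max = 0.001, bin = 0.001) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  thr <- motif_score_threshold(pwm, p_max, bin)$threshold
  ibo <- round(pwm$logodds / bin)
  n_score <- round(colSums(ibo * pwm$background)) # expected background score
  w <- pwm$width
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  scan_one <- function(s) {
    n <- nchar(s)
    if (n < w) return(FALSE)
    x <- code[strsplit(toupper(s), "")[[1]]] # NA for N and friends
    for (strand in 1:2) {
      if (strand == 2) x <- rev(5L - x) # reverse complement
      sc <- numeric(n - w + 1)
      for (j in seq_len(w)) {
        col <- ibo[, j][x[j:(n - w + j)]]
        col[is.na(col)] <- n_score[j]
        sc <- sc + col
      }
      if (any(sc >= thr)) return(TRUE)
    }
    FALSE
  }
  vapply(sequences, scan_one, logical(1), USE.NAMES = FALSE)
}

#' Filter CUT&RUN peaks
#'
#' Per replicate, drops peaks outside the canonical chromosomes (the
#' default excludes chrX/chrY and scaffolds) and peaks overlapping (>= 1 bp)
#' any negative-control peak; replicates are then unified by taking the
#' per-bp intersection of the surviving peak sets, re-extracted as maximal
#' regions.
#'
#' @param reps List of `GRanges`, one per replicate (>= 1).
#' @param control_peaks `GRanges` of input-DNA control peaks (may be empty).
#' @param canonical Allowed chromosome names (default `chr1`..`chr22`).
#' @return `GRanges` of unified peak regions.
#' @export
filter_peaks <- function(reps, control_peaks = GenomicRanges::GRanges(),
                         canonical = paste0("chr", 1:22)) {
  if (!length(reps)) stop("at least one replicate required")
  cleaned <- lapply(reps, function(p) {
    p <- p[is_canonical(p, canonical)]
    if (length(control_peaks))
      p <- subset_by_overlap(p, control_peaks, 1, invert = TRUE)
    GenomicRanges::reduce(GenomicRanges::granges(p), ignore.strand = TRUE)
  })
  out <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, cleaned)
  sort_intervals(out)
}

#' Retain peaks by binding-catalog or motif evidence
#'
#' Keeps peaks overlapping a known binding site of the targeted TF or
#' containing its motif, recording the evidence class for Venn-style
#' reporting.
#'
#' @param peaks `GRanges`.
#' @param gtrd_sites `GRanges` of catalog binding sites for the TF.
#' @param motif_hits Logical vector, one per peak (from [scan_motif()] on
#'   the peak sequences).
#' @return The retained `GRanges` with a `class` metadata column in
#'   \{"gtrd_only", "motif_only", "both"\}.
#' @export
retain_by_evidence <- function(peaks, gtrd_sites, motif_hits) {
  if (length(motif_hits) != length(peaks))
    stop("one motif flag per peak required")
  gtrd <- GenomicRanges::countOverlaps(peaks, gtrd_sites,
                                       ignore.strand = TRUE) > 0
  keep <- gtrd | motif_hits
  out <- peaks[keep]
  S4Vectors::mcols(out)$class <- ifelse(gtrd[keep] & motif_hits[keep], "both",
                                        ifelse(gtrd[keep], "gtrd_only",
                                               "motif_only"))
  out
}

#' Count retained peaks per DMR class
#'
#' @param peaks `GRanges` of retained peaks.
#' @param dmr_classes Named list of `GRanges` region classes (e.g.
#'   "ATRT_vs_MB hyper", cancer-specific sets).
#' @return `data.frame` with class and n_peaks (>= 1 bp overlap).
#' @export
peaks_vs_dmr_classes <- function(peaks, dmr_classes) {
  data.frame(
    class = names(dmr_classes),
    n_peaks = vapply(dmr_classes, function(r)
      sum(GenomicRanges::countOverlaps(peaks, r, ignore.strand = TRUE) > 0),
      0L),
    row.names = NULL)
}

#' Fraction of peaks highly methylated in every sample of a group
#'
#' A peak's methylation per sample is the mean beta of the measurement
#' units (tiles or probes) it overlaps; the reported fraction is the share
#' of peaks whose beta is strictly above `cutoff` in all samples of the
#' group. Peaks overlapping no unit are excluded from the denominator.
#'
#' @param peaks `GRanges`.
#' @param beta_se `RangedSummarizedExperiment` with a `beta` assay and
#'   `group` in `colData`.
#' @param group Group whose samples must all exceed the cutoff.
#' @param cutoff Beta threshold, strict (default 0.5).
#' @return List with `fraction`, `n_high`, `n_evaluated`.
#' @export
peak_high_methylation_fraction <- function(peaks, beta_se, group,
                                           cutoff = 0.5) {
  groups <- as.character(SummarizedExperiment::colData(beta_se)$group)
  anames <- names(SummarizedExperiment::assays(beta_se))
  beta <- if ("beta" %in% anames) {
    SummarizedExperiment::assay(beta_se, "beta")
  } else {
    m <- SummarizedExperiment::assay(beta_se, "meth")
    t <- SummarizedExperiment::assay(beta_se, "total")
    ifelse(t > 0, m / t, NA_real_)
  }
  beta <- beta[, groups == group, drop = FALSE]
  units <- SummarizedExperiment::rowRanges(beta_se)
  h <- GenomicRanges::findOverlaps(peaks, units, ignore.strand = TRUE)
  if (!length(h)) return(list(fraction = NaN, n_high = 0L, n_evaluated = 0L))
  pk <- S4Vectors::queryHits(h)
  pb <- rowsum(beta[S4Vectors::subjectHits(h), , drop = FALSE], pk) /
    as.vector(table(pk))
  high <- rowSums(pb > cutoff, na.rm = TRUE) == ncol(pb) &
    rowSums(is.na(pb)) == 0
  list(fraction = mean(high), n_high = sum(high), n_evaluated = nrow(pb))
}
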