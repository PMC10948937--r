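# Group-difference statistics and matrix utilities shared by the DMR and
# clustering stages.

#' Row-wise Welch t-test
#'
#' Vectorized two-group Welch test over the rows of a matrix; the workhorse
#' behind the probe-level DMR caller and the expression DE stand-in.
#' Zero-variance rows (both groups constant and equal) get p = 1.
#'
#' @param x Numeric matrix (rows = features, columns = samples).
#' @param idx1,idx2 Column indices of the two groups (>= 2 each).
#' @return `data.frame` with `diff` (mean group1 - mean group2), `t`, `df`, `p`.
#' @keywords internal
row_welch <- function(x, idx1, idx2) {
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("each group needs at least 2 samples")
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(1, n1 - 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(1, n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0 | !is.finite(tt)
  p[zero] <- 1; tt[zero] <- 0; df[zero] <- n1[zero] + n2[zero] - 2
  data.frame(diff = m1 - m2, t = tt, df = df, p = p)
}

#' Aggregate probe methylation onto tiles
#'
#' A probe contributes to a tile only when fully contained in it; the tile's
#' value per sample is the mean beta of its contributing probes. Tiles with
#' no contained probe are missing.
#'
#' @param probe_se `RangedSummarizedExperiment` with a `beta` assay.
#' @param tiles `GRanges` of target tiles.
#' @return `RangedSummarizedExperiment` over `tiles` with a `beta` assay
#'   (NA where no probe is contained).
#' @export
aggregate_probes_to_tiles <- function(probe_se, tiles) {
  beta <- SummarizedExperiment::assay(probe_se, "beta")
  probes <- SummarizedExperiment::rowRanges(probe_se)
  hits <- GenomicRanges::findOverlaps(probes, tiles, type = "within",
                                      ignore.strand = TRUE)
  out <- matrix(NA_real_, nrow = length(tiles), ncol = ncol(beta),
                dimnames = list(NULL, colnames(beta)))
  if (length(hits)) {
    ti <- S4Vectors::subjectHits(hits)
    sums <- rowsum(beta[S4Vectors::queryHits(hits), , drop = FALSE], ti)
    cnt <- as.vector(table(ti))
    out[as.integer(rownames(sums)), ] <- sums / cnt
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = out), rowRanges = tiles,
    colData = SummarizedExperiment::colData(probe_se))
}

#' Select the most variable rows of a methylation matrix
#'
#' Rows ranked by variance across samples (missing values ignored); the top
#' `n` row indices are returned. Ties are broken by row order (genomic order
#' for matrices built from sorted region sets), so the selection is
#' deterministic.
#'
#' @param x Numeric matrix.
#' @param n Number of rows to keep (default 10000).
#' @return Integer vector of selected row indices, most variable first.
#' @export
select_most_variable <- function(x, n = 10000) {
  if (n < 1) stop("n must be >= 1")
  if (n > nrow(x)) {
    warning("n exceeds the number of rows; returning all rows")
    n <- nrow(x)
  }
  nv <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(1, nv - 1)
  v[nv < 2] <- 0
  order(-v, seq_along(v))[seq_len(n)]
}

#' K-means clustering with AIC model selection
#'
#' Runs Lloyd's k-means for each k in `k_range` (best of `starts` random
#' initializations, at most `iters` iterations each) and scores each k with
#' AIC(k) = WSS(k) + 2 k d, where WSS is the total within-cluster sum of
#' squares and d the number of columns. The k minimizing AIC is selected.
#' Missing values are mean-imputed per row before clustering.
#'
#' @param x Numeric matrix (rows clustered).
#' @param k_range Candidate cluster counts (default 1:25).
#' @param iters Lloyd iterations per start (default 25).
#' @param starts Random starts per k (default 50).
#' @param seed Integer seed for reproducible initialization.
#' @return List with `labels` (for the chosen k), `chosen_k`, and `aic_curve`
#'   (`data.frame` of k, wss, aic).
#' @export
kmeans_with_aic <- function(x, k_range = 1:25, iters = 25, starts = 50,
                            seed = 1) {
  x <- as.matrix(x)
  if (any(is.na(x))) {
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j]); x[miss, j] <- rm_[miss]
    }
  }
  if (any(!is.finite(x))) stop("non-finite values; impute upstream")
  if (nrow(x) < max(k_range)) stop("fewer rows than max(k_range)")
  set.seed(seed)
  d <- ncol(x)
  wss <- numeric(length(k_range))
  labs <- vector("list", length(k_range))
  n_distinct <- nrow(unique(x))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      ctr <- colMeans(x)
      wss[i] <- sum(sweep(x, 2, ctr)^2)
      labs[[i]] <- rep(1L, nrow(x))
    } else if (n_distinct < k) {
      # fewer distinct points than centers: every distinct row is a center
      key <- apply(x, 1, paste, collapse = "\r")
      wss[i] <- 0
      labs[[i]] <- as.integer(factor(key, levels = unique(key)))
    } else {
      km <- suppressWarnings(stats::kmeans(x, centers = k, iter.max = iters,
                                           nstart = starts, algorithm = "Lloyd"))
      wss[i] <- km$tot.withinss
      labs[[i]] <- km$cluster
    }
  }
  aic <- wss + 2 * k_range * d
  best <- which.min(aic)
  list(labels = labs[[best]], chosen_k = k_range[best],
       aic_curve = data.frame(k = k_range, wss = wss, aic = aic))
}

#' Cliff's delta effect size
#'
#' delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n m), the difference of the
#' probabilities of superiority; ranges over \[-1, 1\] and is invariant under
#' strictly monotone transforms.
#'
#' @param x,y Numeric vectors (nonempty).
#' @return Cliff's delta.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty input")
  mean(sign(outer(x, y, "-")))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact null distribution when min(n, m) <= 8 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric vectors (nonempty).
#' @return Two-sided p-value in (0, 1\].
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty input")
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && min(length(x), length(y)) <= 8
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, adj_(i) = min_(j >= i) m p_(j) / j capped at 1,
#' returned in the input order. Inputs outside \[0, 1\] are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-cluster, per-group median methylation
#'
#' For each cluster, the per-sample median over the cluster's rows is taken,
#' then the per-group median across samples, summarizing the average
#' methylation pattern of the cluster in each sample group.
#'
#' @param x Numeric matrix (rows = regions).
#' @param labels Integer cluster labels, one per row.
#' @param groups Group label per column of `x`.
#' @return Matrix, clusters x groups, of median methylation.
#' @export
cluster_group_medians <- function(x, labels, groups) {
  if (length(labels) != nrow(x)) stop("labels must align with rows")
  groups <- as.character(groups)
  cl <- sort(unique(labels))
  gs <- unique(groups)
  out <- matrix(NA_real_, length(cl), length(gs), dimnames = list(cl, gs))
  for (i in seq_along(cl)) {
    rows <- which(labels == cl[i])
    if (length(rows) == 0) { warning("empty cluster ", cl[i]); next }
    smed <- apply(x[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    out[i, ] <- vapply(gs, function(g) stats::median(smed[groups == g],
                                                     na.rm = TRUE), 0)
  }
  out
}
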