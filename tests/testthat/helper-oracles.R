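# Brute-force oracles and small fixture builders shared across the suite.

# shorthand GRanges constructor (1-based closed)
gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

# mark every covered bp in a boolean vector per chromosome
bp_cover <- function(g, len = 100000) {
  chroms <- unique(as.character(GenomicRanges::seqnames(g)))
  out <- lapply(chroms, function(ch) {
    v <- logical(len)
    gi <- g[as.character(GenomicRanges::seqnames(g)) == ch]
    for (i in seq_along(gi))
      v[GenomicRanges::start(gi)[i]:GenomicRanges::end(gi)[i]] <- TRUE
    v
  })
  names(out) <- chroms
  out
}

# re-extract maximal runs from boolean coverage vectors
runs_from_cover <- function(cov) {
  rows <- list()
  for (ch in sort(names(cov))) {
    r <- rle(cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (any(keep))
      rows[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                               end = ends[keep])
  }
  do.call(rbind, rows)
}

as_df <- function(g) data.frame(
  chrom = as.character(GenomicRanges::seqnames(g)),
  start = GenomicRanges::start(g), end = GenomicRanges::end(g))

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 90000,
                             max_len = 500) {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample(max_pos, n, replace = TRUE)
  gr(ch, s, s + sample(max_len, n, replace = TRUE))
}

# one-sided Fisher p by direct log-gamma hypergeometric summation
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  kmax <- min(a + b, a + c)
  k <- a:kmax
  sum(exp(lchoose(a + c, k) + lchoose(b + d, a + b - k) - lchoose(n, a + b)))
}

# BH step-up by the textbook formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# probe-level SummarizedExperiment from explicit coordinates and betas
make_probe_se <- function(chrom, start, beta, groups, width = 50) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    rowRanges = gr(chrom, start, start + width - 1),
    colData = S4Vectors::DataFrame(group = groups))
}

# minimal DMRSet from explicit regions (units == regions)
dmrset_from <- function(chrom, start, end, delta, platform = "array",
                        comparison = c("A", "B")) {
  dir <- ifelse(delta > 0, "hyper", "hypo")
  regions <- gr(chrom, start, end, delta_beta = delta, q = 0.001,
                direction = dir, n_units = 1L)
  units <- regions
  S4Vectors::mcols(units) <- S4Vectors::DataFrame(region = seq_along(regions),
                                                  delta_beta = delta)
  dmr_set(regions, units, platform, comparison)
}

make_tile_se <- function(chrom, start, meth, total, groups, width = 1000) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total),
    rowRanges = gr(chrom, start, start + width - 1),
    colData = S4Vectors::DataFrame(group = groups))
}
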