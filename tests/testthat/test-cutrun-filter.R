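test_that("peak filtering drops chrX/control peaks and intersects replicates", {
  rep1 <- gr(c("chr1", "chr1", "chrX"), c(100, 1000, 50),
             c(300, 1200, 250))
  rep2 <- gr(c("chr1", "chr1"), c(200, 1000), c(400, 1200))
  out <- filter_peaks(list(rep1, rep2))
  expect_equal(as_df(out), data.frame(chrom = "chr1", start = c(200, 1000),
                                      end = c(300, 1200)))
  # control overlapping by a single bp removes the peak
  ctrl <- gr("chr1", 1200, 1500)
  out2 <- filter_peaks(list(rep1, rep2), ctrl)
  expect_equal(as_df(out2), data.frame(chrom = "chr1", start = 200, end = 300))
  expect_error(filter_peaks(list()), "replicate")
  # footprint is inside every replicate and disjoint from the control
  expect_true(all(overlap_width(out2, rep(ctrl, length(out2))) == 0))
  for (r in list(rep1, rep2)) {
    cov_r <- bp_cover(r); cov_o <- bp_cover(out2)
    for (ch in names(cov_o)) expect_true(all(cov_r[[ch]][cov_o[[ch]]]))
  }
})

test_that("JASPAR PFM and PWM round-trip with normalized columns", {
  counts <- matrix(c(10, 2, 1, 1, 0, 12, 1, 1), 4, 2,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  path <- tempfile(fileext = ".pfm")
  write_jaspar_pfm(counts, "TEST.1", path)
  back <- read_jaspar_pfm(path)
  expect_equal(back$name, "TEST.1")
  expect_equal(back$counts, counts, ignore_attr = TRUE)
  pwm <- pwm_from_counts(counts)
  expect_equal(colSums(pwm$prob), rep(1, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pwm_from_counts(counts, background = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  # FASTA round-trip for peak sequences
  fa <- tempfile(fileext = ".fa")
  write_fasta(c(p1 = "ACGTACGT", p2 = "GGGNNCCC"), fa)
  expect_equal(read_fasta(fa), c(p1 = "ACGTACGT", p2 = "GGGNNCCC"))
})

consensus_pwm <- function(consensus, hi = 100) {
  counts <- matrix(0, 4, nchar(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(nchar(consensus)))
    counts[substr(consensus, j, j), j] <- hi
  # near-zero pseudocount: off-consensus letters score prohibitively low
  pwm_from_counts(counts, pseudocount = 1e-4)
}

test_that("score threshold equals brute-force enumeration for w <= 6", {
  set.seed(61)
  for (w in 3:6) {
    counts <- matrix(rpois(4 * w, 20) + 1, 4, w,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pwm_from_counts(counts)
    thr <- motif_score_threshold(pwm, p_max = 0.001)
    ibo <- round(pwm$logodds / thr$bin)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- rowSums(matrix(ibo[cbind(as.vector(words),
                                       rep(seq_len(w), each = nrow(words)))],
                             nrow(words), w))
    tail_at <- function(s) mean(scores >= s) # uniform background
    # the threshold is the smallest binned score with tail < 1e-3
    expect_lt(tail_at(thr$threshold), 0.001)
    below <- max(scores[scores < thr$threshold])
    expect_gte(tail_at(below), 0.001)
  }
})

test_that("consensus-only PWM of width 5 hits exactly consensus windows", {
  pwm <- consensus_pwm("CAGTC")
  # only the exact consensus scores above threshold: per-window p = 4^-5
  expect_true(scan_motif("AAACAGTCAAA", pwm))
  expect_true(scan_motif("CAGTC", pwm))
  expect_false(scan_motif("AAACAGTAAAA", pwm)) # one mismatch
  expect_true(scan_motif("AAAGACTGAAA", pwm))  # reverse complement
  expect_false(scan_motif("NNNNNNNNN", pwm))   # N scores as background
  expect_false(scan_motif("CAG", pwm))         # shorter than the motif
})

test_that("lowering p_max never yields more motif hits", {
  set.seed(62)
  pwm <- pwm_from_counts(matrix(rpois(4 * 6, 15) + 1, 4, 6,
                                dimnames = list(c("A", "C", "G", "T"), NULL)))
  seqs <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    "")
  hits_loose <- scan_motif(seqs, pwm, p_max = 0.01)
  hits_tight <- scan_motif(seqs, pwm, p_max = 0.0005)
  expect_true(all(hits_loose[hits_tight])) # tight hits are a subset
  expect_lte(sum(hits_tight), sum(hits_loose))
})

test_that("evidence retention records the class breakdown", {
  peaks <- gr("chr1", c(100, 1000, 2000, 3000), c(400, 1400, 2400, 3400))
  gtrd <- gr("chr1", c(150, 1100), c(250, 1200))
  motif <- c(TRUE, FALSE, TRUE, FALSE)
  out <- retain_by_evidence(peaks, gtrd, motif)
  expect_length(out, 3) # the peak with neither line of evidence is dropped
  expect_equal(out$class, c("both", "gtrd_only", "motif_only"))
  expect_error(retain_by_evidence(peaks, gtrd, TRUE), "one motif flag")
})

test_that("peak-vs-DMR class counts match an all-pairs scan", {
  peaks <- gr("chr1", c(100, 5000), c(400, 5400))
  classes <- list(hyperA = gr("chr1", 300, 600),
                  hypoB = gr("chr1", 10000, 11000))
  tab <- peaks_vs_dmr_classes(peaks, classes)
  expect_equal(tab$n_peaks, c(1L, 0L))
})

test_that("high-methylation fraction uses a strict cutoff over all samples", {
  groups <- c("A", "A", "B")
  # unit betas: peak 1 all A-samples above 0.5; peak 2 has one A at exactly 0.5
  beta <- rbind(c(0.9, 0.8, 0.1), c(0.9, 0.5, 0.1))
  se <- make_probe_se("chr1", c(100, 5000), beta, groups, width = 1000)
  peaks <- gr("chr1", c(150, 5050, 90000), c(350, 5250, 90200))
  out <- peak_high_methylation_fraction(peaks, se, "A")
  expect_equal(out$n_evaluated, 2L) # the unit-free peak leaves the denominator
  expect_equal(out$n_high, 1L)      # 0.5 fails the strict > 0.5 rule
  expect_equal(out$fraction, 0.5)
  all1 <- make_probe_se("chr1", c(100, 5000),
                        matrix(1, 2, 3), groups, width = 1000)
  expect_equal(peak_high_methylation_fraction(peaks, all1, "A")$fraction, 1)
})
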