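# A reduced study configuration keeps the generator tests fast while
# preserving the full planted structure.
small_config <- function(seed = 3, ...) {
  study_config(seed = seed,
               chrom_lengths = c(chr1 = 2.5e6, chr2 = 2.5e6, chr3 = 2.5e6,
                                 chr4 = 2.5e6, chrX = 1e5),
               n_dmrs = c(ATRT_hyper = 4, ATRT_hypo = 4, MB_hyper = 2,
                          MB_hypo = 4, PLEX_hyper = 2, PLEX_hypo = 2),
               dmde_spec = c(promoter = 3, enhancer = 2, neighborhood = 2,
                             parallel = 4, crossing = 2),
               sites_per_tf = 500, n_genes = 120, ...)
}

test_that("the generator is deterministic in the seed", {
  a <- simulate_methylomes(small_config(seed = 9))
  b <- simulate_methylomes(small_config(seed = 9))
  expect_identical(SummarizedExperiment::assay(a$probe_se, "beta"),
                   SummarizedExperiment::assay(b$probe_se, "beta"))
  expect_identical(SummarizedExperiment::assay(a$tile_se, "meth"),
                   SummarizedExperiment::assay(b$tile_se, "meth"))
  expect_identical(a$truth$dmrs, b$truth$dmrs)
  c_ <- simulate_methylomes(small_config(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(a$probe_se, "beta"),
                         SummarizedExperiment::assay(c_$probe_se, "beta")))
})

test_that("generated values satisfy the basic data invariants", {
  m <- simulate_methylomes(small_config())
  beta <- SummarizedExperiment::assay(m$probe_se, "beta")
  expect_true(all(beta >= 0 & beta <= 1))
  meth <- SummarizedExperiment::assay(m$tile_se, "meth")
  total <- SummarizedExperiment::assay(m$tile_se, "total")
  expect_true(all(meth <= total))
  expect_true(all(meth >= 0))
  tiles <- SummarizedExperiment::rowRanges(m$tile_se)
  expect_true(all(GenomicRanges::width(tiles) == 1000))
  probes <- SummarizedExperiment::rowRanges(m$probe_se)
  expect_true(all(GenomicRanges::width(probes) == 50))
})

test_that("planted deltas and truth tables are mutually consistent", {
  cfg <- small_config()
  m <- simulate_methylomes(cfg)
  truth <- m$truth$dmrs
  groups <- SummarizedExperiment::colData(m$tile_se)$group
  meth <- SummarizedExperiment::assay(m$tile_se, "meth")
  total <- SummarizedExperiment::assay(m$tile_se, "total")
  bmat <- meth / total
  tiles <- SummarizedExperiment::rowRanges(m$tile_se)
  # empirical group difference inside planted regions averages the
  # configured 0.4 within +/- 0.05
  diffs <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- which(as.character(GenomicRanges::seqnames(tiles)) ==
                   truth$chrom[i] &
                   GenomicRanges::start(tiles) >= truth$start[i] &
                   GenomicRanges::end(tiles) < truth$end[i])
    focal <- rowMeans(bmat[sel, groups == truth$focal[i], drop = FALSE])
    other <- rowMeans(bmat[sel, groups == "CONTR", drop = FALSE])
    mean(focal - other)
  }, 0)
  signed <- ifelse(truth$direction == "hyper", 1, -1) * cfg$delta
  expect_lt(mean(abs(diffs - signed)), 0.05)
  # truth coordinates index real tiles inside the genome
  expect_true(all(truth$start >= 1))
  expect_true(all(truth$chrom %in% names(cfg$chrom_lengths)))

  reg <- simulate_regulatory_genome(cfg)
  expect_true(all(m$truth$tfs$tf %in% reg$catalog$tf))
  expect_true(all(reg$enhancers$confidence >= 0))
  # planted DM-DE genes exist in the gene models
  expect_true(all(m$truth$dmde$gene %in% reg$genes$gene))
})

test_that("a null study plants nothing and calibrates the callers", {
  cfg <- small_config(null_study = TRUE)
  m <- simulate_methylomes(cfg)
  expect_null(m$truth$dmrs)
  out <- call_dmrs_tiles(m$tile_se, c("ATRT", "MB"), all_tested = TRUE)
  # with no planted effects the discovery count stays near the nominal FDR
  expect_lte(length(out$dmrs$regions), 3)
  expect_lte(mean(out$tests$p < 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / nrow(out$tests)))
})

test_that("expression generator plants concordant fold changes", {
  cfg <- small_config()
  e <- simulate_expression(cfg)
  up <- e$truth$dmde[e$truth$dmde$dmde_up, "gene"]
  dn <- e$truth$dmde[!e$truth$dmde$dmde_up, "gene"]
  li <- e$log_intensity
  fc <- rowMeans(li[, e$groups == "ATRT"]) - rowMeans(li[, e$groups == "MB"])
  expect_gt(min(fc[up]), 1)
  expect_lt(max(fc[dn]), -1)
  # both platforms carry the planted signal
  cpm <- log2(t(t(e$counts) / colSums(e$counts)) * 1e6 + 1)
  fc2 <- rowMeans(cpm[, e$groups == "ATRT"]) - rowMeans(cpm[, e$groups == "MB"])
  expect_gt(mean(sign(fc2[up])), 0.9)
})

test_that("study files round-trip through the plain-text writers", {
  cfg <- small_config()
  study <- simulate_study(cfg)
  dir <- file.path(tempdir(), "studyout")
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "probe_beta.tsv", "tile_counts.tsv", "tf_sites.bed", "tads_setA.bed",
    "genes.tsv", "enhancers.tsv", "motif.pfm", "truth.json", "config.yaml")))))
  back <- read_methylation_tsv(file.path(dir, "tile_counts.tsv"))
  expect_identical(SummarizedExperiment::assay(back, "meth"),
                   SummarizedExperiment::assay(study$tile_se, "meth"),
                   ignore_attr = TRUE)
  expect_equal(as_df(SummarizedExperiment::rowRanges(back)),
               as_df(SummarizedExperiment::rowRanges(study$tile_se)))
  pfm <- read_jaspar_pfm(file.path(dir, "motif.pfm"))
  expect_equal(pfm$counts, study$pwm_counts, ignore_attr = TRUE)
  cat_back <- read_bed(file.path(dir, "tf_sites.bed"),
                       extra_cols = "category")
  expect_equal(length(cat_back), length(study$catalog))
  unlink(dir, recursive = TRUE)
})
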