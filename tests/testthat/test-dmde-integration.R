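gene_models <- data.frame(
  gene = c("G1", "G1", "G2", "G3"),
  transcript = c("G1.1", "G1.2", "G2.1", "G3.1"),
  chrom = "chr1", tss = c(10001, 10201, 500001, 800001),
  strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)

test_that("DE caller enforces both significance and fold-change cutoffs", {
  set.seed(51)
  groups <- rep(c("A", "B"), each = 8)
  x <- matrix(rnorm(50 * 16, 8, 0.2), 50, 16,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  x["g01", groups == "A"] <- x["g01", groups == "A"] + 2    # clear DE
  x["g02", groups == "A"] <- x["g02", groups == "A"] + 0.99 # under |lfc| 1
  de <- call_de_genes(x, groups, c("A", "B"), "array")
  expect_true(de$significant[de$gene == "g01"])
  expect_false(de$significant[de$gene == "g02"])
  expect_lt(de$adj_p[de$gene == "g02"], 0.05) # excluded by lfc alone
  # null genes: roughly nominal false positive rate
  expect_lte(mean(de$significant[-(1:2)]), 0.1)
  # duplicated gene rows collapse by mean before testing
  x2 <- rbind(x, x["g01", , drop = FALSE])
  rownames(x2)[51] <- "g01"
  de2 <- call_de_genes(x2, groups, c("A", "B"), "array")
  expect_equal(nrow(de2), 50)
  # count input goes through log2-CPM first
  cn <- matrix(rnbinom(20 * 16, mu = 100, size = 20), 20, 16,
               dimnames = list(sprintf("c%02d", 1:20), NULL))
  cn["c01", groups == "A"] <- cn["c01", groups == "A"] * 8
  des <- call_de_genes(cn, groups, c("A", "B"), "seq")
  expect_true(des$significant[des$gene == "c01"])
  expect_gt(des$log2fc[des$gene == "c01"], 1)
})

test_that("promoters follow strand with clipping", {
  p <- build_promoters(gene_models)
  # + strand TSS 10001 (BED 10000): BED [8000,10500) -> 1-based [8001,10500]
  expect_equal(as_df(p[1, ]), data.frame(chrom = "chr1", start = 8001,
                                         end = 10500))
  # - strand TSS 500001: BED [499500,502000) -> [499501,502000]
  expect_equal(as_df(p[3, ]), data.frame(chrom = "chr1", start = 499501,
                                         end = 502000))
  gm <- data.frame(gene = "X", transcript = "X.1", chrom = "chr1",
                   tss = 101, strand = "+")
  expect_equal(GenomicRanges::start(build_promoters(gm)), 1)
  gm$strand <- "*"
  expect_warning(pu <- build_promoters(gm), "unknown strand")
  expect_equal(GenomicRanges::end(pu), 101 + 499)
})

test_that("DMR-gene linking respects mode-specific rules", {
  dmrs <- gr("chr1", c(9000, 210000, 600500), c(9400, 210400, 600900),
             direction = c("hyper", "hypo", "hyper"))
  # promoter: DMR 1 overlaps both G1 transcript promoters
  lp <- link_dmrs_to_genes(dmrs, gene_models, NULL, "promoter")
  expect_setequal(lp$transcript[lp$gene == "G1"], c("G1.1", "G1.2"))
  # neighborhood boundary: start exactly TSS + 199,999 is linked
  d2 <- gr("chr1", 10000 + 199999 + 1, 10000 + 200400, direction = "hyper")
  ln <- link_dmrs_to_genes(d2, gene_models, NULL, "neighborhood")
  expect_true("G1" %in% ln$gene)
  # beyond 200 kb of every G1 transcript (second TSS at 10201)
  d3 <- gr("chr1", 10200 + 200000 + 1, 10200 + 200400, direction = "hyper")
  ln3 <- link_dmrs_to_genes(d3, gene_models, NULL, "neighborhood")
  expect_false("G1" %in% ln3$gene)
  # enhancer confidence: 4.9 never linked, 5.0 linked
  enh <- data.frame(chrom = "chr1", start = c(9000, 9000),
                    end = c(9500, 9500), gene = c("G2", "G3"),
                    source = "genehancer", confidence = c(4.9, 5.0))
  le <- link_dmrs_to_genes(dmrs, gene_models, enh, "enhancer")
  expect_false("G2" %in% le$gene)
  expect_true("G3" %in% le$gene)
  # fantom-like links carry no confidence cutoff
  enh$source <- "fantom"
  lf <- link_dmrs_to_genes(dmrs, gene_models, enh, "enhancer")
  expect_setequal(unique(lf$gene), c("G2", "G3"))
  expect_error(link_dmrs_to_genes(dmrs, gene_models, NULL, "weird"))
})

pair_row <- function(gene, start, end, dir, tss = 10001, mode = "neighborhood")
  data.frame(gene = gene, transcript = paste0(gene, ".1"), mode = mode,
             dmr = 1L, chrom = "chr1", start = start, end = end,
             direction = dir, tss = tss, stringsAsFactors = FALSE)

test_that("cross-platform validation honors the 5-kb gap and direction", {
  # BED gap of exactly 5,000 bp: array [1000,2000), tile [7000,8000)
  pa <- pair_row("G1", 1001, 2000, "hyper")
  pt_ok <- pair_row("G1", 7001, 8000, "hyper")
  expect_equal(nrow(cross_platform_validate(pa, pt_ok)), 2)
  pt_far <- pair_row("G1", 7002, 8001, "hyper") # 5,001 bp apart
  expect_equal(nrow(cross_platform_validate(pa, pt_far)), 0)
  pt_opp <- pair_row("G1", 1001, 2000, "hypo") # same spot, wrong direction
  expect_equal(nrow(cross_platform_validate(pa, pt_opp)), 0)
  pt_gene <- pair_row("G2", 1001, 2000, "hyper") # right spot, wrong gene
  expect_equal(nrow(cross_platform_validate(pa, pt_gene)), 0)
})

test_that("TAD boundary filter counts boundaries strictly inside spans", {
  tads <- list(set1 = gr("chr1", c(1, 100001), c(100000, 200000)))
  inside <- pair_row("G1", 50001, 51000, "hyper", tss = 20001)
  out <- tad_boundary_filter(inside, tads)
  expect_equal(out$genes, "G1")
  crossing <- pair_row("G2", 150001, 151000, "hyper", tss = 20001)
  out2 <- tad_boundary_filter(rbind(inside, crossing), tads)
  expect_false("G2" %in% out2$genes)
  # literal mode drops a gene when any of its pairs crosses
  multi <- rbind(pair_row("G3", 50001, 51000, "hyper", tss = 20001),
                 pair_row("G3", 150001, 151000, "hyper", tss = 20001))
  expect_length(tad_boundary_filter(multi, tads)$genes, 0)
  expect_equal(tad_boundary_filter(multi, tads, mode = "any_pair")$genes, "G3")
  # a TAD set empty on the chromosome contributes no boundaries
  empty_set <- list(gr("chr2", 1, 100000))
  expect_equal(tad_boundary_filter(crossing, empty_set)$genes, "G2")
  # span endpoints touching a boundary do not count
  touch <- pair_row("G4", 100001, 101000, "hyper", tss = 20001)
  # span [20001, 100001]: boundary at 100000 is inside, 100001 touches
  expect_equal(tad_boundary_filter(touch, tads)$pairs$n_boundaries, 1L)
})

test_that("DM-DE classification separates opposite, parallel and mixed", {
  de_a <- data.frame(gene = c("G1", "G2", "G3"), log2fc = c(2, 2, -2),
                     p = 1e-6, adj_p = 1e-5, significant = TRUE,
                     platform = "array", comparison = "A_vs_B")
  de_s <- de_a; de_s$platform <- "seq"
  vp <- rbind(pair_row("G1", 1001, 2000, "hypo"),   # up + hypo -> opposite
              pair_row("G2", 1001, 2000, "hyper"),  # up + hyper -> parallel
              pair_row("G3", 1001, 2000, "hyper"),  # down + hyper -> opposite
              pair_row("G3", 3001, 4000, "hypo"))   # ... but mixed overall
  out <- classify_dm_de(vp, de_a, de_s)
  expect_equal(out$relation[out$gene == "G1"], "opposite")
  expect_equal(out$relation[out$gene == "G2"], "parallel")
  expect_equal(out$relation[out$gene == "G3"], "mixed")
  # DE significant on one platform only: gene never reported
  de_s2 <- de_s; de_s2$significant[de_s2$gene == "G1"] <- FALSE
  out2 <- classify_dm_de(vp, de_a, de_s2)
  expect_false("G1" %in% out2$gene)
  # opposite and parallel lists are disjoint by construction
  expect_length(intersect(out$gene[out$relation == "opposite"],
                          out$gene[out$relation == "parallel"]), 0)
})
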