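test_that("one-sided Fisher matches the log-gamma hypergeometric oracle", {
  expect_equal(fisher_one_sided(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(0, 10, 10, 0), 1.0)
  expect_error(fisher_one_sided(-1, 2, 3, 4), "non-negative")
  set.seed(12)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 20, 200), 1))
    got <- fisher_one_sided(cells[1], cells[2], cells[3], cells[4])
    exp <- fisher_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, exp, tolerance = 1e-12)
  }
})

# 40 units on chr1; a catalog with two TFs
unit_fixture <- function() {
  units <- gr("chr1", seq(1, by = 1000, length.out = 40),
              seq(1, by = 1000, length.out = 40) + 999)
  cat <- c(
    gr("chr1", seq(1, by = 1000, length.out = 40) + 100,
       seq(1, by = 1000, length.out = 40) + 150, tf = "COVERALL",
       category = "PSC"),
    gr("chr1", c(101, 1101, 2101, 3101), c(150, 1150, 2150, 3150),
       tf = "TARGETED", category = "neural"))
  list(units = units, catalog = cat)
}

test_that("enrichment contingency tables are consistent and bounded", {
  f <- unit_fixture()
  target <- f$units[1:4]
  res <- enrich_tf_sets(target, f$units, f$catalog)
  expect_equal(unique(res$a + res$b + res$c + res$d), 40L)
  # a TF covering every unit cannot be enriched
  expect_equal(res$p[res$tf == "COVERALL"], 1)
  # all four TARGETED sites inside the 4-unit target
  expect_lt(res$adj_p[res$tf == "TARGETED"], 0.05)
  expect_error(enrich_tf_sets(gr("chr2", 1, 10), f$units, f$catalog),
               "subset")
  # TF whose sites touch no background unit is omitted with a warning
  cat2 <- suppressWarnings(c(f$catalog, gr("chr9", 1, 2, tf = "GHOST",
                                           category = "PSC")))
  expect_warning(res2 <- enrich_tf_sets(target, f$units, cat2), "GHOST")
  expect_false("GHOST" %in% res2$tf)
  # category subset restricts the tested TFs to those measured there
  res3 <- enrich_tf_sets(target, f$units, f$catalog, category = "neural")
  expect_equal(res3$tf, "TARGETED")
})

test_that("categorized enrichment flags unmeasured pairs and matches 'all'", {
  f <- unit_fixture()
  target <- f$units[1:4]
  res <- categorized_enrichment(target, f$units, f$catalog)
  # TARGETED measured only in 'neural'
  row_psc <- res[res$tf == "TARGETED" & res$category == "PSC", ]
  expect_false(row_psc$measured)
  row_neu <- res[res$tf == "TARGETED" & res$category == "neural", ]
  expect_true(row_neu$measured)
  # a single-category catalog: category run equals the plain run
  cat1 <- f$catalog[f$catalog$category == "neural"]
  plain <- enrich_tf_sets(target, f$units, cat1)
  catr <- categorized_enrichment(target, f$units, cat1)
  expect_equal(catr[catr$measured, c("a", "b", "c", "d", "p")],
               plain[, c("a", "b", "c", "d", "p")], ignore_attr = TRUE)
})

test_that("cross-platform validation intersects significant TFs", {
  ra <- list(A_hyper = data.frame(tf = c("T1", "T2"), adj_p = c(0.01, 0.2)))
  rt <- list(A_hyper = data.frame(tf = c("T1", "T2"), adj_p = c(0.04, 0.01)))
  expect_equal(validate_across_platforms(ra, rt)$A_hyper, "T1")
  rt2 <- list(A_hyper = data.frame(tf = "T2", adj_p = 0.01))
  expect_length(validate_across_platforms(ra, rt2)$A_hyper, 0)
})

test_that("co-localization matrix is symmetric with calibrated nulls", {
  regions <- gr("chr1", seq(1, by = 1000, length.out = 60),
                seq(1, by = 1000, length.out = 60) + 999)
  # two TFs sharing identical sites over half the regions
  shared <- gr("chr1", seq(1, by = 2000, length.out = 30) + 10,
               seq(1, by = 2000, length.out = 30) + 60)
  cat <- c(shared, shared, gr("chr1", c(5, 25005), c(55, 25055)))
  S4Vectors::mcols(cat)$tf <- c(rep("P", 30), rep("Q", 30), "R", "R")
  cm <- colocalization_matrix(c("P", "Q", "R"), regions, cat)
  expect_equal(cm$adj_p, t(cm$adj_p))
  expect_equal(diag(cm$adj_p), rep(0, 3), ignore_attr = TRUE)
  expect_equal(min(cm$p[upper.tri(cm$p)]), cm$p["P", "Q"])
  expect_lt(cm$p["P", "Q"], 1e-10)

  # TFs that never co-occur: one-sided co-occurrence p = 1
  a <- gr("chr1", c(10, 1010), c(60, 1060), tf = "U")
  b <- gr("chr1", c(2010, 3010), c(2060, 3060), tf = "V")
  cm2 <- colocalization_matrix(c("U", "V"), regions, c(a, b))
  expect_equal(cm2$p["U", "V"], 1)

  # independent random sites: ~5% of pairs nominally significant
  set.seed(33)
  ntf <- 24
  sites <- do.call(c, lapply(seq_len(ntf), function(i) {
    s <- sample(59000, 25)
    gr("chr1", s, s + 40, tf = sprintf("N%02d", i))
  }))
  cm3 <- colocalization_matrix(sprintf("N%02d", seq_len(ntf)), regions, sites)
  frac <- mean(cm3$p[upper.tri(cm3$p)] < 0.05)
  se <- sqrt(0.05 * 0.95 / choose(ntf, 2))
  expect_lte(frac, 0.05 + 3 * se)
  expect_error(colocalization_matrix("P", regions, cat), "at least 2")
})

test_that("binding-site methylation honors the 500-bp gap boundary", {
  groups <- c("A", "A", "B")
  beta <- matrix(c(0.1, 0.2, 0.9), 1)
  cat <- gr("chr1", 10001, 10150, tf = "T")
  # probe ending exactly 500 bp before the site: gap = 500 -> included
  se_in <- make_probe_se("chr1", 9451, beta, groups) # [9451,9500], gap 500
  out <- binding_site_methylation(se_in, cat, "T")
  expect_equal(nrow(out), 2) # one probe x two groups
  expect_equal(out$beta[out$group == "A"], 0.15)
  # gap 501 -> excluded
  se_out <- make_probe_se("chr1", 9450, beta, groups)
  expect_warning(out2 <- binding_site_methylation(se_out, cat, "T"),
                 "no probes")
  expect_equal(nrow(out2), 0)
  expect_error(binding_site_methylation(se_in, cat, "NOPE"), "not in catalog")
})

test_that("clusterwise enrichment localizes the signal to its cluster", {
  f <- unit_fixture()
  regions <- gr("chr1", c(1, 20001), c(4000, 24000))
  res <- clusterwise_enrichment(regions, c(1, 2), f$units, f$catalog)
  r1 <- res[res$cluster == 1 & res$tf == "TARGETED", ]
  r2 <- res[res$cluster == 2 & res$tf == "TARGETED", ]
  expect_lt(r1$p, 0.05)
  expect_equal(r2$a, 0L)
  expect_equal(r2$p, 1)
})
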