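# fixtures: two groups of 4 samples over a handful of tiles/probes
tile_fixture <- function(betas1, betas2, depth = 50, low_cov_tile = NULL) {
  n <- length(betas1)
  groups <- rep(c("A", "B"), each = 4)
  total <- matrix(depth, n, 8)
  if (!is.null(low_cov_tile)) total[low_cov_tile, 1] <- 9
  b <- cbind(matrix(betas1, n, 4), matrix(betas2, n, 4))
  meth <- round(total * b)
  make_tile_se("chr1", seq(1, by = 1000, length.out = n), meth, total, groups)
}

test_that("tile caller drops low-coverage and non-canonical tiles", {
  se <- tile_fixture(c(0.9, 0.9, 0.5), c(0.1, 0.1, 0.5), low_cov_tile = 2)
  out <- call_dmrs_tiles(se, c("A", "B"), all_tested = TRUE)
  expect_equal(nrow(out$tests), 2) # tile 2 excluded before testing
  # chrX tile excluded regardless of coverage
  groups <- rep(c("A", "B"), each = 4)
  se2 <- make_tile_se(c("chr1", "chrX"), c(1, 1),
                      matrix(25, 2, 8), matrix(50, 2, 8), groups)
  out2 <- call_dmrs_tiles(se2, c("A", "B"), all_tested = TRUE)
  expect_equal(nrow(out2$tests), 1)
  expect_error(call_dmrs_tiles(se, c("A", "C")), "at least 2 samples")
})

test_that("tile caller finds strong planted differences with directions", {
  set.seed(31)
  n <- 60
  b1 <- rep(0.4, n); b2 <- rep(0.4, n)
  b1[1:10] <- 0.8 # hyper in A
  b2[11:20] <- 0.8 # hypo in A
  groups <- rep(c("A", "B"), each = 5)
  total <- matrix(rpois(n * 10, 40), n, 10)
  mu <- cbind(matrix(b1, n, 5), matrix(b2, n, 5))
  meth <- matrix(rbinom(n * 10, as.vector(total),
                        as.vector(plogis(qlogis(mu) + rnorm(n * 10, 0, 0.2)))),
                 n, 10)
  se <- make_tile_se("chr1", seq(1, by = 1000, length.out = n), meth, total,
                     groups)
  out <- call_dmrs_tiles(se, c("A", "B"))
  expect_gte(sum(out$regions$direction == "hyper" &
                   GenomicRanges::start(out$regions) <= 10000), 8)
  expect_gte(sum(out$regions$direction == "hypo"), 8)
  expect_true(all(out$regions$direction ==
                    ifelse(out$regions$delta_beta > 0, "hyper", "hypo")))
  # monotonicity: stricter thresholds never yield more DMRs
  n1 <- length(call_dmrs_tiles(se, c("A", "B"), min_delta = 0.30)$regions)
  n2 <- length(call_dmrs_tiles(se, c("A", "B"), max_q = 0.01)$regions)
  expect_lte(n1, length(out$regions))
  expect_lte(n2, length(out$regions))
})

probe_fixture <- function(starts, d, noise = 0.02, n_per_group = 5,
                          seed = 13) {
  set.seed(seed)
  n <- length(starts)
  groups <- rep(c("A", "B"), each = n_per_group)
  base <- matrix(0.4, n, 2 * n_per_group)
  base[, seq_len(n_per_group)] <- base[, seq_len(n_per_group)] + d
  beta <- matrix(pmin(0.99, pmax(0.01, base +
                                   rnorm(n * 2 * n_per_group, 0, noise))),
                 n, 2 * n_per_group)
  make_probe_se("chr1", starts, beta, groups)
}

test_that("probe caller merges by gap and applies the region delta filter", {
  # two significant probes 1,001 bp apart split into two regions
  se <- probe_fixture(c(1000, 2051), d = c(0.4, 0.4)) # gap = 2051-1049-1... BED gap 1001
  out <- call_dmrs_probes(se, c("A", "B"))
  expect_length(out$regions, 2)
  # 1,000 bp apart: merged into one
  se2 <- probe_fixture(c(1000, 2050), d = c(0.4, 0.4))
  out2 <- call_dmrs_probes(se2, c("A", "B"))
  expect_length(out2$regions, 1)
  expect_equal(out2$regions$n_units, 2L)

  # region mean |delta| 0.19 excluded at the 0.20 threshold
  se3 <- probe_fixture(c(1000, 1200), d = c(0.19, 0.19), noise = 0.005)
  out3 <- call_dmrs_probes(se3, c("A", "B"))
  expect_length(out3$regions, 0)
  out3b <- call_dmrs_probes(se3, c("A", "B"), final_delta = 0.15)
  expect_length(out3b$regions, 1)
})

test_that("probe caller recovers a planted multi-probe DMR", {
  set.seed(41)
  starts <- sort(sample(200000, 400))
  d <- rep(0, 400)
  inside <- starts >= 50000 & starts <= 51000
  # ensure the planted window has probes
  starts <- c(starts, seq(50000, 50900, by = 130))
  d <- c(d, rep(0, 8)); o <- order(starts); starts <- starts[o]
  inside <- starts >= 50000 & starts <= 51000
  d <- ifelse(inside, 0.4, 0)
  se <- probe_fixture(starts, d, noise = 0.05)
  out <- call_dmrs_probes(se, c("A", "B"))
  hit <- subset_by_overlap(out$regions, gr("chr1", 50000, 51950))
  expect_gte(length(hit), 1)
  expect_equal(hit$delta_beta[1], 0.4, tolerance = 0.05)
  expect_true(all(out$units$region %in% seq_along(out$regions)))
})

test_that("covariate confounded with group is skipped with a warning", {
  se <- probe_fixture(c(1000, 1200), d = c(0.4, 0.4))
  expect_warning(call_dmrs_probes(se, c("A", "B"),
                                  covariate = rep(c("x", "y"), each = 5)),
                 "confounded")
})

test_that("control filtering keeps only intersecting spans", {
  main <- dmrset_from("chr1", 1001, 2000, 0.5)
  ctrl <- dmrset_from("chr1", 1501, 3000, 0.5, comparison = c("A", "C"))
  out <- filter_by_controls(main, list(ctrl))
  expect_equal(as_df(out$regions),
               data.frame(chrom = "chr1", start = 1501, end = 2000))
  expect_equal(out$regions$delta_beta, 0.5)

  none <- dmrset_from("chr2", 1, 100, 0.5, comparison = c("A", "C"))
  expect_length(filter_by_controls(main, list(none))$regions, 0)
  expect_warning(out2 <- filter_by_controls(main, list()), "no control")
  expect_length(out2$regions, 1)

  two <- dmrset_from("chr1", c(1101, 1601), c(1300, 1900), c(0.5, 0.5),
                     comparison = c("A", "C"))
  spans <- filter_by_controls(main, list(two))$regions
  expect_equal(as_df(spans), data.frame(chrom = "chr1",
                                        start = c(1101, 1601),
                                        end = c(1300, 1900)))
})

test_that("cancer-specific extraction honors the 600-bp overlap rule", {
  # extended probes overlap exactly 600 bp between the two comparisons
  ab <- dmrset_from("chr1", 5001, 5050, 0.4)
  ac <- dmrset_from("chr1", 5451, 5500, 0.4, comparison = c("A", "C"))
  # extended: [4501,5550] and [4951,6000] -> overlap 600
  out <- extract_cancer_specific(ab, ac)
  expect_length(out$hyper, 1)
  ac2 <- dmrset_from("chr1", 5452, 5501, 0.4, comparison = c("A", "C"))
  expect_length(extract_cancer_specific(ab, ac2)$hyper, 0) # overlap 599

  # direction conflict excluded from both outputs
  conf <- dmrset_from("chr1", 5001, 5050, -0.4, comparison = c("A", "C"))
  both <- extract_cancer_specific(ab, conf)
  expect_length(both$hyper, 0); expect_length(both$hypo, 0)

  # inputs under |delta| 0.25 ignored
  weak <- dmrset_from("chr1", 5001, 5050, 0.2)
  expect_length(extract_cancer_specific(weak, ac)$hyper, 0)
  expect_error(extract_cancer_specific(ab, dmrset_from(
    "chr1", 1, 50, 0.4, comparison = c("B", "C"))), "focal")
})

test_that("tile platform requires exact coordinate identity", {
  ab <- dmrset_from("chr1", 1001, 2000, 0.4, platform = "tiles")
  ac_same <- dmrset_from("chr1", 1001, 2000, 0.4, platform = "tiles",
                         comparison = c("A", "C"))
  ac_shift <- dmrset_from("chr1", 1501, 2500, 0.4, platform = "tiles",
                          comparison = c("A", "C"))
  expect_length(extract_cancer_specific(ab, ac_same)$hyper, 1)
  expect_length(extract_cancer_specific(ab, ac_shift)$hyper, 0)
})

test_that("four-field counts and percentages are exact", {
  empty <- list(X = list(array = list(hyper = gr("chr1", 1, 1)[0],
                                      hypo = gr("chr1", 1, 1)[0])))
  t0 <- count_direction_fourfield(empty)
  expect_equal(t0$n, c(0, 0))
  mixed <- list(X = list(array = list(hyper = gr("chr1", seq_len(99) * 100,
                                                 seq_len(99) * 100 + 50),
                                      hypo = gr("chr1", 1, 50))))
  t1 <- count_direction_fourfield(mixed)
  expect_equal(t1$n, c(99, 1))
  expect_equal(t1$pct, c(99, 1))
})
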