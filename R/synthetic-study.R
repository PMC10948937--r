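# Synthetic study generator: a two-platform methylome cohort (three tumor
# groups, controls, PSC, FB), a regulatory genome (genes, enhancers, TADs,
# TF binding catalog, motif), expression data and CUT&RUN peaks, all with
# machine-readable ground truth for every planted signal.

#' Study configuration
#'
#' Defaults define the simulated study conditions: a 20.1-Mb genome (four
#' 5-Mb autosomes giving 20,000 1-kb tiles, plus a 100-kb chrX to
#' exercise canonical-chromosome filtering), 10 samples per tumor/control
#' group and 6 per PSC/FB group, 50-bp probes at two per tile,
#' beta-distributed methylation with concentration 50, 30x mean tile
#' coverage, planted DMRs with |delta beta| 0.4, a TF binding catalog with
#' one TF planted at 5x background in AT/RT-hyper regions and one planted
#' only through its PSC-category sites, TAD-scale shifts in two TADs, and
#' DM-DE genes with |log2FC| 2 in 8-sample expression groups.
#'
#' @param seed Integer seed; all outputs are deterministic in it.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param tile_width Tile width in bp.
#' @param n_samples Named sample counts per methylome group.
#' @param concentration Beta-distribution concentration (larger = less
#'   sample-to-sample noise).
#' @param depth Mean tile read depth per sample.
#' @param probes_per_tile Probes fully contained per tile.
#' @param delta Planted |delta beta| between the focal group and the rest.
#' @param base_low,base_high Baseline means for hypo/hyper planted regions.
#' @param n_dmrs Named planted cancer-specific DMR counts, per cancer and
#'   direction.
#' @param n_largescale Planted DMR regions per large-scale TAD.
#' @param n_tfs,sites_per_tf,site_width TF catalog shape.
#' @param tf_fold Planted enrichment fold over background for the planted
#'   TF.
#' @param n_genes Gene count.
#' @param n_expr Expression samples per tumor group.
#' @param lfc Planted |log2 fold change| for DM-DE genes.
#' @param dmde_spec Named counts of planted DM-DE genes: `promoter`,
#'   `enhancer`, `neighborhood` (opposite-direction), `parallel`, and
#'   `crossing` (TSS-DMR span crossing a TAD boundary).
#' @param null_study If `TRUE`, nothing is planted (calibration runs).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         chrom_lengths = c(chr1 = 5e6, chr2 = 5e6,
                                           chr3 = 5e6, chr4 = 5e6,
                                           chrX = 100000),
                         tile_width = 1000,
                         n_samples = c(ATRT = 10, MB = 10, PLEX = 10,
                                       CONTR = 10, PSC = 6, FB = 6),
                         concentration = 50, depth = 30,
                         probes_per_tile = 2, delta = 0.4,
                         base_low = 0.30, base_high = 0.70,
                         n_dmrs = c(ATRT_hyper = 6, ATRT_hypo = 6,
                                    MB_hyper = 3, MB_hypo = 9,
                                    PLEX_hyper = 2, PLEX_hypo = 6),
                         n_largescale = 6,
                         n_tfs = 30, sites_per_tf = 2000, site_width = 150,
                         tf_fold = 5,
                         n_genes = 300, n_expr = 8, lfc = 2,
                         dmde_spec = c(promoter = 6, enhancer = 5,
                                       neighborhood = 5, parallel = 8,
                                       crossing = 4),
                         null_study = FALSE) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("tile_width", "depth", "concentration")]) <= 0))
    stop("config values must be positive")
  structure(cfg, class = "study_config")
}

# Deterministic layout shared by all generators: tiles, probes, TADs,
# planted regions, genes, enhancers, TF catalog.
study_plan <- function(config) {
  set.seed(config$seed)
  cl <- config$chrom_lengths
  autosomes <- names(cl)[names(cl) %in% paste0("chr", 1:22)]

  # tiles: non-overlapping 1-kb grid over every chromosome
  tile_df <- do.call(rbind, lapply(names(cl), function(ch) {
    starts <- seq(1, cl[[ch]] - config$tile_width + 1, by = config$tile_width)
    data.frame(chrom = ch, start = starts)
  }))
  tiles <- GenomicRanges::GRanges(
    tile_df$chrom, IRanges::IRanges(tile_df$start,
                                    tile_df$start + config$tile_width - 1))
  auto_tile <- which(is_canonical(tiles))

  # TAD set A: random segmentation of autosomes into 150-300 kb domains;
  # TAD set B: the same boundaries jittered by up to 4 kb.
  segment <- function(ch) {
    b <- c(1)
    while (b[length(b)] < cl[[ch]])
      b <- c(b, min(cl[[ch]], b[length(b)] +
                      round(stats::runif(1, 150000, 300000))))
    b
  }
  bounds_a <- lapply(autosomes, segment)
  names(bounds_a) <- autosomes
  tad_tab <- function(bounds) do.call(rbind, lapply(autosomes, function(ch) {
    b <- bounds[[ch]]
    data.frame(chrom = ch, start = b[-length(b)], end = b[-1] - 1)
  }))
  ta <- tad_tab(bounds_a)
  # set B shares set A's layout with jittered internal boundaries
  bounds_b <- lapply(autosomes, function(ch) {
    b <- bounds_a[[ch]]
    inner <- b[-c(1, length(b))]
    c(1, sort(pmin(cl[[ch]] - 1,
                   pmax(2, inner + round(stats::runif(length(inner),
                                                      -4000, 4000))))),
      cl[[ch]])
  })
  names(bounds_b) <- autosomes
  tb <- tad_tab(bounds_b)
  tad_a <- GenomicRanges::GRanges(ta$chrom, IRanges::IRanges(ta$start, ta$end))
  tad_b <- GenomicRanges::GRanges(tb$chrom, IRanges::IRanges(tb$start, tb$end))
  tads <- list(setA = tad_a, setB = tad_b)

  # planted regions -----------------------------------------------------
  # Tile-grid regions of 2-3 tiles. Large-scale regions cluster inside two
  # chr1 TADs; scattered regions get at most one region per TAD so the
  # 5-hit / 50-kb rules cannot fire by accident; DM-DE regions likewise.
  planted <- NULL
  dev_cats_hyper <- c("psc_like", "fb_like", "unique_unchanged", "unique_dev")
  tad_chrom <- as.character(GenomicRanges::seqnames(tad_a))
  tad_start <- GenomicRanges::start(tad_a)
  tad_end <- GenomicRanges::end(tad_a)
  tad_width <- tad_end - tad_start + 1
  ls_idx <- which(tad_chrom == "chr1" & tad_width > 220000)[1:2]
  used_tads <- integer() # indices into tad_a already hosting a region

  region_in_tad <- function(tad_idx, n_tiles, at = NULL) {
    lo_tile <- ceiling((tad_start[tad_idx] + 12000) / config$tile_width)
    hi_tile <- floor((tad_end[tad_idx] - 12000) / config$tile_width) - n_tiles
    t0 <- if (is.null(at)) sample(lo_tile:hi_tile, 1) else at
    start <- (t0 - 1) * config$tile_width + 1
    data.frame(chrom = tad_chrom[tad_idx], start = start,
               end = start + n_tiles * config$tile_width, n_tiles = n_tiles)
  }

  if (!config$null_study) {
    rows <- list()
    add <- function(df) rows[[length(rows) + 1]] <<- df

    # large-scale TADs: n_largescale hyper regions spread over > 50 kb each
    for (i in seq_along(ls_idx)) {
      tad_idx <- ls_idx[i]
      used_tads <- c(used_tads, tad_idx)
      lo_tile <- ceiling((tad_start[tad_idx] + 12000) / config$tile_width)
      anchors <- round(seq(lo_tile, lo_tile + 150, length.out =
                             config$n_largescale))
      for (k in seq_len(config$n_largescale)) {
        r <- region_in_tad(tad_idx, 2, at = anchors[k])
        r$focal <- "ATRT"; r$direction <- "hyper"
        r$category <- dev_cats_hyper[(k - 1) %% 4 + 1]
        r$purpose <- "largescale"; r$largescale_tad <- i
        add(r)
      }
    }

    # scattered cancer-specific regions, one TAD each
    free_tads <- setdiff(which(tad_width > 120000), used_tads)
    free_tads <- sample(free_tads)
    ti <- 1
    for (nm in names(config$n_dmrs)) {
      parts <- strsplit(nm, "_")[[1]]
      for (k in seq_len(config$n_dmrs[[nm]])) {
        r <- region_in_tad(free_tads[ti], sample(2:3, 1))
        ti <- ti + 1
        r$focal <- parts[1]; r$direction <- parts[2]
        r$category <- dev_cats_hyper[(k - 1) %% 4 + 1]
        r$purpose <- "cancer"; r$largescale_tad <- NA
        add(r)
      }
    }

    # DM-DE regions (AT/RT vs MB focal): DMR direction opposite (or equal,
    # for the parallel set) to the planted expression change in AT/RT
    ds <- config$dmde_spec
    n_opp <- ds[["promoter"]] + ds[["enhancer"]] + ds[["neighborhood"]]
    dmde_modes <- c(rep("promoter", ds[["promoter"]]),
                    rep("enhancer", ds[["enhancer"]]),
                    rep("neighborhood", ds[["neighborhood"]]),
                    rep_len(c("promoter", "neighborhood"), ds[["parallel"]]),
                    rep("neighborhood", ds[["crossing"]]))
    dmde_rel <- c(rep("opposite", n_opp), rep("parallel", ds[["parallel"]]),
                  rep("opposite", ds[["crossing"]]))
    dmde_cross <- c(rep(FALSE, n_opp + ds[["parallel"]]),
                    rep(TRUE, ds[["crossing"]]))
    for (k in seq_along(dmde_modes)) {
      # anchor near the TAD start so TSS offsets up to 30 kb stay inside
      # the TAD (both jittered sets) unless boundary-crossing is intended
      host_start <- tad_start[free_tads[ti]]
      r <- region_in_tad(free_tads[ti], 2,
                         at = ceiling((host_start + 20000) / config$tile_width))
      ti <- ti + 1
      up <- k %% 2 == 0 # gene up or down in AT/RT
      dmr_dir <- if (dmde_rel[k] == "opposite") {
        if (up) "hypo" else "hyper"
      } else {
        if (up) "hyper" else "hypo"
      }
      r$focal <- "ATRT"; r$direction <- dmr_dir
      r$category <- "unique_unchanged"
      r$purpose <- "dmde"; r$largescale_tad <- NA
      r$dmde_mode <- dmde_modes[k]; r$dmde_up <- up
      r$dmde_relation <- dmde_rel[k]; r$dmde_cross <- dmde_cross[k]
      r$dmde_tad <- free_tads[ti - 1]
      add(r)
    }
    for (i in seq_along(rows)) {
      for (col in c("dmde_mode", "dmde_up", "dmde_relation", "dmde_cross",
                    "dmde_tad"))
        if (is.null(rows[[i]][[col]]))
          rows[[i]][[col]] <- if (col == "dmde_up" || col == "dmde_cross")
            NA else if (col == "dmde_tad") NA_integer_ else NA_character_
    }
    planted <- do.call(rbind, rows)
    planted$region_id <- seq_len(nrow(planted))
  }

  # per-tile, per-group mean methylation --------------------------------
  groups <- names(config$n_samples)
  mu0 <- 0.05 + 0.9 * stats::rbinom(length(tiles), 1, 0.5) *
    stats::runif(length(tiles), 0.7, 1) +
    0.9 * 0 # bimodal: low around 0.05-0.14, high around 0.68-0.95
  lowside <- mu0 < 0.5
  mu0[lowside] <- stats::runif(sum(lowside), 0.05, 0.25)
  mu <- matrix(mu0, length(tiles), length(groups),
               dimnames = list(NULL, groups))

  tile_of <- function(chrom, pos) { # tile index on the global grid
    idx <- integer(length(chrom))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      base <- which(as.character(GenomicRanges::seqnames(tiles)) == ch)[1] - 1
      idx[sel] <- base + ceiling(pos[sel] / config$tile_width)
    }
    idx
  }

  if (!is.null(planted)) {
    hb <- config$base_high; lb <- config$base_low
    for (i in seq_len(nrow(planted))) {
      t0 <- tile_of(planted$chrom[i], planted$start[i])
      tix <- t0:(t0 + planted$n_tiles[i] - 1)
      hyper <- planted$direction[i] == "hyper"
      base <- if (hyper) lb else hb
      focal_val <- if (hyper) hb else lb
      mu[tix, ] <- base
      mu[tix, planted$focal[i]] <- focal_val
      psc <- base; fb <- base
      if (planted$category[i] == "psc_like") { psc <- focal_val }
      if (planted$category[i] == "fb_like") { fb <- focal_val }
      if (planted$category[i] == "unique_dev") {
        if (hyper) { psc <- 0.35; fb <- 0.03 } else { psc <- 0.65; fb <- 0.97 }
      }
      mu[tix, "PSC"] <- psc; mu[tix, "FB"] <- fb
    }
  }

  # probes: probes_per_tile fully inside each tile, plus a 2% fringe of
  # boundary-straddling probes that the full-containment rule must drop
  off_max <- config$tile_width - 51
  pr_start <- rep(GenomicRanges::start(tiles), config$probes_per_tile) +
    round(stats::runif(length(tiles) * config$probes_per_tile, 0, off_max))
  pr_chrom <- rep(as.character(GenomicRanges::seqnames(tiles)),
                  config$probes_per_tile)
  pr_tile <- rep(seq_along(tiles), config$probes_per_tile)
  n_strad <- round(0.02 * length(tiles))
  strad_tile <- sample(which(GenomicRanges::start(tiles) >
                               config$tile_width), n_strad)
  strad_start <- GenomicRanges::start(tiles)[strad_tile] - 25
  probes <- GenomicRanges::GRanges(
    c(pr_chrom, as.character(GenomicRanges::seqnames(tiles))[strad_tile]),
    IRanges::IRanges(c(pr_start, strad_start),
                     c(pr_start, strad_start) + 49))
  probe_tile <- c(pr_tile, strad_tile)
  o <- order(as.character(GenomicRanges::seqnames(probes)),
             GenomicRanges::start(probes))
  probes <- probes[o]; probe_tile <- probe_tile[o]

  # genes, enhancers ----------------------------------------------------
  genes <- NULL; enhancers <- NULL
  gene_tads <- sample(setdiff(which(tad_width > 120000), used_tads))
  gene_names <- sprintf("G%03d", seq_len(config$n_genes))
  tss <- integer(config$n_genes); gchr <- character(config$n_genes)
  gstr <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  dmde_rows <- if (!is.null(planted)) which(planted$purpose == "dmde") else integer()
  for (g in seq_len(config$n_genes)) {
    if (g <= length(dmde_rows)) {
      i <- dmde_rows[g] # pair gene g with DM-DE region i
      ch <- planted$chrom[i]
      if (planted$dmde_mode[i] == "promoter") {
        # TSS just downstream of the region so the promoter covers it
        tss[g] <- planted$end[i] + 400; gstr[g] <- "+"
      } else if (planted$dmde_mode[i] == "enhancer") {
        tss[g] <- planted$end[i] + 20000
      } else if (!planted$dmde_cross[i]) {
        tss[g] <- planted$end[i] + 30000 # same TAD, neighborhood only
      } else {
        # put the TSS beyond the hosting TAD's end: span crosses a boundary
        tss[g] <- tad_end[planted$dmde_tad[i]] + 15000
      }
      gchr[g] <- ch
    } else {
      td <- gene_tads[(g %% length(gene_tads)) + 1]
      gchr[g] <- tad_chrom[td]
      tss[g] <- tad_start[td] +
        round(stats::runif(1, 20000, tad_width[td] - 20000))
    }
  }
  n_tx <- sample(1:2, config$n_genes, replace = TRUE)
  genes <- do.call(rbind, lapply(seq_len(config$n_genes), function(g) {
    data.frame(gene = gene_names[g],
               transcript = paste0(gene_names[g], ".", seq_len(n_tx[g])),
               chrom = gchr[g],
               tss = tss[g] + c(0, 120)[seq_len(n_tx[g])],
               strand = gstr[g], stringsAsFactors = FALSE)
  }))

  enh_rows <- list()
  for (g in seq_len(config$n_genes)) {
    is_dmde_enh <- g <= length(dmde_rows) &&
      planted$dmde_mode[dmde_rows[g]] == "enhancer"
    if (is_dmde_enh) {
      i <- dmde_rows[g]
      enh_rows[[length(enh_rows) + 1]] <- data.frame(
        chrom = planted$chrom[i], start = planted$start[i] + 100,
        end = planted$end[i] - 100, gene = gene_names[g],
        source = "genehancer", confidence = round(stats::runif(1, 6, 10), 1),
        stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.3) {
      w <- round(stats::runif(1, 500, 2000))
      s <- max(1, tss[g] + round(stats::runif(1, -40000, 40000)))
      enh_rows[[length(enh_rows) + 1]] <- data.frame(
        chrom = gchr[g], start = s, end = s + w, gene = gene_names[g],
        source = sample(c("genehancer", "fantom"), 1),
        confidence = round(stats::runif(1, 0, 10), 1),
        stringsAsFactors = FALSE)
    }
  }
  enhancers <- do.call(rbind, enh_rows)

  # TF binding-site catalog ---------------------------------------------
  categories <- c("brain_tumor_ATRT", "brain_tumor_MB", "brain_tumor_PLEX",
                  "other_brain_tumors", "neural_progenitors",
                  "neural_differentiated", "other_brain_neural", "PSC",
                  "other_cancers", "blood", "other")
  auto_len <- sum(cl[autosomes])
  target_bp <- if (!is.null(planted))
    sum(planted$end[planted$direction == "hyper" & planted$focal == "ATRT"] -
          planted$start[planted$direction == "hyper" &
                          planted$focal == "ATRT"]) else 0
  cat_rows <- list()
  rand_site <- function(n) {
    ch <- sample(autosomes, n, replace = TRUE)
    s <- round(stats::runif(n, 1, cl[ch] - config$site_width))
    data.frame(chrom = ch, start = s, end = s + config$site_width - 1,
               stringsAsFactors = FALSE)
  }
  site_in_target <- function(n) {
    tgt <- planted[planted$direction == "hyper" & planted$focal == "ATRT", ]
    pick <- sample(nrow(tgt), n, replace = TRUE)
    s <- tgt$start[pick] + round(stats::runif(n, 0, tgt$end[pick] -
                                                tgt$start[pick] -
                                                config$site_width))
    data.frame(chrom = tgt$chrom[pick], start = s,
               end = s + config$site_width - 1, stringsAsFactors = FALSE)
  }
  tf_names <- c(sprintf("TF%02d", seq_len(config$n_tfs - 1)), "NEUROD1")
  for (tf in tf_names) {
    n <- config$sites_per_tf
    if (!config$null_study && tf == "TF01") {
      n_in <- round(config$tf_fold * n * target_bp / auto_len)
      df <- rbind(site_in_target(n_in), rand_site(n - n_in))
      df$category <- sample(categories, n, replace = TRUE)
    } else if (!config$null_study && tf == "TF02") {
      # planted only through the PSC category
      n_psc <- round(0.5 * n); n_in <- 30
      df <- rbind(site_in_target(n_in), rand_site(n - n_in))
      df$category <- c(rep("PSC", n_psc),
                       sample(setdiff(categories, "PSC"), n - n_psc,
                              replace = TRUE))
    } else if (!config$null_study && tf == "NEUROD1") {
      n_in <- round(0.05 * n)
      df <- rbind(site_in_target(n_in), rand_site(n - n_in))
      df$category <- sample(categories, n, replace = TRUE)
    } else {
      df <- rand_site(n)
      df$category <- sample(categories, n, replace = TRUE)
    }
    df$tf <- tf
    cat_rows[[length(cat_rows) + 1]] <- df
  }
  cat_df <- do.call(rbind, cat_rows)
  catalog <- GenomicRanges::GRanges(cat_df$chrom,
                                    IRanges::IRanges(cat_df$start, cat_df$end),
                                    tf = cat_df$tf, category = cat_df$category)
  catalog <- sort_intervals(catalog)

  list(tiles = tiles, auto_tile = auto_tile, probes = probes,
       probe_tile = probe_tile, mu = mu, tads = tads, planted = planted,
       genes = genes, enhancers = enhancers, catalog = catalog,
       categories = categories,
       dmde_genes = if (length(dmde_rows))
         data.frame(gene = gene_names[seq_along(dmde_rows)],
                    planted[dmde_rows, c("chrom", "start", "end", "direction",
                                         "dmde_mode", "dmde_up",
                                         "dmde_relation", "dmde_cross")],
                    row.names = NULL) else NULL)
}

#' Generate the two-platform methylomes
#'
#' Draws probe-level beta values and tile-level (methylated, total) read
#' counts over the planted study layout. Per unit and sample the
#' methylation level is Beta(mu c, (1 - mu) c) around the group mean mu;
#' tile totals are Poisson around the configured depth (with per-sample
#' scale factors) and methylated counts Binomial(total, beta).
#'
#' @param config A [study_config()].
#' @return List with `probe_se` and `tile_se`
#'   (`RangedSummarizedExperiment`s) and the `truth` tables.
#' @export
simulate_methylomes <- function(config) {
  plan <- study_plan(config)
  set.seed(config$seed + 1L)
  groups <- rep(names(config$n_samples), config$n_samples)
  ns <- length(groups)
  cc <- config$concentration

  draw_beta <- function(mu_vec) { # units x samples
    m <- matrix(mu_vec, length(mu_vec), ns)
    gm <- plan$mu[, groups, drop = FALSE]
    matrix(stats::rbeta(length(gm), gm * cc, (1 - gm) * cc),
           nrow(gm), ns)
  }

  probe_mu <- plan$mu[plan$probe_tile, , drop = FALSE]
  pg <- probe_mu[, groups, drop = FALSE]
  probe_beta <- matrix(stats::rbeta(length(pg), pg * cc, (1 - pg) * cc),
                       nrow(pg), ns)
  colnames(probe_beta) <- paste0(groups, "_", sequence(config$n_samples))

  tg <- plan$mu[, groups, drop = FALSE]
  tile_beta <- matrix(stats::rbeta(length(tg), tg * cc, (1 - tg) * cc),
                      nrow(tg), ns)
  sample_scale <- stats::runif(ns, 0.7, 1.3)
  total <- matrix(stats::rpois(length(tile_beta),
                               lambda = rep(config$depth * sample_scale,
                                            each = nrow(tile_beta))),
                  nrow(tile_beta), ns)
  meth <- matrix(stats::rbinom(length(total), as.vector(total),
                               as.vector(tile_beta)), nrow(total), ns)
  colnames(total) <- colnames(meth) <- colnames(probe_beta)

  cd <- S4Vectors::DataFrame(group = groups, row.names = colnames(probe_beta))
  probe_se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = probe_beta), rowRanges = plan$probes, colData = cd)
  tile_se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total), rowRanges = plan$tiles,
    colData = cd)
  list(probe_se = probe_se, tile_se = tile_se, truth = study_truth(plan))
}

#' Generate the regulatory genome
#'
#' Gene models, enhancer-gene links (with confidence scores spanning the
#' GeneHancer-style >= 5 cutoff), two jittered TAD sets, the categorized TF
#' binding-site catalog with planted enrichments, and the motif count
#' matrix.
#'
#' @param config A [study_config()].
#' @return List with `genes`, `enhancers`, `tads`, `catalog`, `pwm_counts`
#'   and `truth`.
#' @export
simulate_regulatory_genome <- function(config) {
  plan <- study_plan(config)
  list(genes = plan$genes, enhancers = plan$enhancers, tads = plan$tads,
       catalog = plan$catalog, pwm_counts = neurod_pwm_counts(),
       truth = study_truth(plan))
}

# E-box style consensus motif counts (width 8, 100 observations/position)
neurod_pwm_counts <- function() {
  consensus <- c("C", "A", "G", "C", "T", "G", "G", "C")
  counts <- matrix(4, 4, length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 88
  counts
}

#' Generate expression data
#'
#' Two expression matrices over the tumor groups: RNA-seq-like negative
#' binomial counts and array-like log2 intensities, with the planted DM-DE
#' genes shifted by the configured log2 fold change in AT/RT on both
#' platforms (independent noise).
#'
#' @param config A [study_config()].
#' @return List with `counts`, `log_intensity`, `groups` and `truth`.
#' @export
simulate_expression <- function(config) {
  plan <- study_plan(config)
  set.seed(config$seed + 3L)
  tumor_groups <- c("ATRT", "MB", "PLEX")
  groups <- rep(tumor_groups, each = config$n_expr)
  ng <- nrow(plan$genes)
  gene_names <- unique(plan$genes$gene)
  ng <- length(gene_names)

  base_log <- stats::rnorm(ng, 8, 1.5)
  shift <- matrix(0, ng, length(groups))
  if (!is.null(plan$dmde_genes)) {
    for (i in seq_len(nrow(plan$dmde_genes))) {
      g <- match(plan$dmde_genes$gene[i], gene_names)
      # planted DM-DE genes are expressed at quantifiable levels
      base_log[g] <- max(base_log[g], stats::rnorm(1, 9, 0.5))
      sgn <- if (plan$dmde_genes$dmde_up[i]) 1 else -1
      shift[g, groups == "ATRT"] <- sgn * config$lfc
    }
  }
  mu_log <- base_log + shift
  log_intensity <- mu_log + stats::rnorm(length(mu_log), 0, 0.4)
  dim(log_intensity) <- dim(mu_log)
  mu_counts <- 2^(mu_log - 3)
  counts <- matrix(stats::rnbinom(length(mu_counts), mu = as.vector(mu_counts),
                                  size = 10), ng, length(groups))
  rownames(counts) <- rownames(log_intensity) <- gene_names
  colnames(counts) <- colnames(log_intensity) <-
    paste0(groups, "_e", sequence(rep(config$n_expr, 3)))
  list(counts = counts, log_intensity = log_intensity, groups = groups,
       truth = study_truth(plan))
}

# consolidated truth tables from a plan
study_truth <- function(plan) {
  if (is.null(plan$planted))
    return(list(dmrs = NULL, tfs = NULL, largescale = NULL, dmde = NULL))
  p <- plan$planted
  cat_label <- function(category, direction) {
    hyper <- direction == "hyper"
    like <- c(psc_like = "PSC-like", fb_like = "FB-like",
              unique_unchanged = "unique", unique_dev = "unique")[category]
    dev <- ifelse(category == "unique_unchanged", "unchanged",
      ifelse(category == "psc_like",
             ifelse(hyper, "demethylated during differentiation",
                    "methylated during differentiation"),
      ifelse(category == "fb_like",
             ifelse(hyper, "methylated during differentiation",
                    "demethylated during differentiation"),
             ifelse(hyper, "demethylated during differentiation",
                    "methylated during differentiation"))))
    paste(like, dev, sep = ", ")
  }
  dmrs <- data.frame(p[, c("chrom", "start", "end", "n_tiles", "focal",
                           "direction", "category", "purpose",
                           "largescale_tad", "region_id")],
                     label = cat_label(p$category, p$direction))
  ls <- NULL
  if (any(p$purpose == "largescale")) {
    ls_tabs <- split(p[p$purpose == "largescale", ],
                     p$largescale_tad[p$purpose == "largescale"])
    ls <- do.call(rbind, lapply(ls_tabs, function(t.)
      data.frame(chrom = t.$chrom[1], start = min(t.$start),
                 end = max(t.$end), direction = t.$direction[1],
                 focal = t.$focal[1])))
  }
  tfs <- data.frame(tf = c("TF01", "TF02", "NEUROD1"),
                    target = "ATRT_hyper",
                    category = c("all", "PSC", "all"))
  list(dmrs = dmrs, tfs = tfs, largescale = ls, dmde = plan$dmde_genes)
}

#' Generate the full synthetic study
#'
#' One call producing methylomes, regulatory genome, expression and CUT&RUN
#' data plus the consolidated truth tables. All components are
#' deterministic functions of the configuration (including its seed).
#'
#' @param config A [study_config()].
#' @return List with elements `probe_se`, `tile_se`, `tads`, `genes`,
#'   `enhancers`, `catalog`, `pwm_counts`, `expression`, `cutrun`, `truth`,
#'   `config`.
#' @export
simulate_study <- function(config = study_config()) {
  meth <- simulate_methylomes(config)
  reg <- simulate_regulatory_genome(config)
  expr <- simulate_expression(config)
  cutrun <- simulate_cutrun(config, meth$truth)
  list(probe_se = meth$probe_se, tile_se = meth$tile_se, tads = reg$tads,
       genes = reg$genes, enhancers = reg$enhancers, catalog = reg$catalog,
       pwm_counts = reg$pwm_counts,
       expression = expr[c("counts", "log_intensity", "groups")],
       cutrun = cutrun, truth = meth$truth, config = config)
}

#' Generate CUT&RUN peak data
#'
#' Four simulated cell lines (one MB-like with many true binding events,
#' partly inside AT/RT-hyper planted regions; three AT/RT-like with few),
#' each with two replicates carrying jittered true peaks plus
#' replicate-specific noise, input-DNA control peaks, chrX decoys, and a
#' per-peak sequence with or without the planted motif. Ground truth
#' records each true peak's evidence class.
#'
#' @param config A [study_config()].
#' @param truth Truth tables from [simulate_methylomes()] (regenerated when
#'   missing).
#' @return List per cell line with `reps` (list of two `GRanges`),
#'   `control` (`GRanges`), plus shared `truth_peaks` table and a
#'   `sequences` generator: after [filter_peaks()], call
#'   `peak_sequences(peaks)` to obtain the FASTA-ready sequences.
#' @export
simulate_cutrun <- function(config, truth = NULL) {
  plan <- study_plan(config)
  set.seed(config$seed + 4L)
  cl <- config$chrom_lengths
  autosomes <- names(cl)[names(cl) %in% paste0("chr", 1:22)]
  p <- plan$planted
  pwm <- pwm_from_counts(neurod_pwm_counts())
  consensus <- "CAGCTGGC"

  rand_seq <- function(n, width, with_motif) {
    width <- rep_len(width, n)
    vapply(seq_len(n), function(i) {
      for (try in 1:50) {
        s <- paste(sample(c("A", "C", "G", "T"), width[i], replace = TRUE),
                   collapse = "")
        if (with_motif[i]) {
          at <- sample(width[i] - nchar(consensus), 1)
          substr(s, at, at + nchar(consensus) - 1) <- consensus
          return(s)
        }
        if (!scan_motif(s, pwm)) return(s) # reject accidental motif hits
      }
      s
    }, character(1))
  }

  neurod_sites <- plan$catalog[plan$catalog$tf == "NEUROD1"]
  make_line <- function(n_true, n_in_target, name) {
    width <- 300
    if (!is.null(p) && n_in_target > 0) {
      tgt <- p[p$direction == "hyper" & p$focal == "ATRT", ]
      pick <- sample(nrow(tgt), n_in_target, replace = n_in_target > nrow(tgt))
      s_in <- round((tgt$start[pick] + tgt$end[pick]) / 2) - width / 2
      ch_in <- tgt$chrom[pick]
    } else { s_in <- integer(0); ch_in <- character(0) }
    n_bg <- n_true - length(s_in)
    # half the background peaks sit on known NEUROD1 catalog sites so every
    # evidence class is represented; the rest are placed uniformly
    n_on_site <- floor(n_bg / 2)
    si <- sample(length(neurod_sites), n_on_site)
    ch_st <- as.character(GenomicRanges::seqnames(neurod_sites))[si]
    s_st <- GenomicRanges::start(neurod_sites)[si] - 75
    ch_rd <- sample(autosomes, n_bg - n_on_site, replace = TRUE)
    s_rd <- round(stats::runif(n_bg - n_on_site, 1000, cl[ch_rd] - 1000))
    ch <- c(ch_in, ch_st, ch_rd); s <- pmax(1, round(c(s_in, s_st, s_rd)))
    true <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + width - 1))
    # evidence classes derive from actual catalog overlap and the motif
    # assignment used when sequences are generated
    gtrd <- GenomicRanges::countOverlaps(true, neurod_sites,
                                         ignore.strand = TRUE) > 0
    want_motif <- stats::runif(n_true) < 0.65
    cls <- ifelse(gtrd & want_motif, "both",
                  ifelse(gtrd, "gtrd_only",
                         ifelse(want_motif, "motif_only", "none")))
    # replicates: jittered true peaks + private noise peaks
    jitter_peaks <- function() {
      j1 <- round(stats::runif(n_true, -50, 50))
      j2 <- round(stats::runif(n_true, -50, 50))
      GenomicRanges::GRanges(ch, IRanges::IRanges(pmax(1, s + j1),
                                                  s + width - 1 + j2))
    }
    noise <- function(n) {
      nch <- sample(c(autosomes, "chrX"), n, replace = TRUE,
                    prob = c(rep(0.23, 4), 0.08))
      nst <- vapply(nch, function(c.) round(stats::runif(1, 1000,
                                                         cl[[c.]] - 1000)), 0)
      GenomicRanges::GRanges(nch, IRanges::IRanges(nst, nst + width - 1))
    }
    reps <- suppressWarnings(
      list(sort_intervals(c(jitter_peaks(), noise(15))),
           sort_intervals(c(jitter_peaks(), noise(15)))))
    # control overlaps ~8% of true peaks, removing them downstream
    n_ctrl <- max(1, round(0.08 * n_true))
    ctrl_idx <- sample(n_true, n_ctrl)
    control <- suppressWarnings(
      c(GenomicRanges::GRanges(ch[ctrl_idx],
                               IRanges::IRanges(s[ctrl_idx],
                                                s[ctrl_idx] + 50)),
        noise(5)))
    list(sample = name, true = true, class = cls, reps = reps,
         control = sort_intervals(control))
  }

  lines <- list(make_line(60, 20, "MB1"), make_line(5, 0, "ATRT1"),
                make_line(3, 0, "ATRT2"), make_line(4, 0, "ATRT3"))
  names(lines) <- vapply(lines, `[[`, "", "sample")

  # sequence provider: motif planted iff the covering true peak's class
  # needs it; elsewhere motif-free
  peak_sequences <- function(peaks) {
    all_true <- suppressWarnings(do.call(c, unname(lapply(lines, `[[`,
                                                          "true"))))
    all_cls <- unlist(lapply(lines, `[[`, "class"))
    h <- GenomicRanges::findOverlaps(peaks, all_true, ignore.strand = TRUE)
    wants <- logical(length(peaks))
    i <- S4Vectors::queryHits(h)
    wants[i] <- all_cls[S4Vectors::subjectHits(h)] %in% c("both", "motif_only")
    seqs <- rand_seq(length(peaks), GenomicRanges::width(peaks), wants)
    names(seqs) <- paste0(as.character(GenomicRanges::seqnames(peaks)), ":",
                          GenomicRanges::start(peaks), "-",
                          GenomicRanges::end(peaks))
    seqs
  }

  truth_peaks <- do.call(rbind, lapply(lines, function(l)
    data.frame(sample = l$sample,
               chrom = as.character(GenomicRanges::seqnames(l$true)),
               start = GenomicRanges::start(l$true),
               end = GenomicRanges::end(l$true), class = l$class,
               row.names = NULL)))

  list(lines = lines, peak_sequences = peak_sequences,
       truth_peaks = truth_peaks, pwm_counts = neurod_pwm_counts())
}
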