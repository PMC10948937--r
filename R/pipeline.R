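# End-to-end pipeline over a synthetic study: DMR calling on both
# platforms, control filtering, cancer-specific extraction, clustering, TF
# enrichment with cross-platform validation, TAD-scale shifts,
# developmental categorization, DM-DE integration and CUT&RUN filtering,
# plus recovery evaluation against the planted truth.

#' Region-by-sample methylation matrix
#'
#' Mean beta of the probes hitting (>= 1 bp) each region, per sample.
#'
#' @param probe_se `RangedSummarizedExperiment` with a `beta` assay.
#' @param regions `GRanges`.
#' @return Numeric matrix, regions x samples (NA where no probe hits).
#' @export
region_methylation_matrix <- function(probe_se, regions) {
  beta <- SummarizedExperiment::assay(probe_se, "beta")
  probes <- SummarizedExperiment::rowRanges(probe_se)
  h <- GenomicRanges::findOverlaps(regions, probes, ignore.strand = TRUE)
  out <- matrix(NA_real_, length(regions), ncol(beta),
                dimnames = list(NULL, colnames(beta)))
  if (length(h)) {
    ri <- S4Vectors::queryHits(h)
    sums <- rowsum(beta[S4Vectors::subjectHits(h), , drop = FALSE], ri)
    out[as.integer(rownames(sums)), ] <- sums / as.vector(table(ri))
  }
  out
}

#' Run the full pipeline on a synthetic study
#'
#' Executes every stage in order on the outputs of [simulate_study()]:
#' tile and probe DMR calling for all tumor-pair comparisons (probe DMRs
#' filtered by the tumor-vs-control comparisons), cancer-specific region
#' extraction, direction tabulation, DMR pooling with k-means/AIC
#' clustering, TF enrichment (plain, categorized, clusterwise,
#' co-localization) with cross-platform validation, large-scale TAD
#' detection, developmental categorization against PSC/FB, DM-DE
#' integration, and CUT&RUN peak filtering.
#'
#' @param study Output of [simulate_study()].
#' @param k_range Candidate k for DMR clustering (default 1:10, sized to
#'   the synthetic DMR pool).
#' @return A list of per-stage results.
#' @export
run_study <- function(study, k_range = 1:10) {
  cfg <- study$config
  tumors <- c("ATRT", "MB", "PLEX")
  pairs <- list(c("ATRT", "MB"), c("ATRT", "PLEX"), c("MB", "ATRT"),
                c("MB", "PLEX"), c("PLEX", "ATRT"), c("PLEX", "MB"))
  pname <- vapply(pairs, paste, "", collapse = "_vs_")

  tile_dmrs <- lapply(pairs, function(p) call_dmrs_tiles(study$tile_se, p))
  names(tile_dmrs) <- pname
  probe_dmrs <- lapply(pairs, function(p) call_dmrs_probes(study$probe_se, p))
  names(probe_dmrs) <- pname
  control_dmrs <- lapply(tumors, function(g)
    call_dmrs_probes(study$probe_se, c(g, "CONTR")))
  names(control_dmrs) <- tumors
  probe_filtered <- lapply(pname, function(nm) {
    gs <- strsplit(nm, "_vs_")[[1]]
    filter_by_controls(probe_dmrs[[nm]], control_dmrs[gs])
  })
  names(probe_filtered) <- pname

  specific <- lapply(tumors, function(cn) {
    others <- setdiff(tumors, cn)
    list(
      array = extract_cancer_specific(
        probe_dmrs[[paste0(cn, "_vs_", others[1])]],
        probe_dmrs[[paste0(cn, "_vs_", others[2])]]),
      tiles = extract_cancer_specific(
        tile_dmrs[[paste0(cn, "_vs_", others[1])]],
        tile_dmrs[[paste0(cn, "_vs_", others[2])]]))
  })
  names(specific) <- tumors
  fourfield <- count_direction_fourfield(specific)

  # pooled array DMRs (control-filtered, all main comparisons) -> k-means
  pooled <- merge_intervals(do.call(c, unname(lapply(
    probe_filtered[c("ATRT_vs_MB", "ATRT_vs_PLEX", "MB_vs_PLEX")],
    function(d) GenomicRanges::granges(d$regions)))), 0)
  clustering <- NULL
  if (length(pooled) >= max(k_range)) {
    pm <- region_methylation_matrix(study$probe_se, pooled)
    clustering <- kmeans_with_aic(pm, k_range = k_range, seed = cfg$seed)
  }

  # TF enrichment over both platforms -----------------------------------
  probes <- SummarizedExperiment::rowRanges(study$probe_se)
  bg_array <- extend_intervals(probes[is_canonical(probes)], 500)
  tiles <- SummarizedExperiment::rowRanges(study$tile_se)
  bg_tiles <- tiles[is_canonical(tiles)]
  enr <- function(bg, regions) {
    target <- subset_by_overlap(bg, regions)
    if (!length(target) || !length(regions)) return(NULL)
    suppressWarnings(enrich_tf_sets(target, bg, study$catalog))
  }
  classes <- list()
  for (cn in tumors) for (dir in c("hyper", "hypo"))
    classes[[paste0(cn, "_", dir)]] <- dir
  enrich_array <- lapply(names(classes), function(k) {
    cn <- sub("_(hyper|hypo)$", "", k); dir <- sub("^.*_", "", k)
    enr(bg_array, specific[[cn]]$array[[dir]])
  })
  names(enrich_array) <- names(classes)
  enrich_tiles <- lapply(names(classes), function(k) {
    cn <- sub("_(hyper|hypo)$", "", k); dir <- sub("^.*_", "", k)
    enr(bg_tiles, specific[[cn]]$tiles[[dir]])
  })
  names(enrich_tiles) <- names(classes)
  keep_cls <- !vapply(enrich_array, is.null, TRUE) &
    !vapply(enrich_tiles, is.null, TRUE)
  validated <- validate_across_platforms(enrich_array[keep_cls],
                                         enrich_tiles[keep_cls])
  categorized <- if (length(specific$ATRT$array$hyper)) {
    target <- subset_by_overlap(bg_array, specific$ATRT$array$hyper)
    categorized_enrichment(target, bg_array, study$catalog)
  }

  # large-scale TADs (AT/RT vs MB) ---------------------------------------
  units_arr <- extend_intervals(probe_dmrs$ATRT_vs_MB$units, 500)
  units_til <- tile_dmrs$ATRT_vs_MB$units
  largescale <- detect_largescale_tads(units_arr, units_til, study$tads,
                                       comparison = "ATRT_vs_MB")

  # developmental categorization (focal AT/RT) ---------------------------
  atrt_spec <- suppressWarnings(c(specific$ATRT$array$hyper,
                                  specific$ATRT$array$hypo))
  develop <- NULL
  if (length(atrt_spec)) {
    refs <- call_reference_dmrs(study$probe_se, tumors)
    dm <- build_developmental_matrix(atrt_spec, refs)
    fl <- developmental_flags(dm$flags, "ATRT")
    develop <- list(atoms = dm$atoms, flags = dm$flags,
                    category = categorize_regions(fl), refs = refs)
    develop$largescale_fraction <- largescale_fraction_by_category(
      dm$atoms, develop$category, largescale)
  }

  # DM-DE integration (AT/RT vs MB) --------------------------------------
  de_array <- call_de_genes(study$expression$log_intensity,
                            study$expression$groups, c("ATRT", "MB"), "array")
  de_seq <- call_de_genes(study$expression$counts, study$expression$groups,
                          c("ATRT", "MB"), "seq")
  link <- function(dset) {
    regs <- dset$regions
    do.call(rbind, lapply(c("promoter", "enhancer", "neighborhood"),
                          function(m) link_dmrs_to_genes(
                            regs, study$genes, study$enhancers, m)))
  }
  pa <- link(probe_dmrs$ATRT_vs_MB); pt <- link(tile_dmrs$ATRT_vs_MB)
  validated_pairs <- cross_platform_validate(pa, pt)
  nbh <- validated_pairs[validated_pairs$mode == "neighborhood", , drop = FALSE]
  # "any_pair": a gene keeps its neighborhood link when at least one of its
  # TSS-DMR spans is boundary-free in every TAD set; with 200-kb
  # neighborhoods and 150-300-kb TADs the literal all-pairs rule would
  # discard nearly every gene once unrelated distal DMRs enter the pair set
  tadflt <- tad_boundary_filter(nbh, study$tads, mode = "any_pair")
  nbh_kept <- tadflt$pairs[tadflt$pairs$n_boundaries == 0 &
                             tadflt$pairs$gene %in% tadflt$genes, , drop = FALSE]
  nbh_kept$n_boundaries <- NULL
  kept_pairs <- rbind(
    validated_pairs[validated_pairs$mode != "neighborhood", , drop = FALSE],
    nbh_kept)
  dmde <- classify_dm_de(kept_pairs, de_array, de_seq)
  kept_pairs_out <- kept_pairs

  # CUT&RUN ---------------------------------------------------------------
  pwm <- pwm_from_counts(study$pwm_counts)
  neurod_sites <- study$catalog[study$catalog$tf == "NEUROD1"]
  dmr_classes <- list()
  for (cn in tumors) for (dir in c("hyper", "hypo"))
    dmr_classes[[paste0(cn, "_", dir)]] <- specific[[cn]]$tiles[[dir]]
  cutrun <- lapply(study$cutrun$lines, function(line) {
    peaks <- filter_peaks(line$reps, line$control)
    seqs <- study$cutrun$peak_sequences(peaks)
    hits <- scan_motif(seqs, pwm)
    retained <- retain_by_evidence(peaks, neurod_sites, hits)
    list(sample = line$sample, peaks = peaks, retained = retained,
         class_counts = table(retained$class),
         dmr_counts = peaks_vs_dmr_classes(retained, dmr_classes))
  })
  highmeth <- peak_high_methylation_fraction(
    cutrun$MB1$retained, study$tile_se, "ATRT")

  list(tile_dmrs = tile_dmrs, probe_dmrs = probe_dmrs,
       control_dmrs = control_dmrs, probe_filtered = probe_filtered,
       specific = specific, fourfield = fourfield, clustering = clustering,
       enrich_array = enrich_array, enrich_tiles = enrich_tiles,
       validated_tfs = validated, categorized = categorized,
       largescale = largescale, develop = develop,
       de = list(array = de_array, seq = de_seq),
       validated_pairs = validated_pairs, tad_filter = tadflt,
       kept_pairs = kept_pairs_out, dmde = dmde,
       cutrun = cutrun, highmeth = highmeth)
}

#' Truth intervals for one comparison
#'
#' Planted regions visible in an ordered two-group comparison, with the
#' direction they should show (a region planted hyper in its focal group
#' appears hypo when the focal group is second).
#'
#' @param truth Truth tables from [simulate_study()].
#' @param comparison Ordered group pair.
#' @return `GRanges` with a `direction` column, or empty when nothing
#'   planted.
#' @keywords internal
truth_regions_for <- function(truth, comparison) {
  d <- truth$dmrs
  if (is.null(d)) return(GenomicRanges::GRanges())
  d <- d[d$focal %in% comparison, , drop = FALSE]
  if (!nrow(d)) return(GenomicRanges::GRanges())
  flip <- d$focal == comparison[2]
  dir <- ifelse(flip, ifelse(d$direction == "hyper", "hypo", "hyper"),
                d$direction)
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end - 1),
                         direction = dir, focal = d$focal,
                         region_id = d$region_id)
}

#' Evaluate pipeline results against the planted truth
#'
#' Computes the headline recovery metrics: tile-DMR sensitivity and
#' empirical FDR (against the planted tiles of the AT/RT-vs-MB comparison),
#' planted-region recovery on the array platform, the planted TF's rank and
#' adjusted p on both platforms and its survival of cross-platform
#' validation, exact large-scale TAD recovery, developmental category
#' agreement, and DM-DE recovery (with the parallel-mislabel count and the
#' boundary-gene check).
#'
#' @param study Output of [simulate_study()].
#' @param results Output of [run_study()].
#' @return Named list of metrics.
#' @export
evaluate_recovery <- function(study, results) {
  truth <- study$truth
  out <- list()

  # tile-level sensitivity/FDR on AT/RT vs MB
  tr <- truth_regions_for(truth, c("ATRT", "MB"))
  called <- results$tile_dmrs$ATRT_vs_MB$regions
  if (length(tr)) {
    tiles <- SummarizedExperiment::rowRanges(study$tile_se)
    true_tiles <- subset_by_overlap(tiles, tr)
    # tiles fully inside a truth region, with expected direction
    h <- GenomicRanges::findOverlaps(tiles, tr, type = "within",
                                     ignore.strand = TRUE)
    ti <- S4Vectors::queryHits(h)
    texp <- tiles[ti]
    S4Vectors::mcols(texp)$direction <- tr$direction[S4Vectors::subjectHits(h)]
    key <- function(g) {
      if (length(g) == 0) return(character(0))
      paste0(as.character(GenomicRanges::seqnames(g)), ":",
             GenomicRanges::start(g), "_", S4Vectors::mcols(g)$direction)
    }
    found <- key(texp) %in% key(called)
    out$tile_sensitivity <- mean(found)
    out$tile_fdr <- if (length(called))
      mean(!(key(called) %in% key(texp))) else 0
    out$n_tile_truth <- length(texp)

    # array: fraction of planted regions overlapped by a same-direction DMR
    arr <- results$probe_dmrs$ATRT_vs_MB$regions
    rec <- vapply(seq_along(tr), function(i) {
      any(overlap_width(rep(tr[i], length(arr)), arr) > 0 &
            arr$direction == tr$direction[i])
    }, TRUE)
    out$array_region_recall <- mean(rec)
  }

  # planted TF: rank among the TFs that are not themselves planted in the
  # same class (the category-planted TF and the CUT&RUN TF carry their own,
  # stronger, planted signals)
  other_planted <- setdiff(truth$tfs$tf, "TF01")
  for (pl in c("array", "tiles")) {
    res <- results[[paste0("enrich_", pl)]]$ATRT_hyper
    if (!is.null(res)) {
      res <- res[!(res$tf %in% other_planted), , drop = FALSE]
      o <- order(res$p)
      out[[paste0("tf_rank_", pl)]] <- match("TF01", res$tf[o])
      out[[paste0("tf_adjp_", pl)]] <- res$adj_p[res$tf == "TF01"]
    }
  }
  out$tf_validated <- "TF01" %in% results$validated_tfs$ATRT_hyper

  # large-scale TADs: every truth TAD recovered with matching direction,
  # and no flagged TAD without a truth signal
  ls <- results$largescale
  tl <- truth$largescale
  if (!is.null(tl)) {
    tg <- GenomicRanges::GRanges(tl$chrom, IRanges::IRanges(tl$start, tl$end))
    hit <- GenomicRanges::countOverlaps(tg, ls, ignore.strand = TRUE) > 0
    out$largescale_recovered <- sum(hit)
    out$largescale_expected <- nrow(tl)
    out$largescale_spurious <- sum(
      GenomicRanges::countOverlaps(ls, tg, ignore.strand = TRUE) == 0)
  }

  # developmental categories: majority atom label per planted AT/RT region
  if (!is.null(results$develop)) {
    d <- truth$dmrs[truth$dmrs$focal == "ATRT", , drop = FALSE]
    tg <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end - 1))
    lab <- results$develop$category
    atoms <- results$develop$atoms
    got <- vapply(seq_along(tg), function(i) {
      h <- GenomicRanges::findOverlaps(tg[i], atoms, ignore.strand = TRUE)
      if (!length(h)) return(NA_character_)
      ll <- lab[S4Vectors::subjectHits(h)]
      names(sort(table(ll), decreasing = TRUE))[1]
    }, "")
    ok <- !is.na(got) & got == d$label
    out$category_agreement <- mean(ok)
    out$n_category_regions <- nrow(d)
  }

  # DM-DE
  td <- truth$dmde
  if (!is.null(td)) {
    opp <- td[td$dmde_relation == "opposite" & !td$dmde_cross, ]
    par <- td[td$dmde_relation == "parallel", ]
    cross <- td[td$dmde_cross, ]
    got_opp <- results$dmde$gene[results$dmde$relation == "opposite"]
    out$dmde_recall <- mean(opp$gene %in% got_opp)
    out$dmde_parallel_mislabeled <- sum(par$gene %in% got_opp)
    # the boundary-crossing planted pairs themselves must not survive the
    # TAD filter (the genes may still carry unrelated boundary-free DMRs)
    kp <- results$kept_pairs
    planted_pair_kept <- vapply(seq_len(nrow(cross)), function(i)
      any(kp$gene == cross$gene[i] & kp$start < cross$end[i] &
            kp$end >= cross$start[i] & kp$chrom == cross$chrom[i]), TRUE)
    out$dmde_boundary_excluded <- sum(!planted_pair_kept)
    out$n_dmde_boundary <- nrow(cross)
    out$n_dmde_truth <- nrow(opp)
  }

  # CUT&RUN class counts vs truth on the surviving peaks
  tp <- study$cutrun$truth_peaks
  mb <- results$cutrun$MB1
  if (!is.null(mb)) {
    tpg <- GenomicRanges::GRanges(tp$chrom, IRanges::IRanges(tp$start, tp$end))
    keep <- tp$sample == "MB1" & tp$class != "none" &
      GenomicRanges::countOverlaps(tpg, mb$peaks, ignore.strand = TRUE) > 0
    out$cutrun_expected_retained <- sum(keep)
    out$cutrun_retained <- length(mb$retained)
  }
  out
}
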