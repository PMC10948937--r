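# Situating cancer-specific DMRs relative to pluripotent stem cell (PSC)
# and fetal brain (FB) methylomes: reference DMR calling, the developmental
# membership matrix, and the category truth table.
#
# Direction is always with respect to the FIRST group of a comparison, so a
# "hyper" PSC-vs-FB DMR means PSC more methylated than FB, i.e. the site
# loses methylation during differentiation from PSC to FB ("demethylated
# during differentiation").

#' Call reference DMRs against PSC and FB methylomes
#'
#' Runs the probe-level DMR caller for the seven reference comparisons
#' (each tumor vs PSC, each tumor vs FB, and PSC vs FB) and filters the
#' resulting regions to lengths between `min_len` and `max_len` bp
#' (inclusive).
#'
#' @param probe_se `RangedSummarizedExperiment` with a `beta` assay and a
#'   `group` column covering the tumor groups plus `psc_group`/`fb_group`.
#' @param tumor_groups Character vector of tumor group names.
#' @param psc_group,fb_group Names of the PSC and FB groups.
#' @param max_q FDR threshold (default 0.05).
#' @param min_delta Region |delta beta| threshold (default 0.25).
#' @param min_len,max_len Inclusive region length bounds in bp
#'   (defaults 100 and 5000).
#' @param ... Passed to [call_dmrs_probes()].
#' @return Named list of seven `DMRSet`s
#'   (`"<tumor>_vs_PSC"`, `"<tumor>_vs_FB"`, `"PSC_vs_FB"`).
#' @export
call_reference_dmrs <- function(probe_se, tumor_groups, psc_group = "PSC",
                                fb_group = "FB", max_q = 0.05,
                                min_delta = 0.25, min_len = 100,
                                max_len = 5000, ...) {
  comparisons <- c(
    lapply(tumor_groups, function(g) c(g, psc_group)),
    lapply(tumor_groups, function(g) c(g, fb_group)),
    list(c(psc_group, fb_group)))
  names(comparisons) <- c(paste0(tumor_groups, "_vs_PSC"),
                          paste0(tumor_groups, "_vs_FB"), "PSC_vs_FB")
  lapply(comparisons, function(cmp) {
    d <- call_dmrs_probes(probe_se, cmp, final_delta = min_delta,
                          max_fdr = max_q, ...)
    keep <- which(GenomicRanges::width(d$regions) >= min_len &
                    GenomicRanges::width(d$regions) <= max_len)
    ku <- which(d$units$region %in% keep)
    units <- d$units[ku]
    S4Vectors::mcols(units)$region <- match(S4Vectors::mcols(units)$region, keep)
    dmr_set(d$regions[keep], units, d$platform, d$comparison)
  })
}

#' Build the developmental DMR membership matrix
#'
#' Splits the footprint of the cancer-specific regions into non-overlapping
#' atoms and records, for each atom and each reference comparison, whether
#' the atom overlaps (>= 1 bp) a reference DMR and in which direction
#' (`"none"`, `"hyper"`, `"hypo"`, or `"both"` when DMRs of both directions
#' overlap).
#'
#' @param cancer_specific `GRanges` of cancer-specific regions with a
#'   `direction` metadata column (the focal direction).
#' @param reference_dmrs Named list of `DMRSet`s from
#'   [call_reference_dmrs()].
#' @return List with `atoms` (`GRanges`) and `flags` (`data.frame`, one
#'   column per reference comparison plus `focal_direction`).
#' @export
build_developmental_matrix <- function(cancer_specific, reference_dmrs) {
  atoms <- GenomicRanges::disjoin(cancer_specific, ignore.strand = TRUE)
  src <- GenomicRanges::findOverlaps(atoms, cancer_specific,
                                     ignore.strand = TRUE)
  first <- src[!duplicated(S4Vectors::queryHits(src))]
  focal <- rep(NA_character_, length(atoms))
  focal[S4Vectors::queryHits(first)] <-
    as.character(cancer_specific$direction[S4Vectors::subjectHits(first)])

  flag_one <- function(dset) {
    out <- rep("none", length(atoms))
    for (dir in c("hyper", "hypo")) {
      regs <- dset$regions[dset$regions$direction == dir]
      hit <- GenomicRanges::countOverlaps(atoms, regs,
                                          ignore.strand = TRUE) > 0
      out[hit] <- ifelse(out[hit] == "none", dir,
                         ifelse(out[hit] == dir, dir, "both"))
    }
    out
  }
  flags <- as.data.frame(lapply(reference_dmrs, flag_one),
                         stringsAsFactors = FALSE, optional = TRUE)
  names(flags) <- names(reference_dmrs)
  flags$focal_direction <- focal
  list(atoms = atoms, flags = flags)
}

#' Extract the focal-tumor flag triple from a membership matrix
#'
#' Convenience accessor pulling the three flags that drive categorization
#' (focal tumor vs PSC, focal tumor vs FB, PSC vs FB) out of the full
#' membership table of [build_developmental_matrix()].
#'
#' @param flags The `flags` table from [build_developmental_matrix()].
#' @param focal_tumor Name of the focal tumor group.
#' @return `data.frame` with columns `psc`, `fb`, `dev`, `focal_direction`,
#'   ready for [categorize_regions()].
#' @export
developmental_flags <- function(flags, focal_tumor) {
  data.frame(psc = flags[[paste0(focal_tumor, "_vs_PSC")]],
             fb = flags[[paste0(focal_tumor, "_vs_FB")]],
             dev = flags[["PSC_vs_FB"]],
             focal_direction = flags$focal_direction,
             stringsAsFactors = FALSE)
}

#' Categorize regions against the developmental references
#'
#' Assigns each region a composite developmental category from its focal
#' direction `d` and the membership flags of its tumor-vs-PSC,
#' tumor-vs-FB and PSC-vs-FB comparisons. The likeness component is:
#'
#' * `PSC-like`: no tumor-vs-PSC DMR and a tumor-vs-FB DMR in direction `d`
#'   (the tumor resembles PSC and differs from FB);
#' * `FB-like`: no tumor-vs-FB DMR and a tumor-vs-PSC DMR in direction `d`;
#' * `unique`: tumor-vs-PSC and tumor-vs-FB DMRs both in direction `d`
#'   (the tumor differs from both references), and also the zero-evidence
#'   case with neither overlap (no reference distinguishes the region);
#' * `ambiguous`: any comparison flagged in both directions, or any
#'   reference overlap in the direction opposite to `d`.
#'
#' The differentiation component comes from the PSC-vs-FB flag:
#' `unchanged` (no DMR), `demethylated during differentiation` (PSC-vs-FB
#' hyper: methylation lost from PSC to FB), `methylated during
#' differentiation` (PSC-vs-FB hypo). The mapping is total and
#' deterministic over all flag combinations.
#'
#' @param flags `data.frame` with columns `psc` (tumor-vs-PSC flag), `fb`
#'   (tumor-vs-FB flag), `dev` (PSC-vs-FB flag), each in
#'   \{"none","hyper","hypo","both"\}, and `focal_direction` in
#'   \{"hyper","hypo"\}.
#' @return Character vector `"<likeness>, <differentiation>"`.
#' @export
categorize_regions <- function(flags) {
  stopifnot(all(c("psc", "fb", "dev", "focal_direction") %in% names(flags)))
  d <- flags$focal_direction
  opp <- ifelse(d == "hyper", "hypo", "hyper")
  like <- rep("ambiguous", nrow(flags))
  ok <- !(flags$psc == "both" | flags$fb == "both" |
            flags$psc == opp | flags$fb == opp)
  like[ok & flags$psc == "none" & flags$fb == d] <- "PSC-like"
  like[ok & flags$fb == "none" & flags$psc == d] <- "FB-like"
  like[ok & flags$psc == d & flags$fb == d] <- "unique"
  like[ok & flags$psc == "none" & flags$fb == "none"] <- "unique"
  diffn <- c(none = "unchanged",
             hyper = "demethylated during differentiation",
             hypo = "methylated during differentiation",
             both = "ambiguous differentiation")[flags$dev]
  paste(like, diffn, sep = ", ")
}
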