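# Plain-text serialization of a synthetic study: TSV matrices, BED region
# files, JASPAR PFM, JSON truth tables and a YAML config echo.

#' Write a synthetic study to a directory
#'
#' Emits the generated study as plain-text files: probe beta matrix and
#' tile count matrix TSVs (unit coordinates + one column per sample), TF
#' binding-site BED (name = TF, extra column = category), TAD BEDs per
#' set, gene model and enhancer TSVs, JASPAR-format motif counts,
#' expression matrices, CUT&RUN peak BEDs, JSON truth tables and the YAML
#' configuration.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  coords <- function(gr) data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr))
  tsv <- function(df, name) utils::write.table(
    df, fp(name), sep = "\t", quote = FALSE, row.names = FALSE)

  probes <- SummarizedExperiment::rowRanges(study$probe_se)
  tsv(cbind(coords(probes),
            round(SummarizedExperiment::assay(study$probe_se, "beta"), 4)),
      "probe_beta.tsv")
  tiles <- SummarizedExperiment::rowRanges(study$tile_se)
  meth <- SummarizedExperiment::assay(study$tile_se, "meth")
  total <- SummarizedExperiment::assay(study$tile_se, "total")
  colnames(meth) <- paste0(colnames(meth), ".meth")
  colnames(total) <- paste0(colnames(total), ".total")
  tsv(cbind(coords(tiles), meth, total), "tile_counts.tsv")

  cat_bed <- study$catalog
  S4Vectors::mcols(cat_bed)$name <- cat_bed$tf
  write_bed(cat_bed, fp("tf_sites.bed"), extra_cols = "category")
  for (nm in names(study$tads))
    write_bed(study$tads[[nm]], fp(paste0("tads_", nm, ".bed")))
  tsv(study$genes, "genes.tsv")
  tsv(study$enhancers, "enhancers.tsv")
  write_jaspar_pfm(study$pwm_counts, "SYNTH.NEUROD1", fp("motif.pfm"))
  tsv(cbind(gene = rownames(study$expression$counts),
            as.data.frame(study$expression$counts)), "expr_counts.tsv")
  tsv(cbind(gene = rownames(study$expression$log_intensity),
            as.data.frame(study$expression$log_intensity)),
      "expr_log_intensity.tsv")
  for (line in study$cutrun$lines) {
    for (i in seq_along(line$reps))
      write_bed(line$reps[[i]], fp(sprintf("peaks_%s_rep%d.bed",
                                           line$sample, i)))
    write_bed(line$control, fp(sprintf("peaks_%s_control.bed", line$sample)))
  }
  truth <- study$truth
  truth$cutrun_peaks <- study$cutrun$truth_peaks
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- unclass(study$config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  cfg$n_samples <- as.list(cfg$n_samples)
  cfg$n_dmrs <- as.list(cfg$n_dmrs)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a beta or count matrix TSV back into a SummarizedExperiment
#'
#' Counterpart of the [write_study()] matrix format: chrom/start/end
#' coordinate columns (BED-style half-open) followed by sample columns
#' (plain for beta; `.meth`/`.total` suffix pairs for counts).
#'
#' @param path TSV path.
#' @param groups Optional group label per sample (recycled from sample
#'   names' prefixes when missing: `GROUP_i`).
#' @return `RangedSummarizedExperiment` with a `beta` assay, or `meth` and
#'   `total` assays for count input.
#' @export
read_methylation_tsv <- function(path, groups = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  rest <- df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]
  is_counts <- any(grepl("\\.meth$", names(rest)))
  if (is_counts) {
    meth <- as.matrix(rest[, grepl("\\.meth$", names(rest)), drop = FALSE])
    total <- as.matrix(rest[, grepl("\\.total$", names(rest)), drop = FALSE])
    samples <- sub("\\.meth$", "", colnames(meth))
    colnames(meth) <- colnames(total) <- samples
    assays <- list(meth = meth, total = total)
  } else {
    beta <- as.matrix(rest)
    samples <- colnames(beta)
    assays <- list(beta = beta)
  }
  if (is.null(groups)) groups <- sub("_[^_]*$", "", samples)
  SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = gr,
    colData = S4Vectors::DataFrame(group = groups, row.names = samples))
}
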