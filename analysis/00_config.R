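# Shared settings for the analysis scripts: one study configuration, one
# seed, one output root. Every numbered script sources this file and can be
# run on its own (the generator is deterministic, so all scripts see the
# same study).
library(dmrscape)

STUDY_SEED <- 1
OUT <- "results"
dir.create(OUT, showWarnings = FALSE)

study_cfg <- study_config(seed = STUDY_SEED)

write_tsv <- function(df, name) {
  path <- file.path(OUT, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}

gr_df <- function(g) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                   start = GenomicRanges::start(g) - 1L,
                   end = GenomicRanges::end(g))
  cbind(df, as.data.frame(S4Vectors::mcols(g)))
}
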