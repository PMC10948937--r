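# Generate the synthetic two-platform brain-tumor methylation study and
# write it (with its ground-truth tables) to scratch/study/. The data
# files run to tens of MB, so they go to scratch; every later script
# regenerates the study in memory from the same seed instead of reading
# them back.
source("analysis/00_config.R")

study <- simulate_study(study_cfg)
write_study(study, file.path("scratch", "study"))

truth <- study$truth$dmrs
message(sprintf("study: %d tiles, %d probes, %d samples",
                length(SummarizedExperiment::rowRanges(study$tile_se)),
                length(SummarizedExperiment::rowRanges(study$probe_se)),
                ncol(SummarizedExperiment::assay(study$probe_se, "beta"))))
message(sprintf("planted: %d DMR regions (%d AT/RT, %d MB, %d PLEX), %d DM-DE genes",
                nrow(truth), sum(truth$focal == "ATRT"),
                sum(truth$focal == "MB"), sum(truth$focal == "PLEX"),
                nrow(study$truth$dmde)))
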