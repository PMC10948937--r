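# Detect TADs carrying large-scale (concordant, multi-unit, > 50 kb)
# methylation shifts in the AT/RT-vs-MB comparison and compare with the
# planted truth.
source("analysis/00_config.R")

study <- simulate_study(study_cfg)
res <- suppressWarnings(run_study(study))

write_tsv(gr_df(res$largescale), "largescale_tads_ATRT_vs_MB.tsv")
ev <- evaluate_recovery(study, res)
message(sprintf("large-scale TADs: %d flagged; %d/%d planted recovered, %d spurious",
                length(res$largescale), ev$largescale_recovered,
                ev$largescale_expected, ev$largescale_spurious))

if (!is.null(res$develop))
  write_tsv(res$develop$largescale_fraction, "largescale_fraction_by_category.tsv")
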